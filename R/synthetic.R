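#' Configuration for the synthetic three-species system
#'
#' Defines the study conditions the generator emulates: a reference genome
#' (human-like), two descendant out-group genomes (chimp-like, macaque-like)
#' produced by substitutions and indels, CpG islands, gene models, repeats,
#' a blacklist, planted methylation truth and MeDIP-like fragment
#' simulation. All randomness flows from one master seed through named
#' substreams, so a fixed seed reproduces every output byte-identically.
#'
#' Default scale is two 1-Mb chromosomes with 120 planted regions at 30x
#' nominal coverage; per-branch substitution rates reflect the roughly 1.2%
#' human-chimp and 6% human-macaque genomic divergence, indel lengths are
#' geometric with mean 3 bp, and the MeDIP enrichment weight is
#' \code{1 + enrichment_factor * (methylated CpG count per fragment)}.
#'
#' @param chrom_lengths named vector of reference chromosome lengths.
#' @param islands list: \code{count}, \code{length_range}, \code{cpg_prob}
#'   (per-dinucleotide CpG probability inside islands).
#' @param genes list: \code{count}, \code{exon_count_range},
#'   \code{exon_length_range}, \code{intron_length_range}.
#' @param repeats list: \code{count}, \code{length_range},
#'   \code{subfamilies}.
#' @param blacklist list: \code{count}, \code{length_range}.
#' @param sdmrs planted-region spec: counts per class (\code{n_hypo},
#'   \code{n_hyper}, \code{n_chimp_only}, \code{n_shared},
#'   \code{n_background}), \code{length_range}, methylation
#'   \code{level_high} / \code{level_low}.
#' @param branch per-branch edit rates: each of \code{chimp},
#'   \code{macaque} has \code{sub_rate}, \code{indel_rate},
#'   \code{indel_mean} (geometric mean length).
#' @param medip fragment simulation: \code{coverage}, \code{fraglen_mean},
#'   \code{fraglen_sd}, \code{enrichment_factor}, \code{dup_frac},
#'   \code{lowq_frac}, \code{improper_frac}, \code{depth_scale} (named
#'   per-species multipliers so library totals differ).
#' @param baseline_methylation genome-wide background methylation level.
#' @param plant_motif plant one reference-specific motif-creating site
#'   (single-base edits on both branches) inside a hypomethylated island,
#'   plus a linked gene-body hypermethylated region, emulating a
#'   promoter/gene-body divergence locus.
#' @param seed master seed (integer).
#' @return list of class \code{trio_config}.
#' @export
trio_config <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                        islands = list(count = 40,
                                       length_range = c(700, 1500),
                                       cpg_prob = 0.2),
                        genes = list(count = 24,
                                     exon_count_range = c(2, 5),
                                     exon_length_range = c(200, 600),
                                     intron_length_range = c(500, 2000)),
                        repeats = list(count = 80,
                                       length_range = c(150, 400),
                                       subfamilies = c("AluJ", "AluS",
                                                       "AluY", "L1", "MIR")),
                        blacklist = list(count = 4,
                                         length_range = c(2000, 5000)),
                        sdmrs = list(n_hypo = 30, n_hyper = 30,
                                     n_chimp_only = 20, n_shared = 30,
                                     n_background = 10,
                                     length_range = c(600, 1200),
                                     level_high = 0.85, level_low = 0),
                        branch = list(
                          chimp = list(sub_rate = 0.012,
                                       indel_rate = 0.0015, indel_mean = 3),
                          macaque = list(sub_rate = 0.055,
                                         indel_rate = 0.004,
                                         indel_mean = 3)),
                        medip = list(coverage = 30, fraglen_mean = 200,
                                     fraglen_sd = 30,
                                     enrichment_factor = 1,
                                     dup_frac = 0.03, lowq_frac = 0.02,
                                     improper_frac = 0.02,
                                     depth_scale = c(human = 1,
                                                     chimp = 0.85,
                                                     macaque = 1.15)),
                        baseline_methylation = 0.05,
                        plant_motif = TRUE,
                        seed = 1L) {
  stopifnot(all(chrom_lengths > 0),
            sdmrs$level_high > sdmrs$level_low,
            sdmrs$level_low >= 0, sdmrs$level_high <= 1,
            all(vapply(branch, function(b) b$sub_rate >= 0 &&
                         b$indel_rate >= 0, TRUE)))
  structure(list(chrom_lengths = chrom_lengths, islands = islands,
                 genes = genes, repeats = repeats, blacklist = blacklist,
                 sdmrs = sdmrs, branch = branch, medip = medip,
                 baseline_methylation = baseline_methylation,
                 plant_motif = plant_motif, seed = as.integer(seed)),
            class = "trio_config")
}

# named RNG substream: deterministic function of (master seed, name),
# kept below 2^31
.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.BASES <- c("A", "C", "G", "T")

# sample one integer uniformly from [range[1], range[2]] (safe for
# degenerate ranges, unlike sample())
.sample1 <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  as.integer(range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L)
}

# random genome chromosome as a character vector, CpG-poor background
.random_chrom <- function(L, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(.BASES, L, replace = TRUE, prob = p)
}

# rewrite island stretches with elevated CpG dinucleotide probability
.write_island <- function(len, cpg_prob) {
  ndi <- ceiling(len / 2)
  is_cpg <- runif(ndi) < cpg_prob
  di <- character(ndi)
  di[is_cpg] <- "CG"
  n_other <- sum(!is_cpg)
  if (n_other) {
    # GC-rich non-CpG filler typical of island sequence
    b1 <- sample(.BASES, n_other, replace = TRUE,
                 prob = c(0.2, 0.3, 0.3, 0.2))
    b2 <- sample(.BASES, n_other, replace = TRUE,
                 prob = c(0.2, 0.35, 0.25, 0.2))
    di[!is_cpg] <- paste0(b1, b2)
  }
  substr(paste(di, collapse = ""), 1L, len)
}

# place n non-overlapping intervals of sampled lengths on the genome,
# avoiding `avoid` (GRanges) with the given margin; errors when space
# runs out
.place_random <- function(n, length_range, chrom_lengths, avoid = GRanges(),
                          margin = 0, edge = 200, max_tries = 200L) {
  placed <- GRanges()
  probs <- chrom_lengths / sum(chrom_lengths)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      len <- .sample1(length_range)
      cn <- sample(names(chrom_lengths), 1L, prob = probs)
      L <- chrom_lengths[[cn]]
      if (L - len - 2 * edge <= 0) next
      s0 <- sample.int(L - len - 2L * edge, 1L) + edge
      cand <- gr0(cn, s0, s0 + len)
      block <- suppressWarnings(c(avoid, placed))
      if (length(block) &&
          suppressWarnings(countOverlaps(cand, block + margin))[1L] > 0L) next
      placed <- c(placed, cand)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place interval ", i, " of ", n,
                  " without overlap; genome too crowded")
  }
  placed
}

#' Plant species-specific methylation truth
#'
#' Places the configured numbers of planted regions of each class in CpG
#' islands, island shores and open genome, and assigns per-species
#' methylation levels by class: \code{human_hypo} (reference low, both
#' out-groups high), \code{human_hyper} (reference high, out-groups low),
#' \code{chimp_only} (chimp high only), \code{shared_methylated} (all
#' high) and \code{unmethylated_background} (all low -- explicit negative
#' controls). Regions never overlap one another, the blacklist, or (for
#' non-island classes) islands.
#'
#' @param config \code{trio_config}.
#' @param islands island GRanges on the reference genome.
#' @param blacklist blacklist GRanges (planted regions avoid it).
#' @return list with \code{truth} (GRanges: class, name, level_human,
#'   level_chimp, level_macaque, placement) and \code{motif_anchor}
#'   (island GRanges hosting the planted motif locus, or NULL).
#' @export
plant_sdmrs <- function(config, islands, blacklist = GRanges()) {
  sp <- config$sdmrs
  cl <- config$chrom_lengths
  set.seed(.substream(config$seed, "plant"))
  # slots: class, placement (island / shore / open). Shore-placed regions
  # are attached to islands that host no island-placed region, so an
  # out-group peak over the shore region cannot merge with a peak inside
  # its island (unplanted islands sit at baseline methylation).
  n_hypo_isl <- ceiling(sp$n_hypo / 2)
  n_hyper_isl <- min(5L, ceiling(sp$n_hyper / 3))
  n_hyper_sh <- min(5L, sp$n_hyper - n_hyper_isl)
  n_shared_isl <- ceiling(sp$n_shared / 4)
  slots <- data.frame(
    class = c(rep("human_hypo", sp$n_hypo),
              rep("human_hyper", sp$n_hyper),
              rep("chimp_only", sp$n_chimp_only),
              rep("shared_methylated", sp$n_shared),
              rep("unmethylated_background", sp$n_background)),
    where = c(rep(c("island", "shore"),
                  c(n_hypo_isl, sp$n_hypo - n_hypo_isl)),
              rep(c("island", "shore", "open"),
                  c(n_hyper_isl, n_hyper_sh,
                    sp$n_hyper - n_hyper_isl - n_hyper_sh)),
              rep("open", sp$n_chimp_only),
              rep(c("island", "open"),
                  c(n_shared_isl, sp$n_shared - n_shared_isl)),
              rep("open", sp$n_background)))
  n_island_slots <- sum(slots$where == "island")
  n_shore_slots <- sum(slots$where == "shore")
  if (n_island_slots > length(islands)) {
    stop("not enough islands (", length(islands), ") for ",
         n_island_slots, " island-placed regions")
  }
  isl_order <- sample(seq_along(islands))
  free_isl <- isl_order[-seq_len(n_island_slots)]  # hosts for shore slots
  if (n_shore_slots > 2L * length(free_isl)) {
    stop("not enough unplanted islands to host ", n_shore_slots,
         " shore-placed regions")
  }
  # (island, side) pairs for shore slots: both flanks of each free island
  shore_host <- data.frame(isl = rep(free_isl, each = 2L),
                           side = rep(c(1L, -1L), length(free_isl)))
  isl_ptr <- 0L
  shore_ptr <- 0L
  placed <- GRanges()
  rows <- vector("list", nrow(slots))
  hypo_island_anchor <- NULL
  # a linked gene-body hyper region is attached to the first island-placed
  # hypo region (the promoter/gene-body divergence locus)
  for (i in seq_len(nrow(slots))) {
    len <- .sample1(sp$length_range)
    where <- slots$where[i]
    if (where == "island") {
      # island-placed regions span the whole island: a methylation state
      # switch at a CpG island is an island-level event, and a partially
      # planted island would leave a residual baseline-methylated,
      # CpG-dense remainder with its own weak MeDIP signal
      isl_ptr <- isl_ptr + 1L
      isl <- islands[isl_order[isl_ptr]]
      cand <- granges(isl)
      if (slots$class[i] == "human_hypo" && is.null(hypo_island_anchor)) {
        hypo_island_anchor <- isl
      }
    } else if (where == "shore") {
      ok <- FALSE
      len2 <- min(len, 1700L)
      while (shore_ptr < nrow(shore_host)) {
        shore_ptr <- shore_ptr + 1L
        isl <- islands[shore_host$isl[shore_ptr]]
        side <- shore_host$side[shore_ptr]
        # fully inside the 2-kb shore band, >= 200 bp off the island edge
        room <- 2000L - 200L - len2
        if (room < 0L) next
        off <- sample.int(room + 1L, 1L) - 1L
        s <- if (side > 0L) end(isl) + 200L + off
             else start(isl) - 200L - off - len2
        cand <- GRanges(seqnames(isl), IRanges(s, width = len2))
        if (start(cand) < 201L ||
            end(cand) > cl[[as.character(seqnames(cand))]] - 200L) next
        block <- suppressWarnings(c(blacklist, placed))
        if (length(block) > 0L &&
            suppressWarnings(
              countOverlaps(cand, block + 1000L))[1L] > 0L) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place shore region")
    } else {
      cand <- .place_random(1L, c(len, len), cl,
                            avoid = c(islands + 2300L, blacklist,
                                      placed),
                            margin = 1000L)
    }
    placed <- suppressWarnings(c(placed, granges(cand)))
    rows[[i]] <- data.frame(chrom = as.character(seqnames(cand)),
                            start = start(cand), end = end(cand),
                            class = slots$class[i], where = where)
  }
  if (!length(rows) || all(vapply(rows, is.null, TRUE))) {
    truth <- GRanges(class = character(0), placement = character(0),
                     name = character(0), level_human = numeric(0),
                     level_chimp = numeric(0), level_macaque = numeric(0))
    return(list(truth = truth, motif_anchor = NULL))
  }
  d <- do.call(rbind, rows)
  hi <- sp$level_high; lo <- sp$level_low
  lev <- list(
    human_hypo = c(lo, hi, hi), human_hyper = c(hi, lo, lo),
    chimp_only = c(lo, hi, lo), shared_methylated = c(hi, hi, hi),
    unmethylated_background = c(lo, lo, lo))
  lv <- t(vapply(d$class, function(k) lev[[k]], numeric(3)))
  truth <- GRanges(d$chrom, IRanges(d$start, d$end),
                   class = d$class, placement = d$where,
                   name = paste0(d$class, "_", ave(seq_len(nrow(d)),
                                                   d$class, FUN = seq_along)),
                   level_human = unname(lv[, 1L]),
                   level_chimp = unname(lv[, 2L]),
                   level_macaque = unname(lv[, 3L]))
  list(truth = truth, motif_anchor = hypo_island_anchor)
}

#' Piecewise-constant methylation landscape
#'
#' Background methylation probability plus region overrides; consumed by
#' [simulate_medip()].
#'
#' @param baseline genome-wide background methylation level in [0, 1].
#' @param regions GRanges with a \code{level} metadata column in [0, 1].
#' @return object of class \code{meth_landscape}.
#' @export
meth_landscape <- function(baseline, regions = GRanges()) {
  stopifnot(baseline >= 0, baseline <= 1)
  if (length(regions)) {
    lv <- mcols(regions)$level
    stopifnot(!is.null(lv), all(lv >= 0 & lv <= 1))
  }
  structure(list(baseline = baseline, regions = regions),
            class = "meth_landscape")
}

# planted-truth levels -> per-species piecewise landscape (GRanges + baseline)
.landscape_from_truth <- function(truth, baseline, species) {
  col <- paste0("level_", species)
  gr <- granges(truth)
  mcols(gr)$level <- mcols(truth)[[col]]
  meth_landscape(baseline, gr)
}

# sample substitution and indel edits for one chromosome of one branch.
# protected regions receive no edits (indels additionally keep a margin),
# so planted regions stay fully liftable.
.sample_edits <- function(L, br, protected) {
  prot <- reduce(protected)
  n_sub <- rbinom(1L, L, br$sub_rate)
  sub_pos <- sort(sample.int(L, min(n_sub, L)))  # 1-based
  if (length(prot)) {
    hit <- overlapsAny(IRanges(sub_pos, width = 1L), ranges(prot))
    sub_pos <- sub_pos[!hit]
  }
  n_ind <- rbinom(1L, L, br$indel_rate)
  ind_pos <- sort(sample.int(max(L - 100L, 1L), min(n_ind, L)))
  ind_pos <- ind_pos[ind_pos > 1L]  # keep the first aligned block >= 1 bp
  ind_len <- rgeom(length(ind_pos), 1 / br$indel_mean) + 1L
  ind_type <- sample(c("ins", "del"), length(ind_pos), replace = TRUE)
  if (length(prot) && length(ind_pos)) {
    span <- IRanges(ind_pos, width = ifelse(ind_type == "del", ind_len, 1L))
    hit <- overlapsAny(span, ranges(prot) + 100L)
    ind_pos <- ind_pos[!hit]; ind_len <- ind_len[!hit]
    ind_type <- ind_type[!hit]
  }
  # enforce separation so aligned blocks stay >= 1 bp
  if (length(ind_pos) > 1L) {
    keep <- logical(length(ind_pos))
    last_end <- -10L
    for (j in seq_along(ind_pos)) {
      extent <- ind_pos[j] +
        (if (ind_type[j] == "del") ind_len[j] else 0L)
      if (ind_pos[j] > last_end + 1L) {
        keep[j] <- TRUE
        last_end <- extent
      }
    }
    ind_pos <- ind_pos[keep]; ind_len <- ind_len[keep]
    ind_type <- ind_type[keep]
  }
  list(sub_pos = sub_pos,
       indels = data.frame(pos = ind_pos, len = ind_len, type = ind_type))
}

# apply edits to one chromosome (character vector); returns the derived
# chromosome and the alignment blocks (size, ds = source gap, dt = target
# gap) -- k indels produce k + 1 aligned blocks
.apply_edits <- function(seqv, sub_pos, indels) {
  if (length(sub_pos)) {
    old <- seqv[sub_pos]
    pick <- sample.int(3L, length(sub_pos), replace = TRUE)
    alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                 c("A", "C", "T"), c("A", "C", "G"))
    rownames(alt) <- .BASES
    seqv[sub_pos] <- alt[cbind(match(old, .BASES), pick)]
  }
  L <- length(seqv)
  if (!nrow(indels)) {
    return(list(seq = seqv,
                blocks = data.frame(size = L, ds = 0, dt = 0)))
  }
  segs <- vector("list", 2L * nrow(indels) + 1L)
  size <- ds <- dt <- numeric(nrow(indels) + 1L)
  cur <- 0L  # 0-based source cursor
  si <- 0L
  for (j in seq_len(nrow(indels))) {
    p <- indels$pos[j] - 1L  # 0-based edit position
    size[j] <- p - cur
    si <- si + 1L
    segs[[si]] <- seqv[(cur + 1L):p]
    if (indels$type[j] == "del") {
      ds[j] <- indels$len[j]; dt[j] <- 0
      cur <- p + indels$len[j]
    } else {
      ds[j] <- 0; dt[j] <- indels$len[j]
      si <- si + 1L
      segs[[si]] <- sample(.BASES, indels$len[j], replace = TRUE)
      cur <- p
    }
  }
  size[nrow(indels) + 1L] <- L - cur
  si <- si + 1L
  segs[[si]] <- seqv[(cur + 1L):L]
  list(seq = unlist(segs[seq_len(si)]),
       blocks = data.frame(size = size, ds = ds, dt = dt))
}

# build a chain_set from per-chromosome block tables
.chain_set_from_blocks <- function(blocks_by_chrom, s_sizes, t_sizes) {
  chains <- list()
  for (cn in names(blocks_by_chrom)) {
    b <- blocks_by_chrom[[cn]]
    ch <- list(score = sum(b$size), s_chrom = cn, s_size = s_sizes[[cn]],
               s_strand = "+", s_start = 0, s_end = s_sizes[[cn]],
               t_chrom = cn, t_size = t_sizes[[cn]], t_strand = "+",
               t_start = 0, t_end = t_sizes[[cn]],
               id = cn, blocks = b)
    ch$s_bs <- ch$s_start + cumsum(c(0, b$size + b$ds))[seq_len(nrow(b))]
    ch$t_bs <- ch$t_start + cumsum(c(0, b$size + b$dt))[seq_len(nrow(b))]
    chains[[length(chains) + 1L]] <- ch
  }
  structure(list(chains = chains), class = "chain_set")
}

# invert a chain_set built by the generator (swap source and target)
.invert_chain_set <- function(cs) {
  chains <- lapply(cs$chains, function(ch) {
    b <- data.frame(size = ch$blocks$size, ds = ch$blocks$dt,
                    dt = ch$blocks$ds)
    out <- list(score = ch$score, s_chrom = ch$t_chrom, s_size = ch$t_size,
                s_strand = "+", s_start = ch$t_start, s_end = ch$t_end,
                t_chrom = ch$s_chrom, t_size = ch$s_size, t_strand = "+",
                t_start = ch$s_start, t_end = ch$s_end,
                id = ch$id, blocks = b)
    out$s_bs <- out$s_start + cumsum(c(0, b$size + b$ds))[seq_len(nrow(b))]
    out$t_bs <- out$t_start + cumsum(c(0, b$size + b$dt))[seq_len(nrow(b))]
    out
  })
  structure(list(chains = chains), class = "chain_set")
}

# RFX-like palindromic consensus used for the planted motif locus
.RFX_CONSENSUS <- "GTTGCCATGGCAAC"
.RFX_EDIT_OFFSET <- 8L  # 1-based offset of the base toggled on both branches

#' Generate the synthetic trio
#'
#' Builds the reference genome (with CpG islands), plants the methylation
#' truth, derives the two out-group genomes by branch-specific
#' substitutions and indels (edits are excluded from planted regions so
#' orthology there is exact), emits exact chain files in both directions,
#' and annotates islands, genes, repeats and a blacklist. When
#' \code{plant_motif} is set, a motif consensus is written into the first
#' island-placed hypomethylated region and a single-base edit on each
#' branch weakens it in both out-groups, with a linked gene-body
#' hypermethylated region downstream and a gene model anchored on the
#' island.
#'
#' @param config \code{trio_config}.
#' @return \code{trio_data}: genomes (DNAStringSet per species), chain sets
#'   in all four directions, per-species chromosome lengths, annotations
#'   (islands, genes, exons, repeats, blacklist), planted truth,
#'   per-species methylation landscapes, motif-site bookkeeping, config.
#' @export
generate_trio <- function(config = trio_config()) {
  stopifnot(inherits(config, "trio_config"))
  cl <- config$chrom_lengths
  set.seed(.substream(config$seed, "genome"))
  genome_h <- lapply(cl, .random_chrom)
  # islands: non-overlapping, clear of chromosome ends and of one another
  islands <- .place_random(config$islands$count,
                           config$islands$length_range, cl,
                           margin = 4500, edge = 5000)
  mcols(islands)$name <- paste0("cpgi_", seq_along(islands))
  islands <- islands[order(as.character(seqnames(islands)), start(islands))]
  mcols(islands)$name <- paste0("cpgi_", seq_along(islands))
  for (k in seq_along(islands)) {
    cn <- as.character(seqnames(islands))[k]
    w <- width(islands)[k]
    isl_seq <- .write_island(w, config$islands$cpg_prob)
    genome_h[[cn]][start(islands)[k]:end(islands)[k]] <-
      strsplit(isl_seq, "")[[1L]]
  }
  blacklist <- .place_random(config$blacklist$count,
                             config$blacklist$length_range, cl,
                             avoid = islands, margin = 3000, edge = 1000)
  mcols(blacklist)$name <- paste0("blacklist_", seq_along(blacklist))

  planted <- plant_sdmrs(config, islands, blacklist)
  truth <- planted$truth

  # planted motif locus: consensus written into the reference inside the
  # anchor hypo region; both branches get a single-base motif-weakening edit
  motif_site <- NULL
  if (isTRUE(config$plant_motif) && !is.null(planted$motif_anchor)) {
    anchor_region <- truth[mcols(truth)$class == "human_hypo" &
                             mcols(truth)$placement == "island"][1L]
    cn <- as.character(seqnames(anchor_region))
    w <- nchar(.RFX_CONSENSUS)
    pos <- start(anchor_region) + floor(width(anchor_region) / 2)
    genome_h[[cn]][pos:(pos + w - 1L)] <- strsplit(.RFX_CONSENSUS, "")[[1L]]
    edit_pos <- pos + .RFX_EDIT_OFFSET - 1L
    ref_base <- genome_h[[cn]][edit_pos]
    alt_base <- if (ref_base == "T") "C" else "T"
    motif_site <- list(chrom = cn, start = pos, width = w,
                       edit_pos = edit_pos, ref_base = ref_base,
                       alt_base = alt_base, region = anchor_region)
    # decoy weakened instances (the single-mismatch variant) in every
    # other island: motif families occur genome-wide, so the null
    # distribution of island affinities must contain partial matches --
    # otherwise even a weakened site would look significant
    weak <- strsplit(.RFX_CONSENSUS, "")[[1L]]
    weak[.RFX_EDIT_OFFSET] <- alt_base
    for (k in seq_along(islands)) {
      if (k %% 2L != 0L) next
      isl_k <- islands[k]
      if (suppressWarnings(countOverlaps(isl_k, anchor_region))[1L] > 0L) next
      cn_k <- as.character(seqnames(isl_k))
      p_k <- start(isl_k) + floor(width(isl_k) / 2)
      genome_h[[cn_k]][p_k:(p_k + w - 1L)] <- weak
    }
  }

  # branch genomes + exact chains
  protected <- reduce(granges(truth))
  genomes <- list(human = genome_h)
  chains <- list()
  chrom_lengths <- list(human = cl)
  for (sp in c("chimp", "macaque")) {
    set.seed(.substream(config$seed, paste0("edits_", sp)))
    br <- config$branch[[sp]]
    gsp <- list()
    blocks <- list()
    for (cn in names(cl)) {
      prot <- ranges(protected[seqnames(protected) == cn])
      ed <- .sample_edits(cl[[cn]], br, prot)
      ap <- .apply_edits(genomes$human[[cn]], ed$sub_pos, ed$indels)
      if (!is.null(motif_site) && motif_site$chrom == cn) {
        # targeted motif-weakening substitution (inside a protected
        # region, so coordinates are identical in the derived genome
        # up to upstream indels -- none exist inside the region)
        m <- liftover_map(GRanges(cn, IRanges(motif_site$edit_pos,
                                              width = 1L)),
                          .chain_set_from_blocks(
                            setNames(list(ap$blocks), cn),
                            setNames(cl[[cn]], cn),
                            setNames(length(ap$seq), cn)))
        ap$seq[m$t_start + 1L] <- motif_site$alt_base
      }
      gsp[[cn]] <- ap$seq
      blocks[[cn]] <- ap$blocks
    }
    genomes[[sp]] <- gsp
    chrom_lengths[[sp]] <- vapply(gsp, length, 0)
    fwd <- .chain_set_from_blocks(blocks, cl, chrom_lengths[[sp]])
    chains[[paste0("human_", sp)]] <- fwd
    chains[[paste0(sp, "_human")]] <- .invert_chain_set(fwd)
  }

  # annotations: repeats and gene models on the reference
  set.seed(.substream(config$seed, "annot"))
  repeats <- .place_random(config$repeats$count,
                           config$repeats$length_range, cl, margin = 0,
                           edge = 500)
  mcols(repeats)$name <- sample(config$repeats$subfamilies,
                                length(repeats), replace = TRUE)
  gm <- .build_gene_models(config, islands, truth, motif_site)

  landscape <- list(
    human = .landscape_from_truth(truth, config$baseline_methylation,
                                  "human"),
    chimp = .transfer_landscape(truth, config$baseline_methylation,
                                "chimp", chains$human_chimp),
    macaque = .transfer_landscape(truth, config$baseline_methylation,
                                  "macaque", chains$human_macaque))

  genomes_dss <- lapply(genomes, function(g) {
    DNAStringSet(vapply(g, paste, "", collapse = ""))
  })
  # one common seqlevels universe for every annotation object
  for (nm in c("islands", "repeats", "blacklist")) {
    obj <- get(nm)
    seqlevels(obj) <- union(seqlevels(obj), names(cl))
    assign(nm, obj)
  }
  seqlevels(truth) <- union(seqlevels(truth), names(cl))
  ex <- gm$exons
  seqlevels(ex) <- union(seqlevels(ex), names(cl))
  gm$exons <- ex
  structure(list(genomes = genomes_dss, chains = chains,
                 chrom_lengths = chrom_lengths,
                 annotations = list(islands = islands, repeats = repeats,
                                    blacklist = blacklist,
                                    genes = gm$genes, exons = gm$exons),
                 truth = truth, landscape = landscape,
                 motif_site = motif_site, config = config),
            class = "trio_data")
}

# planted truth mapped into a branch genome's own coordinates (exact by
# construction: planted regions carry no indels)
.transfer_landscape <- function(truth, baseline, species, chain_fwd) {
  m <- liftover_map(truth, chain_fwd, min_match = 0.9)
  ok <- m$status %in% c("mapped", "low_match")
  gr <- gr0(m$t_chrom[ok], m$t_start[ok], m$t_end[ok])
  mcols(gr)$level <- mcols(truth)[[paste0("level_", species)]][ok]
  structure(list(baseline = baseline, regions = gr),
            class = "meth_landscape")
}

# gene models anchored on islands (TSS at island center); the planted
# motif locus gets a transcript whose second exon covers the linked
# gene-body region
.build_gene_models <- function(config, islands, truth, motif_site) {
  g <- config$genes
  cl <- config$chrom_lengths
  n <- g$count
  anchor_idx <- if (!is.null(motif_site)) {
    which(overlapsAny(islands, motif_site$region))[1L]
  } else NA_integer_
  ord <- seq_along(islands)
  if (!is.na(anchor_idx)) ord <- c(anchor_idx, setdiff(ord, anchor_idx))
  ord <- rep(ord, length.out = n)
  genes <- vector("list", n)
  exon_rows <- list()
  linked_hyper <- NULL
  if (!is.null(motif_site)) {
    cand <- truth[mcols(truth)$class == "human_hyper"]
    cn <- motif_site$chrom
    cand <- cand[as.character(seqnames(cand)) == cn &
                   start(cand) > end(motif_site$region)]
    if (length(cand)) {
      linked_hyper <- cand[which.min(start(cand))]
    }
  }
  for (i in seq_len(n)) {
    isl <- islands[ord[i]]
    cn <- as.character(seqnames(isl))
    strand <- if (i %% 2L == 0L) "-" else "+"
    tss <- start(isl) + floor(width(isl) / 2)
    # exons begin well downstream of the island: the island covers the
    # promoter and 5' UTR, and island peaks extend a few hundred bp past
    # the island edge, so exonic scores must not touch that overhang
    first_exon <- if (strand == "+") end(isl) + 600L
                  else start(isl) - 600L
    nex <- .sample1(g$exon_count_range)
    elen <- vapply(seq_len(nex), function(.)
      .sample1(g$exon_length_range), 0L)
    ilen <- vapply(seq_len(nex), function(.)
      .sample1(g$intron_length_range), 0L)
    if (i == 1L && !is.null(linked_hyper)) {
      strand <- "+"
      first_exon <- end(isl) + 600L
      # nudge the short first exon clear of any planted region
      for (tr_try in seq_len(20L)) {
        cand <- GRanges(cn, IRanges(first_exon, first_exon + 199L))
        hit <- suppressWarnings(findOverlaps(cand, truth))
        if (!length(hit)) break
        first_exon <- max(end(truth[subjectHits(hit)])) + 300L
      }
      # never cross the linked gene-body exon
      first_exon <- min(first_exon, start(linked_hyper) - 400L)
      # two exons only: the 5' exon and the linked gene-body region
      nex <- 2L
      elen <- c(200L, width(linked_hyper))
      starts <- c(first_exon, start(linked_hyper))
    } else if (strand == "+") {
      starts <- first_exon +
        cumsum(c(0L, head(elen, -1L) + head(ilen, -1L)))
    } else {
      ends <- first_exon -
        cumsum(c(0L, head(elen, -1L) + head(ilen, -1L)))
      starts <- ends - elen + 1L
    }
    keep <- starts >= 1L & (starts + elen - 1L) <= cl[[cn]]
    starts <- starts[keep]; elen <- elen[keep]
    if (!length(starts)) next
    tid <- sprintf("TX%03d-001", i)
    prom <- IRanges(max(1L, tss - 1000L), min(cl[[cn]], tss + 1000L))
    genes[[i]] <- data.frame(
      transcript_id = tid, gene_id = sprintf("GENE%03d", i),
      chrom = cn, strand = strand, tss = tss,
      promoter_start = start(prom), promoter_end = end(prom),
      island = mcols(isl)$name)
    exon_rows[[i]] <- data.frame(chrom = cn, start = starts,
                                 end = starts + elen - 1L,
                                 transcript_id = tid, strand = strand)
  }
  genes <- do.call(rbind, genes)
  ex <- do.call(rbind, exon_rows)
  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand,
                   transcript_id = ex$transcript_id)
  list(genes = genes, exons = exons)
}

#' Simulate MeDIP-like fragments for one species
#'
#' Fragment start positions are drawn with weight
#' \code{1 + enrichment_factor * (methylated CpG content of the fragment)},
#' where methylated CpG content sums the landscape methylation level over
#' the CpG dinucleotides in a nominal fragment-length window. Fragment
#' lengths are normal (truncated at 50 bp). A configurable fraction of
#' fragments is emitted as exact duplicates, with low mapping quality, or
#' flagged as improperly paired, to exercise the filtering stage.
#'
#' @param genome DNAStringSet (one entry per chromosome).
#' @param landscape \code{meth_landscape} for the same genome.
#' @param coverage nominal fold coverage (> 0 unless 0 for an empty set).
#' @param fraglen_mean,fraglen_sd fragment length distribution (bp).
#' @param enrichment_factor weight per methylated CpG.
#' @param dup_frac,lowq_frac,improper_frac artifact fractions.
#' @param seed RNG seed for this simulation.
#' @return GRanges of raw fragments with \code{quality} and \code{proper}.
#' @export
simulate_medip <- function(genome, landscape, coverage,
                           fraglen_mean = 200, fraglen_sd = 30,
                           enrichment_factor = 1,
                           dup_frac = 0.03, lowq_frac = 0.02,
                           improper_frac = 0.02, seed = 1L) {
  stopifnot(inherits(landscape, "meth_landscape"), coverage >= 0)
  reg_chroms <- unique(as.character(seqnames(landscape$regions)))
  if (!all(reg_chroms %in% names(genome))) {
    stop("landscape refers to chromosomes absent from the genome")
  }
  if (any(end(landscape$regions) >
            width(genome)[match(as.character(seqnames(landscape$regions)),
                                names(genome))])) {
    stop("landscape regions extend past chromosome ends")
  }
  set.seed(seed)
  out <- list()
  Lf <- as.integer(round(fraglen_mean))
  for (cn in names(genome)) {
    L <- width(genome)[names(genome) == cn]
    n_frag <- as.integer(round(coverage * L / fraglen_mean))
    if (n_frag == 0L || L <= Lf) next
    # per-position methylated-CpG mass
    cpg <- start(Biostrings::matchPattern("CG", genome[[cn]]))
    lev <- rep(landscape$baseline, L)
    reg <- landscape$regions[as.character(seqnames(landscape$regions)) == cn]
    for (k in seq_along(reg)) {
      lev[start(reg)[k]:end(reg)[k]] <- mcols(reg)$level[k]
    }
    m <- numeric(L)
    m[cpg] <- lev[cpg]
    cm <- c(0, cumsum(m))
    ns <- L - Lf + 1L
    w <- 1 + enrichment_factor * (cm[(Lf + 1L):(L + 1L)] - cm[seq_len(ns)])
    cw <- cumsum(w)
    u <- runif(n_frag) * cw[ns]
    s1 <- findInterval(u, cw) + 1L  # 1-based fragment starts
    len <- pmax(50L, as.integer(round(rnorm(n_frag, fraglen_mean,
                                            fraglen_sd))))
    e1 <- pmin(s1 + len - 1L, L)
    q <- ifelse(runif(n_frag) < lowq_frac,
                sample(0:9, n_frag, replace = TRUE), 30L)
    proper <- runif(n_frag) >= improper_frac
    n_dup <- as.integer(round(dup_frac * n_frag))
    if (n_dup > 0L) {
      di <- sample.int(n_frag, n_dup, replace = TRUE)
      s1 <- c(s1, s1[di]); e1 <- c(e1, e1[di])
      q <- c(q, rep(30L, n_dup)); proper <- c(proper, rep(TRUE, n_dup))
    }
    out[[cn]] <- GRanges(cn, IRanges(s1, e1), quality = as.integer(q),
                         proper = proper)
  }
  if (!length(out)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(quality = integer(0),
                                      proper = logical(0))
    return(gr)
  }
  suppressWarnings(unname(do.call(c, unname(out))))
}

#' Simulate fragments for all three species of a trio
#'
#' @param trio \code{trio_data}.
#' @param seed seed; per-species substreams are derived from it.
#' @return named list of raw fragment GRanges (human, chimp, macaque).
#' @export
simulate_trio_medip <- function(trio, seed = trio$config$seed) {
  md <- trio$config$medip
  out <- list()
  for (sp in c("human", "chimp", "macaque")) {
    out[[sp]] <- simulate_medip(
      trio$genomes[[sp]], trio$landscape[[sp]],
      coverage = md$coverage * md$depth_scale[[sp]],
      fraglen_mean = md$fraglen_mean, fraglen_sd = md$fraglen_sd,
      enrichment_factor = md$enrichment_factor,
      dup_frac = md$dup_frac, lowq_frac = md$lowq_frac,
      improper_frac = md$improper_frac,
      seed = .substream(seed, paste0("frag_", sp)))
  }
  out
}

#' Write all trio artifacts as plain-text files
#'
#' FASTA genomes, chain files in both directions, BED annotations
#' (islands, repeats with subfamily in the name column, blacklist), gene
#' and exon tables (TSV / BED6), and the planted truth table (TSV).
#'
#' @param trio \code{trio_data}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_trio <- function(trio, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sp in names(trio$genomes)) {
    f <- file.path(dir, paste0(sp, ".fa"))
    write_fasta(trio$genomes[[sp]], f)
    files <- c(files, f)
  }
  for (nm in names(trio$chains)) {
    f <- file.path(dir, paste0(nm, ".chain"))
    write_chain(trio$chains[[nm]], f)
    files <- c(files, f)
  }
  ann <- trio$annotations
  for (nm in c("islands", "repeats", "blacklist")) {
    f <- file.path(dir, paste0(nm, ".bed"))
    gr <- ann[[nm]]
    mcols(gr)$score <- 0
    write_intervals(gr, f, "bed6")
    files <- c(files, f)
  }
  f <- file.path(dir, "genes.tsv")
  write.table(ann$genes, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "exons.bed")
  ex <- ann$exons
  mcols(ex)$name <- mcols(ex)$transcript_id
  mcols(ex)$score <- 0
  write_intervals(ex, f, "bed6")
  files <- c(files, f)
  f <- file.path(dir, "truth.tsv")
  tt <- cbind(bed0(trio$truth)[, c("chrom", "start", "end")],
              as.data.frame(mcols(trio$truth)))
  write.table(tt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}

#' @export
print.trio_data <- function(x, ...) {
  cat("trio_data:", length(x$genomes$human), "chromosome(s),",
      sum(x$chrom_lengths$human), "bp reference;",
      length(x$truth), "planted regions\n")
  invisible(x)
}
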