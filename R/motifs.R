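#' Biophysical affinity model parameters
#'
#' Mismatch-energy occupancy model: for a window of width W the energy is
#' \eqn{E = (1/\lambda) \sum_j \ln(f_{max,j} / f(b_j, j))} and the window
#' occupancy \eqn{p = R_0 e^{-E} / (1 + R_0 e^{-E})} with
#' \eqn{\ln R_0 = 0.584 W - 5.66}. Total affinity of a sequence is the sum
#' of window occupancies over both strands.
#'
#' @param lambda energy scale (> 0, default 0.7).
#' @param r0_slope,r0_intercept parameters of \eqn{\ln R_0} as a linear
#'   function of motif width.
#' @return list of class \code{affinity_model}.
#' @export
affinity_model <- function(lambda = 0.7, r0_slope = 0.584,
                           r0_intercept = -5.66) {
  stopifnot(lambda > 0)
  structure(list(lambda = lambda, r0_slope = r0_slope,
                 r0_intercept = r0_intercept),
            class = "affinity_model")
}

# per-start window occupancies (forward + reverse strand at each start);
# windows containing N are NA
.window_occupancy <- function(sequence, wm, model) {
  s <- toupper(as.character(sequence))
  x <- match(strsplit(s, "")[[1L]], .BASES)  # NA for N
  L <- length(x)
  W <- wm$width
  if (L < W) stop("sequence shorter than motif width")
  lnf <- log(wm$freqs)
  smat <- (apply(lnf, 1L, max) - lnf) / model$lambda  # W x 4 mismatch energy
  # reverse strand: reverse-complemented matrix scanned forward
  smat_rc <- smat[rev(seq_len(W)), c(4L, 3L, 2L, 1L), drop = FALSE]
  nw <- L - W + 1L
  e_f <- e_r <- numeric(nw)
  for (j in seq_len(W)) {
    xj <- x[j:(j + nw - 1L)]
    e_f <- e_f + smat[j, ][xj]
    e_r <- e_r + smat_rc[j, ][xj]
  }
  r0 <- exp(model$r0_slope * W + model$r0_intercept)
  occ <- function(e) 1 / (1 + exp(e) / r0)
  occ(e_f) + occ(e_r)
}

#' Expected occupancy (total binding affinity) of a sequence
#'
#' Sums the window occupancy over every window on both strands; windows
#' containing N are skipped. Invariant under reverse-complementation of
#' the sequence.
#'
#' @param sequence character, DNAString or one-element DNAStringSet.
#' @param wm \code{weight_matrix}.
#' @param model \code{affinity_model}.
#' @return total affinity (expected number of bound molecules).
#' @export
expected_occupancy <- function(sequence, wm, model = affinity_model()) {
  o <- .window_occupancy(sequence, wm, model)
  sum(o, na.rm = TRUE)
}

#' Precomputed affinity index over a background pool
#'
#' Per-sequence prefix sums of window occupancies, so the total affinity
#' of any subsequence can be read off in O(1). Used by the resampling
#' null of [region_set_pvalue()] and [empirical_directional_p()].
#'
#' @param wm weight_matrix.
#' @param seqs character vector / DNAStringSet of background sequences.
#' @param model affinity_model.
#' @return list of class \code{affinity_index}.
#' @export
affinity_index <- function(wm, seqs, model = affinity_model()) {
  seqs <- as.character(seqs)
  W <- wm$width
  keep <- nchar(seqs) >= W
  seqs <- seqs[keep]
  if (!length(seqs)) stop("no background sequence is as long as the motif")
  pf <- lapply(seqs, function(s) {
    o <- .window_occupancy(s, wm, model)
    o[is.na(o)] <- 0
    c(0, cumsum(o))
  })
  structure(list(W = W, lens = nchar(seqs), prefix = pf), class = "affinity_index")
}

# affinity of one random length-l subsequence from the indexed pool
.draw_affinity <- function(idx, l) {
  W <- idx$W
  ok <- which(idx$lens >= l)
  if (!length(ok)) {
    # fall back to the longest pool sequence truncation
    ok <- which.max(idx$lens)
    l <- idx$lens[ok]
  }
  k <- if (length(ok) > 1L) ok[sample.int(length(ok), 1L)] else ok
  nwin_sub <- l - W + 1L
  if (nwin_sub < 1L) return(0)
  max_start <- idx$lens[k] - l + 1L
  s <- if (max_start > 1L) sample.int(max_start, 1L) else 1L
  idx$prefix[[k]][s + nwin_sub] - idx$prefix[[k]][s]
}

#' Aggregate binding p-value for a region set
#'
#' The observed statistic is the summed affinity over the region set. The
#' null resamples \code{B} sets of length-matched subsequences from a
#' background pool (promoter-like sequences in real use); the p-value is
#' \code{(r + 1) / (B + 1)} where \code{r} counts null statistics greater
#' than or equal to the observed (ties count as exceeding).
#'
#' @param region_seqs character vector / DNAStringSet of region sequences
#'   (each <= 5 kb).
#' @param wm weight_matrix.
#' @param background background pool: character/DNAStringSet, or a
#'   prebuilt \code{affinity_index} for this motif.
#' @param model affinity_model.
#' @param B number of null draws (default 999).
#' @param seed RNG seed.
#' @return list: \code{p}, \code{observed}, \code{null} (the B null sums).
#' @export
region_set_pvalue <- function(region_seqs, wm, background,
                              model = affinity_model(), B = 999L,
                              seed = 1L) {
  region_seqs <- as.character(region_seqs)
  if (any(nchar(region_seqs) > 5000L)) {
    stop("regions longer than 5 kb are excluded from motif analysis")
  }
  idx <- if (inherits(background, "affinity_index")) background
         else affinity_index(wm, background, model)
  obs <- sum(vapply(region_seqs, expected_occupancy, 0, wm = wm,
                    model = model))
  set.seed(seed)
  lens <- nchar(region_seqs)
  null <- vapply(seq_len(B), function(b) {
    sum(vapply(lens, function(l) .draw_affinity(idx, l), 0))
  }, 0)
  r <- sum(null >= obs)
  list(p = (r + 1) / (B + 1), observed = obs, null = null)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity; input order is
#' preserved. Values outside (0, 1] are an error.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Two-dimensional motif divergence map
#'
#' For each motif with per-species aggregate p-values, computes
#' \code{d_hc = (-log10 p_H) - (-log10 p_C)} and
#' \code{d_hm = (-log10 p_H) - (-log10 p_M)}. A motif is flagged as a
#' consistent reference-species change when both differences share a sign
#' and the smaller magnitude reaches \code{threshold} (default one log10
#' unit).
#'
#' @param p_table data.frame with columns \code{motif}, \code{p_human},
#'   \code{p_chimp}, \code{p_macaque} (BH-adjusted upstream).
#' @param threshold divergence magnitude threshold in log10 units.
#' @return data.frame: motif, the three p's, \code{d_hc}, \code{d_hm},
#'   \code{consistent} flag, \code{direction} ("gain", "loss" or "none"),
#'   \code{clamped} flag for p = 0 inputs.
#' @export
divergence_map <- function(p_table, threshold = 1) {
  stopifnot(all(c("motif", "p_human", "p_chimp", "p_macaque") %in%
                  names(p_table)))
  clamp <- function(p) pmax(p, .Machine$double.xmin)
  clamped <- p_table$p_human == 0 | p_table$p_chimp == 0 |
    p_table$p_macaque == 0
  lh <- -log10(clamp(p_table$p_human))
  lc <- -log10(clamp(p_table$p_chimp))
  lm <- -log10(clamp(p_table$p_macaque))
  d_hc <- lh - lc
  d_hm <- lh - lm
  consistent <- sign(d_hc) == sign(d_hm) & sign(d_hc) != 0 &
    pmin(abs(d_hc), abs(d_hm)) >= threshold
  direction <- ifelse(!consistent, "none",
                      ifelse(d_hc > 0, "gain", "loss"))
  data.frame(motif = p_table$motif, p_human = p_table$p_human,
             p_chimp = p_table$p_chimp, p_macaque = p_table$p_macaque,
             d_hc = d_hc, d_hm = d_hm, consistent = consistent,
             direction = direction, clamped = clamped,
             stringsAsFactors = FALSE)
}

#' Empirical directional p-value for one motif's divergence
#'
#' Randomization test in the style used for CTCF: random region sets of
#' the observed sizes are drawn from candidate pools of orthologous
#' sequence triplets, the motif's divergence coordinates are recomputed
#' for each draw, and the p-value is \code{(r + 1) / (N + 1)} over the
#' pooled \code{N = reps * n} draws, where \code{r} counts draws whose
#' divergence exceeds the observed magnitude in the same direction on
#' both axes.
#'
#' @param observed list or row with \code{d_hc}, \code{d_hm} (observed
#'   divergence coordinates; their common sign defines the direction).
#' @param pool_h,pool_c,pool_m parallel character vectors of orthologous
#'   pool sequences (human, chimp, macaque) to resample region sets from.
#' @param set_size number of regions per drawn set (the observed set
#'   size).
#' @param wm weight_matrix.
#' @param background background pool for the per-draw aggregate p-values
#'   (character/DNAStringSet or \code{affinity_index}).
#' @param model affinity_model.
#' @param reps,n randomization structure: \code{reps} batches of \code{n}
#'   draws (defaults 4 x 1000).
#' @param B null draws inside each per-draw p-value.
#' @param seed RNG seed.
#' @return list: \code{p}, \code{n_draws}, \code{n_exceed}, the observed
#'   coordinates and direction.
#' @export
empirical_directional_p <- function(observed, pool_h, pool_c, pool_m,
                                    set_size, wm, background,
                                    model = affinity_model(),
                                    reps = 4L, n = 1000L, B = 99L,
                                    seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  stopifnot(length(pool_h) == length(pool_c),
            length(pool_h) == length(pool_m))
  if (length(pool_h) < set_size) {
    stop("pool smaller than the observed set size")
  }
  dir_hc <- sign(observed$d_hc)
  dir_hm <- sign(observed$d_hm)
  idx <- if (inherits(background, "affinity_index")) background
         else affinity_index(wm, background, model)
  # per-pool-region affinities, computed once per species
  aff <- lapply(list(pool_h, pool_c, pool_m), function(pool) {
    vapply(pool, expected_occupancy, 0, wm = wm, model = model)
  })
  lens <- lapply(list(pool_h, pool_c, pool_m), nchar)
  set.seed(seed)
  N <- reps * n
  n_exceed <- 0L
  for (d in seq_len(N)) {
    pick <- sample.int(length(pool_h), set_size)
    ps <- vapply(1:3, function(sp) {
      obs <- sum(aff[[sp]][pick])
      null <- vapply(seq_len(B), function(b) {
        sum(vapply(lens[[sp]][pick], function(l) .draw_affinity(idx, l), 0))
      }, 0)
      (sum(null >= obs) + 1) / (B + 1)
    }, 0)
    lp <- -log10(ps)
    d_hc <- lp[1L] - lp[2L]
    d_hm <- lp[1L] - lp[3L]
    if (sign(d_hc) == dir_hc && sign(d_hm) == dir_hm &&
        abs(d_hc) > abs(observed$d_hc) && abs(d_hm) > abs(observed$d_hm)) {
      n_exceed <- n_exceed + 1L
    }
  }
  list(p = (n_exceed + 1) / (N + 1), n_draws = N, n_exceed = n_exceed,
       d_hc = observed$d_hc, d_hm = observed$d_hm,
       direction = if (dir_hc > 0) "gain" else "loss")
}

#' Orthologous region triplet
#'
#' @param id region identifier.
#' @param seq_human,seq_chimp,seq_macaque orthologous sequences (all
#'   present, each <= 5 kb).
#' @return list of class \code{region_triplet}.
#' @export
region_triplet <- function(id, seq_human, seq_chimp, seq_macaque) {
  seqs <- c(human = as.character(seq_human),
            chimp = as.character(seq_chimp),
            macaque = as.character(seq_macaque))
  if (any(!nzchar(seqs))) stop("all three orthologous sequences required")
  if (any(nchar(seqs) > 5000L)) stop("regions > 5 kb are excluded")
  structure(list(id = id, seqs = seqs, lengths = nchar(seqs)),
            class = "region_triplet")
}

#' Screen one region triplet for species-specific motif binding
#'
#' For each motif, per-species aggregate p-values are computed on the
#' single region; a motif is flagged \code{human_gain} when the human p
#' is below \code{alpha} while chimp and macaque are not
#' (\code{human_loss}: the inverse).
#'
#' @param triplet \code{region_triplet}.
#' @param motifs named list of \code{weight_matrix}.
#' @param background background pool (character/DNAStringSet).
#' @param model affinity_model.
#' @param alpha significance level (default 0.05).
#' @param B,seed resampling controls.
#' @return data.frame: motif, p_human, p_chimp, p_macaque, call.
#' @export
mdr_screen <- function(triplet, motifs, background,
                       model = affinity_model(), alpha = 0.05,
                       B = 999L, seed = 1L) {
  stopifnot(inherits(triplet, "region_triplet"))
  if (!length(motifs)) {
    return(data.frame(motif = character(0), p_human = numeric(0),
                      p_chimp = numeric(0), p_macaque = numeric(0),
                      call = character(0)))
  }
  rows <- lapply(names(motifs), function(mn) {
    wm <- motifs[[mn]]
    idx <- affinity_index(wm, background, model)
    ps <- vapply(c("human", "chimp", "macaque"), function(sp) {
      region_set_pvalue(triplet$seqs[[sp]], wm, idx, model, B = B,
                        seed = .substream(seed, paste0(mn, "_", sp)))$p
    }, 0)
    call <- if (ps[1L] < alpha && ps[2L] >= alpha && ps[3L] >= alpha) {
      "human_gain"
    } else if (ps[1L] >= alpha && ps[2L] < alpha && ps[3L] < alpha) {
      "human_loss"
    } else "none"
    data.frame(motif = mn, p_human = ps[1L], p_chimp = ps[2L],
               p_macaque = ps[3L], call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent identity of an interval across a chain alignment
#'
#' Walks the aligned blocks overlapping a source-build interval and
#' compares the aligned bases of the two genomes:
#' \code{identity = matches / aligned columns * 100}. Indel (gap)
#' positions are not aligned columns.
#'
#' @param interval length-1 GRanges on the source build.
#' @param cs chain_set source -> target.
#' @param genome_src,genome_tgt DNAStringSet genomes.
#' @return percent identity.
#' @export
orthologous_identity <- function(interval, cs, genome_src, genome_tgt) {
  stopifnot(length(interval) == 1L)
  b <- bed0(interval)
  cn <- b$chrom
  matches <- 0; columns <- 0
  for (ch in cs$chains) {
    if (ch$s_chrom != cn || ch$t_strand != "+") next
    s_bs <- ch$s_bs; size <- ch$blocks$size
    lo_i <- max(1L, findInterval(b$start, s_bs))
    hi_i <- findInterval(b$end - 1, s_bs)
    if (hi_i < lo_i) next
    for (k in lo_i:hi_i) {
      o_s <- max(b$start, s_bs[k])
      o_e <- min(b$end, s_bs[k] + size[k])
      if (o_e <= o_s) next
      src <- strsplit(as.character(
        subseq(genome_src[[cn]], o_s + 1L, o_e)), "")[[1L]]
      t0 <- ch$t_bs[k] + (o_s - s_bs[k])
      tgt <- strsplit(as.character(
        subseq(genome_tgt[[ch$t_chrom]], t0 + 1L, t0 + (o_e - o_s))),
        "")[[1L]]
      matches <- matches + sum(toupper(src) == toupper(tgt))
      columns <- columns + (o_e - o_s)
    }
  }
  if (columns == 0) stop("no aligned columns for this interval")
  100 * matches / columns
}

#' Extract orthologous sequences for reference-build regions
#'
#' Lifts each region to the two out-group builds and pulls the sequences;
#' regions failing either lift (or exceeding 5 kb) are dropped.
#'
#' @param regions GRanges on the reference build.
#' @param trio \code{trio_data} (genomes + chains).
#' @param min_match liftover threshold.
#' @return list of \code{region_triplet}s, named by region index.
#' @export
orthologous_sequences <- function(regions, trio, min_match = 0.7) {
  if (!length(regions)) return(list())
  keep0 <- width(regions) <= 5000L
  regions <- regions[keep0]
  mc <- liftover_map(regions, trio$chains$human_chimp, min_match)
  mm <- liftover_map(regions, trio$chains$human_macaque, min_match)
  ok <- mc$status == "mapped" & mm$status == "mapped" &
    (mc$t_end - mc$t_start) <= 5000 & (mm$t_end - mm$t_start) <= 5000
  out <- list()
  for (i in which(ok)) {
    cn <- as.character(seqnames(regions))[i]
    sh <- as.character(subseq(trio$genomes$human[[cn]],
                              start(regions)[i], end(regions)[i]))
    sc <- as.character(subseq(trio$genomes$chimp[[mc$t_chrom[i]]],
                              mc$t_start[i] + 1L, mc$t_end[i]))
    sm <- as.character(subseq(trio$genomes$macaque[[mm$t_chrom[i]]],
                              mm$t_start[i] + 1L, mm$t_end[i]))
    out[[length(out) + 1L]] <- region_triplet(paste0("region_", i),
                                              sh, sc, sm)
  }
  out
}

#' Load the bundled synthetic demonstration motifs
#'
#' Twenty-two synthetic count matrices in TRANSFAC-like format, including
#' CTCF-like, SP1-like, RFX-like and MeCP2-like stand-ins. These are
#' demonstration matrices, not licensed TRANSFAC data; real-matrix
#' analyses should load user-supplied files with [read_weight_matrix()].
#'
#' @param pseudocount passed to [read_weight_matrix()].
#' @return named list of weight_matrix objects.
#' @export
demo_motifs <- function(pseudocount = 1) {
  read_weight_matrix(system.file("extdata", "motifs_demo_synthetic.txt",
                                 package = "triodmr", mustWork = TRUE),
                     pseudocount = pseudocount)
}
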