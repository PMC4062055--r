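# Shared fixtures and independent brute-force oracles.
# All fixtures are built in code; nothing is read from disk except files
# the tests themselves write to tempdirs.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# 0-based half-open constructor mirroring the package's I/O convention
gr0 <- function(chrom, start0, end0, ..., strand = "*") {
  GRanges(chrom, IRanges(start0 + 1L, end0),
          strand = rep_len(strand, length(chrom)), ...)
}

# ---- small synthetic trio, memoized across test files ----

small_trio_config <- function(seed = 5L) {
  trio_config(
    chrom_lengths = c(chrA = 250e3, chrB = 250e3),
    islands = list(count = 18, length_range = c(700, 1200), cpg_prob = 0.2),
    genes = list(count = 10, exon_count_range = c(2, 4),
                 exon_length_range = c(200, 500),
                 intron_length_range = c(500, 1500)),
    repeats = list(count = 20, length_range = c(150, 400),
                   subfamilies = c("AluJ", "AluS", "AluY", "L1")),
    blacklist = list(count = 2, length_range = c(1500, 3000)),
    sdmrs = list(n_hypo = 8, n_hyper = 8, n_chimp_only = 5, n_shared = 8,
                 n_background = 3, length_range = c(600, 1100),
                 level_high = 0.85, level_low = 0),
    seed = seed)
}

.trio_cache <- new.env(parent = emptyenv())

small_trio <- function(seed = 5L) {
  key <- paste0("trio_", seed)
  if (is.null(.trio_cache[[key]])) {
    .trio_cache[[key]] <- generate_trio(small_trio_config(seed))
  }
  .trio_cache[[key]]
}

# ---- toy chain construction ----

# write a chain file for a single chain and read it back
toy_chain <- function(blocks, s_chrom = "chr1", t_chrom = "chr1",
                      s_size = NULL, t_size = NULL, t_strand = "+",
                      s_start = 0, t_start = 0) {
  size <- vapply(blocks, `[[`, 0, 1)
  ds <- vapply(blocks, function(b) if (length(b) > 1) b[[2]] else 0, 0)
  dt <- vapply(blocks, function(b) if (length(b) > 2) b[[3]] else 0, 0)
  ds[length(ds)] <- 0; dt[length(dt)] <- 0
  s_span <- sum(size) + sum(ds)
  t_span <- sum(size) + sum(dt)
  if (is.null(s_size)) s_size <- s_start + s_span
  if (is.null(t_size)) t_size <- t_start + t_span
  f <- tempfile(fileext = ".chain")
  con <- file(f, "w")
  writeLines(paste("chain 100", s_chrom, s_size, "+", s_start,
                   s_start + s_span, t_chrom, t_size, t_strand,
                   t_start, t_start + t_span, "1"), con)
  n <- length(size)
  if (n > 1) writeLines(paste(size[-n], ds[-n], dt[-n]), con)
  writeLines(c(as.character(size[n]), ""), con)
  close(con)
  read_chain(f)
}

# ---- brute-force oracles ----

# per-base liftover oracle: maps every source base independently through
# the raw block table of every chain, then applies the same envelope /
# split / minMatch rules as the liftover contract defines them
bf_liftover <- function(chrom, start0, end0, cs, min_match = 0.7) {
  per_chain <- lapply(cs$chains, function(ch) {
    if (ch$s_chrom != chrom) return(NULL)
    hits <- list()
    for (pos in start0:(end0 - 1)) {
      s_cursor <- ch$s_start; t_cursor <- ch$t_start
      for (k in seq_len(nrow(ch$blocks))) {
        sz <- ch$blocks$size[k]
        if (pos >= s_cursor && pos < s_cursor + sz) {
          hits[[length(hits) + 1L]] <- t_cursor + (pos - s_cursor)
          break
        }
        s_cursor <- s_cursor + sz + ch$blocks$ds[k]
        t_cursor <- t_cursor + sz + ch$blocks$dt[k]
      }
    }
    if (!length(hits)) return(NULL)
    tp <- unlist(hits)
    lo <- min(tp); hi <- max(tp) + 1
    if (ch$t_strand == "-") {
      tmp <- ch$t_size - hi; hi <- ch$t_size - lo; lo <- tmp
    }
    list(n = length(tp), chrom = ch$t_chrom, lo = lo, hi = hi)
  })
  per_chain <- Filter(Negate(is.null), per_chain)
  if (!length(per_chain)) {
    return(list(status = "unmapped", fraction = 0))
  }
  if (length(per_chain) > 1L) return(list(status = "split", fraction = 0))
  h <- per_chain[[1L]]
  fr <- h$n / (end0 - start0)
  list(status = if (fr >= min_match) "mapped" else "low_match",
       fraction = fr, chrom = h$chrom, lo = h$lo, hi = h$hi)
}

# per-base source->target position tables for every chain, built by
# walking the raw block list once; an independent re-derivation of the
# chain coordinate arithmetic used for bulk oracle comparisons
bf_chain_tables <- function(cs) {
  lapply(cs$chains, function(ch) {
    map <- rep(NA_real_, ch$s_end)        # index = 0-based source pos + 1
    s_cursor <- ch$s_start; t_cursor <- ch$t_start
    for (k in seq_len(nrow(ch$blocks))) {
      sz <- ch$blocks$size[k]
      map[(s_cursor + 1):(s_cursor + sz)] <- t_cursor + 0:(sz - 1)
      s_cursor <- s_cursor + sz + ch$blocks$ds[k]
      t_cursor <- t_cursor + sz + ch$blocks$dt[k]
    }
    list(chrom = ch$s_chrom, t_chrom = ch$t_chrom,
         t_strand = ch$t_strand, t_size = ch$t_size, map = map)
  })
}

# envelope liftover oracle driven by the per-base tables
bf_liftover_tab <- function(chrom, start0, end0, tables, min_match = 0.7) {
  hits <- list()
  for (tb in tables) {
    if (tb$chrom != chrom || start0 + 1 > length(tb$map)) next
    idx <- (start0 + 1):min(end0, length(tb$map))
    tp <- tb$map[idx]
    tp <- tp[!is.na(tp)]
    if (!length(tp)) next
    lo <- min(tp); hi <- max(tp) + 1
    if (tb$t_strand == "-") {
      tmp <- tb$t_size - hi; hi <- tb$t_size - lo; lo <- tmp
    }
    hits[[length(hits) + 1L]] <- list(n = length(tp), chrom = tb$t_chrom,
                                      lo = lo, hi = hi)
  }
  if (!length(hits)) return(list(status = "unmapped", fraction = 0))
  if (length(hits) > 1L) return(list(status = "split", fraction = 0))
  h <- hits[[1L]]
  fr <- h$n / (end0 - start0)
  list(status = if (fr >= min_match) "mapped" else "low_match",
       fraction = fr, chrom = h$chrom, lo = h$lo, hi = h$hi)
}

# O(n^2) interval intersection oracle (>= min_overlap bp, 0-based half-open)
bf_overlap_any <- function(a_start, a_end, b_start, b_end, min_overlap = 1) {
  vapply(seq_along(a_start), function(i) {
    any(pmin(a_end[i], b_end) - pmax(a_start[i], b_start) >= min_overlap)
  }, TRUE)
}

# fractional-coverage oracle on 0-based half-open intervals: fraction of
# region i covered by the merged union of features
bf_cover_fraction <- function(r_start, r_end, f_start, f_end) {
  vapply(seq_along(r_start), function(i) {
    if (r_end[i] <= r_start[i]) return(0)
    pos <- r_start[i]:(r_end[i] - 1)
    covered <- vapply(pos, function(p) any(p >= f_start & p < f_end), TRUE)
    mean(covered)
  }, 0)
}

# direct Poisson upper-tail by term summation: P(X >= k), summing the
# upper-tail terms themselves so tiny tails keep full precision
bf_pois_upper <- function(k, lambda, kmax = 3000) {
  if (k <= 0) return(1)
  sum(dpois(k:max(kmax, k + 200), lambda))
}

# exhaustive-window occupancy oracle for small motifs
bf_occupancy <- function(sequence, wm, model) {
  s <- strsplit(toupper(sequence), "")[[1]]
  W <- wm$width
  r0 <- exp(model$r0_slope * W + model$r0_intercept)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  score_window <- function(win) {
    if (any(!win %in% c("A", "C", "G", "T"))) return(NA_real_)
    e <- 0
    for (j in seq_len(W)) {
      f <- wm$freqs[j, ]
      e <- e + log(max(f) / f[[win[j]]]) / model$lambda
    }
    r0 * exp(-e) / (1 + r0 * exp(-e))
  }
  total <- 0
  for (i in seq_len(length(s) - W + 1)) {
    win <- s[i:(i + W - 1)]
    win_rc <- rev(unname(rc[win]))
    pf <- score_window(win)
    pr <- score_window(win_rc)
    if (!is.na(pf)) total <- total + pf
    if (!is.na(pr)) total <- total + pr
  }
  total
}

# hand step-up BH oracle
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) {
    for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# random interval set on one chromosome (0-based half-open), for set-logic
# oracle comparisons
random_intervals <- function(n, genome_len = 10000, max_len = 300,
                             chrom = "chr1") {
  s <- sample.int(genome_len - max_len, n)
  w <- sample.int(max_len, n)
  GRanges(chrom, IRanges(s + 1, width = w))
}
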