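#' Filter raw MeDIP fragments
#'
#' Applies the standard alignment filters in sequence: drop fragments with
#' mapping quality below 10, drop fragments not flagged as a correctly
#' aligned pair, then collapse PCR duplicates by keeping exactly one
#' fragment per identical (chrom, start, end) group. Order-stable.
#'
#' @param fragments GRanges with metadata columns \code{quality} (numeric)
#'   and \code{proper} (logical; missing column means all proper).
#' @param species species label stored on the result.
#' @return \code{fragment_set}: list with \code{species}, \code{fragments}
#'   (filtered GRanges) and \code{total_retained}.
#' @export
filter_fragments <- function(fragments, species = "unknown") {
  q <- mcols(fragments)$quality
  if (is.null(q)) q <- rep(Inf, length(fragments))
  proper <- mcols(fragments)$proper
  if (is.null(proper)) proper <- rep(TRUE, length(fragments))
  keep <- q >= 10 & proper
  fr <- fragments[keep]
  key <- paste(seqnames(fr), start(fr), end(fr))
  fr <- fr[!duplicated(key)]
  structure(list(species = species, fragments = fr,
                 total_retained = length(fr)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", x$species, "-", x$total_retained,
      "retained fragments\n")
  invisible(x)
}

#' Library-size normalization to a reference total
#'
#' Rescales a raw count so libraries of different depth are comparable:
#' \code{reads / species_total * reference_total}.
#'
#' @param reads raw count(s) in a region.
#' @param species_total total retained fragments for that species' library.
#' @param reference_total total retained fragments of the reference library.
#' @export
normalize_to_reference <- function(reads, species_total, reference_total) {
  if (species_total <= 0) stop("species_total must be > 0")
  reads / species_total * reference_total
}

#' Binned fragment-midpoint coverage track
#'
#' @param fs \code{fragment_set} (or fragment GRanges).
#' @param bin_width bin width in bp (>= 1).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return \code{coverage_track}: bin width, per-chromosome midpoint count
#'   vectors, chromosome lengths and the library total. RPM values are
#'   \code{count * 1e6 / library_total}.
#' @export
rpm_track <- function(fs, bin_width, chrom_lengths) {
  stopifnot(bin_width >= 1)
  fr <- if (inherits(fs, "fragment_set")) fs$fragments else fs
  total <- length(fr)
  mid0 <- floor((start(fr) - 1 + end(fr)) / 2)  # 0-based midpoint
  chrom <- as.character(seqnames(fr))
  bins <- lapply(names(chrom_lengths), function(cn) {
    nb <- ceiling(chrom_lengths[[cn]] / bin_width)
    m <- mid0[chrom == cn]
    tabulate(pmin(floor(m / bin_width) + 1L, nb), nbins = nb)
  })
  names(bins) <- names(chrom_lengths)
  structure(list(bin_width = bin_width, bins = bins,
                 chrom_lengths = chrom_lengths, library_total = total),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$bins), "chromosome(s), bin",
      x$bin_width, "bp, library total", x$library_total, "\n")
  invisible(x)
}

# -10*log10(p) (or -log10) from a log-scale p-value; numerically safe
.score_from_logp <- function(log_p, score_scale) {
  s <- -log_p / log(10)
  if (score_scale == "minus10log10") s <- 10 * s
  s
}

#' Poisson sliding-window peak caller
#'
#' MACS-style fixed-window scan against a single genome-wide background
#' rate. A window of width \code{fraglen} (stepped one bin at a time) is
#' significant when the upper-tail Poisson probability
#' \eqn{P(X \ge k \mid \lambda = rate \times fraglen)} is below
#' \code{p_threshold}. Significant windows closer than \code{fraglen} are
#' merged into one peak; the peak score is the transformed p-value of its
#' best window (default \eqn{-10 \log_{10} p}) and the summit is the center
#' of the leftmost best window.
#'
#' @param track \code{coverage_track} built from fragment midpoints.
#' @param fraglen fragment length in bp (window width).
#' @param p_threshold per-window significance threshold (default 1e-3).
#' @param score_scale \code{"minus10log10"} (MACS convention, default) or
#'   \code{"minuslog10"}.
#' @return GRanges of peaks with \code{name}, \code{score}, \code{pvalue},
#'   \code{summit} (0-based offset in the peak) and \code{caller}.
#' @export
call_peaks_poisson <- function(track, fraglen, p_threshold = 1e-3,
                               score_scale = c("minus10log10", "minuslog10")) {
  score_scale <- match.arg(score_scale)
  stopifnot(inherits(track, "coverage_track"))
  bw <- track$bin_width
  total_bins <- sum(lengths(track$bins))
  if (total_bins == 0L) return(.empty_peaks())
  rate <- sum(vapply(track$bins, sum, 0)) / total_bins  # per bin
  wbins <- max(1L, as.integer(round(fraglen / bw)))
  lambda <- rate * wbins
  out <- list()
  for (cn in names(track$bins)) {
    v <- track$bins[[cn]]
    nb <- length(v)
    if (nb < wbins) next
    cum <- c(0, cumsum(v))
    nwin <- nb - wbins + 1L
    k <- cum[(wbins + 1L):(nb + 1L)] - cum[seq_len(nwin)]
    log_p <- ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE)
    sig <- which(log_p < log(p_threshold))
    if (!length(sig)) next
    win <- IRanges(start = (sig - 1L) * bw + 1L,
                   width = wbins * bw)
    merged <- reduce(win, min.gapwidth = fraglen)
    hits <- findOverlaps(win, merged)
    for (j in seq_along(merged)) {
      wi <- sig[queryHits(hits)[subjectHits(hits) == j]]
      lp <- log_p[wi]
      best <- wi[which.min(lp)]  # which.min returns leftmost tie
      summit_bp <- (best - 1L) * bw + floor(wbins * bw / 2)
      pk_start <- start(merged)[j]
      pk_end <- min(end(merged)[j], track$chrom_lengths[[cn]])
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = pk_start - 1L, end = pk_end,
        log_p = min(lp), summit = summit_bp - (pk_start - 1L))
    }
  }
  if (!length(out)) return(.empty_peaks())
  d <- do.call(rbind, out)
  gr <- gr0(d$chrom, d$start, d$end,
            name = paste0("pois_peak_", seq_len(nrow(d))),
            score = .score_from_logp(d$log_p, score_scale),
            pvalue = exp(d$log_p),
            summit = pmin(pmax(d$summit, 0L), d$end - d$start - 1L),
            caller = "poisson")
  seqlevels(gr) <- union(seqlevels(gr), names(track$bins))
  sort(gr, ignore.strand = TRUE)
}

.empty_peaks <- function() {
  gr <- GRanges()
  mcols(gr) <- S4Vectors::DataFrame(name = character(0), score = numeric(0),
                                    pvalue = numeric(0), summit = integer(0),
                                    caller = character(0))
  gr
}

#' Two-component Poisson mixture peak caller
#'
#' An independent second caller used for consensus confirmation. Bin counts
#' are modeled as a mixture of a background and an enriched Poisson
#' component, fitted by EM with deterministic moment-based initialization
#' (bins split at the overall mean). Bins with enriched-state posterior
#' above 0.5 are merged into peaks. If the fitted enriched mean is not at
#' least twice the background mean the fit is considered degenerate and no
#' peaks are returned. Scores are \eqn{-10\log_{10}(1 - posterior)} of the
#' best bin, capped at 1000.
#'
#' @param track \code{coverage_track} (>= 100 bins).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return GRanges of peaks (same columns as [call_peaks_poisson()]), with
#'   the mixture fit attached as attribute \code{fit}.
#' @export
call_peaks_posterior <- function(track, max_iter = 200L, tol = 1e-8) {
  stopifnot(inherits(track, "coverage_track"))
  counts <- unlist(track$bins, use.names = FALSE)
  if (length(counts) < 100L) stop("need >= 100 bins for the mixture fit")
  fit <- .fit_poisson_mixture(counts, max_iter, tol)
  empty <- .empty_peaks()
  attr(empty, "fit") <- fit
  if (!fit$usable) return(empty)
  out <- list()
  for (cn in names(track$bins)) {
    v <- track$bins[[cn]]
    post <- .posterior_enriched(v, fit)
    hot <- which(post > 0.5)
    if (!length(hot)) next
    bw <- track$bin_width
    runs <- reduce(IRanges(start = hot, width = 1L))
    for (j in seq_along(runs)) {
      idx <- start(runs)[j]:end(runs)[j]
      best <- idx[which.max(post[idx])]
      p_best <- post[best]
      pk_start <- (start(runs)[j] - 1L) * bw
      pk_end <- min(end(runs)[j] * bw, track$chrom_lengths[[cn]])
      score <- min(1000, -10 * log10(max(1 - p_best, 1e-300)))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = pk_start, end = pk_end, score = score,
        pvalue = 1 - p_best,
        summit = (best - 1L) * bw + floor(bw / 2) - pk_start)
    }
  }
  if (!length(out)) return(empty)
  d <- do.call(rbind, out)
  gr <- gr0(d$chrom, d$start, d$end,
            name = paste0("post_peak_", seq_len(nrow(d))),
            score = d$score, pvalue = d$pvalue,
            summit = pmin(pmax(d$summit, 0L), d$end - d$start - 1L),
            caller = "posterior")
  seqlevels(gr) <- union(seqlevels(gr), names(track$bins))
  gr <- sort(gr, ignore.strand = TRUE)
  attr(gr, "fit") <- fit
  gr
}

# deterministic EM for a two-component Poisson mixture
.fit_poisson_mixture <- function(counts, max_iter = 200L, tol = 1e-8) {
  m <- mean(counts)
  hi <- counts > m
  if (!any(hi) || all(hi) || stats::var(counts) == 0) {
    return(list(usable = FALSE, mu_bg = m, mu_en = m, pi_en = 0,
                loglik = NA_real_, converged = TRUE))
  }
  mu_bg <- mean(counts[!hi]); mu_en <- mean(counts[hi])
  pi_en <- mean(hi)
  mu_bg <- max(mu_bg, 1e-6); mu_en <- max(mu_en, mu_bg + 1e-6)
  # EM over the count histogram (counts are small integers)
  tab <- table(counts)
  k <- as.numeric(names(tab)); w <- as.numeric(tab)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    l_bg <- log(1 - pi_en) + dpois(k, mu_bg, log = TRUE)
    l_en <- log(pi_en) + dpois(k, mu_en, log = TRUE)
    mx <- pmax(l_bg, l_en)
    ll <- sum(w * (mx + log(exp(l_bg - mx) + exp(l_en - mx))))
    r_en <- 1 / (1 + exp(l_bg - l_en))
    pi_en <- sum(w * r_en) / sum(w)
    mu_en <- sum(w * r_en * k) / max(sum(w * r_en), 1e-12)
    mu_bg <- sum(w * (1 - r_en) * k) / max(sum(w * (1 - r_en)), 1e-12)
    if (mu_en < mu_bg) {  # keep component identity stable
      tmp <- mu_en; mu_en <- mu_bg; mu_bg <- tmp
      pi_en <- 1 - pi_en
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("mixture EM did not converge in ", max_iter,
            " iterations; using best iterate")
  }
  list(usable = mu_en >= 2 * mu_bg && pi_en > 0 && pi_en < 1,
       mu_bg = mu_bg, mu_en = mu_en, pi_en = pi_en,
       loglik = ll_old, converged = converged)
}

.posterior_enriched <- function(counts, fit) {
  l_bg <- log(1 - fit$pi_en) + dpois(counts, fit$mu_bg, log = TRUE)
  l_en <- log(fit$pi_en) + dpois(counts, fit$mu_en, log = TRUE)
  1 / (1 + exp(l_bg - l_en))
}

#' Dual-caller consensus
#'
#' Keeps the peaks of caller A that are confirmed by at least
#' \code{min_overlap} bp of overlap with any peak of caller B. A's
#' coordinates and scores are retained unchanged.
#'
#' @param peaks_a,peaks_b peak GRanges on the same build.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return subset of \code{peaks_a}.
#' @export
consensus <- function(peaks_a, peaks_b, min_overlap = 1L) {
  if (!length(peaks_b)) return(peaks_a[0])
  peaks_a[countOverlaps(peaks_a, peaks_b, minoverlap = min_overlap) > 0L]
}

#' Count fragments whose midpoint falls inside each region
#' @param fs fragment_set or fragment GRanges.
#' @param regions GRanges.
#' @return integer vector, one count per region.
#' @export
count_fragments_in <- function(fs, regions) {
  fr <- if (inherits(fs, "fragment_set")) fs$fragments else fs
  mid0 <- floor((start(fr) - 1 + end(fr)) / 2)
  mids <- GRanges(seqnames(fr), IRanges(mid0 + 1L, width = 1L))
  countOverlaps(regions, mids)
}
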