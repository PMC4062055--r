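make_frags <- function(starts, ends, quality = 30, proper = TRUE,
                       chrom = "chr1") {
  GRanges(chrom, IRanges(starts, ends),
          quality = rep_len(quality, length(starts)),
          proper = rep_len(proper, length(starts)))
}

test_that("fragment filtering applies quality, pairing and dedup rules", {
  fr <- make_frags(c(10, 10, 10), c(200, 200, 200))
  expect_equal(filter_fragments(fr)$total_retained, 1L)

  fr <- make_frags(1:5 * 100, 1:5 * 100 + 150, quality = 0)
  expect_equal(filter_fragments(fr)$total_retained, 0L)

  # mixed set of 10: 2 low-quality, 1 improper pair, 2 duplicates of kept
  # fragments -> brute-force application of the three rules leaves 6
  starts <- c(100, 300, 500, 700, 900, 1100, 1300, 100, 1700, 1500)
  ends <- starts + 180
  q <- c(30, 30, 5, 30, 9, 30, 30, 30, 30, 30)
  proper <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  fr <- make_frags(starts, ends, q, proper)
  keep <- q >= 10 & proper
  dedup <- !duplicated(paste(starts, ends)[keep])
  expect_equal(sum(dedup), 6L)
  fs <- filter_fragments(fr)
  expect_equal(fs$total_retained, 6L)
  # order-stable: first occurrence survives
  expect_equal(start(fs$fragments), starts[keep][dedup])
})

test_that("normalization to the reference total follows the formula", {
  expect_equal(normalize_to_reference(50, 1e6, 2e6), 100)
  expect_equal(normalize_to_reference(0, 1e6, 2e6), 0)
  expect_equal(normalize_to_reference(123, 5e5, 5e5), 123)
  expect_error(normalize_to_reference(10, 0, 1e6), "species_total")
})

test_that("coverage track counts midpoints and conserves totals", {
  cl <- c(chr1 = 10000)
  fr <- make_frags(1, 100)
  tr <- rpm_track(filter_fragments(fr), 50, cl)
  expect_equal(sum(tr$bins$chr1), 1L)
  expect_equal(max(tr$bins$chr1) * 1e6 / tr$library_total, 1e6)

  # uniform 100 fragments, one per 100-bp bin -> rpm 1e4 each
  fr <- make_frags(0:99 * 100 + 1, 0:99 * 100 + 60)
  tr <- rpm_track(filter_fragments(fr), 100, cl)
  expect_true(all(tr$bins$chr1 == 1L))
  expect_equal(unique(tr$bins$chr1 * 1e6 / tr$library_total), 1e4)

  set.seed(3)
  s <- sample.int(9000, 500)
  fr <- make_frags(s, s + 150)
  fs <- filter_fragments(fr)
  tr <- rpm_track(fs, 37, cl)
  expect_equal(sum(tr$bins$chr1), fs$total_retained)
})

test_that("Poisson caller matches direct tail summation and examples", {
  # tail probabilities to 1e-12 against term-by-term summation
  for (lam in c(0.5, 1, 4, 12.3)) {
    for (k in c(1, 3, 8, 20, 50)) {
      expect_equal(ppois(k - 1, lam, lower.tail = FALSE),
                   bf_pois_upper(k, lam), tolerance = 1e-12)
    }
  }
  # window count 8 at lambda 1: p ~ 1.02e-5, score ~ 49.9
  p8 <- bf_pois_upper(8, 1)
  expect_equal(p8, 1.0219e-5, tolerance = 1e-3)
  expect_equal(-10 * log10(p8), 49.9, tolerance = 0.05)

  # homogeneous background -> no peaks
  cl <- c(chr1 = 50000)
  set.seed(11)
  starts <- sample.int(49800, 3000)
  tr <- rpm_track(make_frags(starts, starts + 199), 50, cl)
  expect_length(call_peaks_poisson(tr, 200), 0)
})

test_that("Poisson caller calls and merges enriched windows correctly", {
  cl <- c(chr1 = 100000)
  set.seed(12)
  bg <- sample.int(99800, 4000)
  # two hot spots separated by 3x fraglen of background
  hot1 <- round(rnorm(200, 20000, 60))
  hot2 <- round(rnorm(200, 20000 + 4 * 200 + 800, 60))
  starts <- c(bg, hot1, hot2)
  tr <- rpm_track(make_frags(starts, starts + 199), 50, cl)
  pk <- call_peaks_poisson(tr, 200)
  # the two hot spots give exactly two distinct peaks, never merged
  near <- pk[overlapsAny(pk, gr0("chr1", 19000, 23500))]
  expect_equal(length(near), 2L)
  expect_true(all(mcols(pk)$score > 0))
  expect_true(all(mcols(pk)$summit >= 0 &
                    mcols(pk)$summit < width(pk)))
  # summit near the planted centers
  expect_lt(abs(start(near)[1] + mcols(near)$summit[1] - 20000), 300)
  # score equals the transformed minimum window p
  expect_equal(mcols(pk)$score,
               -10 * log10(mcols(pk)$pvalue), tolerance = 1e-9)
})

test_that("mixture caller is deterministic and recovers parameters", {
  cl <- c(chr1 = 60000)
  # degenerate: identical counts -> 2x-mean guard -> no peaks
  fr <- make_frags(0:1199 * 50 + 1, 0:1199 * 50 + 40)
  tr <- rpm_track(filter_fragments(fr), 50, cl)
  expect_length(call_peaks_posterior(tr), 0)

  # bimodal counts: 95% Pois(1), 5% Pois(20)
  set.seed(21)
  nbin <- 1200
  enriched <- seq_len(nbin) %in% sample.int(nbin, 60)
  counts <- ifelse(enriched, rpois(nbin, 20), rpois(nbin, 1))
  starts <- rep((seq_len(nbin) - 1) * 50 + 10, counts)
  tr <- rpm_track(make_frags(starts, starts + 20), 50, cl)
  pk <- call_peaks_posterior(tr)
  fit <- attr(pk, "fit")
  expect_true(fit$usable)
  expect_lt(abs(fit$mu_bg - 1) / 1, 0.1)
  expect_lt(abs(fit$mu_en - 20) / 20, 0.1)
  expect_lt(abs(fit$pi_en - 0.05) / 0.05, 0.5)
  # the enriched bins are the called ones
  called_bins <- unique(unlist(lapply(seq_along(pk), function(i) {
    (floor((start(pk)[i] - 1) / 50) + 1):ceiling(end(pk)[i] / 50)
  })))
  expect_gt(mean(which(enriched & counts >= 10) %in% called_bins), 0.95)

  pk2 <- call_peaks_posterior(tr)
  expect_identical(granges(pk), granges(pk2))  # deterministic

  expect_error(call_peaks_posterior(
    rpm_track(make_frags(1, 100), 50, c(chr1 = 1000))), ">= 100 bins")
})

test_that("EM beats a coarse grid search on the same likelihood", {
  set.seed(31)
  counts <- c(rpois(950, 2), rpois(50, 15))
  ll <- function(mu0, mu1, pi1) {
    sum(log((1 - pi1) * dpois(counts, mu0) + pi1 * dpois(counts, mu1)))
  }
  grid <- expand.grid(mu0 = seq(1, 4, 0.25), mu1 = seq(8, 22, 0.5),
                      pi1 = c(0.02, 0.05, 0.1))
  best <- max(mapply(ll, grid$mu0, grid$mu1, grid$pi1))
  tr <- rpm_track(make_frags(rep(seq_along(counts) * 50 - 25, counts),
                             rep(seq_along(counts) * 50 - 5, counts)),
                  50, c(chr1 = 50000))
  fit <- attr(call_peaks_posterior(tr), "fit")
  expect_gte(fit$loglik + 1e-6, best)
})

test_that("consensus keeps confirmed A-peaks and is idempotent", {
  a <- gr0("chr1", c(0, 1000, 5000), c(500, 1400, 5600),
           score = c(10, 20, 30))
  expect_length(consensus(a, GRanges()), 0)
  expect_identical(consensus(a, a), a)

  set.seed(41)
  x <- random_intervals(80)
  y <- random_intervals(50)
  got <- consensus(x, y)
  want <- x[bf_overlap_any(start(x) - 1, end(x), start(y) - 1, end(y))]
  expect_identical(got, want)
  expect_identical(consensus(consensus(x, y), y), consensus(x, y))
})
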