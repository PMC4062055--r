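uniform_wm <- function(W = 1) {
  weight_matrix("flat", matrix(1, W, 4))
}

test_that("occupancy of a width-1 uniform motif is closed-form", {
  model <- affinity_model()
  wm <- uniform_wm(1)
  r0 <- exp(model$r0_slope * 1 + model$r0_intercept)
  L <- 20
  seqs <- paste(rep("A", L), collapse = "")
  expect_equal(expected_occupancy(seqs, wm, model),
               2 * L * r0 / (1 + r0), tolerance = 1e-12)
  # all-N sequence: no scorable window
  expect_equal(expected_occupancy(strrep("N", 10), wm, model), 0)
  expect_error(expected_occupancy("AC", uniform_wm(3), model), "shorter")
})

test_that("occupancy equals exhaustive window enumeration", {
  model <- affinity_model()
  set.seed(71)
  for (W in 2:4) {
    counts <- matrix(rpois(4 * W, 5), W, 4)
    wm <- weight_matrix(paste0("m", W), counts)
    for (rep in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
      expect_equal(expected_occupancy(s, wm, model),
                   bf_occupancy(s, wm, model), tolerance = 1e-9)
    }
  }
})

test_that("occupancy is reverse-complement invariant and monotone", {
  model <- affinity_model()
  set.seed(72)
  wm <- weight_matrix("m", matrix(rpois(4 * 6, 4) + 1, 6, 4))
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(expected_occupancy(s, wm, model),
                 expected_occupancy(rc, wm, model), tolerance = 1e-9)
  }
  # mutating one window base toward the consensus never lowers occupancy
  # (checked on a palindromic matrix: both strands move together, so the
  # window-level monotonicity shows in the strand-summed total)
  half <- matrix(rpois(4 * 3, 4) + 1, 3, 4)
  pal <- rbind(half, half[3:1, 4:1])
  wmp <- weight_matrix("pal", pal)
  cons <- apply(wmp$freqs, 1, which.max)
  s <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
  for (j in 1:6) {
    chars <- strsplit(s, "")[[1]]
    chars[j] <- c("A", "C", "G", "T")[cons[j]]
    s2 <- paste(chars, collapse = "")
    expect_gte(expected_occupancy(s2, wmp, model) + 1e-12,
               expected_occupancy(s, wmp, model))
    s <- s2
  }
})

test_that("aggregate p-values follow the (r+1)/(B+1) tie convention", {
  # an exactly-representable occupancy (E = 0, R0 = 1 -> each window
  # contributes exactly 1.0) makes the tie comparison exact
  model <- affinity_model(r0_slope = 0, r0_intercept = 0)
  wm <- uniform_wm(2)
  regions <- c(strrep("ACGT", 20), strrep("GGCC", 15))
  # background identical to the observed regions: every draw ties
  same_len_pool <- c(strrep("ACGT", 20), strrep("GGCC", 15))
  out <- region_set_pvalue(regions, wm, same_len_pool, model, B = 37,
                           seed = 2)
  expect_equal(out$p, 1.0)

  # observed strictly above every null draw
  model <- affinity_model()
  strong <- weight_matrix("s", matrix(c(20, 1, 1, 1), 1, 4,
                                      byrow = TRUE))
  obs_regions <- strrep("A", 100)
  bg <- strrep("C", 2000)
  out <- region_set_pvalue(obs_regions, strong, bg, model, B = 999,
                           seed = 3)
  expect_equal(out$p, 1 / 1000)
  expect_error(region_set_pvalue(strrep("A", 5001), strong, bg, model),
               "5 kb")
})

test_that("BH adjustment equals the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  set.seed(73)
  for (n in c(1, 2, 5, 10)) {
    p <- runif(n)
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
  }
  # monotone, elementwise >= input, order preserved
  p <- runif(10)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in input ranks
})

test_that("divergence map computes deltas and consistency flags", {
  tab <- data.frame(motif = c("a", "b", "c"),
                    p_human = c(0.05, 1e-3, 1e-4),
                    p_chimp = c(0.05, 0.1, 1e-4),
                    p_macaque = c(0.05, 0.1, 0.05))
  dm <- divergence_map(tab)
  expect_equal(dm$d_hc, c(0, 2, 0))
  expect_equal(dm$d_hm[2], 2)
  expect_equal(dm$consistent, c(FALSE, TRUE, FALSE))
  expect_equal(dm$direction[2], "gain")

  # randomized inputs against direct rule application
  set.seed(74)
  tab <- data.frame(motif = paste0("m", 1:50),
                    p_human = 10^-runif(50, 0, 4),
                    p_chimp = 10^-runif(50, 0, 4),
                    p_macaque = 10^-runif(50, 0, 4))
  dm <- divergence_map(tab, threshold = 1)
  dhc <- -log10(tab$p_human) + log10(tab$p_chimp)
  dhm <- -log10(tab$p_human) + log10(tab$p_macaque)
  want <- sign(dhc) == sign(dhm) & sign(dhc) != 0 &
    pmin(abs(dhc), abs(dhm)) >= 1
  expect_equal(dm$consistent, want)

  # p = 0 clamped and flagged
  dm0 <- divergence_map(data.frame(motif = "z", p_human = 0,
                                   p_chimp = 0.5, p_macaque = 0.5))
  expect_true(dm0$clamped)
  expect_true(is.finite(dm0$d_hc))
})

test_that("null divergence flags fewer than 5 percent of motifs", {
  model <- affinity_model()
  motifs <- demo_motifs()
  set.seed(75)
  pool <- vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  }, "")
  # three "species" sets drawn from the same null pool
  rows <- lapply(names(motifs)[1:10], function(mn) {
    wm <- motifs[[mn]]
    idx <- affinity_index(wm, pool, model)
    ps <- vapply(1:3, function(sp) {
      region_set_pvalue(pool[sample.int(40, 8)], wm, idx, model, B = 49,
                        seed = 75 + sp)$p
    }, 0)
    data.frame(motif = mn, p_human = ps[1], p_chimp = ps[2],
               p_macaque = ps[3])
  })
  dm <- divergence_map(do.call(rbind, rows))
  expect_lt(mean(dm$consistent), 0.25)  # 10 motifs: at most 2 by chance
})

test_that("empirical directional p follows the pooled-draw convention", {
  model <- affinity_model()
  wm <- uniform_wm(2)
  set.seed(76)
  pool <- vapply(1:12, function(i) {
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  }, "")
  # an observed divergence far beyond anything a uniform motif can give:
  # no draw exceeds it, p = 1/(N+1)
  obs <- list(d_hc = 50, d_hm = 50)
  out <- empirical_directional_p(obs, pool, pool, pool, set_size = 4,
                                 wm = wm, background = pool, model = model,
                                 reps = 2, n = 10, B = 19, seed = 5)
  expect_equal(out$n_draws, 20)
  expect_equal(out$p, 1 / 21)

  # near-null observed divergence on a null fixture: p comfortably > 0.1
  # (a structured motif so per-draw p-values actually vary)
  wm2 <- weight_matrix("s2", matrix(rpois(4 * 4, 4) + 1, 4, 4))
  obs0 <- list(d_hc = 1e-6, d_hm = 1e-6)
  out0 <- empirical_directional_p(obs0, pool, pool, pool, set_size = 4,
                                  wm = wm2, background = pool,
                                  model = model, reps = 2, n = 25, B = 19,
                                  seed = 6)
  expect_gt(out0$p, 0.1)
  expect_error(
    empirical_directional_p(obs, pool, pool, pool, 4, wm, pool, model,
                            reps = 1, n = 0), "positive")
})

test_that("the screen flags a planted single-base human motif gain", {
  trio <- small_trio()
  ms <- trio$motif_site
  trips <- orthologous_sequences(ms$region, trio)
  expect_length(trips, 1)
  motifs <- demo_motifs()
  # background: island sequences elsewhere in the genome
  isl <- trio$annotations$islands
  isl <- isl[!overlapsAny(isl, ms$region)]
  bg <- vapply(seq_along(isl), function(k) {
    cn <- as.character(seqnames(isl))[k]
    as.character(Biostrings::subseq(trio$genomes$human[[cn]],
                                    start(isl)[k], end(isl)[k]))
  }, "")
  scr <- mdr_screen(trips[[1]], motifs["RFX_like_01"], bg,
                    B = 199, seed = 9)
  expect_equal(scr$call, "human_gain")
  expect_lt(scr$p_human, 0.05)
  expect_gte(scr$p_chimp, 0.05)
  expect_gte(scr$p_macaque, 0.05)

  # identical sequences -> never flagged
  trip0 <- region_triplet("t", trips[[1]]$seqs[["chimp"]],
                          trips[[1]]$seqs[["chimp"]],
                          trips[[1]]$seqs[["chimp"]])
  scr0 <- mdr_screen(trip0, motifs["RFX_like_01"], bg, B = 199, seed = 9)
  expect_equal(scr0$call, "none")
  expect_equal(nrow(mdr_screen(trips[[1]], list(), bg)), 0L)
})

test_that("orthologous identity counts matching aligned columns", {
  ident <- toy_chain(list(c(200)))
  g <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")))
  expect_equal(orthologous_identity(gr0("chr1", 50, 150), ident, g, g), 100)

  g2 <- g
  chars <- strsplit(as.character(g2[[1]]), "")[[1]]
  chars[100] <- setdiff(c("A", "C", "G", "T"), chars[100])[1]
  g2 <- Biostrings::DNAStringSet(stats::setNames(
    paste(chars, collapse = ""), "chr1"))
  expect_equal(orthologous_identity(gr0("chr1", 50, 150), ident, g, g2), 99)
  expect_error(orthologous_identity(gr0("chr2", 0, 10), ident, g, g),
               "aligned columns")
})
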