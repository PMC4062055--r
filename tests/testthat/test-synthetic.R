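zero_edit_config <- function(seed = 2L) {
  cfg <- small_trio_config(seed)
  cfg$branch$chimp$sub_rate <- 0
  cfg$branch$chimp$indel_rate <- 0
  cfg$branch$macaque$sub_rate <- 0
  cfg$branch$macaque$indel_rate <- 0
  cfg$plant_motif <- FALSE
  cfg
}

test_that("zero edit rates give identical genomes and identity chains", {
  trio <- generate_trio(zero_edit_config())
  expect_identical(as.character(trio$genomes$human),
                   as.character(trio$genomes$chimp))
  expect_identical(as.character(trio$genomes$human),
                   as.character(trio$genomes$macaque))
  for (cs in trio$chains) {
    for (ch in cs$chains) {
      expect_equal(nrow(ch$blocks), 1L)
      expect_equal(ch$blocks$size, ch$s_end - ch$s_start)
    }
  }
})

test_that("k indels produce k + 1 aligned chain blocks", {
  seqv <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  indels <- data.frame(pos = c(50, 200, 310), len = c(3, 5, 2),
                       type = c("del", "ins", "del"))
  ap <- triodmr:::.apply_edits(seqv, integer(0), indels)
  expect_equal(nrow(ap$blocks), 4L)
  expect_equal(sum(ap$blocks$size) + sum(ap$blocks$ds), 500)
  expect_equal(sum(ap$blocks$size) + sum(ap$blocks$dt), length(ap$seq))
  # deletions shorten, insertions lengthen
  expect_equal(length(ap$seq), 500 - 3 - 2 + 5)
})

test_that("the same seed reproduces every artifact byte-identically", {
  cfg <- small_trio_config(seed = 9L)
  d1 <- file.path(tempdir(), "trio_a")
  d2 <- file.path(tempdir(), "trio_b")
  write_trio(generate_trio(cfg), d1)
  write_trio(generate_trio(cfg), d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the genome
  cfg2 <- small_trio_config(seed = 10L)
  trio2 <- generate_trio(cfg2)
  expect_false(identical(as.character(trio2$genomes$human),
                         as.character(generate_trio(cfg)$genomes$human)))
})

test_that("planted truth follows class semantics and never overlaps", {
  trio <- small_trio()
  truth <- trio$truth
  md <- mcols(truth)
  hi <- trio$config$sdmrs$level_high
  lo <- trio$config$sdmrs$level_low
  for (i in seq_along(truth)) {
    lv <- c(md$level_human[i], md$level_chimp[i], md$level_macaque[i])
    want <- switch(md$class[i],
      human_hypo = c(lo, hi, hi),
      human_hyper = c(hi, lo, lo),
      chimp_only = c(lo, hi, lo),
      shared_methylated = c(hi, hi, hi),
      unmethylated_background = c(lo, lo, lo))
    expect_equal(lv, want)
  }
  # mutually exclusive in reference coordinates
  expect_equal(sum(countOverlaps(truth, truth) != 1L), 0L)
  # island-placed regions live in islands; shore regions in the 2-kb band
  isl <- trio$annotations$islands
  sh <- make_shores(isl, 2000, trio$config$chrom_lengths)
  in_isl <- overlap_fraction(truth, isl)
  expect_true(all(in_isl[md$placement == "island"] == 1))
  expect_true(all(overlap_fraction(truth[md$placement == "shore"], sh) == 1))
  expect_true(all(in_isl[md$placement == "open"] == 0))
})

test_that("zero planted regions give a pure-background landscape", {
  cfg <- zero_edit_config()
  cfg$sdmrs$n_hypo <- 0; cfg$sdmrs$n_hyper <- 0
  cfg$sdmrs$n_chimp_only <- 0; cfg$sdmrs$n_shared <- 0
  cfg$sdmrs$n_background <- 0
  trio <- generate_trio(cfg)
  expect_length(trio$truth, 0)
  expect_length(trio$landscape$human$regions, 0)
  expect_equal(trio$landscape$human$baseline, cfg$baseline_methylation)
})

test_that("fragment simulation respects coverage, artifacts and edges", {
  trio <- small_trio()
  expect_length(
    simulate_medip(trio$genomes$human, trio$landscape$human, coverage = 0),
    0)

  fr <- simulate_medip(trio$genomes$human, trio$landscape$human,
                       coverage = 5, dup_frac = 0.05, lowq_frac = 0.04,
                       improper_frac = 0.03, seed = 3)
  gl <- sum(trio$chrom_lengths$human)
  expect_equal(length(fr), round(5 * gl / 200) * 1.05, tolerance = 0.01)
  expect_equal(mean(mcols(fr)$quality < 10), 0.04 * (1 / 1.05),
               tolerance = 0.25)
  expect_gt(sum(duplicated(paste(seqnames(fr), start(fr), end(fr)))),
            0.8 * 0.05 * 5 * gl / 200)
  expect_true(all(end(fr) <= rep(
    trio$chrom_lengths$human[as.character(seqnames(fr))])))

  # mismatched landscape -> error
  bad <- meth_landscape(0.05, GRanges("chrZ", IRanges(1, 10), level = 1))
  expect_error(simulate_medip(trio$genomes$human, bad, 1), "absent")
})

test_that("library totals differ across species by design", {
  trio <- small_trio()
  raw <- simulate_trio_medip(trio)
  n <- vapply(raw, length, 0)
  expect_gt(abs(n[["chimp"]] - n[["human"]]) / n[["human"]], 0.05)
  expect_gt(abs(n[["macaque"]] - n[["human"]]) / n[["human"]], 0.05)
})

test_that("background-only coverage is Poisson-homogeneous", {
  set.seed(13)
  genome <- Biostrings::DNAStringSet(c(chrU = paste(
    sample(c("A", "C", "G", "T"), 150e3, replace = TRUE), collapse = "")))
  land <- meth_landscape(0)   # nothing methylated anywhere
  pvals <- vapply(1:8, function(s) {
    fr <- simulate_medip(genome, land, coverage = 10, dup_frac = 0,
                         lowq_frac = 0, improper_frac = 0, seed = 100 + s)
    tr <- rpm_track(filter_fragments(fr), 200, c(chrU = 150e3))
    counts <- tr$bins$chrU
    counts <- counts[2:(length(counts) - 2)]  # trim edge bins
    lam <- mean(counts)
    # chi-square GOF against Poisson(lam), bins pooled at >= 5 expected
    br <- c(-0.5, seq(floor(lam - 3 * sqrt(lam)),
                      ceiling(lam + 3 * sqrt(lam))), Inf)
    obs <- table(cut(counts, br))
    exp_p <- diff(ppois(br, lam))
    keep <- exp_p * length(counts) >= 5
    suppressWarnings(chisq.test(obs[keep], p = exp_p[keep],
                                rescale.p = TRUE))$p.value
  }, 0)
  expect_gte(mean(pvals > 0.01), 7 / 8)
})

test_that("a fully methylated island is recovered by the Poisson caller", {
  set.seed(14)
  base <- sample(c("A", "C", "G", "T"), 120e3, replace = TRUE)
  isl <- rep(c("C", "G"), 500)   # 1-kb CpG-saturated island at 60-61 kb
  base[60001:61000] <- isl
  genome <- Biostrings::DNAStringSet(c(chrI = paste(base, collapse = "")))
  land <- meth_landscape(0, GRanges("chrI", IRanges(60001, 61000),
                                    level = 1))
  hits <- vapply(1:10, function(s) {
    fr <- simulate_medip(genome, land, coverage = 30,
                         enrichment_factor = 8, dup_frac = 0,
                         lowq_frac = 0, improper_frac = 0, seed = 200 + s)
    pk <- call_peaks_poisson(rpm_track(filter_fragments(fr), 50,
                                       c(chrI = 120e3)), 200)
    sum(countOverlaps(GRanges("chrI", IRanges(60001, 61000)), pk)) > 0
  }, TRUE)
  expect_true(all(hits))
})

test_that("the planted motif locus differs between species as designed", {
  trio <- small_trio()
  ms <- trio$motif_site
  expect_false(is.null(ms))
  h <- as.character(Biostrings::subseq(trio$genomes$human[[ms$chrom]],
                                       ms$start, ms$start + ms$width - 1))
  expect_equal(h, triodmr:::.RFX_CONSENSUS)
  # both branch genomes carry the single-base weakening edit
  for (sp in c("chimp", "macaque")) {
    m <- liftover_map(GRanges(ms$chrom, IRanges(ms$edit_pos, ms$edit_pos)),
                      trio$chains[[paste0("human_", sp)]])
    b <- as.character(Biostrings::subseq(
      trio$genomes[[sp]][[m$t_chrom]], m$t_start + 1, m$t_end))
    expect_equal(b, ms$alt_base)
    expect_false(b == ms$ref_base)
  }
})

test_that("orthologous identity tracks the branch substitution rate", {
  trio <- small_trio()
  sub_rate <- trio$config$branch$chimp$sub_rate
  set.seed(15)
  ids <- vapply(1:40, function(i) {
    s0 <- sample.int(200e3, 1)
    orthologous_identity(gr0("chrA", s0, s0 + 2000),
                         trio$chains$human_chimp,
                         trio$genomes$human, trio$genomes$chimp)
  }, 0)
  # planted regions are edit-free, so genome-wide identity is slightly
  # above 100 * (1 - r); allow 2 SE around the expectation
  p_hat <- mean(ids) / 100
  se <- sqrt(sub_rate * (1 - sub_rate) / (40 * 2000))
  expect_lt(abs((1 - p_hat) - sub_rate), 2 * se + 0.1 * sub_rate)
})
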