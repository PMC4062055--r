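toy_genes <- function() {
  data.frame(
    transcript_id = c("TXA-001", "TXA-002", "TXB-001", "TXC-001"),
    gene_id = c("GA", "GA2", "GB", "GC"),
    chrom = "chr1", strand = c("+", "-", "+", "+"),
    tss = c(10500, 10600, 50000, 90000),
    promoter_start = c(9500, 9600, 49000, 89000),
    promoter_end = c(11500, 11600, 51000, 91000))
}

test_that("promoter s-DMR transcript selection joins through islands", {
  genes <- toy_genes()
  islands <- gr0("chr1", c(10000, 49500), c(11000, 50500))
  # one s-DMR in the first (bidirectional) promoter island
  sdmr <- gr0("chr1", 10200, 10800, class = "hypo")
  got <- promoter_sdmr_transcripts(sdmr, genes, islands)
  expect_setequal(got, c("TXA-001", "TXA-002"))

  expect_length(promoter_sdmr_transcripts(GRanges(), genes, islands), 0)
  far <- gr0("chr1", 200000, 200600)
  expect_length(promoter_sdmr_transcripts(far, genes, islands), 0)

  # brute-force join oracle on random fixtures
  set.seed(81)
  for (rep in 1:5) {
    isl <- random_intervals(12, 50000, 800)
    sd <- random_intervals(15, 50000, 500)
    tss <- sample.int(48000, 8)
    g <- data.frame(transcript_id = paste0("T", 1:8), gene_id = "g",
                    chrom = "chr1", strand = "+", tss = tss,
                    promoter_start = pmax(1, tss - 1000),
                    promoter_end = tss + 1000)
    want <- vapply(seq_len(8), function(i) {
      p_s <- g$promoter_start[i]; p_e <- g$promoter_end[i]
      any(vapply(seq_along(isl), function(k) {
        is_s <- max(p_s, start(isl)[k]); is_e <- min(p_e, end(isl)[k])
        is_s <= is_e &&
          any(start(sd) <= is_e & end(sd) >= is_s)
      }, TRUE))
    }, TRUE)
    got <- promoter_sdmr_transcripts(sd, g, isl)
    expect_setequal(got, g$transcript_id[want])
  }
})

test_that("exon scores take the maximum overlapping peak score or zero", {
  exons <- gr0("chr1", c(1000, 3000), c(1500, 3600), transcript_id = "t")
  expect_equal(exon_score(exons, GRanges()), 0)
  pk1 <- gr0("chr1", 1200, 1300, score = 17.5)
  expect_equal(exon_score(exons, pk1), 17.5)
  pk2 <- gr0("chr1", c(1200, 3100), c(1300, 3200), score = c(10, 40))
  expect_equal(exon_score(exons, pk2), 40)
  # peaks not touching any exon score zero
  pk3 <- gr0("chr1", 2000, 2500, score = 99)
  expect_equal(exon_score(exons, pk3), 0)
  # unmappable exons score zero with a warning
  off_chain <- toy_chain(list(c(100)), s_chrom = "chrZ")
  expect_warning(s <- exon_score(exons, pk2, off_chain), "mappable")
  expect_equal(s, 0)
})

test_that("differentials and fold ratios reproduce the published rows", {
  # transcript-level exon scores printed for the bidirectional-promoter
  # locus: the reverse-strand neighbor transcripts
  d1 <- differentials(47.6, 205.6, 155.5)
  expect_equal(unname(d1["d_hc"]), -158.0)
  d2 <- differentials(83.4, 374.1, 391.4)
  expect_equal(unname(d2["d_hm"]), -308.0)
  expect_equal(differentials(0, 0, 0), c(d_hc = 0, d_hm = 0, d_havg = 0))

  # the receptor-gene major isoform: 1.29-fold at two decimals
  expect_equal(round(fold_ratio(2943.7, 2397.8, 2180.8), 2), 1.29)
  expect_equal(fold_ratio(5, 5, 5), 1)
  expect_equal(fold_ratio(0, 3, 5), 0)
  expect_true(is.na(fold_ratio(10, 0, 0)))
})

test_that("published six-row table ranks the receptor isoform first", {
  tab <- data.frame(
    transcript_id = c("LTB4R-001", "CIDEB-001", "CIDEB-201", "CIDEB-002",
                      "LTB4R2-002", "LTB4R2-201"),
    score_h = c(2943.7, 47.6, 47.6, 83.4, 0, 0),
    score_c = c(2397.8, 205.6, 205.6, 374.1, 456.6, 456.6),
    score_m = c(2180.8, 155.5, 155.5, 391.4, 477.1, 477.1))
  rk <- rank_records(tab, "hypo")
  expect_equal(rk$transcript_id[1], "LTB4R-001")
  expect_equal(rk$d_havg[1], 654.45, tolerance = 0.11 / 654)
  # printed pairwise differentials within the table's rounding slack
  expect_lt(max(abs(rk$d_hc[rk$transcript_id == "CIDEB-002"] - (-290.8))),
            0.11)
  # ties break lexicographically
  tied <- data.frame(transcript_id = c("b", "a", "c"),
                     score_h = 5, score_c = 5, score_m = 5)
  expect_equal(rank_records(tied, "hypo")$transcript_id, c("a", "b", "c"))
  # hyper sets rank ascending
  rk2 <- rank_records(tab, "hyper")
  expect_equal(rk2$transcript_id[1], "LTB4R2-002")
  empty <- rank_records(tab[0, ], "hypo")
  expect_equal(nrow(empty), 0L)
})

test_that("differentials agree with recomputation from exon scores", {
  set.seed(82)
  exons <- gr0("chr1", c(1000, 4000, 8000), c(1800, 4700, 8900),
               transcript_id = "t")
  peaks <- lapply(1:3, function(i) {
    s <- sample.int(9000, 6)
    gr0("chr1", s, s + 500, score = round(runif(6, 0, 300), 1))
  })
  names(peaks) <- c("human", "chimp", "macaque")
  ident <- toy_chain(list(c(20000)))
  chains <- list(human_chimp = ident, human_macaque = ident)
  sc <- score_transcripts("t", exons, peaks, chains)
  rk <- rank_records(sc, "hypo")
  d <- differentials(sc$score_h, sc$score_c, sc$score_m)
  expect_equal(rk$d_havg, unname(d["d_havg"]), tolerance = 1e-9)
  expect_equal(rk$d_hc, unname(d["d_hc"]), tolerance = 1e-9)
})

test_that("a promoter-hypo, gene-body-high fixture outranks decoys", {
  set.seed(83)
  n_decoy <- 24
  wins <- vapply(1:20, function(s) {
    set.seed(900 + s)
    # decoy transcripts: similar gene-body methylation in all species
    base <- runif(n_decoy, 0, 400)
    tab <- data.frame(
      transcript_id = sprintf("DEC%02d-001", seq_len(n_decoy)),
      score_h = round(base + rnorm(n_decoy, 0, 30), 1),
      score_c = round(base + rnorm(n_decoy, 0, 30), 1),
      score_m = round(base + rnorm(n_decoy, 0, 30), 1))
    tab$score_h <- pmax(tab$score_h, 0)
    tab$score_c <- pmax(tab$score_c, 0)
    tab$score_m <- pmax(tab$score_m, 0)
    # the planted locus: strong human-only gene-body signal
    tab <- rbind(tab, data.frame(transcript_id = "PLANT-001",
                                 score_h = round(runif(1, 500, 900), 1),
                                 score_c = 0, score_m = 0))
    rank_records(tab, "hypo")$transcript_id[1] == "PLANT-001"
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})
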