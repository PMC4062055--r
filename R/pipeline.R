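#' Run the full synthetic-mode pipeline
#'
#' Executes the stages in order: generate trio -> simulate and filter
#' fragments -> binned coverage -> two peak callers per species ->
#' dual-caller consensus -> liftover of out-group peaks -> s-DMR
#' triangulation (hypo and hyper) -> signal benchmark -> island/shore
#' enrichment -> (optionally) motif divergence -> gene-body ranking ->
#' truth-vs-called recovery metrics. Fully deterministic for a fixed
#' config seed.
#'
#' @param config \code{trio_config}.
#' @param outdir optional directory; when given, trio artifacts, peak and
#'   s-DMR BED files and the text report are written there.
#' @param bin_width coverage bin width in bp (default 50).
#' @param p_threshold Poisson caller threshold (default 1e-3).
#' @param min_match liftover minMatch (default 0.7).
#' @param score_scale peak score convention (see [call_peaks_poisson()]).
#' @param with_motifs run the motif-divergence stage (slowest stage).
#' @param motif_B null draws per motif p-value.
#' @return list of class \code{pipeline_result}.
#' @export
run_pipeline <- function(config = trio_config(), outdir = NULL,
                         bin_width = 50L, p_threshold = 1e-3,
                         min_match = 0.7,
                         score_scale = "minus10log10",
                         with_motifs = TRUE, motif_B = 99L) {
  t0 <- Sys.time()
  trio <- generate_trio(config)
  raw <- simulate_trio_medip(trio)
  species <- c("human", "chimp", "macaque")
  fs <- lapply(setNames(species, species), function(sp) {
    filter_fragments(raw[[sp]], species = sp)
  })
  fraglen <- config$medip$fraglen_mean
  tracks <- lapply(setNames(species, species), function(sp) {
    rpm_track(fs[[sp]], bin_width, trio$chrom_lengths[[sp]])
  })
  peaks_pois <- lapply(tracks, call_peaks_poisson, fraglen = fraglen,
                       p_threshold = p_threshold,
                       score_scale = score_scale)
  peaks_post <- lapply(tracks, call_peaks_posterior)
  cons <- lapply(setNames(species, species), function(sp) {
    consensus(peaks_pois[[sp]], peaks_post[[sp]])
  })
  # out-group peaks on the reference build
  ch <- trio$chains
  chimp_cons_l <- lift_intervals(cons$chimp, ch$chimp_human, min_match)
  mac_cons_l <- lift_intervals(cons$macaque, ch$macaque_human, min_match)
  chimp_all_l <- suppressWarnings(
    c(lift_intervals(peaks_pois$chimp, ch$chimp_human, min_match),
      lift_intervals(peaks_post$chimp, ch$chimp_human, min_match)))
  mac_all_l <- suppressWarnings(
    c(lift_intervals(peaks_pois$macaque, ch$macaque_human, min_match),
      lift_intervals(peaks_post$macaque, ch$macaque_human, min_match)))
  blacklist <- trio$annotations$blacklist
  shared <- shared_nonhuman(chimp_cons_l, mac_cons_l)
  hypo <- call_hypo(shared, peaks_pois$human, peaks_post$human)
  hyper <- call_hyper(cons$human, chimp_all_l, mac_all_l, ch,
                      blacklist, min_match)
  # two-species mode (no macaque out-group), for the triangulation gain
  hypo2 <- call_hypo(chimp_cons_l, peaks_pois$human, peaks_post$human)
  cand2 <- cons$human[countOverlaps(cons$human, chimp_all_l) == 0L]
  if (length(cand2)) {
    cand2 <- cand2[reciprocal_filter(cand2, ch$human_chimp,
                                     ch$chimp_human, min_match)]
  }
  hyper2 <- exclude_blacklist(cand2, blacklist)
  gain <- triangulation_gain(length(hypo2) + length(hyper2),
                             length(hypo) + length(hyper))
  benchmark <- list(
    hypo = benchmark_sdmr_signal(hypo, fs, ch, min_match),
    hyper = benchmark_sdmr_signal(hyper, fs, ch, min_match))
  # island / shore prevalence
  islands <- trio$annotations$islands
  shores <- make_shores(islands, 2000, config$chrom_lengths)
  enr <- .island_shore_table(hypo, hyper, islands, shores)
  motif_table <- NULL
  if (with_motifs) {
    motif_table <- .motif_stage(trio, hypo, hyper, islands,
                                B = motif_B, seed = config$seed)
  }
  genes <- trio$annotations$genes
  tids <- promoter_sdmr_transcripts(hypo, genes, islands)
  ranked <- NULL
  if (length(tids)) {
    scored <- score_transcripts(tids, trio$annotations$exons,
                                peaks_pois, ch, min_match)
    ranked <- rank_records(scored, "hypo")
  }
  recovery <- sdmr_recovery(trio$truth, hypo, hyper)
  res <- structure(list(
    trio = trio, fragment_sets = fs,
    peaks = list(poisson = peaks_pois, posterior = peaks_post,
                 consensus = cons),
    lifted = list(chimp_consensus = chimp_cons_l,
                  macaque_consensus = mac_cons_l,
                  chimp_all = chimp_all_l, macaque_all = mac_all_l),
    sdmrs = list(hypo = hypo, hyper = hyper),
    two_species = list(hypo = hypo2, hyper = hyper2),
    triangulation_gain = gain,
    benchmark = benchmark, islands_shores = enr,
    motif_table = motif_table, ranked = ranked,
    recovery = recovery, seed = config$seed,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_result")
  if (!is.null(outdir)) .persist_pipeline(res, outdir)
  res
}

.island_shore_table <- function(hypo, hyper, islands, shores) {
  isl_bp <- sum(width(reduce(granges(islands))))
  sh_bp <- sum(width(shores))
  k_isl <- count_overlaps_frac(hypo, islands, 0.5) +
    count_overlaps_frac(hyper, islands, 0.5)
  k_sh <- count_overlaps_frac(hypo, shores, 0.5) +
    count_overlaps_frac(hyper, shores, 0.5)
  data.frame(
    feature = c("islands", "shores"),
    sdmr_count = c(k_isl, k_sh),
    feature_mb = c(isl_bp, sh_bp) / 1e6,
    density_per_mb = c(density_per_mb(k_isl, isl_bp),
                       density_per_mb(k_sh, sh_bp)))
}

# motif divergence over the island-associated s-DMR sets; background pool
# is the island sequence complement of the analysed set
.motif_stage <- function(trio, hypo, hyper, islands, B = 99L, seed = 1L) {
  motifs <- demo_motifs()
  model <- affinity_model()
  isl_seqs <- vapply(seq_along(islands), function(k) {
    cn <- as.character(seqnames(islands))[k]
    as.character(subseq(trio$genomes$human[[cn]], start(islands)[k],
                        end(islands)[k]))
  }, "")
  out <- list()
  for (cls in c("hypo", "hyper")) {
    sd <- if (cls == "hypo") hypo else hyper
    sd <- sd[overlapsAny(sd, islands)]
    if (length(sd) < 3L) next
    trips <- orthologous_sequences(sd, trio)
    if (length(trips) < 3L) next
    seq_by_sp <- lapply(c("human", "chimp", "macaque"), function(sp) {
      vapply(trips, function(tr) tr$seqs[[sp]], "")
    })
    rows <- lapply(names(motifs), function(mn) {
      wm <- motifs[[mn]]
      idx <- affinity_index(wm, isl_seqs, model)
      ps <- vapply(1:3, function(sp) {
        region_set_pvalue(seq_by_sp[[sp]], wm, idx, model, B = B,
                          seed = .substream(seed, paste0(cls, mn, sp)))$p
      }, 0)
      data.frame(class = cls, motif = mn, p_human = ps[1L],
                 p_chimp = ps[2L], p_macaque = ps[3L],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    for (col in c("p_human", "p_chimp", "p_macaque")) {
      tab[[col]] <- bh_adjust(tab[[col]])
    }
    dm <- divergence_map(tab)
    dm$class <- cls
    out[[cls]] <- dm
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Truth-vs-called recovery metrics
#'
#' Sensitivity and precision per s-DMR class (>= 1 bp overlap with a call
#' of the correct class), plus the count of calls overlapping planted
#' out-group-specific or shared regions (which a correct triangulation
#' must not call).
#'
#' @param truth planted-truth GRanges (from the generator).
#' @param hypo,hyper called s-DMR GRanges.
#' @return list of per-class metrics and \code{cross_class_calls}.
#' @export
sdmr_recovery <- function(truth, hypo, hyper) {
  t_hypo <- truth[mcols(truth)$class == "human_hypo"]
  t_hyper <- truth[mcols(truth)$class == "human_hyper"]
  t_other <- truth[mcols(truth)$class %in%
                     c("chimp_only", "shared_methylated")]
  calls <- suppressWarnings(c(granges(hypo), granges(hyper)))
  list(
    hypo = list(
      n_truth = length(t_hypo), n_called = length(hypo),
      sensitivity = if (length(t_hypo))
        mean(overlapsAny(t_hypo, hypo)) else NA_real_,
      precision = if (length(hypo))
        mean(overlapsAny(hypo, t_hypo)) else NA_real_),
    hyper = list(
      n_truth = length(t_hyper), n_called = length(hyper),
      sensitivity = if (length(t_hyper))
        mean(overlapsAny(t_hyper, hyper)) else NA_real_,
      precision = if (length(hyper))
        mean(overlapsAny(hyper, t_hyper)) else NA_real_),
    cross_class_calls = sum(overlapsAny(calls, t_other)))
}

.persist_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_trio(res$trio, file.path(outdir, "trio"))
  for (sp in names(res$peaks$consensus)) {
    write_intervals(res$peaks$consensus[[sp]],
                    file.path(outdir, paste0("consensus_", sp, ".bed")))
  }
  for (cls in c("hypo", "hyper")) {
    gr <- res$sdmrs[[cls]]
    write_intervals(gr, file.path(outdir, paste0("sdmr_", cls, ".bed")))
  }
  writeLines(make_report(res), file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Human-readable run report
#'
#' Per-stage counts, s-DMR totals, island/shore densities, triangulation
#' gain, and (synthetic mode) the truth-vs-called confusion summary.
#'
#' @param res \code{pipeline_result}.
#' @return character vector of report lines.
#' @export
make_report <- function(res) {
  stopifnot(inherits(res, "pipeline_result"))
  fmt <- function(...) sprintf(...)
  lines <- c(
    "== trio s-DMR pipeline report ==",
    fmt("seed: %d", res$seed),
    fmt("fragments retained: %s",
        paste(vapply(res$fragment_sets, function(f)
          fmt("%s=%d", f$species, f$total_retained), ""),
          collapse = " ")),
    fmt("peaks (poisson/posterior/consensus): %s",
        paste(vapply(names(res$peaks$consensus), function(sp)
          fmt("%s=%d/%d/%d", sp, length(res$peaks$poisson[[sp]]),
              length(res$peaks$posterior[[sp]]),
              length(res$peaks$consensus[[sp]])), ""),
          collapse = " ")),
    fmt("s-DMRs: hypo=%d hyper=%d", length(res$sdmrs$hypo),
        length(res$sdmrs$hyper)),
    fmt("two-species calls: hypo=%d hyper=%d (gain over triangulation: %s)",
        length(res$two_species$hypo), length(res$two_species$hyper),
        ifelse(is.na(res$triangulation_gain), "NA",
               fmt("%.1f%%", 100 * res$triangulation_gain))),
    fmt("island density: %.2f /Mb; shore density: %.2f /Mb",
        res$islands_shores$density_per_mb[1L],
        res$islands_shores$density_per_mb[2L]))
  rec <- res$recovery
  lines <- c(lines,
    "-- truth recovery (synthetic mode) --",
    fmt("hypo:  truth=%d called=%d sensitivity=%.3f precision=%.3f",
        rec$hypo$n_truth, rec$hypo$n_called,
        rec$hypo$sensitivity, rec$hypo$precision),
    fmt("hyper: truth=%d called=%d sensitivity=%.3f precision=%.3f",
        rec$hyper$n_truth, rec$hyper$n_called,
        rec$hyper$sensitivity, rec$hyper$precision),
    fmt("calls overlapping planted out-group/shared regions: %d",
        rec$cross_class_calls))
  if (!is.null(res$ranked) && nrow(res$ranked)) {
    top <- res$ranked[1L, ]
    lines <- c(lines,
      fmt("top-ranked gene-body differential: %s (H=%.1f C=%.1f M=%.1f, H-avg=%.1f)",
          top$transcript_id, top$score_h, top$score_c, top$score_m,
          top$d_havg))
  }
  if (!is.null(res$motif_table)) {
    flagged <- res$motif_table[res$motif_table$consistent, , drop = FALSE]
    lines <- c(lines,
      fmt("motifs flagged for consistent divergence: %d of %d",
          nrow(flagged), nrow(res$motif_table)))
  }
  lines <- c(lines, fmt("elapsed: %.1f s", res$elapsed_sec))
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(make_report(x))
  invisible(x)
}
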