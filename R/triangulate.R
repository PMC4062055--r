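#' Shared non-reference peaks
#'
#' Out-group peak sets (already lifted to the reference build) are
#' intersected: the chimp-side peaks that overlap at least \code{min_overlap}
#' bp with any macaque-side peak are returned, in their lifted chimp
#' coordinates. These shared peaks carry the methylation signal common to
#' both out-groups and are the candidate set for reference-species
#' hypomethylation.
#'
#' @param chimp_lifted,macaque_lifted consensus peak GRanges lifted to the
#'   reference build.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return subset of \code{chimp_lifted}.
#' @export
shared_nonhuman <- function(chimp_lifted, macaque_lifted, min_overlap = 1L) {
  consensus(chimp_lifted, macaque_lifted, min_overlap)
}

#' Call hypomethylated s-DMRs
#'
#' A shared out-group peak becomes a hypomethylated s-DMR when it overlaps
#' no reference-species peak from either caller (>= 1 bp rule). The lifted
#' chimp peak location determines the s-DMR coordinates.
#'
#' @param shared shared out-group peaks on the reference build
#'   (see [shared_nonhuman()]).
#' @param human_a,human_b the reference species' two caller outputs.
#' @return GRanges of hypo s-DMRs with \code{class = "hypo"}.
#' @export
call_hypo <- function(shared, human_a, human_b) {
  keep <- countOverlaps(shared, human_a) == 0L &
    countOverlaps(shared, human_b) == 0L
  out <- shared[keep]
  mcols(out)$class <- rep("hypo", length(out))
  out
}

#' Call hypermethylated s-DMRs
#'
#' Reference-species consensus peaks that (1) overlap no out-group peak
#' from either caller in either species, (2) survive a reciprocal
#' back-lift through each out-group genome (lifted over and back at the
#' minMatch threshold, landing on the original location), and (3) touch no
#' blacklist region.
#'
#' @param human_consensus reference-species consensus peaks.
#' @param chimp_all_lifted,macaque_all_lifted unions of both callers'
#'   out-group peaks, lifted to the reference build.
#' @param chains list with \code{human_chimp}, \code{chimp_human},
#'   \code{human_macaque}, \code{macaque_human} chain sets.
#' @param blacklist poor-mappability exclusion GRanges (may be empty).
#' @param min_match minMatch used for the back-lift (both directions).
#' @return GRanges of hyper s-DMRs with \code{class = "hyper"}.
#' @export
call_hyper <- function(human_consensus, chimp_all_lifted,
                       macaque_all_lifted, chains,
                       blacklist = GRanges(), min_match = 0.7) {
  cand <- human_consensus[
    countOverlaps(human_consensus, chimp_all_lifted) == 0L &
      countOverlaps(human_consensus, macaque_all_lifted) == 0L]
  if (length(cand)) {
    pass_c <- reciprocal_filter(cand, chains$human_chimp,
                                chains$chimp_human, min_match)
    pass_m <- reciprocal_filter(cand, chains$human_macaque,
                                chains$macaque_human, min_match)
    cand <- cand[pass_c & pass_m]
  }
  out <- exclude_blacklist(cand, blacklist)
  mcols(out)$class <- rep("hyper", length(out))
  out
}

#' Benchmark s-DMR methylation signal across species
#'
#' For each s-DMR the raw fragment counts are measured in each species'
#' native genome (the reference coordinates directly for the reference
#' species; through the chain lift for the out-groups) and normalized to
#' the reference library total
#' (\code{reads / species_total * reference_total}). The per-region
#' reference-vs-out-group contrasts (H-C and H-M) are each compared with
#' the out-group-vs-out-group contrast (C-M) by a two-sided
#' Mann-Whitney test: hyper s-DMRs should show both human contrasts
#' stochastically greater, hypo s-DMRs the inverse.
#'
#' @param sdmrs s-DMR GRanges on the reference build.
#' @param fragment_sets named list of \code{fragment_set}s (human, chimp,
#'   macaque).
#' @param chains chain list as in [call_hyper()].
#' @param min_match minMatch for locating out-group native coordinates.
#' @return list: per-region normalized counts (data.frame), the contrast
#'   p-values \code{p_hc_vs_cm}, \code{p_hm_vs_cm}, median contrasts, and
#'   \code{note} ("ok", "insufficient n", or "degenerate").
#' @export
benchmark_sdmr_signal <- function(sdmrs, fragment_sets, chains,
                                  min_match = 0.7) {
  if (length(sdmrs) < 5L) {
    return(list(counts = NULL, p_hc_vs_cm = NA_real_,
                p_hm_vs_cm = NA_real_, note = "insufficient n"))
  }
  mc <- liftover_map(sdmrs, chains$human_chimp, min_match)
  mm <- liftover_map(sdmrs, chains$human_macaque, min_match)
  ok <- mc$status == "mapped" & mm$status == "mapped"
  sd2 <- sdmrs[ok]
  if (length(sd2) < 5L) {
    return(list(counts = NULL, p_hc_vs_cm = NA_real_,
                p_hm_vs_cm = NA_real_, note = "insufficient n"))
  }
  gr_c <- gr0(mc$t_chrom[ok], mc$t_start[ok], mc$t_end[ok])
  gr_m <- gr0(mm$t_chrom[ok], mm$t_start[ok], mm$t_end[ok])
  tot <- vapply(fragment_sets, function(f) f$total_retained, 0)
  n_h <- count_fragments_in(fragment_sets$human, sd2)
  n_c <- normalize_to_reference(
    count_fragments_in(fragment_sets$chimp, gr_c),
    tot[["chimp"]], tot[["human"]])
  n_m <- normalize_to_reference(
    count_fragments_in(fragment_sets$macaque, gr_m),
    tot[["macaque"]], tot[["human"]])
  d_hc <- n_h - n_c
  d_hm <- n_h - n_m
  d_cm <- n_c - n_m
  if (all(d_hc == d_cm) && all(d_hm == d_cm)) {
    return(list(counts = data.frame(n_h, n_c, n_m),
                p_hc_vs_cm = 1, p_hm_vs_cm = 1, note = "degenerate"))
  }
  p1 <- suppressWarnings(wilcox.test(d_hc, d_cm)$p.value)
  p2 <- suppressWarnings(wilcox.test(d_hm, d_cm)$p.value)
  list(counts = data.frame(n_h = n_h, n_c = n_c, n_m = n_m,
                           d_hc = d_hc, d_hm = d_hm, d_cm = d_cm),
       p_hc_vs_cm = p1, p_hm_vs_cm = p2,
       median_d_hc = stats::median(d_hc),
       median_d_hm = stats::median(d_hm),
       median_d_cm = stats::median(d_cm), note = "ok")
}

#' Size inflation of the two-species call set over triangulation
#'
#' Quantifies the value of the out-group: the relative excess of
#' "reference-specific" calls made from a two-species comparison alone
#' over the triangulated call set,
#' \code{(|two-species| - |triangulated|) / |triangulated|}.
#'
#' @param two_species_calls,triangulated_calls GRanges (or lengths).
#' @return the excess ratio (0 when the sets have equal size; NA when the
#'   triangulated set is empty).
#' @export
triangulation_gain <- function(two_species_calls, triangulated_calls) {
  n2 <- if (is.numeric(two_species_calls)) two_species_calls
        else length(two_species_calls)
  nt <- if (is.numeric(triangulated_calls)) triangulated_calls
        else length(triangulated_calls)
  if (nt == 0) return(NA_real_)
  (n2 - nt) / nt
}
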