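#' Transcripts whose 5' promoter island carries an s-DMR
#'
#' A transcript qualifies when the CpG island overlapping its promoter
#' (TSS +/- 1 kb intersected with the island) also overlaps (>= 1 bp) an
#' s-DMR of the queried class. A bidirectional promoter island returns
#' every transcript anchored on it.
#'
#' @param sdmrs s-DMR GRanges.
#' @param genes gene table (one row per transcript: \code{transcript_id},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{promoter_start},
#'   \code{promoter_end}).
#' @param islands island GRanges.
#' @return character vector of transcript ids.
#' @export
promoter_sdmr_transcripts <- function(sdmrs, genes, islands) {
  if (!nrow(genes) || !length(sdmrs) || !length(islands)) return(character(0))
  prom <- GRanges(genes$chrom,
                  IRanges(genes$promoter_start, genes$promoter_end))
  hits <- findOverlaps(prom, islands)
  if (!length(hits)) return(character(0))
  # promoter restricted to its 5' island
  pi <- pintersect(prom[queryHits(hits)], islands[subjectHits(hits)])
  qual <- countOverlaps(pi, sdmrs) > 0L
  unique(genes$transcript_id[queryHits(hits)[qual]])
}

#' Exon methylation score of a transcript in one species
#'
#' The transcript score is the maximum peak score among peaks overlapping
#' (>= 1 bp) any exon; 0 when no peak overlaps any exon. For a
#' non-reference species, exons are first mapped to that species' build
#' through the chain; exons that fail to map contribute nothing (a
#' warning is logged when all fail).
#'
#' @param exons exon GRanges for the transcript (reference build).
#' @param peaks ScoredPeak GRanges on the scoring species' native build.
#' @param chain optional chain_set mapping exons to that build.
#' @param min_match liftover threshold when \code{chain} is given.
#' @return maximum overlapping peak score (0 if none).
#' @export
exon_score <- function(exons, peaks, chain = NULL, min_match = 0.7) {
  if (!length(exons) || !length(peaks)) return(0)
  if (!is.null(chain)) {
    m <- liftover_map(exons, chain, min_match)
    ok <- m$status == "mapped"
    if (!any(ok)) {
      warning("no exon mappable to target build; score 0")
      return(0)
    }
    exons <- gr0(m$t_chrom[ok], m$t_start[ok], m$t_end[ok])
  }
  hits <- findOverlaps(exons, peaks, ignore.strand = TRUE)
  if (!length(hits)) return(0)
  max(mcols(peaks)$score[subjectHits(hits)])
}

#' Per-transcript cross-species score differentials
#'
#' @param score_h,score_c,score_m per-species exon peak scores (>= 0).
#' @return named numeric: \code{d_hc} (H - C), \code{d_hm} (H - M),
#'   \code{d_havg} (H - mean(C, M)). Exact arithmetic, no rounding.
#' @export
differentials <- function(score_h, score_c, score_m) {
  c(d_hc = score_h - score_c,
    d_hm = score_h - score_m,
    d_havg = score_h - (score_c + score_m) / 2)
}

#' Fold ratio of reference score over the out-group mean
#'
#' @inheritParams differentials
#' @return \code{score_h / mean(score_c, score_m)}; NA when the out-group
#'   mean is 0.
#' @export
fold_ratio <- function(score_h, score_c, score_m) {
  m <- (score_c + score_m) / 2
  if (m == 0) return(NA_real_)
  score_h / m
}

#' Build and rank the gene-body differential table
#'
#' For each transcript, per-species exon scores are combined into
#' differentials and the fold ratio, then ranked: the hypo-promoter set
#' descending by \code{d_havg} (most reference-elevated gene body first,
#' the promoter-hypomethylation / gene-body-hypermethylation signature),
#' the hyper-promoter set ascending. Ties break lexicographically by
#' transcript id.
#'
#' @param records data.frame with \code{transcript_id}, \code{score_h},
#'   \code{score_c}, \code{score_m}.
#' @param class "hypo" or "hyper" (the promoter s-DMR class the set came
#'   from).
#' @return the records with \code{d_hc}, \code{d_hm}, \code{d_havg},
#'   \code{fold} and \code{rank}, ordered by rank.
#' @export
rank_records <- function(records, class = c("hypo", "hyper")) {
  class <- match.arg(class)
  if (!nrow(records)) {
    return(cbind(records, d_hc = numeric(0), d_hm = numeric(0),
                 d_havg = numeric(0), fold = numeric(0),
                 rank = integer(0)))
  }
  d <- t(mapply(differentials, records$score_h, records$score_c,
                records$score_m))
  records$d_hc <- d[, "d_hc"]
  records$d_hm <- d[, "d_hm"]
  records$d_havg <- d[, "d_havg"]
  records$fold <- mapply(fold_ratio, records$score_h, records$score_c,
                         records$score_m)
  key <- if (class == "hypo") -records$d_havg else records$d_havg
  ord <- order(key, records$transcript_id)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Score every transcript of a gene set across the trio
#'
#' Convenience wrapper: per-species exon scores via [exon_score()] (with
#' chain mapping for the out-groups), assembled into the input expected
#' by [rank_records()].
#'
#' @param transcript_ids transcripts to score.
#' @param exons exon GRanges with \code{transcript_id} metadata.
#' @param peaks named list of peak GRanges (human, chimp, macaque) on
#'   native builds.
#' @param chains chain list (\code{human_chimp}, \code{human_macaque}).
#' @param min_match liftover threshold.
#' @return data.frame of per-transcript scores.
#' @export
score_transcripts <- function(transcript_ids, exons, peaks, chains,
                              min_match = 0.7) {
  rows <- lapply(transcript_ids, function(tid) {
    ex <- exons[mcols(exons)$transcript_id == tid]
    data.frame(
      transcript_id = tid,
      score_h = exon_score(ex, peaks$human),
      score_c = suppressWarnings(
        exon_score(ex, peaks$chimp, chains$human_chimp, min_match)),
      score_m = suppressWarnings(
        exon_score(ex, peaks$macaque, chains$human_macaque, min_match)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
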