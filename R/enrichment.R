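#' CpG island shores
#'
#' Shores are the 2-kb flanks on either side of each island, minus all
#' island sequence, clipped to chromosome bounds and merged.
#'
#' @param islands island GRanges (merged internally).
#' @param flank shore width in bp (default 2000).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return merged shore GRanges with zero island overlap.
#' @export
make_shores <- function(islands, flank = 2000, chrom_lengths = NULL) {
  isl <- reduce(granges(islands))
  if (!length(isl)) return(GRanges())
  cn <- as.character(seqnames(isl))
  l_start <- pmax(start(isl) - flank, 1L)
  l_end <- start(isl) - 1L
  r_start <- end(isl) + 1L
  r_end <- end(isl) + flank
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[cn])
    r_end <- pmin(r_end, lim)
  }
  keep_l <- l_end >= l_start
  keep_r <- r_end >= r_start
  sh <- c(GRanges(cn[keep_l], IRanges(l_start[keep_l], l_end[keep_l])),
          GRanges(cn[keep_r], IRanges(r_start[keep_r], r_end[keep_r])))
  if (!length(sh)) return(GRanges())
  sh <- GenomicRanges::setdiff(reduce(sh), isl)
  sh[width(sh) > 0]
}

#' Count regions overlapping a feature at a fractional threshold
#'
#' A region is counted when its overlap with the feature covers at least
#' \code{min_fraction} of the *region's* length (inclusive threshold,
#' matching intersect -f semantics on the query). \code{min_fraction} of
#' a single bp divided by the length reduces to the any-overlap (1-bp)
#' rule as the threshold goes to zero.
#'
#' @param regions query GRanges.
#' @param feature feature GRanges (merged internally for coverage).
#' @param min_fraction minimum covered fraction of the region (default 0.5).
#' @return integer: number of regions counted.
#' @export
count_overlaps_frac <- function(regions, feature, min_fraction = 0.5) {
  sum(overlap_fraction(regions, feature) >= min_fraction)
}

#' Fraction of each region covered by a feature
#' @inheritParams count_overlaps_frac
#' @return numeric vector in [0, 1], one value per region.
#' @export
overlap_fraction <- function(regions, feature) {
  if (!length(regions)) return(numeric(0))
  feat <- reduce(granges(feature))
  if (!length(feat)) return(numeric(length(regions)))
  hits <- findOverlaps(regions, feat)
  ov <- width(pintersect(regions[queryHits(hits)], feat[subjectHits(hits)]))
  covered <- numeric(length(regions))
  if (length(hits)) {
    agg <- tapply(ov, queryHits(hits), sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / width(regions)
}

#' Regions per megabase of feature sequence
#'
#' @param count number of regions attributed to the feature.
#' @param feature_total_bp merged feature size in bp (> 0).
#' @return density in regions per Mb (unrounded; rounding is presentation).
#' @export
density_per_mb <- function(count, feature_total_bp) {
  if (feature_total_bp <= 0) stop("feature_total_bp must be > 0")
  count / (feature_total_bp / 1e6)
}

#' Two-proportion chi-square enrichment
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' regions-in-feature vs background-in-feature. When any expected cell is
#' below 5 a Fisher exact test is computed instead and flagged.
#'
#' @param k_regions,n_regions feature hits and totals for the test set.
#' @param k_background,n_background same for the background set.
#' @return list of class \code{enrichment_result}: observed, expected,
#'   \code{ratio} (relative proportion), \code{statistic}, \code{p_value},
#'   \code{method} ("chi-square" or "fisher").
#' @export
chi2_enrichment <- function(k_regions, n_regions, k_background,
                            n_background) {
  stopifnot(k_regions >= 0, k_background >= 0,
            n_regions >= k_regions, n_background >= k_background)
  if (n_regions == 0 || n_background == 0) stop("empty set")
  tab <- matrix(c(k_regions, n_regions - k_regions,
                  k_background, n_background - k_background), nrow = 2L)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  p_b <- k_background / n_background
  ratio <- if (p_b > 0) (k_regions / n_regions) / p_b else NA_real_
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    res <- list(observed = k_regions,
                expected = expected[1L, 1L], ratio = ratio,
                statistic = NA_real_, p_value = ft$p.value,
                method = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    res <- list(observed = k_regions, expected = expected[1L, 1L],
                ratio = ratio,
                statistic = unname(ct$statistic),
                p_value = ct$p.value, method = "chi-square")
  }
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: observed %s, ratio %.3f, %s p = %.3g\n",
              x$observed, x$ratio, x$method, x$p_value))
  invisible(x)
}

#' Shuffle-control enrichment
#'
#' Each control set preserves the region count and the exact length
#' multiset, re-placed uniformly on the genome excluding a blacklist and
#' without intra-set overlap. The enrichment ratio is the observed feature
#' overlap count over the mean control overlap count.
#'
#' @param regions observed GRanges.
#' @param chrom_lengths named chromosome lengths.
#' @param feature feature GRanges overlaps are counted against (any-bp
#'   rule via \code{min_fraction}).
#' @param n_controls number of control sets.
#' @param seed RNG seed.
#' @param blacklist excluded placement space.
#' @param min_fraction overlap threshold passed to
#'   [count_overlaps_frac()]; the default \code{1e-9} is the any-overlap
#'   rule.
#' @param max_tries placement retries per region before failing.
#' @return list: \code{observed}, \code{control_counts},
#'   \code{control_mean}, \code{ratio} (NA when the control mean is 0),
#'   \code{empirical_p} = (1 + #controls >= observed) / (n + 1).
#' @export
shuffle_control <- function(regions, chrom_lengths, feature,
                            n_controls = 100L, seed = 1L,
                            blacklist = GRanges(), min_fraction = 1e-9,
                            max_tries = 1000L) {
  set.seed(seed)
  lens <- width(regions)
  observed <- count_overlaps_frac(regions, feature, min_fraction)
  ctrl <- integer(n_controls)
  for (b in seq_len(n_controls)) {
    placed_chrom <- character(length(lens))
    placed_start <- integer(length(lens))
    occupied <- list()
    for (j in seq_along(lens)) {
      ok <- FALSE
      for (tr in seq_len(max_tries)) {
        cn <- sample(names(chrom_lengths), 1L,
                     prob = chrom_lengths / sum(chrom_lengths))
        L <- chrom_lengths[[cn]]
        if (L <= lens[j]) next
        s <- sample.int(L - lens[j] + 1L, 1L)
        cand <- GRanges(cn, IRanges(s, width = lens[j]))
        if (length(blacklist) && countOverlaps(cand, blacklist) > 0) next
        if (length(occupied) &&
            countOverlaps(cand, do.call(c, occupied)) > 0) next
        occupied[[length(occupied) + 1L]] <- cand
        placed_chrom[j] <- cn; placed_start[j] <- s
        ok <- TRUE
        break
      }
      if (!ok) stop("shuffle_control: could not place region after ",
                    max_tries, " tries")
    }
    ctrl_set <- GRanges(placed_chrom, IRanges(placed_start, width = lens))
    ctrl[b] <- count_overlaps_frac(ctrl_set, feature, min_fraction)
  }
  cm <- mean(ctrl)
  list(observed = observed, control_counts = ctrl, control_mean = cm,
       ratio = if (cm > 0) observed / cm else NA_real_,
       empirical_p = (1 + sum(ctrl >= observed)) / (n_controls + 1))
}

#' Point-position overlap with regions
#'
#' Overlap bookkeeping between a region set and single-bp positions
#' (CpG probes, SNPs): how many regions are hit, how many positions land
#' in a region, and both as fractions.
#'
#' @param regions GRanges.
#' @param positions GRanges of width-1 positions.
#' @return list: \code{n_regions_hit}, \code{n_positions_in},
#'   \code{frac_regions} and \code{frac_positions} (proportions in [0,1]).
#' @export
point_overlap <- function(regions, positions) {
  if (!length(positions) || !length(regions)) {
    return(list(n_regions_hit = 0L, n_positions_in = 0L,
                frac_regions = if (length(regions)) 0 else NA_real_,
                frac_positions = if (length(positions)) 0 else NA_real_))
  }
  nr <- sum(countOverlaps(regions, positions) > 0L)
  np <- sum(countOverlaps(positions, regions) > 0L)
  list(n_regions_hit = nr, n_positions_in = np,
       frac_regions = nr / length(regions),
       frac_positions = np / length(positions))
}

#' CpG dinucleotide density of a sequence
#'
#' Percentage of overlapping CG dinucleotides:
#' \code{100 * #CG / (length - 1)}. The observed/expected CpG ratio
#' (\code{#CG * L / (#C * #G)}) is also returned for reference.
#'
#' @param sequence character or DNAString/DNAStringSet element, length >= 2.
#' @return list: \code{percent}, \code{n_cpg}, \code{obs_exp}.
#' @export
cpg_density <- function(sequence) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  if (L < 2L) stop("sequence must be at least 2 bp")
  m <- gregexpr("(?=CG)", s, perl = TRUE)[[1L]]
  n_cpg <- if (m[1L] == -1L) 0L else length(m)
  chars <- strsplit(s, "")[[1L]]
  nc <- sum(chars == "C")
  ng <- sum(chars == "G")
  obs_exp <- if (nc > 0 && ng > 0) n_cpg * L / (nc * ng) else NA_real_
  list(percent = 100 * n_cpg / (L - 1L), n_cpg = n_cpg, obs_exp = obs_exp)
}
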