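#' Map intervals across assemblies through a chain set
#'
#' Per-base liftover with UCSC liftOver semantics. Every base of each query
#' interval is pushed through the aligned blocks of the chains whose source
#' chromosome matches; the target interval is the [min, max+1) envelope of
#' the mapped target positions (strand-adjusted for minus-strand chains).
#'
#' Status values: \code{mapped} (mapped fraction >= \code{min_match},
#' inclusive, matching liftOver's minMatch), \code{low_match} (some bases
#' map but too few), \code{split} (mapped bases fall in more than one chain
#' -- never stitched, treated as failure), \code{unmapped} (no base maps).
#'
#' @param gr query GRanges on the chain source build.
#' @param cs \code{chain_set} from [read_chain()].
#' @param min_match minimum mapped fraction for success (default 0.7).
#' @return data.frame with one row per query: \code{status},
#'   \code{mapped_fraction}, and target coordinates \code{t_chrom},
#'   \code{t_start}, \code{t_end} (0-based half-open; NA unless status is
#'   \code{mapped} or \code{low_match}).
#' @export
liftover_map <- function(gr, cs, min_match = 0.7) {
  stopifnot(inherits(cs, "chain_set"))
  b <- bed0(gr)
  n <- nrow(b)
  status <- rep("unmapped", n)
  frac <- numeric(n)
  t_chrom <- rep(NA_character_, n)
  t_start <- t_end <- rep(NA_real_, n)
  chrom_idx <- split(seq_along(cs$chains),
                     vapply(cs$chains, `[[`, "", "s_chrom"))
  for (i in seq_len(n)) {
    s <- b$start[i]; e <- b$end[i]
    cands <- chrom_idx[[b$chrom[i]]]
    if (is.null(cands)) next
    best <- NULL; best_mapped <- 0; n_hit <- 0L
    for (ci in cands) {
      ch <- cs$chains[[ci]]
      hit <- .map_in_chain(s, e, ch)
      if (hit$mapped > 0) {
        n_hit <- n_hit + 1L
        if (hit$mapped > best_mapped) {
          best_mapped <- hit$mapped
          best <- c(hit, list(chain = ch))
        }
      }
    }
    if (n_hit == 0L) next
    if (n_hit > 1L) { status[i] <- "split"; next }
    ch <- best$chain
    lo <- best$t_lo; hi <- best$t_hi
    if (ch$t_strand == "-") {
      tmp <- ch$t_size - hi
      hi <- ch$t_size - lo
      lo <- tmp
    }
    frac[i] <- best_mapped / (e - s)
    status[i] <- if (frac[i] >= min_match) "mapped" else "low_match"
    t_chrom[i] <- ch$t_chrom
    t_start[i] <- lo
    t_end[i] <- hi
  }
  data.frame(status = status, mapped_fraction = frac,
             t_chrom = t_chrom, t_start = t_start, t_end = t_end,
             stringsAsFactors = FALSE)
}

# mapped-base count and target envelope of [s,e) within one chain
# (coordinates in the chain's own target space, possibly reverse-strand)
.map_in_chain <- function(s, e, ch) {
  if (e <= ch$s_start || s >= ch$s_end) {
    return(list(mapped = 0, t_lo = NA_real_, t_hi = NA_real_))
  }
  s_bs <- ch$s_bs
  size <- ch$blocks$size
  lo_i <- max(1L, findInterval(s, s_bs))
  hi_i <- findInterval(e - 1, s_bs)
  if (hi_i < lo_i) return(list(mapped = 0, t_lo = NA_real_, t_hi = NA_real_))
  idx <- lo_i:hi_i
  o_s <- pmax(s, s_bs[idx])
  o_e <- pmin(e, s_bs[idx] + size[idx])
  keep <- o_e > o_s
  if (!any(keep)) return(list(mapped = 0, t_lo = NA_real_, t_hi = NA_real_))
  idx <- idx[keep]; o_s <- o_s[keep]; o_e <- o_e[keep]
  t_lo <- ch$t_bs[idx] + (o_s - s_bs[idx])
  t_hi <- ch$t_bs[idx] + (o_e - s_bs[idx])
  list(mapped = sum(o_e - o_s), t_lo = min(t_lo), t_hi = max(t_hi))
}

#' Lift a single interval (MappedInterval view)
#'
#' @inheritParams liftover_map
#' @param interval length-1 GRanges.
#' @return list with \code{source}, \code{target} (GRanges or NULL),
#'   \code{mapped_fraction}, \code{status}.
#' @export
liftover <- function(interval, cs, min_match = 0.7) {
  stopifnot(length(interval) == 1L)
  m <- liftover_map(interval, cs, min_match)
  target <- NULL
  if (m$status %in% c("mapped", "low_match")) {
    target <- gr0(m$t_chrom, m$t_start, m$t_end)
  }
  list(source = interval, target = target,
       mapped_fraction = m$mapped_fraction, status = m$status)
}

#' Lift a set of intervals, keeping only successful mappings
#'
#' @inheritParams liftover_map
#' @return GRanges of target-build intervals for queries with status
#'   \code{mapped}; metadata columns of the query are carried over, plus
#'   \code{origin} (index into \code{gr}) and \code{mapped_fraction}.
#' @export
lift_intervals <- function(gr, cs, min_match = 0.7) {
  m <- liftover_map(gr, cs, min_match)
  keep <- which(m$status == "mapped")
  if (!length(keep)) {
    out <- GRanges()
    mcols(out)$origin <- integer(0)
    return(out)
  }
  out <- gr0(m$t_chrom[keep], m$t_start[keep], m$t_end[keep])
  mcols(out) <- cbind(mcols(gr)[keep, , drop = FALSE],
                      S4Vectors::DataFrame(origin = keep,
                                           mapped_fraction =
                                             m$mapped_fraction[keep]))
  seqlevels(out) <- union(seqlevels(out),
                          vapply(cs$chains, `[[`, "", "t_chrom"))
  out
}

#' Reciprocal (back-lift) liftover filter
#'
#' Guards against asymmetric-assembly artifacts: each interval is lifted to
#' the other build and back, and is retained only if both lifts succeed at
#' the minMatch threshold and the round-trip interval still overlaps the
#' original location by at least 1 bp (set \code{strict = TRUE} to require
#' exact coordinates instead).
#'
#' @param gr intervals on the chain_fwd source build.
#' @param chain_fwd,chain_rev chain sets for the outward and return lift.
#' @param min_match minMatch threshold applied in both directions.
#' @param strict require exact coordinate identity on return.
#' @return logical vector: which elements of \code{gr} pass.
#' @export
reciprocal_filter <- function(gr, chain_fwd, chain_rev, min_match = 0.7,
                              strict = FALSE) {
  if (!length(gr)) return(logical(0))
  fwd <- liftover_map(gr, chain_fwd, min_match)
  pass <- rep(FALSE, length(gr))
  ok <- which(fwd$status == "mapped")
  if (!length(ok)) return(pass)
  mid <- gr0(fwd$t_chrom[ok], fwd$t_start[ok], fwd$t_end[ok])
  rev <- liftover_map(mid, chain_rev, min_match)
  ok2 <- which(rev$status == "mapped")
  if (!length(ok2)) return(pass)
  back <- gr0(rev$t_chrom[ok2], rev$t_start[ok2], rev$t_end[ok2])
  orig <- gr[ok[ok2]]
  if (strict) {
    hit <- as.character(seqnames(back)) == as.character(seqnames(orig)) &
      start(back) == start(orig) & end(back) == end(orig)
  } else {
    # each interval must land back on its *own* original location
    hit <- poverlaps_any(back, orig)
  }
  pass[ok[ok2]] <- hit
  pass
}

# pairwise >=1 bp overlap between equal-length GRanges
poverlaps_any <- function(a, b) {
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

#' Drop intervals touching a blacklist
#'
#' Whole-interval rejection on any >= 1 bp overlap with a blacklist region
#' (poor-mappability exclusion). Abutting intervals (half-open end equal to
#' a blacklist start) do not overlap and are retained.
#'
#' @param gr intervals.
#' @param blacklist blacklist GRanges on the same build.
#' @return subset of \code{gr} with zero blacklist overlap.
#' @export
exclude_blacklist <- function(gr, blacklist) {
  if (!length(blacklist)) return(gr)
  gr[countOverlaps(gr, blacklist) == 0L]
}
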