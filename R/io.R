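#' Build a GRanges from 0-based half-open coordinates
#'
#' Internal constructor used at every I/O boundary: BED, chain and bedGraph
#' files are 0-based half-open on disk, GRanges is 1-based closed in memory.
#'
#' @param chrom character vector of chromosome names.
#' @param start0,end0 integer vectors, 0-based half-open.
#' @param ... metadata columns.
#' @param strand strand vector, defaults to "*" (unstranded MeDIP signal).
#' @return A \link[GenomicRanges]{GRanges}.
#' @keywords internal
gr0 <- function(chrom, start0, end0, ..., strand = "*") {
  if (any(start0 < 0) || any(end0 <= start0)) {
    stop("invalid interval: require 0 <= start < end")
  }
  GRanges(chrom, IRanges(start0 + 1L, end0),
          strand = rep_len(strand, length(chrom)), ...)
}

#' 0-based start/end of a GRanges
#' @param gr A GRanges.
#' @return data.frame with chrom, start (0-based), end (exclusive), strand.
#' @keywords internal
bed0 <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L,
             end   = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read genomic intervals from a BED-like file
#'
#' Supported dialects: \code{bed3} (chrom, start, end), \code{bed6} (+ name,
#' score, strand) and \code{scored-peak} (bed6 + summit offset + caller tag,
#' as written by the peak callers). Coordinates on disk are 0-based
#' half-open; the returned GRanges is 1-based closed. Input order is
#' preserved. Malformed lines (non-integer coordinates, start >= end) raise
#' an error naming the offending line.
#'
#' @param path file path.
#' @param dialect one of "bed3", "bed6", "scored-peak".
#' @return GRanges; for bed6 with \code{name}, \code{score} metadata columns,
#'   for scored-peak additionally \code{summit} (0-based offset within the
#'   interval) and \code{caller}.
#' @export
read_intervals <- function(path, dialect = c("bed3", "bed6", "scored-peak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncol_needed <- switch(dialect, bed3 = 3L, bed6 = 6L, `scored-peak` = 8L)
  if (length(lines) == 0L) {
    gr <- GRanges()
    if (dialect != "bed3") {
      mcols(gr)$name <- character(0)
      mcols(gr)$score <- numeric(0)
    }
    if (dialect == "scored-peak") {
      mcols(gr)$summit <- integer(0)
      mcols(gr)$caller <- character(0)
    }
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad)) {
    stop("line ", bad[1L], ": expected >= ", ncol_needed, " tab-separated fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_needed)))
  s <- suppressWarnings(as.integer(m[, 2L]))
  e <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad)) stop("line ", bad[1L], ": non-integer coordinate")
  bad <- which(s < 0L | e <= s)
  if (length(bad)) {
    stop("line ", bad[1L], ": invalid interval (require 0 <= start < end)")
  }
  if (any(!nzchar(m[, 1L]))) stop("empty chromosome name")
  if (dialect == "bed3") return(gr0(m[, 1L], s, e))
  strand <- m[, 6L]
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- gr0(m[, 1L], s, e, strand = strand,
            name = m[, 4L], score = as.numeric(m[, 5L]))
  if (dialect == "scored-peak") {
    summit <- suppressWarnings(as.integer(m[, 7L]))
    bad <- which(is.na(summit) | summit < 0L | summit >= (e - s))
    if (length(bad)) stop("line ", bad[1L], ": summit outside interval")
    mcols(gr)$summit <- summit
    mcols(gr)$caller <- m[, 8L]
  }
  gr
}

#' Write intervals as BED (or scored-peak) text
#'
#' BED6 score column is the transformed p-value rounded to one decimal;
#' strand "." for unstranded regions.
#'
#' @param gr GRanges (metadata columns name/score/summit/caller used when
#'   present).
#' @param path output path.
#' @param dialect output dialect, see [read_intervals()].
#' @export
write_intervals <- function(gr, path, dialect = c("bed6", "bed3", "scored-peak")) {
  dialect <- match.arg(dialect)
  b <- bed0(gr)
  b$strand[b$strand == "*"] <- "."
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    paste0("region_", seq_along(gr))
  sc <- if (!is.null(mcols(gr)$score)) round(mcols(gr)$score, 1) else 0
  out <- switch(dialect,
    bed3 = b[, c("chrom", "start", "end")],
    bed6 = data.frame(b$chrom, b$start, b$end, nm, sc, b$strand),
    `scored-peak` = data.frame(b$chrom, b$start, b$end, nm, sc, b$strand,
                               summit = mcols(gr)$summit,
                               caller = mcols(gr)$caller))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Parses gapped alignment chains between two assemblies. The first genome
#' in each header is the source (the build coordinates are lifted from), the
#' second the target. Block sums are validated against the declared spans:
#' aligned sizes plus source gaps must equal the source span, plus target
#' gaps the target span.
#'
#' @param path chain file path.
#' @return A \code{chain_set}: list of chains, each carrying score,
#'   source/target (chrom, size, strand, start, end), an id, and a block
#'   table with columns \code{size} (aligned length), \code{ds} (gap on the
#'   source between this block and the next) and \code{dt} (gap on the
#'   target). Coordinates are 0-based half-open as in the file; minus-strand
#'   target coordinates are kept in reverse-complement space as written.
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (f[1L] != "chain" || length(f) < 12L) {
      stop("line ", i, ": expected chain header")
    }
    hd <- list(score = as.numeric(f[2L]),
               s_chrom = f[3L], s_size = as.numeric(f[4L]), s_strand = f[5L],
               s_start = as.numeric(f[6L]), s_end = as.numeric(f[7L]),
               t_chrom = f[8L], t_size = as.numeric(f[9L]), t_strand = f[10L],
               t_start = as.numeric(f[11L]), t_end = as.numeric(f[12L]),
               id = if (length(f) >= 13L) f[13L] else NA_character_)
    i <- i + 1L
    size <- ds <- dt <- numeric(0)
    repeat {
      if (i > n) stop("truncated chain block list")
      bf <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
      i <- i + 1L
      if (length(bf) == 1L && nzchar(bf)) {
        size <- c(size, as.numeric(bf)); ds <- c(ds, 0); dt <- c(dt, 0)
        break
      }
      if (length(bf) != 3L) stop("malformed chain block line")
      size <- c(size, as.numeric(bf[1L]))
      ds <- c(ds, as.numeric(bf[2L]))
      dt <- c(dt, as.numeric(bf[3L]))
    }
    if (sum(size) + sum(ds) != hd$s_end - hd$s_start) {
      stop("chain ", hd$id, ": block sums inconsistent with source span")
    }
    if (sum(size) + sum(dt) != hd$t_end - hd$t_start) {
      stop("chain ", hd$id, ": block sums inconsistent with target span")
    }
    hd$blocks <- data.frame(size = size, ds = ds, dt = dt)
    # per-block 0-based start offsets, precomputed for fast per-base mapping
    hd$s_bs <- hd$s_start + cumsum(c(0, size + ds))[seq_along(size)]
    hd$t_bs <- hd$t_start + cumsum(c(0, size + dt))[seq_along(size)]
    chains[[length(chains) + 1L]] <- hd
  }
  structure(list(chains = chains), class = "chain_set")
}

#' Write a chain_set in UCSC chain format
#' @param cs chain_set as returned by [read_chain()].
#' @param path output path.
#' @export
write_chain <- function(cs, path) {
  stopifnot(inherits(cs, "chain_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(cs$chains)) {
    ch <- cs$chains[[k]]
    id <- if (is.na(ch$id)) as.character(k) else ch$id
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$s_chrom, format(ch$s_size, scientific = FALSE),
                     ch$s_strand,
                     format(ch$s_start, scientific = FALSE),
                     format(ch$s_end, scientific = FALSE),
                     ch$t_chrom, format(ch$t_size, scientific = FALSE),
                     ch$t_strand,
                     format(ch$t_start, scientific = FALSE),
                     format(ch$t_end, scientific = FALSE), id), con)
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1L) {
      writeLines(paste(b$size[-nb], b$ds[-nb], b$dt[-nb]), con)
    }
    writeLines(c(as.character(b$size[nb]), ""), con)
  }
  invisible(path)
}

#' @export
print.chain_set <- function(x, ...) {
  cat("chain_set with", length(x$chains), "chains\n")
  for (ch in head(x$chains, 5L)) {
    cat(sprintf("  %s:%d-%d -> %s:%d-%d (%s) %d blocks\n",
                ch$s_chrom, ch$s_start, ch$s_end,
                ch$t_chrom, ch$t_start, ch$t_end, ch$t_strand,
                nrow(ch$blocks)))
  }
  invisible(x)
}

#' Read / write FASTA
#'
#' Thin validated wrappers over Biostrings. Sequences are restricted to the
#' analysis alphabet A, C, G, T, N; case is normalized to upper on read
#' (analysis is case-insensitive; soft-masking is not used). Duplicate
#' record names are an error.
#'
#' @param path file path.
#' @return \link[Biostrings]{DNAStringSet}.
#' @export
read_fasta <- function(path) {
  x <- readDNAStringSet(path)
  if (anyDuplicated(names(x))) stop("duplicate sequence names in ", path)
  freq <- alphabetFrequency(x)
  ok <- c("A", "C", "G", "T", "N")
  extra <- rowSums(freq[, !colnames(freq) %in% ok, drop = FALSE])
  if (any(extra > 0)) {
    stop("illegal character(s) in sequence: ",
         names(x)[which(extra > 0)[1L]])
  }
  x
}

#' @rdname read_fasta
#' @param seqs named DNAStringSet or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read position count matrices (TRANSFAC-like)
#'
#' Format: records delimited by \code{//}, each starting with an \code{ID}
#' line, followed by a \code{PO A C G T} column header and one numbered
#' count row per motif position. Counts are converted to per-position base
#' frequencies with a pseudocount:
#' \code{f = (count + pc) / (rowsum + 4 pc)}.
#'
#' @param path file path.
#' @param pseudocount small positive number added to every count (default 1).
#' @return named list of \code{weight_matrix} objects (id, counts, freqs,
#'   width, pseudocount).
#' @export
read_weight_matrix <- function(path, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  recs <- split(lines, cumsum(lines == "//"))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "//"]
    if (!length(rec)) next
    idl <- grep("^ID\\b", rec, value = TRUE)
    if (!length(idl)) stop("weight matrix record without ID line")
    id <- strsplit(idl[1L], "[ \t]+")[[1L]][2L]
    rows <- grep("^[0-9]+[ \t]", rec, value = TRUE)
    if (!length(rows)) stop("zero-width matrix: ", id)
    cnt <- do.call(rbind, lapply(strsplit(rows, "[ \t]+"), function(f) {
      as.numeric(f[2:5])
    }))
    if (any(is.na(cnt))) stop("non-numeric count in matrix ", id)
    if (any(cnt < 0)) stop("negative count in matrix ", id)
    colnames(cnt) <- c("A", "C", "G", "T")
    out[[id]] <- weight_matrix(id, cnt, pseudocount)
  }
  out
}

#' Construct a weight_matrix from a count matrix
#' @param id motif name.
#' @param counts W x 4 numeric matrix, columns A, C, G, T.
#' @param pseudocount positive pseudocount.
#' @return weight_matrix object with normalized frequencies.
#' @export
weight_matrix <- function(id, counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) != 4L) {
    stop("counts must be a W x 4 matrix with W >= 1")
  }
  if (any(counts < 0)) stop("negative count")
  colnames(counts) <- c("A", "C", "G", "T")
  freqs <- (counts + pseudocount) /
    (rowSums(counts) + 4 * pseudocount)
  structure(list(id = id, counts = counts, freqs = freqs,
                 width = nrow(counts), pseudocount = pseudocount),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("weight_matrix", x$id, "width", x$width, "\n")
  print(round(x$freqs, 3))
  invisible(x)
}

#' Write a binned coverage track as bedGraph
#' @param track coverage track from [rpm_track()].
#' @param path output path.
#' @param value "count" or "rpm".
#' @export
write_bedgraph <- function(track, path, value = c("count", "rpm")) {
  value <- match.arg(value)
  rows <- lapply(names(track$bins), function(chrom) {
    v <- track$bins[[chrom]]
    if (value == "rpm") v <- v * 1e6 / track$library_total
    nb <- length(v)
    data.frame(chrom = chrom,
               start = (seq_len(nb) - 1L) * track$bin_width,
               end = pmin(seq_len(nb) * track$bin_width,
                          track$chrom_lengths[[chrom]]),
               value = v)
  })
  out <- do.call(rbind, rows)
  out <- out[out$value != 0, , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
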