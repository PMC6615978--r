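#' Genomic intervals and BED input
#'
#' Throughout the package a genomic region is a data frame with columns
#' `chrom`, `start`, `end` (and optionally `name`), using 0-based
#' half-open coordinates as in the BED format. These helpers convert
#' between that representation, `GRanges`, and BED files on disk.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name optional character vector of region names.
#' @return A `genomic_intervals` data frame.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop(sprintf("empty or inverted interval: %s:%d-%d",
                 chrom[bad], start[bad], end[bad]))
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read a BED file into 0-based half-open intervals
#'
#' @param path BED file location.
#' @return A `genomic_intervals` data frame (with `name` when the BED has
#'   a name column).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr),
                    name = nm)
}

#' Write intervals to a BED file
#'
#' @param intervals a `genomic_intervals` data frame.
#' @param path output location.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, intersect(c("chrom", "start", "end", "name"),
                                names(intervals)), drop = FALSE]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view (1-based closed) of a 0-based half-open interval frame.
as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end),
    name = if (!is.null(intervals$name)) intervals$name else NA_character_
  )
}

# Check intervals against a sequence dictionary; fatal on violation.
validate_intervals <- function(intervals, dict) {
  for (i in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[i]
    len <- dict$length[match(chrom, dict$name)]
    if (is.na(len)) {
      stop(sprintf("interval %s:%d-%d names a chromosome absent from the reference",
                   chrom, intervals$start[i], intervals$end[i]))
    }
    if (intervals$end[i] > len) {
      stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                   chrom, intervals$start[i], intervals$end[i], len))
    }
  }
  invisible(intervals)
}
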