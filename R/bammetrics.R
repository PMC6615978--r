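#' Approximate window depth from read lengths
#'
#' The traversal heuristic: depth over a window is the total length of
#' the primary-alignment reads assigned to it divided by the window
#' length. It equals exact per-base depth whenever every read lies wholly
#' inside one window, and converges to it as windows grow.
#'
#' @param read_lengths lengths of the primary reads assigned to the
#'   window (query lengths by default throughout the package).
#' @param window_start,window_end 0-based half-open window bounds.
#' @return approximate depth (>= 0; 0 when no reads).
#' @export
approx_window_depth <- function(read_lengths, window_start, window_end) {
  len <- window_end - window_start
  if (len <= 0) stop("zero-length window: ", window_start, "-", window_end)
  if (length(read_lengths) == 0L) return(0)
  sum(as.numeric(read_lengths)) / len
}

#' Mean mapping quality of a window
#'
#' @param mapqs MAPQ values of the assigned primary reads.
#' @return list with `mean_mapq` (0 when empty) and `empty` flag.
#' @export
window_mean_mapq <- function(mapqs) {
  if (length(mapqs) == 0L) return(list(mean_mapq = 0, empty = TRUE))
  list(mean_mapq = mean(mapqs), empty = FALSE)
}

scan_primary <- function(bam, chrom, chrom_len, exclude_duplicates = FALSE) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (exclude_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("pos", "qwidth", "mapq", "cigar"),
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, chrom_len)))
  Rsamtools::scanBam(bam, param = param)[[1L]]
}

#' Traverse a BAM in windows of depth and mapping quality
#'
#' Tiles each chromosome with consecutive non-overlapping windows (the
#' final window truncated at the chromosome end) and reports, per window,
#' the approximate depth, mean MAPQ and primary-read count. Each primary
#' alignment is assigned to exactly one window — the one containing its
#' leftmost aligned position — so read counts are conserved across the
#' traversal.
#'
#' @param bam coordinate-sorted, indexed BAM path.
#' @param chroms chromosomes to traverse (default: all in the header).
#' @param window_size window size in bp (the field's scatter plots
#'   typically use 5 kb windows; 1-5 kb is the useful range).
#' @param exclude_duplicates drop duplicate-flagged reads (kept by
#'   default).
#' @param length_mode `"query"` counts each read's query sequence length;
#'   `"reference"` counts its CIGAR span on the reference.
#' @return data frame of class `window_metrics`: chrom, start, end
#'   (0-based half-open), approx_depth, mean_mapq, n_primary, empty.
#' @export
traverse_bam <- function(bam, chroms = NULL, window_size = 5000L,
                         exclude_duplicates = FALSE,
                         length_mode = c("query", "reference")) {
  length_mode <- match.arg(length_mode)
  require_bam_index(bam)
  window_size <- as.integer(window_size)
  stopifnot(window_size > 0L)
  dict <- bam_dictionary(bam)
  if (is.null(chroms)) chroms <- dict$name
  missing <- setdiff(chroms, dict$name)
  if (length(missing)) {
    stop("chromosome(s) absent from BAM header: ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(chroms, function(chrom) {
    len <- dict$length[dict$name == chrom]
    n_win <- as.integer(ceiling(len / window_size))
    start <- (seq_len(n_win) - 1L) * window_size
    end <- pmin(start + window_size, len)
    res <- scan_primary(bam, chrom, len, exclude_duplicates)
    rl <- if (length_mode == "query") res$qwidth else
      GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
    win <- (res$pos - 1L) %/% window_size + 1L
    depth_sum <- numeric(n_win)
    mapq_sum <- numeric(n_win)
    n_reads <- integer(n_win)
    if (length(win)) {
      n_reads <- tabulate(win, nbins = n_win)
      depth_sum <- as.numeric(rowsum_by(as.numeric(rl), win, n_win))
      mapq_sum <- as.numeric(rowsum_by(as.numeric(res$mapq), win, n_win))
    }
    data.frame(chrom = chrom, start = start, end = end,
               approx_depth = depth_sum / (end - start),
               mean_mapq = ifelse(n_reads > 0L, mapq_sum / n_reads, 0),
               n_primary = n_reads,
               empty = n_reads == 0L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("window_metrics", "data.frame")
  res
}

# sum of x by integer group 1..n (dense)
rowsum_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Threshold windows into pass and fail sets
#'
#' A window passes when its mean MAPQ is at or above `min_mapq` and its
#' approximate depth lies within `depth_bounds` multiples of its
#' chromosome's mean window depth (all comparisons inclusive). Empty
#' windows always fail. Pass and fail partition the input exactly.
#'
#' @param windows a `window_metrics` frame from [traverse_bam()].
#' @param min_mapq minimum mean MAPQ (default 30; the `"strict"` preset
#'   uses 55, the threshold needed to suppress residual XTR homology).
#' @param depth_bounds `(low, high)` multiples of the per-chromosome mean
#'   window depth (default `c(0.25, 4)`).
#' @param preset `"default"` or `"strict"`; `"strict"` raises `min_mapq`
#'   to 55 unless `min_mapq` was given explicitly.
#' @return list with `pass` and `fail` `window_metrics` frames.
#' @export
filter_windows <- function(windows, min_mapq = 30,
                           depth_bounds = c(0.25, 4),
                           preset = c("default", "strict")) {
  preset <- match.arg(preset)
  if (preset == "strict" && missing(min_mapq)) min_mapq <- 55
  if (depth_bounds[1L] > depth_bounds[2L]) {
    stop("depth_bounds low > high: ", depth_bounds[1L], " > ", depth_bounds[2L])
  }
  mu <- stats::ave(windows$approx_depth, windows$chrom, FUN = mean)
  ok <- !windows$empty &
    windows$mean_mapq >= min_mapq &
    windows$approx_depth >= depth_bounds[1L] * mu &
    windows$approx_depth <= depth_bounds[2L] * mu
  list(pass = windows[ok, , drop = FALSE],
       fail = windows[!ok, , drop = FALSE])
}

#' Write window sets to BED
#'
#' @param windows a `window_metrics` frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  write_bed(genomic_intervals(windows$chrom, windows$start, windows$end), path)
}

#' Per-chromosome summary statistics over one or more BAMs
#'
#' Quick whole-chromosome comparison of primary-read count, mean MAPQ and
#' approximate depth (the chromosome treated as a single window) across
#' samples — sufficient to cluster XX and XY individuals in
#' well-differentiated systems.
#'
#' @param bams character vector of BAM paths.
#' @param chroms chromosomes to summarise.
#' @param sample_ids identifiers per BAM (defaults to file names).
#' @return data frame of class `chrom_stats`: sample_id, chrom, n_reads,
#'   mean_mapq, mean_depth.
#' @export
chrom_stats <- function(bams, chroms, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- basename(bams)
  stopifnot(length(sample_ids) == length(bams))
  rows <- list()
  for (i in seq_along(bams)) {
    require_bam_index(bams[i])
    dict <- bam_dictionary(bams[i])
    for (chrom in chroms) {
      len <- dict$length[match(chrom, dict$name)]
      if (is.na(len)) {
        warning("chromosome ", chrom, " missing from ", bams[i],
                "; reporting zero reads")
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_ids[i], chrom = chrom, n_reads = 0L,
          mean_mapq = 0, mean_depth = 0, stringsAsFactors = FALSE)
        next
      }
      res <- scan_primary(bams[i], chrom, len)
      n <- length(res$pos)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids[i], chrom = chrom, n_reads = n,
        mean_mapq = if (n) mean(res$mapq) else 0,
        mean_depth = if (n) sum(as.numeric(res$qwidth)) / len else 0,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("chrom_stats", "data.frame")
  res
}

#' Normalize chromosome statistics to a denominator chromosome
#'
#' Divides each sample's per-chromosome depth, MAPQ and read count by the
#' same sample's value on a denominator chromosome (an autosome such as
#' chr19 in human work), yielding the relative metrics used to separate
#' XX from XY samples across sequencing strategies.
#'
#' @param stats a `chrom_stats` frame.
#' @param denominator chromosome to normalize by (must be present for
#'   every sample).
#' @return the input with `rel_depth`, `rel_mapq`, `rel_reads` columns;
#'   relative values are `NA` where the denominator is 0 and the
#'   numerator is not (0/0 is reported as 0).
#' @export
normalize_to_chrom <- function(stats, denominator) {
  out <- list()
  for (sid in unique(stats$sample_id)) {
    s <- stats[stats$sample_id == sid, , drop = FALSE]
    d <- s[s$chrom == denominator, , drop = FALSE]
    if (nrow(d) != 1L) {
      stop("denominator chromosome ", denominator,
           " not present exactly once for sample ", sid)
    }
    rel <- function(num, den) {
      if (den == 0) ifelse(num == 0, 0, NA_real_) else num / den
    }
    s$rel_depth <- rel(s$mean_depth, d$mean_depth)
    s$rel_mapq <- rel(s$mean_mapq, d$mean_mapq)
    s$rel_reads <- rel(s$n_reads, d$n_reads)
    out[[sid]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("chrom_stats", "data.frame")
  res
}
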