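#' Plot windowed depth and mapping quality along chromosomes
#'
#' One row per chromosome, with approximate depth (left axis, points)
#' and mean MAPQ (right axis, points) against window midpoints — the
#' genomic scatter view in which PARs and XTR-like regions stand out as
#' MAPQ troughs and depth anomalies.
#'
#' @param x a `window_metrics` frame from [traverse_bam()].
#' @param chroms chromosomes to draw (default all present).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.window_metrics <- function(x, chroms = unique(x$chrom), ...) {
  old <- graphics::par(mfrow = c(length(chroms), 2L),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (chrom in chroms) {
    w <- x[x$chrom == chrom, , drop = FALSE]
    mid <- (w$start + w$end) / 2 / 1e3
    graphics::plot(mid, w$approx_depth, pch = 20, cex = 0.5,
                   xlab = paste(chrom, "position (kb)"),
                   ylab = "approx. depth", main = paste(chrom, "depth"), ...)
    graphics::plot(mid, w$mean_mapq, pch = 20, cex = 0.5, ylim = c(0, 61),
                   xlab = paste(chrom, "position (kb)"),
                   ylab = "mean MAPQ", main = paste(chrom, "MAPQ"), ...)
  }
  invisible(x)
}

#' Plot a read-balance histogram
#'
#' @param x a `balance_histogram`.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.balance_histogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = formatC(x$mids, format = "f",
                                                  digits = 2),
                    las = 2, cex.names = 0.6,
                    xlab = "read balance (alt / (ref + alt))",
                    ylab = "sites",
                    main = if (x$heterozygous_view)
                      "Read balance (0.05 < b < 1.0)" else
                        "Read balance (all sites)", ...)
  invisible(x)
}

#' Plot relative depth of sex chromosomes across samples
#'
#' Scatter of X vs Y depth relative to the denominator autosome; XX and
#' XY samples separate along the Y axis.
#'
#' @param x a normalized `chrom_stats` frame (see [normalize_to_chrom()]).
#' @param x_chrom,y_chrom sex chromosome names.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.chrom_stats <- function(x, x_chrom = "chrX", y_chrom = "chrY", ...) {
  if (is.null(x$rel_depth)) {
    stop("plot.chrom_stats needs normalized stats; run normalize_to_chrom()")
  }
  xs <- x[x$chrom == x_chrom, ]
  ys <- x[x$chrom == y_chrom, ]
  m <- merge(xs[, c("sample_id", "rel_depth")],
             ys[, c("sample_id", "rel_depth")], by = "sample_id",
             suffixes = c("_x", "_y"))
  graphics::plot(m$rel_depth_x, m$rel_depth_y,
                 xlab = paste("relative depth", x_chrom),
                 ylab = paste("relative depth", y_chrom),
                 pch = 19, ...)
  graphics::text(m$rel_depth_x, m$rel_depth_y, m$sample_id,
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' Plot before/after deltas from a pipeline run
#'
#' Signed log10 depth deltas and raw MAPQ deltas per window for one
#' sample, highlighting where remapping changed the metrics.
#'
#' @param x an `xy_pipeline` object.
#' @param sample sample identifier (default first remapped sample).
#' @param chroms chromosomes to draw.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.xy_pipeline <- function(x, sample = NULL, chroms = NULL, ...) {
  remapped <- Filter(function(s) isTRUE(s$remapped), x$samples)
  if (length(remapped) == 0L) stop("no remapped samples to plot")
  s <- if (is.null(sample)) remapped[[1L]] else x$samples[[sample]]
  d <- s$delta
  if (is.null(chroms)) chroms <- unique(d$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (chrom in chroms) {
    w <- d[d$chrom == chrom, , drop = FALSE]
    mid <- (w$start + w$end) / 2 / 1e3
    graphics::plot(mid, w$depth_delta, pch = 20, cex = 0.5,
                   xlab = paste(chrom, "position (kb)"),
                   ylab = "sign x |log10 depth diff|",
                   main = paste(s$sample_id, chrom, "depth delta"), ...)
    graphics::abline(h = 0, lty = 2)
    graphics::plot(mid, w$mapq_delta, pch = 20, cex = 0.5,
                   xlab = paste(chrom, "position (kb)"),
                   ylab = "MAPQ after - before",
                   main = paste(s$sample_id, chrom, "MAPQ delta"), ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
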