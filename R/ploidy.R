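#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the window depths with replacement `n_boot` times and takes
#' the `alpha/2` and `1 - alpha/2` percentiles of the resampled means —
#' the 95% interval (default) used to test whether two chromosomes'
#' mean window depths overlap.
#'
#' @param values numeric vector (e.g. per-window approximate depths).
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param alpha two-sided miss probability (default 0.05).
#' @param seed optional integer seed; identical seeds give bit-identical
#'   intervals.
#' @return list with `mean`, `low`, `high`, `n`, `n_boot`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 10000L, alpha = 0.05,
                              seed = NULL) {
  if (length(values) == 0L) stop("cannot bootstrap an empty vector")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  # resample in chunks to bound memory at large n * n_boot
  chunk <- max(1L, min(n_boot, as.integer(ceiling(2e7 / n))))
  means <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    k <- min(chunk, n_boot - done)
    m <- matrix(values[sample.int(n, n * k, replace = TRUE)], nrow = n)
    means[done + seq_len(k)] <- colMeans(m)
    done <- done + k
  }
  ci <- unname(stats::quantile(means, c(alpha / 2, 1 - alpha / 2)))
  list(mean = mean(values), low = ci[1L], high = ci[2L],
       n = n, n_boot = n_boot)
}

# bootstrap CI of the ratio mean(a)/mean(b); a may be empty (ratio 0)
bootstrap_ratio_ci <- function(a, b, n_boot = 10000L, alpha = 0.05,
                               seed = NULL) {
  if (length(b) == 0L) stop("denominator window set is empty")
  if (!is.null(seed)) set.seed(seed)
  if (length(a) == 0L) {
    return(list(ratio = 0, low = 0, high = 0, n_a = 0L, n_b = length(b)))
  }
  na <- length(a)
  nb <- length(b)
  ratios <- vapply(seq_len(n_boot), function(i) {
    mean(a[sample.int(na, na, replace = TRUE)]) /
      mean(b[sample.int(nb, nb, replace = TRUE)])
  }, 0)
  ci <- unname(stats::quantile(ratios, c(alpha / 2, 1 - alpha / 2),
                               na.rm = TRUE))
  list(ratio = mean(a) / mean(b), low = ci[1L], high = ci[2L],
       n_a = length(a), n_b = length(b))
}

#' Permutation test for a difference in mean depth
#'
#' Statistic: absolute difference in means. Labels are shuffled
#' `n_perm` times and the Monte-Carlo p-value carries the add-one
#' correction `(b + 1) / (n_perm + 1)`, so it is never exactly 0. With
#' `exact = TRUE` (or `"auto"` on small inputs) every distinct label
#' assignment is enumerated instead and the p-value is the exact
#' fraction of assignments at or beyond the observed statistic.
#'
#' @param a,b numeric vectors of window depths.
#' @param n_perm number of random label shuffles (default 10000).
#' @param seed optional integer seed.
#' @param exact `TRUE`, `FALSE`, or `"auto"` (exact when
#'   `choose(n, n_a) <= 200000`).
#' @return list with `p`, `observed`, `method`, and `n_perm` or
#'   `n_assignments`.
#' @export
permutation_depth_test <- function(a, b, n_perm = 10000L, seed = NULL,
                                   exact = FALSE) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  tol <- 1e-12 * max(1, obs)
  if (identical(exact, "auto")) exact <- choose(n, na) <= 2e5
  if (isTRUE(exact)) {
    if (choose(n, na) > 2e5) stop("too many label assignments to enumerate")
    idx <- utils::combn(n, na)
    tot <- sum(pool)
    sa <- colSums(matrix(pool[idx], nrow = na))
    stats <- abs(sa / na - (tot - sa) / (n - na))
    p <- mean(stats >= obs - tol)
    return(list(p = p, observed = obs, method = "exact",
                n_assignments = ncol(idx)))
  }
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  tot <- sum(pool)
  for (i in seq_len(n_perm)) {
    ia <- sample.int(n, na)
    sa <- sum(pool[ia])
    stat <- abs(sa / na - (tot - sa) / (n - na))
    if (stat >= obs - tol) exceed <- exceed + 1L
  }
  list(p = (exceed + 1L) / (n_perm + 1L), observed = obs,
       method = "monte-carlo", n_perm = n_perm)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the
#' p-value uses the asymptotic two-sample formula.
#'
#' @param a,b numeric vectors.
#' @return list with `d` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(d = unname(res$statistic), p = unname(res$p.value))
}

#' Compare window depth between a chromosome pair
#'
#' Runs the three depth comparisons (bootstrap CIs with overlap check,
#' permutation test, two-sample KS test) on threshold-passing window
#' depths of two chromosomes. One side may be empty (e.g. the Y of an XX
#' sample after filtering drops every window): its mean is reported as 0
#' with a degenerate (0, 0) interval and NA permutation/KS results, with
#' a warning.
#'
#' @param windows_a,windows_b numeric depth vectors, or `window_metrics`
#'   frames (their `approx_depth` column is used).
#' @param chrom_a,chrom_b chromosome labels for reporting.
#' @param n_boot,n_perm,alpha test parameters.
#' @param seed integer seed; all three tests draw from one seeded stream.
#' @return object of class `depth_comparison`.
#' @export
compare_chrom_pair <- function(windows_a, windows_b,
                               chrom_a = "a", chrom_b = "b",
                               n_boot = 10000L, n_perm = 10000L,
                               alpha = 0.05, seed = 1L) {
  depths <- function(w) if (is.data.frame(w)) w$approx_depth else as.numeric(w)
  a <- depths(windows_a)
  b <- depths(windows_b)
  set.seed(seed)
  side <- function(v, label) {
    if (length(v) == 0L) {
      warning("no windows for ", label, "; reporting depth 0")
      list(mean = 0, low = 0, high = 0, n = 0L, n_boot = n_boot)
    } else {
      bootstrap_mean_ci(v, n_boot = n_boot, alpha = alpha)
    }
  }
  ci_a <- side(a, chrom_a)
  ci_b <- side(b, chrom_b)
  both <- length(a) > 0L && length(b) > 0L
  perm <- if (both) permutation_depth_test(a, b, n_perm = n_perm) else
    list(p = NA_real_, observed = NA_real_)
  ks <- if (both) ks_two_sample(a, b) else list(d = NA_real_, p = NA_real_)
  structure(list(
    chrom_a = chrom_a, chrom_b = chrom_b,
    mean_a = ci_a$mean, mean_b = ci_b$mean,
    ci_a = c(ci_a$low, ci_a$high), ci_b = c(ci_b$low, ci_b$high),
    ci_overlap = ci_a$low <= ci_b$high && ci_b$low <= ci_a$high,
    perm_p = perm$p, ks_d = ks$d, ks_p = ks$p,
    n_windows_a = length(a), n_windows_b = length(b),
    values_a = a, values_b = b,
    seed = seed, n_boot = n_boot, n_perm = n_perm, alpha = alpha),
    class = "depth_comparison")
}

#' @export
print.depth_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Depth comparison: %s vs %s\n", x$chrom_a, x$chrom_b))
  cat(sprintf("  %s: mean %.4g, %d%% CI [%.4g, %.4g], %d windows\n",
              x$chrom_a, x$mean_a, round(100 * (1 - x$alpha)),
              x$ci_a[1L], x$ci_a[2L], x$n_windows_a))
  cat(sprintf("  %s: mean %.4g, %d%% CI [%.4g, %.4g], %d windows\n",
              x$chrom_b, x$mean_b, round(100 * (1 - x$alpha)),
              x$ci_b[1L], x$ci_b[2L], x$n_windows_b))
  cat("  CI overlap:", x$ci_overlap,
      sprintf("| permutation p = %.4g | KS D = %.4g (p = %.4g)\n",
              x$perm_p, x$ks_d, x$ks_p))
  invisible(x)
}

#' Thresholds for the sex-complement decision rule
#'
#' The decision runs on depth ratios relative to a reference autosome.
#' With rY = mean Y depth / mean autosome depth (bootstrap CI), the Y is
#' called absent when the CI upper bound is below `t_absent`, present
#' when the lower bound exceeds `t_present`, else indeterminate. The X
#' is diploid-like when its ratio CI overlaps `x_diploid`, haploid-like
#' when the CI lies inside `x_haploid`. All are engineering defaults
#' exposed for tuning; no universal threshold separates complements
#' across organisms and sequencing strategies.
#'
#' @param t_absent,t_present Y-ratio CI bounds for absence/presence.
#' @param x_diploid,x_haploid X-ratio intervals (see above).
#' @return list of thresholds.
#' @export
sex_call_thresholds <- function(t_absent = 0.10, t_present = 0.25,
                                x_diploid = c(0.8, 1.2),
                                x_haploid = c(0.3, 0.7)) {
  list(t_absent = t_absent, t_present = t_present,
       x_diploid = x_diploid, x_haploid = x_haploid)
}

#' Infer the sex-chromosome complement from depth comparisons
#'
#' Combines an X-vs-autosome and a Y-vs-autosome depth comparison (both
#' against the same autosome) into a complement call. Only the bootstrap
#' ratio intervals drive the decision; the permutation and KS results
#' are carried as evidence. A chromosome with zero passing windows
#' contributes ratio 0 with a degenerate interval (absence evidence).
#'
#' @param comparison_x `depth_comparison` of X vs the autosome.
#' @param comparison_y `depth_comparison` of Y vs the same autosome.
#' @param thresholds from [sex_call_thresholds()].
#' @param labels chromosome-complement labels for (homogametic,
#'   heterogametic), by default `c("XX", "XY")`; use `c("ZZ", "ZW")`
#'   with roles swapped for ZW systems.
#' @param sample_id identifier carried into the call.
#' @param n_boot bootstrap resamples for the ratio intervals.
#' @param seed integer seed.
#' @return object of class `sex_call`: `complement_label`, `y_present`,
#'   `x_ploidy_hint`, ratio evidence and the two comparisons.
#' @export
infer_sex_complement <- function(comparison_x, comparison_y,
                                 thresholds = sex_call_thresholds(),
                                 labels = c("XX", "XY"),
                                 sample_id = "sample",
                                 n_boot = NULL, seed = 1L) {
  if (!inherits(comparison_x, "depth_comparison") ||
      !inherits(comparison_y, "depth_comparison")) {
    stop("both comparisons must be depth_comparison objects")
  }
  if (comparison_x$chrom_b != comparison_y$chrom_b) {
    stop("comparisons use different denominator chromosomes: ",
         comparison_x$chrom_b, " vs ", comparison_y$chrom_b)
  }
  if (is.null(n_boot)) n_boot <- comparison_x$n_boot
  set.seed(seed)
  r_x <- bootstrap_ratio_ci(comparison_x$values_a, comparison_x$values_b,
                            n_boot = n_boot, alpha = comparison_x$alpha)
  r_y <- bootstrap_ratio_ci(comparison_y$values_a, comparison_y$values_b,
                            n_boot = n_boot, alpha = comparison_y$alpha)
  y_present <- if (r_y$high < thresholds$t_absent) "absent"
  else if (r_y$low > thresholds$t_present) "present"
  else "indeterminate"
  x_ploidy <- if (r_x$low > thresholds$x_haploid[1L] &&
                  r_x$high < thresholds$x_haploid[2L]) "haploid-like"
  else if (r_x$high >= thresholds$x_diploid[1L] &&
           r_x$low <= thresholds$x_diploid[2L]) "diploid-like"
  else "indeterminate"
  label <- if (y_present == "absent" && x_ploidy == "diploid-like") labels[1L]
  else if (y_present == "present" && x_ploidy == "haploid-like") labels[2L]
  else "indeterminate"
  structure(list(sample_id = sample_id,
                 complement_label = label,
                 y_present = y_present,
                 x_ploidy_hint = x_ploidy,
                 ratio_x = r_x, ratio_y = r_y,
                 thresholds = thresholds,
                 comparison_x = comparison_x,
                 comparison_y = comparison_y,
                 seed = seed),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("Sex-chromosome complement call for %s: %s\n",
              x$sample_id, x$complement_label))
  cat(sprintf("  Y: %s  (ratio %.3f, CI [%.3f, %.3f] vs %s)\n",
              x$y_present, x$ratio_y$ratio, x$ratio_y$low, x$ratio_y$high,
              x$comparison_y$chrom_b))
  cat(sprintf("  X: %s  (ratio %.3f, CI [%.3f, %.3f])\n",
              x$x_ploidy_hint, x$ratio_x$ratio, x$ratio_x$low, x$ratio_x$high))
  invisible(x)
}

#' @export
summary.sex_call <- function(object, ...) {
  print(object)
  cat("\nUnderlying depth comparisons:\n")
  print(object$comparison_x)
  print(object$comparison_y)
  invisible(object)
}

#' Quick complement classification from chromosome statistics
#'
#' Uses length-normalized Y read-count ratios (reads per bp on Y over
#' reads per bp on the denominator autosome) from [chrom_stats()] output.
#' With two or more samples, a largest-gap split separates the low (no
#' Y) and high (Y-bearing) clusters; when the largest gap is below
#' `min_gap` the samples form one cluster and all are reported
#' indeterminate with a warning. A single sample is classified against
#' the fixed thresholds directly.
#'
#' @param stats a `chrom_stats` frame covering the needed chromosomes.
#' @param x_chrom,y_chrom,denom_chrom chromosome names.
#' @param thresholds from [sex_call_thresholds()] (single-sample mode).
#' @param labels complement labels (homogametic, heterogametic).
#' @param min_gap minimum ratio gap accepted as a two-cluster split.
#' @return data frame: sample_id, y_ratio, complement_label.
#' @export
classify_samples_quick <- function(stats, x_chrom, y_chrom, denom_chrom,
                                   thresholds = sex_call_thresholds(),
                                   labels = c("XX", "XY"),
                                   min_gap = 0.05) {
  samples <- unique(stats$sample_id)
  get <- function(sid, chrom, col) {
    v <- stats[stats$sample_id == sid & stats$chrom == chrom, col]
    if (length(v) != 1L) stop("missing ", chrom, " stats for ", sid)
    v
  }
  # per-bp read densities need lengths; depth is already per-bp, use it
  ratio <- vapply(samples, function(sid) {
    den <- get(sid, denom_chrom, "mean_depth")
    if (den == 0) return(NA_real_)
    get(sid, y_chrom, "mean_depth") / den
  }, 0)
  label <- rep("indeterminate", length(samples))
  if (length(samples) == 1L) {
    r <- ratio[1L]
    if (!is.na(r)) {
      if (r < thresholds$t_absent) label[1L] <- labels[1L]
      else if (r > thresholds$t_present) label[1L] <- labels[2L]
    }
  } else {
    ord <- order(ratio)
    sorted <- ratio[ord]
    gaps <- diff(sorted)
    if (length(gaps) == 0L || max(gaps, na.rm = TRUE) < min_gap) {
      warning("no clear two-cluster separation in Y depth ratios; ",
              "all samples reported indeterminate")
    } else {
      cut <- which.max(gaps)
      low_set <- samples[ord][seq_len(cut)]
      label[samples %in% low_set] <- labels[1L]
      label[!(samples %in% low_set)] <- labels[2L]
    }
  }
  data.frame(sample_id = samples, y_ratio = unname(ratio),
             complement_label = label, stringsAsFactors = FALSE,
             row.names = NULL)
}
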