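test_that("bootstrap CI degenerates correctly on constant and singleton data", {
  ci <- bootstrap_mean_ci(c(5, 5, 5, 5), n_boot = 100L, seed = 1L)
  expect_equal(c(ci$mean, ci$low, ci$high), c(5, 5, 5))
  ci1 <- bootstrap_mean_ci(7, n_boot = 50L, seed = 2L)
  expect_equal(c(ci1$mean, ci1$low, ci1$high), c(7, 7, 7))
  expect_error(bootstrap_mean_ci(numeric()), "empty")
})

test_that("bootstrap CI width shrinks monotonically with sample size", {
  widths <- vapply(c(50L, 500L, 5000L), function(n) {
    set.seed(100L + n)
    x <- rnorm(n, 10, 1)
    ci <- bootstrap_mean_ci(x, n_boot = 2000L, seed = n)
    ci$high - ci$low
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("permutation p-values behave at the extremes and are never zero", {
  expect_equal(permutation_depth_test(c(1, 1, 1), c(1, 1, 1),
                                      n_perm = 99L, seed = 1L)$p, 1.0)
  # complete separation: only the identity-equivalent labelling attains
  # the observed statistic, so p = 1/(n_perm + 1)
  p <- permutation_depth_test(rep(0, 20), rep(100, 20),
                              n_perm = 999L, seed = 1L)$p
  expect_equal(p, 1 / 1000)
  for (s in 1:5) {
    set.seed(s)
    res <- permutation_depth_test(rnorm(8), rnorm(6), n_perm = 99L, seed = s)
    expect_gt(res$p, 0)
    expect_lte(res$p, 1)
  }
  expect_error(permutation_depth_test(numeric(), 1:3), "non-empty")
  expect_error(permutation_depth_test(1:3, 1:3, n_perm = 0L), "n_perm")
})

test_that("exact permutation p equals independent exhaustive enumeration", {
  enumerate_p <- function(a, b) {
    pool <- c(a, b)
    n <- length(pool)
    obs <- abs(mean(a) - mean(b))
    combos <- utils::combn(n, length(a), simplify = FALSE)
    stats <- vapply(combos, function(ix)
      abs(mean(pool[ix]) - mean(pool[-ix])), 0)
    mean(stats >= obs - 1e-12 * max(1, obs))
  }
  set.seed(33)
  for (rep in 1:20) {
    na <- sample(2:5, 1L)
    nb <- sample(2:5, 1L)
    a <- round(rnorm(na, 5, 2), 2)
    b <- round(rnorm(nb, 6, 2), 2)
    res <- permutation_depth_test(a, b, exact = TRUE)
    expect_equal(res$method, "exact")
    expect_equal(res$p, enumerate_p(a, b))
  }
  auto <- permutation_depth_test(1:4, 5:8, exact = "auto")
  expect_equal(auto$method, "exact")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(77)
  pvals <- vapply(1:100, function(i) {
    permutation_depth_test(rnorm(15, 10), rnorm(15, 10), n_perm = 199L)$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("KS statistic equals the brute-force ECDF supremum distance", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$d, 1)
  sup_oracle <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  }
  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(sample(5:40, 1L))
    b <- rnorm(sample(5:40, 1L), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$d, sup_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("chromosome-pair comparisons separate XY and overlap XX", {
  xy_w <- fx("xy_windows", function() {
    f <- filter_windows(traverse_bam(xy_sim()$bam, window_size = 1000L),
                        min_mapq = 30)
    f$pass
  })
  pick <- function(w, chrom) w[w$chrom == chrom, ]
  cmp <- compare_chrom_pair(pick(xy_w, "chrX"), pick(xy_w, "chrA"),
                            "chrX", "chrA", n_boot = 2000L, n_perm = 500L,
                            seed = 42L)
  expect_false(cmp$ci_overlap)
  expect_lt(abs(cmp$mean_a / cmp$mean_b - 0.5), 0.1)
  expect_lt(cmp$perm_p, 0.01)

  xx_w <- fx("xx_windows", function() {
    f <- filter_windows(traverse_bam(xx_sim()$bam, window_size = 1000L),
                        min_mapq = 30)
    f$pass
  })
  cmp_xx <- compare_chrom_pair(pick(xx_w, "chrX"), pick(xx_w, "chrA"),
                               "chrX", "chrA", n_boot = 2000L,
                               n_perm = 500L, seed = 42L)
  expect_true(cmp_xx$ci_overlap)

  # self-comparison: full overlap, high permutation p, tiny D
  self <- compare_chrom_pair(pick(xy_w, "chrA"), pick(xy_w, "chrA"),
                             "chrA", "chrA", n_boot = 1000L,
                             n_perm = 500L, seed = 7L)
  expect_true(self$ci_overlap)
  expect_gt(self$perm_p, 0.9)
  expect_equal(self$ks_d, 0)
})

test_that("identical seeds reproduce comparisons bit for bit", {
  set.seed(1); a <- rnorm(80, 20, 2)
  set.seed(2); b <- rnorm(70, 10, 2)
  c1 <- compare_chrom_pair(a, b, n_boot = 500L, n_perm = 500L, seed = 11L)
  c2 <- compare_chrom_pair(a, b, n_boot = 500L, n_perm = 500L, seed = 11L)
  expect_identical(c1$ci_a, c2$ci_a)
  expect_identical(c1$ci_b, c2$ci_b)
  expect_identical(c1$perm_p, c2$perm_p)
  c3 <- compare_chrom_pair(a, b, n_boot = 500L, n_perm = 500L, seed = 12L)
  expect_false(identical(c1$ci_a, c3$ci_a))
})

test_that("complement inference follows the ratio-interval decision rule", {
  # constant depths make the ratio CIs degenerate and easy to steer:
  # rY = 0.17 falls between t_absent and t_present -> indeterminate
  cmp_x <- compare_chrom_pair(rep(10, 50), rep(20, 50), "chrX", "chrA",
                              n_boot = 200L, n_perm = 10L, seed = 1L)
  cmp_y <- compare_chrom_pair(rep(3.4, 50), rep(20, 50), "chrY", "chrA",
                              n_boot = 200L, n_perm = 10L, seed = 2L)
  call <- infer_sex_complement(cmp_x, cmp_y, seed = 3L)
  expect_equal(call$y_present, "indeterminate")
  expect_equal(call$complement_label, "indeterminate")

  # clean haploid X + absent Y -> XY / XX routing
  cmp_y0 <- compare_chrom_pair(rep(0.5, 50), rep(20, 50), "chrY", "chrA",
                               n_boot = 200L, n_perm = 10L, seed = 4L)
  call_xx <- infer_sex_complement(
    compare_chrom_pair(rep(20, 50), rep(20, 50), "chrX", "chrA",
                       n_boot = 200L, n_perm = 10L, seed = 5L),
    cmp_y0, seed = 6L)
  expect_equal(call_xx$complement_label, "XX")

  call_xy <- infer_sex_complement(
    cmp_x,
    compare_chrom_pair(rep(10, 50), rep(20, 50), "chrY", "chrA",
                       n_boot = 200L, n_perm = 10L, seed = 7L),
    seed = 8L)
  expect_equal(call_xy$complement_label, "XY")

  # mismatched denominators are rejected
  bad <- compare_chrom_pair(rep(10, 50), rep(20, 50), "chrY", "chr7",
                            n_boot = 100L, n_perm = 10L, seed = 9L)
  expect_error(infer_sex_complement(cmp_x, bad), "denominator")
})

test_that("quick classification splits samples at the largest ratio gap", {
  mk_stats <- function(ids, y_depth) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(sample_id = ids[i], chrom = c("chr19", "chrY"),
                 n_reads = c(1000L, as.integer(y_depth[i] * 50)),
                 mean_mapq = c(60, 60),
                 mean_depth = c(20, 20 * y_depth[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  st <- mk_stats(paste0("s", 1:4), c(0.001, 0.002, 0.40, 0.42))
  out <- classify_samples_quick(st, "chrX", "chrY", "chr19")
  expect_equal(out$complement_label, c("XX", "XX", "XY", "XY"))

  one <- classify_samples_quick(mk_stats("solo", 0), "chrX", "chrY", "chr19")
  expect_equal(one$complement_label, "XX")

  expect_warning(
    flat <- classify_samples_quick(mk_stats(paste0("t", 1:3), rep(0.2, 3)),
                                   "chrX", "chrY", "chr19"),
    "indeterminate")
  expect_true(all(flat$complement_label == "indeterminate"))
})
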