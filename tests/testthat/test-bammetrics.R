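test_that("window depth heuristic sums read lengths over the window length", {
  expect_equal(approx_window_depth(rep(100L, 5L), 0L, 1000L), 0.5)
  expect_equal(approx_window_depth(integer(), 0L, 1000L), 0)
  # two 100-bp reads starting at 0 and 50 assigned to window [0,100)
  expect_equal(approx_window_depth(c(100L, 100L), 0L, 100L), 2)
  expect_error(approx_window_depth(100L, 10L, 10L), "zero-length")
})

test_that("window MAPQ is the arithmetic mean with an explicit empty flag", {
  expect_equal(window_mean_mapq(c(60, 60, 0))$mean_mapq, 40)
  expect_equal(window_mean_mapq(37)$mean_mapq, 37)
  empty <- window_mean_mapq(numeric())
  expect_equal(empty$mean_mapq, 0)
  expect_true(empty$empty)
})

test_that("traversal tiles the chromosome, truncates the last window, and conserves reads", {
  dict <- data.frame(name = c("chrT", "chrU"), length = c(12000L, 10000L))
  rec <- rbind(
    align_rec("r1", "chrT", 10L), align_rec("r2", "chrT", 4950L),
    align_rec("r3", "chrT", 5001L), align_rec("r4", "chrT", 11000L),
    align_rec("r5", "chrU", 9950L, len = 50L, seq = strrep("C", 50L)))
  bam <- make_bam(rec, dict, "tiles.bam")

  w <- traverse_bam(bam, "chrT", window_size = 5000L)
  expect_equal(w$start, c(0L, 5000L, 10000L))
  expect_equal(w$end, c(5000L, 10000L, 12000L))
  expect_equal(w$n_primary, c(2L, 1L, 1L))
  # read assigned by leftmost position even when it spans the boundary
  expect_equal(w$approx_depth, c(200 / 5000, 100 / 5000, 100 / 2000))

  w10 <- traverse_bam(bam, "chrU", window_size = 5000L)
  expect_equal(nrow(w10), 2L)
  expect_equal(w10$end, c(5000L, 10000L))

  # conservation: window read counts sum to total primary reads
  expect_equal(sum(traverse_bam(bam, window_size = 3000L)$n_primary), nrow(rec))
  expect_error(traverse_bam(bam, "chrZ"), "absent")
})

test_that("uniform-coverage windows sit within 15% of the simulated depth", {
  sim <- fx("uniform10", function() {
    simulate_alignments(toy_genome(), ploidy_config("XX", mean_depth = 10),
                        file.path(fx_dir(), "uniform10.bam"), seed = 106L)
  })
  w <- traverse_bam(sim$bam, "chrA", window_size = 5000L)
  frac <- mean(abs(w$approx_depth - 10) / 10 <= 0.15)
  expect_gte(frac, 0.95)
})

test_that("approximate depth equals exact per-base depth for window-contained reads", {
  dict <- data.frame(name = "chrT", length = 10000L)
  set.seed(42)
  pos <- sample(1:4901, 300, replace = TRUE)
  rec <- do.call(rbind, lapply(seq_along(pos), function(i)
    align_rec(paste0("r", i), "chrT", pos[i])))
  bam <- make_bam(rec, dict, "contained.bam")
  w <- traverse_bam(bam, "chrT", window_size = 5000L)
  # oracle: exact mean per-base depth from interval coverage
  cov <- IRanges::coverage(IRanges::IRanges(pos, width = 100L), width = 10000L)
  exact1 <- mean(as.numeric(cov[1:5000]))
  expect_identical(w$approx_depth[1L], exact1)
  expect_identical(w$approx_depth[2L], 0)
})

test_that("chromosome-as-one-window depth equals the length-weighted mean of window depths", {
  sim <- xy_sim()
  cs <- chrom_stats(sim$bam, c("chrA", "chrX", "chrY"))
  w <- traverse_bam(sim$bam, window_size = 1000L)
  for (chrom in c("chrA", "chrX", "chrY")) {
    wc <- w[w$chrom == chrom, ]
    weighted <- sum(wc$approx_depth * (wc$end - wc$start)) / sum(wc$end - wc$start)
    expect_equal(cs$mean_depth[cs$chrom == chrom], weighted, tolerance = 1e-9)
  }
})

test_that("chrom_stats counts primary reads and warns on missing chromosomes", {
  dict <- data.frame(name = "chrA", length = 60000L)
  rec <- do.call(rbind, lapply(1:500, function(i)
    align_rec(paste0("p", i), "chrA", ((i - 1L) %% 590L) * 100L + 1L)))
  # secondary and supplementary records must not be counted
  extra <- rbind(align_rec("sec", "chrA", 5L, flag = 256L),
                 align_rec("sup", "chrA", 9L, flag = 2048L))
  bam <- make_bam(rbind(rec, extra), dict, "count500.bam")
  cs <- chrom_stats(bam, "chrA")
  expect_equal(cs$n_reads, 500L)

  expect_warning(cs2 <- chrom_stats(bam, c("chrA", "chrQ")), "chrQ")
  expect_equal(cs2$n_reads[cs2$chrom == "chrQ"], 0L)
})

test_that("XX sample has zero chrY reads after remapping to the Y-masked reference", {
  cs <- chrom_stats(xx_corrected()$merged, "chrY")
  expect_equal(cs$n_reads, 0L)
})

test_that("XY sample shows the haploid X:autosome depth ratio", {
  cs <- chrom_stats(xy_sim()$bam, c("chrA", "chrX"))
  ratio <- cs$mean_depth[cs$chrom == "chrX"] / cs$mean_depth[cs$chrom == "chrA"]
  expect_gte(ratio, 0.4)
  expect_lte(ratio, 0.6)
})

test_that("window filtering partitions windows with inclusive thresholds", {
  w <- data.frame(
    chrom = "chrT", start = c(0, 1, 2, 3, 4) * 1000L,
    end = c(1, 2, 3, 4, 5) * 1000L,
    approx_depth = c(10, 10, 10, 50, 0),
    mean_mapq = c(55, 10, 30, 60, 0),
    n_primary = c(10L, 10L, 10L, 50L, 0L),
    empty = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # chromosome mean depth = 16; bounds (0.25, 4) -> [4, 64]
  f <- filter_windows(w, min_mapq = 30, depth_bounds = c(0.25, 4))
  expect_equal(nrow(f$pass) + nrow(f$fail), nrow(w))
  expect_equal(intersect(f$pass$start, f$fail$start), numeric(0))
  expect_setequal(f$pass$start, c(0, 2000, 3000))  # mapq 30 passes (inclusive)
  expect_true(1000 %in% f$fail$start)   # low MAPQ fails regardless of depth
  expect_true(4000 %in% f$fail$start)   # empty windows always fail
  expect_error(filter_windows(w, depth_bounds = c(4, 0.25)), "low > high")
  # strict preset raises the MAPQ threshold to 55
  fs <- filter_windows(w, preset = "strict")
  expect_setequal(fs$pass$start, c(0, 3000))
})

test_that("normalization divides each metric by the denominator chromosome", {
  stats <- data.frame(
    sample_id = rep(c("s1", "s2", "s3"), each = 3L),
    chrom = rep(c("chr19", "chrX", "chrY"), 3L),
    n_reads = c(100L, 100L, 0L, 200L, 100L, 50L, 80L, 40L, 2L),
    mean_mapq = c(50, 50, 0, 60, 58, 55, 40, 20, 10),
    mean_depth = c(20, 20, 0, 30, 15, 7.5, 10, 5, 0.2))
  out <- normalize_to_chrom(stats, "chr19")
  expect_equal(out$rel_depth[out$sample_id == "s1" & out$chrom == "chrX"], 1.0)
  expect_equal(out$rel_depth[out$sample_id == "s1" & out$chrom == "chrY"], 0.0)
  # brute-force oracle over every cell
  for (i in seq_len(nrow(out))) {
    den <- stats[stats$sample_id == out$sample_id[i] & stats$chrom == "chr19", ]
    expect_equal(out$rel_depth[i],
                 if (den$mean_depth == 0) NA_real_ else
                   out$mean_depth[i] / den$mean_depth)
    expect_equal(out$rel_reads[i], out$n_reads[i] / den$n_reads)
  }
  # zero denominator marks undefined rather than erroring
  z <- stats
  z$mean_depth[z$sample_id == "s1" & z$chrom == "chr19"] <- 0
  out_z <- normalize_to_chrom(z, "chr19")
  expect_true(is.na(out_z$rel_depth[out_z$sample_id == "s1" &
                                      out_z$chrom == "chrX"]))
})
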