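test_that("variant filtering applies inclusive >= 30 style thresholds", {
  sites <- rbind(
    site_row(pos = 1L, qual = 29.9),                 # below site QUAL
    site_row(pos = 2L, qual = 30, mq = 30),          # exactly at thresholds
    site_row(pos = 3L, qual = 80, gq = 29),          # below GQ
    site_row(pos = 4L, qual = 80, depth = 7L),       # below depth
    site_row(pos = 5L, qual = 80, mq = 29.5),        # below MQ
    site_row(pos = 6L, qual = 80))
  kept <- filter_variants(sites)
  expect_equal(kept$pos, c(2L, 6L))

  # brute-force record-by-record oracle on a depth-threshold toy set
  toy <- do.call(rbind, lapply(1:6, function(i)
    site_row(pos = i, depth = c(30L, 7L, 30L, 5L, 30L, 30L)[i])))
  kept2 <- filter_variants(toy, min_depth = 8)
  oracle <- toy[vapply(seq_len(nrow(toy)), function(i)
    toy$qual[i] >= 30 && toy$gq[i] >= 30 && toy$depth[i] >= 8 &&
      toy$mq[i] >= 30, TRUE), ]
  expect_equal(kept2$pos, oracle$pos)
  expect_equal(nrow(kept2), 4L)

  # missing MQ passes with a warning; missing GQ fails
  na_sites <- rbind(site_row(pos = 1L, mq = NA), site_row(pos = 2L, gq = NA))
  expect_warning(kept3 <- filter_variants(na_sites), "MQ annotation missing")
  expect_equal(kept3$pos, 1L)
})

test_that("read balance is alt over informative total", {
  expect_equal(read_balance(5L, 5L), 0.5)
  expect_equal(read_balance(0L, 10L), 1.0)
  expect_equal(read_balance(7L, 3L), 0.3)
  expect_warning(b <- read_balance(c(5L, 0L), c(5L, 0L)), "zero")
  expect_equal(b, c(0.5, NA))
})

test_that("heterozygous view excludes balances outside (0.05, 1.0) strictly", {
  h <- balance_histogram(c(0.02, 0.5, 1.0), heterozygous_view = TRUE,
                         n_bins = 20L)
  expect_equal(h$n_binned, 1L)
  expect_equal(sum(h$counts), 1L)
  expect_equal(h$mids[which(h$counts == 1L)], 0.475)
  # boundary values 0.05 and 1.0 are themselves excluded
  h2 <- balance_histogram(c(0.05, 1.0), heterozygous_view = TRUE)
  expect_equal(h2$n_binned, 0L)
  # full view keeps everything; het view output is a subset of it
  hf <- balance_histogram(c(0.02, 0.5, 1.0), n_bins = 20L)
  expect_equal(sum(hf$counts), 3L)
  expect_true(all(h$counts <= hf$counts))
  expect_equal(sum(balance_histogram(numeric())$counts), 0L)
  expect_error(balance_histogram(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("simulated diploid balances peak near 0.5 and (full view) 1.0", {
  v <- fx("dip30", function() {
    simulate_variants(toy_genome(), ploidy_config("XX", mean_depth = 30),
                      het_rate = 0.004, hom_rate = 0.002, seed = 107L)
  })
  bal <- read_balance(v$sites$ref_count, v$sites$alt_count)
  full <- balance_histogram(bal, n_bins = 20L)
  het <- balance_histogram(bal, heterozygous_view = TRUE, n_bins = 20L)
  # heterozygous peak near 0.5 and a second full-view peak at 1.0
  expect_lt(abs(het$mids[which.max(het$counts)] - 0.5), 0.05)
  upper <- full$mids > 0.75
  expect_equal(full$mids[upper][which.max(full$counts[upper])], 0.975)
})

test_that("per-window variant summaries match brute-force binning", {
  lens <- c(chrT = 10000L)
  s <- rbind(site_row(chrom = "chrT", pos = 100L, ref_count = 6L, alt_count = 4L),
             site_row(chrom = "chrT", pos = 4900L, ref_count = 4L, alt_count = 6L),
             site_row(chrom = "chrT", pos = 5100L, ref_count = 5L, alt_count = 5L))
  out <- window_variant_summary(s, 5000L, lens)
  expect_equal(out$n_variants, c(2L, 1L))
  expect_equal(out$mean_balance, c(0.5, 0.5))

  # randomized oracle
  set.seed(9)
  n <- 200L
  rs <- site_row(chrom = "chrT", pos = sample.int(10000L, n, replace = TRUE),
                 ref_count = sample.int(20L, n, replace = TRUE),
                 alt_count = sample.int(20L, n, replace = TRUE))
  out2 <- window_variant_summary(rs, 1000L, lens)
  for (w in seq_len(nrow(out2))) {
    sel <- rs$pos - 1L >= out2$start[w] & rs$pos - 1L < out2$end[w]
    expect_equal(out2$n_variants[w], sum(sel))
    if (sum(sel)) {
      expect_equal(out2$mean_balance[w],
                   mean(rs$alt_count[sel] / (rs$ref_count[sel] + rs$alt_count[sel])))
    } else {
      expect_true(is.na(out2$mean_balance[w]))
    }
  }
  # boundary: 1-based position 5000 belongs to the first 0-based window
  b <- window_variant_summary(site_row(chrom = "chrT", pos = 5000L), 5000L, lens)
  expect_equal(b$n_variants, c(1L, 0L))
})

test_that("per-Mb rates reproduce the printed region table arithmetic", {
  expect_equal(round(per_mb_rate(7563, 2589520), 1), 2920.6)
  expect_equal(round(per_mb_rate(366, 4287237), 1), 85.4)
  expect_equal(per_mb_rate(0, 1e6), 0)
  expect_error(per_mb_rate(5, 0), "length")
})

test_that("region-unique counting is a set difference, anti-symmetric, and additive", {
  a <- rbind(site_row(chrom = "chr1", pos = 100L, ref = "A", alt = "T"),
             site_row(chrom = "chr1", pos = 200L, ref = "G", alt = "C"))
  b <- rbind(site_row(chrom = "chr1", pos = 200L, ref = "G", alt = "C"),
             site_row(chrom = "chr1", pos = 300L, ref = "C", alt = "G"))
  all_reg <- genomic_intervals("chr1", 0L, 1000L, name = "ALL")
  r <- region_unique_variants(a, b, all_reg)
  expect_equal(r$unique_to_a, 1L)
  expect_equal(r$unique_to_b, 1L)
  expect_equal(r$rate_a, per_mb_rate(1, 1000))

  # identical call sets have no unique variants
  r0 <- region_unique_variants(a, a, all_reg)
  expect_equal(c(r0$unique_to_a, r0$unique_to_b), c(0L, 0L))

  # anti-symmetry: swapping the call sets swaps the columns exactly
  rs <- region_unique_variants(b, a, all_reg)
  expect_equal(rs$unique_to_a, r$unique_to_b)
  expect_equal(rs$unique_to_b, r$unique_to_a)

  # additivity over disjoint regions, with a multi-interval Total region
  set.seed(11)
  mk <- function(n, seed) {
    set.seed(seed)
    site_row(chrom = "chr1", pos = sample.int(3000L, n),
             ref = "A", alt = sample(c("C", "G", "T"), n, replace = TRUE))
  }
  big_a <- mk(120L, 21L)
  big_b <- mk(120L, 22L)
  regions <- rbind(
    genomic_intervals("chr1", 0L, 1000L, "R1"),
    genomic_intervals("chr1", 1000L, 2000L, "R2"),
    genomic_intervals("chr1", 2000L, 3000L, "R3"),
    genomic_intervals(rep("chr1", 3L), c(0L, 1000L, 2000L),
                      c(1000L, 2000L, 3000L), rep("Total", 3L)))
  rep4 <- region_unique_variants(big_a, big_b, regions)
  tot <- rep4[rep4$region == "Total", ]
  parts <- rep4[rep4$region != "Total", ]
  expect_equal(sum(parts$unique_to_a), tot$unique_to_a)
  expect_equal(sum(parts$unique_to_b), tot$unique_to_b)
  expect_equal(tot$length_bp, 3000L)

  zero_len <- data.frame(chrom = "chr1", start = 5L, end = 5L, name = "Z",
                         stringsAsFactors = FALSE)
  expect_error(region_unique_variants(a, b, zero_len), "length 0")
})

test_that("VCF round trip preserves site annotations and allele depths", {
  v <- xx_variants()
  dict <- sequence_dictionary(toy_genome()$fasta)
  path <- file.path(fx_dir(), "truth.vcf")
  write_truth_vcf(v, dict, path)
  sites <- read_variant_sites(path)
  expect_equal(nrow(sites), nrow(v$sites))
  ord <- order(match(v$sites$chrom, dict$name), v$sites$pos)
  expect_equal(sites$pos, v$sites$pos[ord])
  expect_equal(sites$ref, v$sites$ref[ord])
  expect_equal(sites$alt, v$sites$alt[ord])
  expect_equal(sites$ref_count, v$sites$ref_count[ord])
  expect_equal(sites$alt_count, v$sites$alt_count[ord])
  expect_equal(sites$mq, v$sites$mq[ord])
})

test_that("naive pileup caller recovers simulated sites on a clean fixture", {
  sim <- xx_clean_sim()
  truth <- xx_variants()$sites
  called <- call_variants(sim$bam, toy_fasta(),
                          file.path(fx_dir(), "clean_calls.vcf"))
  key <- function(s) paste(s$chrom, s$pos, s$ref, s$alt)
  false_pos <- setdiff(key(called), key(truth))
  missed <- setdiff(key(truth), key(called))
  expect_length(false_pos, 0L)           # error-free reads: no spurious sites
  expect_lte(length(missed), 3L)         # only sites no alt-carrying read covers
  # the written VCF is readable and consistent
  back <- read_variant_sites(file.path(fx_dir(), "clean_calls.vcf"))
  expect_equal(nrow(back), nrow(called))
})

test_that("empty BAM yields a header-only VCF", {
  dict <- data.frame(name = "chrT", length = 1000L)
  bam <- make_bam(sexchromr:::empty_alignments(), dict, "empty.bam")
  out <- file.path(fx_dir(), "empty.vcf")
  called <- call_variants(bam, Biostrings::DNAStringSet(c(chrT = strrep("A", 1000L))),
                          out)
  expect_equal(nrow(called), 0L)
  lines <- readLines(out)
  expect_true(all(grepl("^#", lines)))
})

test_that("external caller templates validate placeholders and surface failures", {
  expect_error(
    call_variants_external("x.bam", "ref.fa", "caller --in {bam} --ref {ref}",
                           "out.vcf"),
    "\\{out\\} placeholder")
  # a template whose command exits non-zero is fatal with the command shown
  expect_error(
    call_variants_external("x.bam", "ref.fa",
                           "ls {bam} {ref} {out}", "/nonexistent/out.vcf"),
    "external command failed")
  # successful template runs produce the output path
  src <- file.path(fx_dir(), "template_src.vcf")
  writeLines("##fileformat=VCFv4.2", src)
  dst <- file.path(fx_dir(), "template_dst.vcf")
  call_variants_external(src, "ref.fa", "cp {bam} {out} # {ref}", dst)
  expect_true(file.exists(dst))
})
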