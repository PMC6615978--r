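#' Read variant sites from a VCF
#'
#' Parses a VCF (plain or bgzipped) into the flat site table the
#' read-balance machinery works on. Allele read counts come from the
#' allelic-depth (AD) genotype field when present; otherwise they can be
#' recomputed by pileup over a BAM. Multi-allelic records are restricted
#' to the alt allele with the highest read count.
#'
#' @param vcf VCF path.
#' @param sample sample column index or name (default first).
#' @param bam optional BAM used to recompute allele counts when the VCF
#'   carries no AD field.
#' @return data frame of class `variant_sites`: chrom, pos (1-based),
#'   ref, alt, qual, mq (NA when the VCF has no MQ annotation), gq,
#'   depth, ref_count, alt_count.
#' @export
read_variant_sites <- function(vcf, sample = 1L, bam = NULL) {
  v <- VariantAnnotation::readVcf(vcf)
  rr <- SummarizedExperiment::rowRanges(v)
  n <- length(rr)
  geno <- VariantAnnotation::geno(v)
  info <- VariantAnnotation::info(v)

  alt_list <- as.list(methods::as(VariantAnnotation::alt(v), "CharacterList"))
  ad <- if ("AD" %in% names(geno)) as.list(geno$AD[, sample]) else NULL
  alt_idx <- rep(1L, n)
  if (!is.null(ad) && n > 0L) {
    alt_idx <- vapply(seq_len(n), function(i) {
      counts <- ad[[i]]
      if (length(counts) <= 2L || all(is.na(counts))) return(1L)
      which.max(counts[-1L])
    }, 1L)
  }
  alt <- vapply(seq_len(n), function(i) {
    a <- alt_list[[i]]
    if (length(a) == 0L) NA_character_ else a[[min(alt_idx[i], length(a))]]
  }, "")

  ref_count <- alt_count <- rep(NA_integer_, n)
  if (!is.null(ad)) {
    ref_count <- vapply(seq_len(n), function(i) as.integer(ad[[i]][1L]), 1L)
    alt_count <- vapply(seq_len(n), function(i)
      as.integer(ad[[i]][alt_idx[i] + 1L]), 1L)
  }
  depth <- if ("DP" %in% names(geno)) as.integer(geno$DP[, sample]) else
    if ("DP" %in% names(info)) as.integer(info$DP) else
      ref_count + alt_count
  gq <- if ("GQ" %in% names(geno)) as.numeric(geno$GQ[, sample]) else
    rep(NA_real_, n)
  mq <- if ("MQ" %in% names(info)) as.numeric(info$MQ) else rep(NA_real_, n)

  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt,
    qual = as.numeric(VariantAnnotation::qual(v)),
    mq = mq, gq = gq, depth = depth,
    ref_count = ref_count, alt_count = alt_count,
    stringsAsFactors = FALSE)

  if (!is.null(bam) && all(is.na(sites$ref_count)) && nrow(sites) > 0L) {
    counts <- pileup_allele_counts(bam, sites)
    sites$ref_count <- counts$ref_count
    sites$alt_count <- counts$alt_count
  }
  class(sites) <- c("variant_sites", "data.frame")
  sites
}

# allele counts at given sites by pileup over a BAM
pileup_allele_counts <- function(bam, sites) {
  require_bam_index(bam)
  which <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, sites$pos))
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(which = which),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L, distinguish_strands = FALSE,
      include_deletions = FALSE))
  key <- paste(p$seqnames, p$pos, p$nucleotide)
  cnt <- function(chrom, pos, base) {
    i <- match(paste(chrom, pos, base), key)
    ifelse(is.na(i), 0L, p$count[i])
  }
  list(ref_count = cnt(sites$chrom, sites$pos, sites$ref),
       alt_count = cnt(sites$chrom, sites$pos, sites$alt))
}

#' Filter variant sites on quality annotations
#'
#' Keeps sites passing all of: site QUAL, genotype quality, read depth,
#' and the site MQ annotation when present (all thresholds inclusive,
#' i.e. a value exactly at the threshold passes). A missing MQ annotation
#' passes with a warning; a missing GQ fails — permissive on
#' caller-specific extras, conservative on genotype confidence. Input
#' order is preserved.
#'
#' @param sites a `variant_sites` frame.
#' @param min_site_qual minimum site QUAL (default 30).
#' @param min_genotype_qual minimum GQ (default 30).
#' @param min_depth minimum read depth (default 8).
#' @param min_mq minimum site MQ (default 30).
#' @return the retained rows, same class.
#' @export
filter_variants <- function(sites, min_site_qual = 30,
                            min_genotype_qual = 30, min_depth = 8,
                            min_mq = 30) {
  if (anyNA(sites$mq) && nrow(sites) > 0L) {
    warning("MQ annotation missing for ", sum(is.na(sites$mq)),
            " site(s); treating as passing the MQ filter")
  }
  keep <- sites$qual >= min_site_qual &
    (!is.na(sites$gq) & sites$gq >= min_genotype_qual) &
    sites$depth >= min_depth &
    (is.na(sites$mq) | sites$mq >= min_mq)
  keep[is.na(keep)] <- FALSE
  sites[keep, , drop = FALSE]
}

#' Read balance at a variant site
#'
#' The fraction of reads supporting the non-reference allele:
#' `alt / (ref + alt)`. Diploid heterozygotes cluster near 0.5,
#' haploid (or homozygous-alt) calls near 1.0.
#'
#' @param ref_count,alt_count allele-supporting read counts (vectors).
#' @return numeric vector in `[0, 1]`; sites with `ref + alt == 0` are
#'   returned as `NA` with a warning (skipped downstream).
#' @export
read_balance <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  if (any(total == 0, na.rm = TRUE)) {
    warning(sum(total == 0, na.rm = TRUE),
            " site(s) with zero allele-informative reads skipped")
  }
  ifelse(is.na(total) | total == 0, NA_real_, alt_count / total)
}

#' Histogram of read balances
#'
#' Bins read-balance values over `[0, 1]`. The heterozygous view keeps
#' only balances strictly between 0.05 and 1.0, hiding fixed sites and
#' low-balance noise to highlight the heterozygous peak; the full view
#' keeps everything.
#'
#' @param balances read-balance values in `[0, 1]` (NAs dropped).
#' @param heterozygous_view restrict to `0.05 < balance < 1.0`.
#' @param n_bins number of equal-width bins over `[0, 1]`.
#' @return object of class `balance_histogram`: list with `breaks`,
#'   `mids`, `counts`, `heterozygous_view`, `n_input`, `n_binned`.
#' @export
balance_histogram <- function(balances, heterozygous_view = FALSE,
                              n_bins = 50L) {
  balances <- balances[!is.na(balances)]
  if (any(balances < 0 | balances > 1)) {
    stop("read balances must lie in [0, 1]")
  }
  n_input <- length(balances)
  if (heterozygous_view) {
    balances <- balances[balances > 0.05 & balances < 1.0]
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- if (length(balances))
    graphics::hist(balances, breaks = breaks, plot = FALSE,
                   include.lowest = TRUE, right = TRUE)$counts
  else integer(n_bins)
  structure(list(breaks = breaks,
                 mids = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
                 counts = counts,
                 heterozygous_view = heterozygous_view,
                 n_input = n_input, n_binned = length(balances)),
            class = "balance_histogram")
}

#' @export
print.balance_histogram <- function(x, ...) {
  cat("Read-balance histogram (",
      if (x$heterozygous_view) "heterozygous view: 0.05 < b < 1" else "full view",
      ")\n", sep = "")
  cat("  sites:", x$n_input, "input,", x$n_binned, "binned\n")
  if (x$n_binned > 0L) {
    cat("  modal bin:", format(x$mids[which.max(x$counts)], digits = 3), "\n")
  }
  invisible(x)
}

#' Per-window variant count and mean read balance
#'
#' Bins sites into the same non-overlapping windows as [traverse_bam()]
#' (0-based tiling; a 1-based VCF position `p` falls in the window
#' containing `p - 1`). Empty windows report count 0 and `NA` balance.
#'
#' @param sites a `variant_sites` frame (one chromosome or several).
#' @param window_size window size in bp.
#' @param chrom_lengths named vector of chromosome lengths (the sequence
#'   dictionary) defining the tiling extent.
#' @return data frame: chrom, start, end, n_variants, mean_balance.
#' @export
window_variant_summary <- function(sites, window_size, chrom_lengths) {
  window_size <- as.integer(window_size)
  stopifnot(window_size > 0L, !is.null(names(chrom_lengths)))
  bal <- read_balance(sites$ref_count, sites$alt_count)
  out <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    n_win <- as.integer(ceiling(len / window_size))
    start <- (seq_len(n_win) - 1L) * window_size
    end <- pmin(start + window_size, len)
    sel <- sites$chrom == chrom
    win <- (sites$pos[sel] - 1L) %/% window_size + 1L
    counts <- tabulate(win, nbins = n_win)
    bal_sum <- rowsum_by(ifelse(is.na(bal[sel]), 0, bal[sel]), win, n_win)
    bal_n <- rowsum_by(as.numeric(!is.na(bal[sel])), win, n_win)
    data.frame(chrom = chrom, start = start, end = end,
               n_variants = counts,
               mean_balance = ifelse(bal_n > 0, bal_sum / bal_n, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Variants-per-megabase rate
#'
#' @param count variant count.
#' @param length_bp region length in bp (> 0).
#' @return `count / (length_bp / 1e6)` (vectorized).
#' @export
per_mb_rate <- function(count, length_bp) {
  if (any(length_bp <= 0)) stop("region length must be > 0 bp")
  count / (length_bp / 1e6)
}

#' Count variants unique to each of two call sets, by region
#'
#' Compares two identically filtered call sets by the variant identity
#' key (chrom, pos, ref, alt) and counts, for each named region, the
#' variants present only in the first set and only in the second —
#' the before/after-masking contrast. Regions sharing a name (e.g. a
#' multi-interval "Total") are treated as one region: counts over the
#' union, length summed.
#'
#' @param calls_a,calls_b `variant_sites` frames or VCF paths.
#' @param regions named intervals (`genomic_intervals` with `name`, or a
#'   BED path with a name column).
#' @return data frame of class `region_variant_report`: region,
#'   length_bp, unique_to_a, rate_a, unique_to_b, rate_b (rates per Mb,
#'   unrounded).
#' @export
region_unique_variants <- function(calls_a, calls_b, regions) {
  as_sites <- function(x) {
    if (is.character(x) && length(x) == 1L) read_variant_sites(x) else x
  }
  a <- as_sites(calls_a)
  b <- as_sites(calls_b)
  if (is.character(regions) && length(regions) == 1L) regions <- read_bed(regions)
  if (is.null(regions$name)) stop("regions must carry a name column")
  if (any(regions$end - regions$start <= 0L)) stop("region with length 0")

  key_a <- paste(a$chrom, a$pos, a$ref, a$alt)
  key_b <- paste(b$chrom, b$pos, b$ref, b$alt)
  only_a <- !(key_a %in% key_b) & !duplicated(key_a)
  only_b <- !(key_b %in% key_a) & !duplicated(key_b)

  in_region <- function(sites, rr) {
    hit <- rep(FALSE, nrow(sites))
    for (i in seq_len(nrow(rr))) {
      hit <- hit | (sites$chrom == rr$chrom[i] &
                      sites$pos - 1L >= rr$start[i] &
                      sites$pos - 1L < rr$end[i])
    }
    hit
  }
  out <- lapply(unique(regions$name), function(nm) {
    rr <- regions[regions$name == nm, , drop = FALSE]
    len <- sum(rr$end - rr$start)
    ua <- sum(only_a & in_region(a, rr))
    ub <- sum(only_b & in_region(b, rr))
    data.frame(region = nm, length_bp = len,
               unique_to_a = ua, rate_a = per_mb_rate(ua, len),
               unique_to_b = ub, rate_b = per_mb_rate(ub, len),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("region_variant_report", "data.frame")
  res
}

#' @export
print.region_variant_report <- function(x, ...) {
  cat("Region-unique variant counts (rates per Mb in parentheses)\n")
  fmt <- function(cnt, rate) sprintf("%s (%s)", format(cnt, big.mark = ","),
                                     formatC(rate, format = "f", digits = 1))
  df <- data.frame(Region = x$region,
                   `Length (bp)` = format(x$length_bp, big.mark = ","),
                   `Unique to A` = fmt(x$unique_to_a, x$rate_a),
                   `Unique to B` = fmt(x$unique_to_b, x$rate_b),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Naive pileup variant caller
#'
#' A dependency-free caller for testing and toy data: every position
#' carrying at least `min_alt` non-reference reads becomes a site. QUAL
#' is the phred-scaled binomial probability of seeing that many alt
#' reads from sequencing error alone; the genotype is `1/1` when the
#' read balance is at least `hom_threshold`, else `0/1`; the MQ
#' annotation is the mean MAPQ of the covering primary reads. Not a
#' replacement for a production caller on real data.
#'
#' @param bam coordinate-sorted, indexed BAM.
#' @param reference FASTA path or `DNAStringSet` the BAM was mapped to.
#' @param out_vcf output VCF path.
#' @param min_alt minimum alt-supporting reads for a site (default 1).
#' @param min_depth minimum total depth at a site (default 1).
#' @param error_rate assumed per-base error rate for the QUAL model.
#' @param hom_threshold read balance at or above which the genotype is
#'   called homozygous alt.
#' @return the site table written, invisibly (class `variant_sites`).
#' @export
call_variants <- function(bam, reference, out_vcf, min_alt = 1L,
                          min_depth = 1L, error_rate = 0.01,
                          hom_threshold = 0.9) {
  require_bam_index(bam)
  seqs <- load_fasta(reference)
  dict <- bam_dictionary(bam)
  p <- Rsamtools::pileup(
    bam,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L, distinguish_strands = FALSE,
      include_deletions = FALSE))
  sites_list <- list()
  for (chrom in unique(as.character(p$seqnames))) {
    pc <- p[p$seqnames == chrom, , drop = FALSE]
    pos <- sort(unique(pc$pos))
    base_mat <- matrix(0L, nrow = length(pos), ncol = 4L,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
    keep <- pc$nucleotide %in% colnames(base_mat)
    idx <- cbind(match(pc$pos[keep], pos),
                 match(as.character(pc$nucleotide[keep]), colnames(base_mat)))
    base_mat[idx] <- pc$count[keep]
    ref <- strsplit(as.character(Biostrings::extractAt(
      seqs[[chrom]], IRanges::IRanges(pos, pos))), NULL)
    ref <- vapply(ref, `[`, "", 1L)
    depth <- rowSums(base_mat)
    ref_count <- base_mat[cbind(seq_along(pos), match(ref, colnames(base_mat)))]
    ref_count[is.na(ref_count)] <- 0L
    alt_mat <- base_mat
    alt_mat[cbind(seq_along(pos), match(ref, colnames(base_mat)))] <- -1L
    alt_idx <- max.col(alt_mat, ties.method = "first")
    alt <- colnames(base_mat)[alt_idx]
    alt_count <- base_mat[cbind(seq_along(pos), alt_idx)]
    sel <- alt_count >= min_alt & depth >= min_depth & !is.na(ref) &
      ref %in% colnames(base_mat)
    if (!any(sel)) next
    pos <- pos[sel]; ref <- ref[sel]; alt <- alt[sel]
    depth <- depth[sel]; ref_count <- ref_count[sel]; alt_count <- alt_count[sel]
    qual <- -10 * log10(pmax(stats::pbinom(alt_count - 1L, depth, error_rate,
                                           lower.tail = FALSE), 1e-100))
    qual <- round(pmin(qual, 999), 1)
    # site MQ: mean MAPQ of primary reads overlapping each position
    len <- dict$length[dict$name == chrom]
    reads <- scan_primary(bam, chrom, len)
    mq <- rep(NA_real_, length(pos))
    if (length(reads$pos)) {
      spans <- IRanges::IRanges(reads$pos, width = reads$qwidth)
      hits <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), spans)
      mq_sum <- rowsum_by(as.numeric(reads$mapq[S4Vectors::subjectHits(hits)]),
                          S4Vectors::queryHits(hits), length(pos))
      mq_n <- rowsum_by(rep(1, length(S4Vectors::queryHits(hits))),
                        S4Vectors::queryHits(hits), length(pos))
      mq <- ifelse(mq_n > 0, round(mq_sum / mq_n, 2), NA_real_)
    }
    balance <- alt_count / pmax(ref_count + alt_count, 1L)
    sites_list[[chrom]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
      mq = mq, gq = pmin(99L, as.integer(round(qual))), depth = depth,
      ref_count = ref_count, alt_count = alt_count,
      gt = ifelse(balance >= hom_threshold, "1/1", "0/1"),
      stringsAsFactors = FALSE)
  }
  sites <- if (length(sites_list)) do.call(rbind, sites_list) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), qual = numeric(), mq = numeric(),
               gq = integer(), depth = integer(), ref_count = integer(),
               alt_count = integer(), gt = character(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  write_vcf_sites(sites, dict, out_vcf)
  class(sites) <- c("variant_sites", "data.frame")
  invisible(sites)
}

#' Call variants through an external command template
#'
#' Runs a user-supplied caller command with `{bam}`, `{ref}`, `{out}`
#' (and optionally `{threads}`) placeholders, e.g.
#' `"platypus callVariants --bamFiles={bam} --refFile={ref} -o {out} --nCPU={threads}"`.
#'
#' @param bam input BAM path.
#' @param reference FASTA path.
#' @param caller_cmd_template command template containing the `{bam}`,
#'   `{ref}` and `{out}` placeholders.
#' @param out_vcf output VCF path substituted for `{out}`.
#' @param threads substituted for `{threads}` when present.
#' @return `out_vcf`, invisibly.
#' @export
call_variants_external <- function(bam, reference, caller_cmd_template,
                                   out_vcf, threads = 1L) {
  cmd <- fill_template(caller_cmd_template,
                       list(bam = bam, ref = reference, out = out_vcf,
                            threads = threads),
                       required = c("bam", "ref", "out"))
  run_external(cmd)
  invisible(out_vcf)
}

# substitute {name} placeholders; fatal if a required one is absent
fill_template <- function(template, values, required = names(values)) {
  for (r in required) {
    if (!grepl(paste0("{", r, "}"), template, fixed = TRUE)) {
      stop("command template is missing the {", r, "} placeholder: ", template)
    }
  }
  for (nm in names(values)) {
    template <- gsub(paste0("{", nm, "}"), as.character(values[[nm]]),
                     template, fixed = TRUE)
  }
  template
}

run_external <- function(cmd) {
  err_file <- tempfile(fileext = ".stderr")
  on.exit(unlink(err_file), add = TRUE)
  status <- system(paste(cmd, "2>", shQuote(err_file)))
  if (status != 0L) {
    err <- paste(readLines(err_file, warn = FALSE), collapse = "\n")
    stop("external command failed (exit ", status, "): ", cmd, "\n", err)
  }
  invisible(status)
}
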