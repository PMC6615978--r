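#' Specification for the toy genome
#'
#' Describes a three-chromosome genome (one autosome, an X and a Y) whose
#' X and Y carry the hallmarks of gametologous homology: two
#' pseudoautosomal blocks copied identically between the sex chromosomes,
#' and an XTR-like block duplicated from X to Y at high (but sub-100%)
#' identity. Coordinates are 0-based half-open.
#'
#' Defaults give 120 kb autosome/X and a 60 kb Y with 5 kb PARs at both
#' chromosome ends and a 10 kb XTR at 98% identity — large enough for
#' >=100 characterization windows per chromosome at 1 kb, small enough to
#' simulate in seconds.
#'
#' @param autosome_len,x_len,y_len chromosome lengths in bp.
#' @param par1_len,par2_len lengths of the two pseudoautosomal blocks,
#'   placed at the start (PAR1) and end (PAR2) of both X and Y.
#' @param xtr_x,xtr_y 0-based half-open `(start, end)` of the XTR-like
#'   block on X and Y (must be the same length).
#' @param xtr_identity fraction of identical bases between the X and Y
#'   copies of the XTR block, in (0, 1].
#' @param chrom_names names for (autosome, X, Y).
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(autosome_len = 120000L, x_len = 120000L,
                        y_len = 60000L,
                        par1_len = 5000L, par2_len = 5000L,
                        xtr_x = c(60000L, 70000L),
                        xtr_y = c(20000L, 30000L),
                        xtr_identity = 0.98,
                        chrom_names = c("chrA", "chrX", "chrY")) {
  stopifnot(autosome_len > 0, x_len > 0, y_len > 0,
            xtr_identity > 0, xtr_identity <= 1,
            diff(xtr_x) == diff(xtr_y), diff(xtr_x) > 0)
  spec <- list(autosome_len = as.integer(autosome_len),
               x_len = as.integer(x_len), y_len = as.integer(y_len),
               par1_len = as.integer(par1_len),
               par2_len = as.integer(par2_len),
               xtr_x = as.integer(xtr_x), xtr_y = as.integer(xtr_y),
               xtr_identity = xtr_identity,
               chrom_names = chrom_names)
  class(spec) <- "genome_spec"
  spec
}

# feature table (0-based half-open) implied by a genome_spec
genome_features <- function(spec) {
  x <- spec$chrom_names[2L]; y <- spec$chrom_names[3L]
  feats <- genomic_intervals(
    chrom = c(x, y, x, y, x, y),
    start = c(0L, 0L,
              spec$x_len - spec$par2_len, spec$y_len - spec$par2_len,
              spec$xtr_x[1L], spec$xtr_y[1L]),
    end = c(spec$par1_len, spec$par1_len,
            spec$x_len, spec$y_len,
            spec$xtr_x[2L], spec$xtr_y[2L]),
    name = c("PAR1", "PAR1", "PAR2", "PAR2", "XTR", "XTR"))
  for (chrom in unique(feats$chrom)) {
    f <- feats[feats$chrom == chrom, ]
    f <- f[order(f$start), ]
    if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)])) {
      stop("overlapping feature intervals on ", chrom)
    }
  }
  feats
}

#' Simulate the toy genome
#'
#' Draws uniform-ACGT sequences for the three chromosomes, copies the X
#' PAR blocks byte-identically onto the Y, and copies the X XTR block
#' onto the Y with random substitutions at rate `1 - xtr_identity`. All
#' output is a pure function of `(spec, seed)`.
#'
#' @param spec a [genome_spec()].
#' @param seed integer RNG seed.
#' @return object of class `sim_genome`: list with `fasta`
#'   (`DNAStringSet`), `features` (interval frame naming PAR1/PAR2/XTR),
#'   `spec` and `seed`.
#' @export
simulate_genome <- function(spec = genome_spec(), seed = 1L) {
  feats <- genome_features(spec)  # validates overlap
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  draw <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  a_seq <- draw(spec$autosome_len)
  x_seq <- draw(spec$x_len)
  y_seq <- draw(spec$y_len)

  x_nm <- spec$chrom_names[2L]; y_nm <- spec$chrom_names[3L]
  copy_block <- function(from, to, f_start, t_start, len) {
    substr(to, t_start + 1L, t_start + len) <-
      substr(from, f_start + 1L, f_start + len)
    to
  }
  # PARs: identical copies
  y_seq <- copy_block(x_seq, y_seq, 0L, 0L, spec$par1_len)
  y_seq <- copy_block(x_seq, y_seq, spec$x_len - spec$par2_len,
                      spec$y_len - spec$par2_len, spec$par2_len)
  # XTR: copy with divergence
  xtr_len <- diff(spec$xtr_x)
  xtr <- substr(x_seq, spec$xtr_x[1L] + 1L, spec$xtr_x[2L])
  if (spec$xtr_identity < 1) {
    chars <- strsplit(xtr, "")[[1L]]
    mut <- which(stats::runif(xtr_len) < 1 - spec$xtr_identity)
    for (i in mut) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    xtr <- paste(chars, collapse = "")
  }
  substr(y_seq, spec$xtr_y[1L] + 1L, spec$xtr_y[2L]) <- xtr

  fasta <- Biostrings::DNAStringSet(c(a_seq, x_seq, y_seq))
  names(fasta) <- spec$chrom_names
  structure(list(fasta = fasta, features = feats, spec = spec, seed = seed),
            class = "sim_genome")
}

#' Write a simulated genome to FASTA + BED
#'
#' @param genome a `sim_genome`.
#' @param prefix output path prefix; writes `<prefix>.fa` (+ `.fai`) and
#'   `<prefix>_features.bed`.
#' @return named list of the written paths.
#' @export
write_genome <- function(genome, prefix) {
  fa <- paste0(prefix, ".fa")
  Biostrings::writeXStringSet(genome$fasta, fa, width = 60L)
  Rsamtools::indexFa(fa)
  bed <- paste0(prefix, "_features.bed")
  write_bed(genome$features, bed)
  list(fasta = fa, features = bed)
}

#' Ploidy / sequencing configuration for the read simulator
#'
#' @param complement `"XX"` or `"XY"`; copy numbers follow
#'   (XX: autosome 2, X 2, Y 0; XY: autosome 2, X 1, Y 1).
#' @param mean_depth target fold-coverage of a two-copy chromosome.
#' @param read_len read length in bp.
#' @param paired simulate read pairs (insert `insert_size`) or single-end.
#' @param error_rate per-base sequencing error substitution rate.
#' @param n_read_groups reads are assigned round-robin by fragment to this
#'   many read groups (`rg1`, `rg2`, ...).
#' @param insert_size outer fragment length for pairs.
#' @param mapq_unique MAPQ given to uniquely placed reads; ambiguous reads
#'   (homologous-region placement) get MAPQ 0.
#' @return object of class `ploidy_config`.
#' @export
ploidy_config <- function(complement = c("XY", "XX"), mean_depth = 20,
                          read_len = 100L, paired = TRUE,
                          error_rate = 0, n_read_groups = 1L,
                          insert_size = 300L, mapq_unique = 60L) {
  complement <- match.arg(complement)
  stopifnot(mean_depth > 0, read_len > 0, insert_size >= 2L * read_len)
  cn <- if (complement == "XX") c(A = 2L, X = 2L, Y = 0L) else
    c(A = 2L, X = 1L, Y = 1L)
  structure(list(complement = complement, copy_number = cn,
                 mean_depth = mean_depth, read_len = as.integer(read_len),
                 paired = isTRUE(paired), error_rate = error_rate,
                 n_read_groups = as.integer(n_read_groups),
                 insert_size = as.integer(insert_size),
                 mapq_unique = as.integer(mapq_unique)),
            class = "ploidy_config")
}

# Homologous block table for a genome: rows map an X block to its Y copy.
homology_blocks <- function(genome) {
  spec <- genome$spec
  x <- spec$chrom_names[2L]; y <- spec$chrom_names[3L]
  data.frame(
    name = c("PAR1", "PAR2", "XTR"),
    x_chrom = x,
    x_start = c(0L, spec$x_len - spec$par2_len, spec$xtr_x[1L]),
    y_chrom = y,
    y_start = c(0L, spec$y_len - spec$par2_len, spec$xtr_y[1L]),
    len = c(spec$par1_len, spec$par2_len, diff(spec$xtr_x)),
    stringsAsFactors = FALSE)
}

# Divergent offsets (1-based within block) between the X and Y XTR copies.
xtr_divergent_offsets <- function(genome) {
  spec <- genome$spec
  xs <- as.character(Biostrings::subseq(genome$fasta[[spec$chrom_names[2L]]],
                                        spec$xtr_x[1L] + 1L, spec$xtr_x[2L]))
  ys <- as.character(Biostrings::subseq(genome$fasta[[spec$chrom_names[3L]]],
                                        spec$xtr_y[1L] + 1L, spec$xtr_y[2L]))
  which(strsplit(xs, "")[[1L]] != strsplit(ys, "")[[1L]])
}

#' Simulate alignments of known ploidy
#'
#' Draws fragments uniformly along each chromosome in proportion to its
#' copy number (so expected depth(X)/depth(autosome) is 1.0 for XX and 0.5
#' for XY), writes read sequences copied from the true origin (optionally
#' carrying truth-variant alleles and sequencing errors), and places reads
#' deterministically — a "toy aligner" baked into the simulator, so no
#' external aligner runs.
#'
#' The placement model encodes the homology mechanism: under
#' `reference_mode = "unmasked"` (a reference carrying both sex
#' chromosomes), a read falling entirely inside a PAR block — or inside
#' the XTR with no divergent site within its span — maps equally well to
#' both gametologs, so it is assigned MAPQ 0 and placed on the X or Y copy
#' with equal probability. Under `reference_mode = "masked"` every read is
#' placed uniquely at high MAPQ (PAR reads on the X when the Y PARs are
#' masked).
#'
#' @param genome a `sim_genome`.
#' @param ploidy a [ploidy_config()].
#' @param bam_path output BAM location (sorted + indexed).
#' @param variants optional truth set from [simulate_variants()]; its
#'   alleles are written into reads covering each site (heterozygous sites
#'   on one of the two haplotypes, homozygous-alt on both).
#' @param reference_mode `"unmasked"` or `"masked"` (see above).
#' @param seed integer RNG seed.
#' @return list with `bam` (path), `truth` (per-read data frame: qname,
#'   mate, true/placed chromosome and position, MAPQ, ambiguity flag, read
#'   group) and `ploidy`.
#' @export
simulate_alignments <- function(genome, ploidy, bam_path,
                                variants = NULL,
                                reference_mode = c("unmasked", "masked"),
                                seed = 1L) {
  reference_mode <- match.arg(reference_mode)
  spec <- genome$spec
  set.seed(seed)
  dict <- sequence_dictionary(genome$fasta)
  chroms <- spec$chrom_names
  cn <- ploidy$copy_number
  names(cn) <- chroms
  rl <- ploidy$read_len
  ins <- if (ploidy$paired) ploidy$insert_size else rl
  blocks <- homology_blocks(genome)
  div_off <- xtr_divergent_offsets(genome)
  # cumulative divergent-site counts within the XTR block, for O(1) span queries
  xtr_len <- blocks$len[blocks$name == "XTR"]
  div_cum <- cumsum(tabulate(div_off, nbins = xtr_len))

  frag_list <- list()
  for (chrom in chroms) {
    k <- cn[[chrom]]
    if (k == 0L) next
    len <- dict$length[dict$name == chrom]
    depth <- ploidy$mean_depth * k / 2
    n_frag <- round(depth * len / (if (ploidy$paired) 2 * rl else rl))
    n_frag <- max(0L, as.integer(n_frag))
    if (n_frag == 0L) next
    s <- sample.int(len - ins + 1L, n_frag, replace = TRUE)  # 1-based start
    frag_list[[chrom]] <- data.frame(
      chrom = chrom, start = s,
      hap = if (k == 2L) sample.int(2L, n_frag, replace = TRUE)
            else rep(1L, n_frag),
      stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frag_list)
  if (is.null(frags) || nrow(frags) == 0L) {
    bam <- write_bam(empty_alignments(), dict, bam_path)
    return(list(bam = bam, truth = NULL, ploidy = ploidy))
  }
  rownames(frags) <- NULL
  n <- nrow(frags)
  frags$rg <- paste0("rg", (seq_len(n) - 1L) %% ploidy$n_read_groups + 1L)
  frags$qname <- sprintf("sim_%s_%07d", frags$chrom, seq_len(n))

  chrom_str <- vapply(chroms, function(ch) as.character(genome$fasta[[ch]]), "")

  # forward-orientation sequences for both mates (mate 2 is the reverse
  # strand read: extracted forward here, reverse-complemented at output)
  r1_start <- frags$start
  r2_start <- frags$start + ins - rl
  seq1 <- substring(chrom_str[frags$chrom], r1_start, r1_start + rl - 1L)
  seq2 <- if (ploidy$paired)
    substring(chrom_str[frags$chrom], r2_start, r2_start + rl - 1L) else NULL

  inject <- function(seqs, starts, v) {
    # v: one truth site; seqs/starts restricted to reads on v's chromosome
    hit <- starts <= v$pos & v$pos <= starts + rl - 1L
    if (v$genotype == "het") hit <- hit & frags$hap == v$hap
    idx <- which(frags$chrom == v$chrom & hit)
    if (length(idx)) {
      off <- v$pos - starts[idx] + 1L
      substr(seqs[idx], off, off) <- v$alt
    }
    seqs
  }
  if (!is.null(variants)) {
    sites <- if (is.list(variants) && !is.data.frame(variants))
      variants$sites else variants
    for (i in seq_len(nrow(sites))) {
      v <- sites[i, ]
      seq1 <- inject(seq1, r1_start, v)
      if (ploidy$paired) seq2 <- inject(seq2, r2_start, v)
    }
  }
  if (ploidy$error_rate > 0) {
    add_errors <- function(seqs) {
      n_err <- stats::rbinom(length(seqs), rl, ploidy$error_rate)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(rl, n_err[i])
        for (p in pos) {
          cur <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
      seqs
    }
    seq1 <- add_errors(seq1)
    if (ploidy$paired) seq2 <- add_errors(seq2)
  }

  # placement: ambiguity per read under the unmasked (both-gametolog) reference
  place_reads <- function(chrom, start) {
    end <- start + rl - 1L
    placed_chrom <- chrom
    placed_pos <- start
    ambiguous <- rep(FALSE, length(start))
    if (reference_mode == "unmasked") {
      for (b in seq_len(nrow(blocks))) {
        blk <- blocks[b, ]
        for (side in c("x", "y")) {
          b_chrom <- blk[[paste0(side, "_chrom")]]
          b_start <- blk[[paste0(side, "_start")]]
          inside <- chrom == b_chrom & start > b_start & end <= b_start + blk$len
          if (!any(inside)) next
          if (blk$name == "XTR") {
            off_s <- start[inside] - b_start  # 1-based offset of read start
            off_e <- end[inside] - b_start
            n_div <- div_cum[off_e] - ifelse(off_s > 1L, div_cum[off_s - 1L], 0)
            inside[inside] <- n_div == 0
          }
          ambiguous <- ambiguous | inside
          # relocate half of the ambiguous reads to the homologous copy
          flip <- inside & stats::runif(length(start)) < 0.5
          other <- if (side == "x") "y" else "x"
          placed_chrom[flip] <- blk[[paste0(other, "_chrom")]]
          placed_pos[flip] <- start[flip] - b_start +
            blk[[paste0(other, "_start")]]
        }
      }
    } else {
      # masked reference: the Y copies of the shared blocks are Ns, so every
      # block read maps uniquely to the X copy
      for (b in seq_len(nrow(blocks))) {
        blk <- blocks[b, ]
        if (blk$name == "XTR") next  # diverged: Y XTR stays unmasked
        on_y <- chrom == blk$y_chrom & start > blk$y_start &
          end <= blk$y_start + blk$len
        placed_chrom[on_y] <- blk$x_chrom
        placed_pos[on_y] <- start[on_y] - blk$y_start + blk$x_start
      }
    }
    list(chrom = placed_chrom, pos = placed_pos, ambiguous = ambiguous)
  }
  p1 <- place_reads(frags$chrom, r1_start)
  p2 <- if (ploidy$paired) place_reads(frags$chrom, r2_start) else NULL

  mapq1 <- ifelse(p1$ambiguous, 0L, ploidy$mapq_unique)
  qual <- strrep("I", rl)
  cigar <- paste0(rl, "M")

  if (ploidy$paired) {
    mapq2 <- ifelse(p2$ambiguous, 0L, ploidy$mapq_unique)
    same <- p1$chrom == p2$chrom
    flag1 <- FLAG_PAIRED + FLAG_FIRST + FLAG_MATE_REVERSE +
      ifelse(same, FLAG_PROPER, 0L)
    flag2 <- FLAG_PAIRED + FLAG_SECOND + FLAG_REVERSE +
      ifelse(same, FLAG_PROPER, 0L)
    isize1 <- ifelse(same, p2$pos + rl - p1$pos, 0L)
    rec <- data.frame(
      qname = c(frags$qname, frags$qname),
      flag = c(flag1, flag2),
      rname = c(p1$chrom, p2$chrom),
      pos = c(p1$pos, p2$pos),
      mapq = c(mapq1, mapq2),
      cigar = cigar,
      mrnm = c(p2$chrom, p1$chrom),
      mpos = c(p2$pos, p1$pos),
      isize = c(isize1, -isize1),
      # SAM stores reverse-strand reads in forward reference orientation,
      # so mate 2 keeps its forward-extracted sequence here; the REVERSE
      # flag marks that the sequenced read was its reverse complement
      seq = c(seq1, seq2),
      qual = qual,
      rg = c(frags$rg, frags$rg),
      zr = NA_integer_,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      qname = c(frags$qname, frags$qname),
      mate = rep(c(1L, 2L), each = n),
      true_chrom = c(frags$chrom, frags$chrom),
      true_pos = c(r1_start, r2_start),
      placed_chrom = c(p1$chrom, p2$chrom),
      placed_pos = c(p1$pos, p2$pos),
      mapq = c(mapq1, mapq2),
      ambiguous = c(p1$ambiguous, p2$ambiguous),
      rg = c(frags$rg, frags$rg),
      stringsAsFactors = FALSE)
  } else {
    rec <- data.frame(
      qname = frags$qname, flag = 0L, rname = p1$chrom, pos = p1$pos,
      mapq = mapq1, cigar = cigar, mrnm = NA_character_, mpos = NA_integer_,
      isize = NA_integer_, seq = seq1, qual = qual, rg = frags$rg,
      zr = NA_integer_, stringsAsFactors = FALSE)
    truth <- data.frame(
      qname = frags$qname, mate = 1L, true_chrom = frags$chrom,
      true_pos = r1_start, placed_chrom = p1$chrom, placed_pos = p1$pos,
      mapq = mapq1, ambiguous = p1$ambiguous, rg = frags$rg,
      stringsAsFactors = FALSE)
  }
  bam <- write_bam(rec, dict, bam_path)
  list(bam = bam, truth = truth, ploidy = ploidy)
}

#' Simulate truth variants with allele read counts
#'
#' Diploid chromosomes receive heterozygous sites (alt read counts drawn
#' Binomial(depth, 0.5)) and homozygous-alt sites (Binomial(depth,
#' 1 - error)); haploid chromosomes receive homozygous-alt sites only, so
#' a haploid X shows the expected single read-balance peak near 1.0 while
#' diploid chromosomes show peaks near 0.5 and 1.0.
#'
#' @param genome a `sim_genome`.
#' @param ploidy a [ploidy_config()]; copy numbers decide which
#'   chromosomes may carry heterozygous sites.
#' @param het_rate,hom_rate per-bp rates of heterozygous and
#'   homozygous-alt sites on eligible chromosomes.
#' @param error_rate base-call error rate used for the homozygous-alt
#'   binomial (reference-supporting reads at a fixed site).
#' @param seed integer RNG seed.
#' @return list with `sites` (data frame: chrom, pos (1-based), ref, alt,
#'   genotype, hap, depth, ref_count, alt_count, qual, mq, gq) and the
#'   `genome`/`ploidy` used.
#' @export
simulate_variants <- function(genome, ploidy, het_rate = 0.002,
                              hom_rate = 0.001, error_rate = 0.01,
                              seed = 1L) {
  stopifnot(het_rate >= 0, het_rate <= 1, hom_rate >= 0, hom_rate <= 1)
  set.seed(seed)
  spec <- genome$spec
  dict <- sequence_dictionary(genome$fasta)
  cn <- ploidy$copy_number
  names(cn) <- spec$chrom_names
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (chrom in spec$chrom_names) {
    k <- cn[[chrom]]
    if (k == 0L) next
    len <- dict$length[dict$name == chrom]
    n_het <- if (k == 2L) stats::rbinom(1L, len, het_rate) else 0L
    n_hom <- stats::rbinom(1L, len, hom_rate)
    n_tot <- n_het + n_hom
    if (n_tot == 0L) next
    pos <- sort(sample.int(len, n_tot))
    genotype <- sample(rep(c("het", "hom"), c(n_het, n_hom)))
    ref <- strsplit(as.character(Biostrings::extractAt(
      genome$fasta[[chrom]], IRanges::IRanges(pos, pos))), NULL)
    ref <- vapply(ref, `[`, "", 1L)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    depth <- pmax(1L, stats::rpois(n_tot, ploidy$mean_depth * k / 2))
    p_alt <- ifelse(genotype == "het", 0.5, 1 - error_rate)
    alt_count <- stats::rbinom(n_tot, depth, p_alt)
    out[[chrom]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      genotype = genotype,
      hap = ifelse(genotype == "het", sample.int(2L, n_tot, replace = TRUE), 0L),
      depth = depth, ref_count = depth - alt_count, alt_count = alt_count,
      qual = round(stats::runif(n_tot, 40, 90), 1),
      mq = 60, gq = 99L,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character(), hap = integer(),
               depth = integer(), ref_count = integer(),
               alt_count = integer(), qual = numeric(), mq = numeric(),
               gq = integer(), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  list(sites = sites, genome = genome, ploidy = ploidy, seed = seed)
}

#' Write a truth variant set as a VCF
#'
#' @param variants result of [simulate_variants()] (or its `sites` frame).
#' @param dict sequence dictionary for the contig header lines.
#' @param path output VCF location (plain text).
#' @param sample_id sample column name.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(variants, dict, path, sample_id = "sample") {
  sites <- if (is.list(variants) && !is.data.frame(variants))
    variants$sites else variants
  write_vcf_sites(sites, dict, path, sample_id)
}

# shared VCF writer used by the truth set and the naive caller
write_vcf_sites <- function(sites, dict, path, sample_id = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", dict$name, dict$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
  body <- character()
  if (nrow(sites) > 0L) {
    sites <- sites[order(match(sites$chrom, dict$name), sites$pos), ]
    gt <- if (!is.null(sites$genotype))
      ifelse(sites$genotype == "het", "0/1", "1/1") else sites$gt
    body <- paste0(sites$chrom, "\t", sites$pos, "\t.\t", sites$ref, "\t",
                   sites$alt, "\t", sites$qual, "\t.\t",
                   "DP=", sites$depth, ";MQ=", sites$mq, "\t",
                   "GT:GQ:DP:AD\t",
                   gt, ":", sites$gq, ":", sites$depth, ":",
                   sites$ref_count, ",", sites$alt_count)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
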