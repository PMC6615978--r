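# Shared fixtures, built once per test session and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk except
# files these helpers write into the session temp directory.

fx_env <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = fx_env)) assign(name, build(), envir = fx_env)
  get(name, envir = fx_env)
}

fx_dir <- function() {
  d <- file.path(tempdir(), "sexchromr-fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

toy_genome <- function() fx("genome", function() simulate_genome(seed = 101L))

toy_fasta <- function() fx("fasta", function() {
  write_genome(toy_genome(), file.path(fx_dir(), "toy"))$fasta
})

y_par_intervals <- function() {
  feats <- toy_genome()$features
  feats[feats$chrom == "chrY" & feats$name != "XTR", ]
}

toy_pair <- function() fx("pair", function() {
  prepare_reference_pair(toy_fasta(), "chrY",
                         shared_region_mask = y_par_intervals(),
                         out_prefix = file.path(fx_dir(), "ref_"))
})

xx_variants <- function() fx("xx_variants", function() {
  simulate_variants(toy_genome(), ploidy_config("XX"), seed = 102L)
})

# XX sample mapped to the unmasked (both-gametolog) reference: carries the
# homology artifact (ambiguous PAR/XTR reads, some mismapped to chrY)
xx_sim <- function() fx("xx_sim", function() {
  simulate_alignments(toy_genome(), ploidy_config("XX"),
                      file.path(fx_dir(), "xx.bam"),
                      variants = xx_variants(), seed = 103L)
})

xy_sim <- function() fx("xy_sim", function() {
  simulate_alignments(toy_genome(), ploidy_config("XY"),
                      file.path(fx_dir(), "xy.bam"), seed = 104L)
})

# artifact-free XX alignments (masked-reference placement), same variants
xx_clean_sim <- function() fx("xx_clean_sim", function() {
  simulate_alignments(toy_genome(), ploidy_config("XX"),
                      file.path(fx_dir(), "xx_clean.bam"),
                      variants = xx_variants(),
                      reference_mode = "masked", seed = 103L)
})

# strip -> remap (homogametic reference) -> merge on the XX fixture
xx_corrected <- function() fx("xx_corrected", function() {
  pair <- toy_pair()
  simv <- xx_sim()
  bundles <- strip_reads(simv$bam, c("chrX", "chrY"),
                         out_dir = file.path(fx_dir(), "fq_xx"))
  remapped <- file.path(fx_dir(), "xx_remap.bam")
  remap_reads(bundles, pair$homogametic_path, remapped, seed = 105L)
  merged <- file.path(fx_dir(), "xx_merged.bam")
  merge_with_nonsex(simv$bam, remapped, c("chrX", "chrY"), merged)
  list(bundles = bundles, remapped = remapped, merged = merged)
})

# hand-built BAM from alignment records (internal writer)
make_bam <- function(records, dict, name) {
  sexchromr:::write_bam(records, dict, file.path(fx_dir(), name))
}

align_rec <- function(qname, rname, pos, mapq = 60L, len = 100L,
                      flag = 0L, seq = NULL, rg = NA_character_) {
  if (is.null(seq)) seq <- strrep("A", len)
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq),
             cigar = paste0(nchar(seq), "M"), mrnm = NA_character_,
             mpos = NA_integer_, isize = NA_integer_, seq = seq,
             qual = strrep("I", nchar(seq)), rg = rg, zr = NA_integer_,
             stringsAsFactors = FALSE)
}

# minimal variant-site frame for filter / balance tests
site_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     qual = 50, mq = 60, gq = 99, depth = 30L,
                     ref_count = 15L, alt_count = 15L) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             mq = mq, gq = gq, depth = depth, ref_count = ref_count,
             alt_count = alt_count, stringsAsFactors = FALSE)
}
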