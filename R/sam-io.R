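# Internal alignment-record layer.
#
# Alignment records move through the package as a plain data frame with
# the SAM mandatory fields (qname, flag, rname, pos, mapq, cigar, mrnm,
# mpos, isize, seq, qual) plus the read-group `rg` and the remap marker
# `zr` (NA when untagged). Writing goes through SAM text + Rsamtools::asBam,
# which coordinate-sorts and indexes; reading goes through scanBam.

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             mrnm = character(), mpos = integer(), isize = integer(),
             seq = character(), qual = character(), rg = character(),
             zr = integer(), stringsAsFactors = FALSE)
}

# dict: data.frame(name, length); rg_ids: character vector for @RG lines.
sam_header_lines <- function(dict, rg_ids = character()) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", dict$name, dict$length),
    if (length(rg_ids)) sprintf("@RG\tID:%s\tSM:sample", rg_ids))
}

# Write alignment records to a coordinate-sorted, indexed BAM.
write_bam <- function(records, dict, bam_path) {
  rg_ids <- unique(records$rg)
  rg_ids <- rg_ids[!is.na(rg_ids)]
  opt <- character(nrow(records))
  if (nrow(records) > 0L) {
    opt <- ifelse(is.na(records$rg), "", paste0("\tRG:Z:", records$rg))
    opt <- paste0(opt, ifelse(is.na(records$zr), "",
                              paste0("\tZR:i:", records$zr)))
  }
  body <- if (nrow(records) == 0L) character() else
    paste0(records$qname, "\t", records$flag, "\t",
           ifelse(is.na(records$rname), "*", records$rname), "\t",
           ifelse(is.na(records$pos), 0L, records$pos), "\t",
           records$mapq, "\t",
           ifelse(is.na(records$cigar), "*", records$cigar), "\t",
           ifelse(is.na(records$mrnm), "*", records$mrnm), "\t",
           ifelse(is.na(records$mpos), 0L, records$mpos), "\t",
           ifelse(is.na(records$isize), 0L, records$isize), "\t",
           records$seq, "\t", records$qual, opt)
  sam_path <- tempfile(fileext = ".sam")
  on.exit(unlink(sam_path), add = TRUE)
  writeLines(c(sam_header_lines(dict, rg_ids), body), sam_path)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam_path, dest, overwrite = TRUE, indexDestination = TRUE)
  bam_path
}

# Read every record of a BAM into the package's alignment data frame.
read_bam_records <- function(bam_path) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual"),
    tag = c("RG", "ZR"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1L]]
  n <- length(res$qname)
  rg <- res$tag$RG
  zr <- res$tag$ZR
  data.frame(qname = res$qname,
             flag = as.integer(res$flag),
             rname = as.character(res$rname),
             pos = res$pos,
             mapq = as.integer(res$mapq),
             cigar = res$cigar,
             mrnm = as.character(res$mrnm),
             mpos = res$mpos,
             isize = res$isize,
             seq = as.character(res$seq),
             qual = as.character(res$qual),
             rg = if (is.null(rg)) rep(NA_character_, n) else as.character(rg),
             zr = if (is.null(zr)) rep(NA_integer_, n) else as.integer(zr),
             stringsAsFactors = FALSE)
}

# Sequence dictionary recorded in a BAM header.
bam_dictionary <- function(bam_path) {
  targets <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  data.frame(name = names(targets), length = as.integer(targets),
             stringsAsFactors = FALSE)
}

require_bam_index <- function(bam_path) {
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("BAM index (.bai) not found for ", bam_path,
         "; coordinate-sort and index the BAM first")
  }
  invisible(bam_path)
}
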