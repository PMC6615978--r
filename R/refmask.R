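#' Sequence dictionary of a FASTA or DNAStringSet
#'
#' The ordered (name, length) table shared by a reference and every file
#' derived from it. Masked and unmasked reference versions must have
#' identical dictionaries so BAMs and VCFs from either can be processed
#' jointly.
#'
#' @param x a FASTA path or a [Biostrings::DNAStringSet].
#' @return data frame with columns `name` and `length`, in record order.
#' @export
sequence_dictionary <- function(x) {
  seqs <- load_fasta(x)
  nm <- names(seqs)
  if (anyDuplicated(nm)) stop("duplicated sequence names in reference")
  data.frame(name = nm, length = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}

load_fasta <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (!file.exists(x)) stop("cannot read FASTA: ", x)
  seqs <- Biostrings::readDNAStringSet(x)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Hard-mask whole chromosomes with Ns
#'
#' Replaces every base of the named chromosomes with uppercase `N`,
#' leaving lengths, record order and all other records untouched. Used to
#' remove the Y chromosome from the reference version intended for
#' homogametic (XX) samples.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param names chromosome names to mask (may be empty).
#' @return `DNAStringSet` with the named records masked.
#' @export
mask_chromosomes <- function(reference, names) {
  seqs <- load_fasta(reference)
  names <- as.character(names)
  missing <- setdiff(names, base::names(seqs))
  if (length(missing) > 0L) {
    stop("chromosome(s) not present in reference: ",
         paste(missing, collapse = ", "))
  }
  for (nm in names) {
    seqs[[nm]] <- Biostrings::DNAString(
      strrep("N", Biostrings::nchar(seqs[[nm]])))
  }
  seqs
}

#' Hard-mask BED regions with Ns
#'
#' Replaces the bases in the union of the given 0-based half-open
#' intervals with uppercase `N`. Overlapping intervals are unioned;
#' everything outside them is untouched and lengths are conserved.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param regions a `genomic_intervals` data frame (see [genomic_intervals()])
#'   or a BED path.
#' @return masked `DNAStringSet`.
#' @export
mask_regions <- function(reference, regions) {
  seqs <- load_fasta(reference)
  if (is.character(regions) && length(regions) == 1L) regions <- read_bed(regions)
  if (nrow(regions) == 0L) return(seqs)
  validate_intervals(regions, sequence_dictionary(seqs))
  for (chrom in unique(regions$chrom)) {
    rr <- regions[regions$chrom == chrom, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(rr$start + 1L, rr$end))
    repl <- Biostrings::DNAStringSet(strrep("N", IRanges::width(ir)))
    seqs[[chrom]] <- Biostrings::replaceAt(
      seqs[[chrom]], ir, as.character(repl))
  }
  seqs
}

#' Build the homogametic/heterogametic reference pair
#'
#' Writes two versions of the same reference sharing one sequence
#' dictionary: the homogametic version (e.g. "XX") with the
#' heterogametic-only chromosomes (e.g. Y) fully hard-masked, and the
#' heterogametic version (e.g. "XY") with the shared gametologous regions
#' (e.g. the Y-chromosome PARs) hard-masked so reads from those regions
#' map exclusively to the X. Optional extra masks are applied to both.
#' Both FASTAs are written at 60 columns and faidx-indexed.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param heterogametic_only_chroms chromosomes present only in the
#'   heterogametic sex (masked in the homogametic version), e.g. `"chrY"`.
#' @param shared_region_mask intervals (or BED path) masked in the
#'   heterogametic version only, typically the Y PARs. May be `NULL`.
#' @param extra_masks optional list of interval frames / BED paths masked
#'   in both versions.
#' @param out_prefix path prefix for the output FASTAs
#'   (`<prefix>homogametic.fa`, `<prefix>heterogametic.fa`).
#' @return an object of class `reference_pair` with elements
#'   `homogametic_path`, `heterogametic_path`, `masked_chroms`,
#'   `masked_regions` and `dictionary`.
#' @export
prepare_reference_pair <- function(reference, heterogametic_only_chroms,
                                   shared_region_mask = NULL,
                                   extra_masks = NULL,
                                   out_prefix = "reference_") {
  seqs <- load_fasta(reference)
  dict <- sequence_dictionary(seqs)
  if (length(heterogametic_only_chroms) == 0L) {
    warning("no heterogametic-only chromosomes given; ",
            "the two reference versions differ only by shared/extra masks")
  }
  norm_regions <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) read_bed(x) else x
  }
  shared <- norm_regions(shared_region_mask)
  if (!is.null(extra_masks)) {
    if (!is.list(extra_masks) || is.data.frame(extra_masks)) {
      extra_masks <- list(extra_masks)
    }
    extra <- do.call(rbind, lapply(extra_masks, function(x) {
      norm_regions(x)[, c("chrom", "start", "end")]
    }))
  } else {
    extra <- NULL
  }

  homo <- mask_chromosomes(seqs, heterogametic_only_chroms)
  hetero <- if (!is.null(shared)) mask_regions(seqs, shared) else seqs
  if (!is.null(extra) && nrow(extra) > 0L) {
    homo <- mask_regions(homo, extra)
    hetero <- mask_regions(hetero, extra)
  }

  homo_path <- paste0(out_prefix, "homogametic.fa")
  hetero_path <- paste0(out_prefix, "heterogametic.fa")
  write_fasta <- function(s, path) {
    Biostrings::writeXStringSet(s, path, width = 60L)
    Rsamtools::indexFa(path)
    path
  }
  write_fasta(homo, homo_path)
  write_fasta(hetero, hetero_path)

  masked_regions <- if (!is.null(shared)) shared[, c("chrom", "start", "end")] else
    genomic_intervals(character(), integer(), integer())

  structure(list(homogametic_path = homo_path,
                 heterogametic_path = hetero_path,
                 masked_chroms = as.character(heterogametic_only_chroms),
                 masked_regions = masked_regions,
                 dictionary = dict),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat("Sex-specific reference pair\n")
  cat("  homogametic  :", x$homogametic_path, "\n")
  cat("  heterogametic:", x$heterogametic_path, "\n")
  cat("  fully masked chromosomes (homogametic):",
      if (length(x$masked_chroms)) paste(x$masked_chroms, collapse = ", ") else "none", "\n")
  cat("  shared-region masks (heterogametic):", nrow(x$masked_regions), "interval(s)\n")
  cat("  dictionary:", nrow(x$dictionary), "sequence(s),",
      sum(x$dictionary$length), "bp\n")
  invisible(x)
}

#' Compare the sequence dictionaries of two references
#'
#' @param a,b FASTA paths or `DNAStringSet`s.
#' @return list with `identical` (logical) and `report` (character vector
#'   of mismatches, empty when identical).
#' @export
verify_dictionaries <- function(a, b) {
  da <- sequence_dictionary(a)
  db <- sequence_dictionary(b)
  report <- character()
  only_a <- setdiff(da$name, db$name)
  only_b <- setdiff(db$name, da$name)
  if (length(only_a)) report <- c(report, paste0("only in first: ", only_a))
  if (length(only_b)) report <- c(report, paste0("only in second: ", only_b))
  common <- intersect(da$name, db$name)
  la <- da$length[match(common, da$name)]
  lb <- db$length[match(common, db$name)]
  diff_len <- common[la != lb]
  if (length(diff_len)) {
    report <- c(report, sprintf("length mismatch for %s: %d vs %d", diff_len,
                                la[la != lb], lb[la != lb]))
  }
  if (length(report) == 0L && !identical(da$name, db$name)) {
    report <- c(report, paste0("record order differs: [",
                               paste(da$name, collapse = ","), "] vs [",
                               paste(db$name, collapse = ","), "]"))
  }
  list(identical = length(report) == 0L, report = report)
}
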