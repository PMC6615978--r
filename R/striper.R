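#' Strip reads from target chromosomes into per-read-group FASTQs
#'
#' Extracts, by read group, every primary read pair with either mate
#' aligned to a target chromosome (the pair-rescue rule keeps FASTQs
#' valid for paired remapping), restoring original read orientation
#' (reverse-strand records are reverse-complemented back) and base
#' qualities. Mates are written in matched order across the two FASTQ
#' files; reads whose mate record is missing go to a singles file with a
#' warning. Records without an RG tag form a single `"default"` group.
#'
#' @param bam coordinate-sorted, indexed BAM.
#' @param target_chroms chromosomes whose reads are stripped (e.g.
#'   `c("chrX", "chrY")`).
#' @param out_dir directory for the FASTQ files.
#' @param paired treat the BAM as paired-end.
#' @return list of class `strip_bundles`; each element has
#'   `read_group_id`, `fastq_1`, `fastq_2` (NA for single-end),
#'   `n_pairs` (or `n_reads`), `singles` path and `n_singles`.
#' @export
strip_reads <- function(bam, target_chroms, out_dir = tempfile("strip_"),
                        paired = TRUE) {
  require_bam_index(bam)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- read_bam_records(bam)
  rec <- rec[!has_flag(rec$flag, FLAG_SECONDARY) &
               !has_flag(rec$flag, FLAG_SUPPLEMENTARY), , drop = FALSE]
  rec$rg[is.na(rec$rg)] <- "default"

  on_target <- !is.na(rec$rname) & rec$rname %in% target_chroms
  keep_qnames <- unique(rec$qname[on_target])
  rec <- rec[rec$qname %in% keep_qnames, , drop = FALSE]

  # restore original orientation
  rev <- has_flag(rec$flag, FLAG_REVERSE)
  if (any(rev)) {
    rec$seq[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rec$seq[rev])))
    rec$qual[rev] <- vapply(rec$qual[rev], function(q)
      paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "")
  }

  write_fastq <- function(df, path) {
    if (nrow(df) == 0L) {
      file.create(path)
    } else {
      writeLines(paste0("@", df$qname, "\n", df$seq, "\n+\n", df$qual), path)
    }
    path
  }

  bundles <- lapply(sort(unique(rec$rg)), function(rg) {
    g <- rec[rec$rg == rg, , drop = FALSE]
    if (!paired) {
      g <- g[order(g$qname), , drop = FALSE]
      fq1 <- write_fastq(g, file.path(out_dir, paste0(rg, ".fastq")))
      return(list(read_group_id = rg, fastq_1 = fq1, fastq_2 = NA_character_,
                  n_reads = nrow(g), singles = NA_character_, n_singles = 0L))
    }
    m1 <- g[has_flag(g$flag, FLAG_FIRST), , drop = FALSE]
    m2 <- g[has_flag(g$flag, FLAG_SECOND), , drop = FALSE]
    complete <- intersect(m1$qname, m2$qname)
    orphan <- rbind(m1[!(m1$qname %in% complete), , drop = FALSE],
                    m2[!(m2$qname %in% complete), , drop = FALSE])
    m1 <- m1[m1$qname %in% complete, , drop = FALSE]
    m2 <- m2[m2$qname %in% complete, , drop = FALSE]
    m1 <- m1[order(m1$qname), , drop = FALSE]
    m2 <- m2[order(m2$qname), , drop = FALSE]
    fq1 <- write_fastq(m1, file.path(out_dir, paste0(rg, "_1.fastq")))
    fq2 <- write_fastq(m2, file.path(out_dir, paste0(rg, "_2.fastq")))
    singles <- NA_character_
    if (nrow(orphan) > 0L) {
      warning(nrow(orphan), " orphaned mate(s) in read group ", rg,
              " written to a singles file")
      singles <- write_fastq(orphan,
                             file.path(out_dir, paste0(rg, "_singles.fastq")))
    }
    list(read_group_id = rg, fastq_1 = fq1, fastq_2 = fq2,
         n_pairs = nrow(m1), singles = singles, n_singles = nrow(orphan))
  })
  names(bundles) <- vapply(bundles, `[[`, "", "read_group_id")
  class(bundles) <- "strip_bundles"
  bundles
}

#' @export
print.strip_bundles <- function(x, ...) {
  cat("Stripped read bundles (", length(x), " read group(s))\n", sep = "")
  for (b in x) {
    n <- if (!is.null(b$n_pairs)) paste(b$n_pairs, "pairs") else
      paste(b$n_reads, "reads")
    cat("  ", b$read_group_id, ": ", n,
        if (b$n_singles > 0L) paste0(" + ", b$n_singles, " singles") else "",
        "\n", sep = "")
  }
  invisible(x)
}

read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(qname = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  n <- length(lines) %/% 4L
  data.frame(qname = sub("^@", "", lines[seq(1L, by = 4L, length.out = n)]),
             seq = lines[seq(2L, by = 4L, length.out = n)],
             qual = lines[seq(4L, by = 4L, length.out = n)],
             stringsAsFactors = FALSE)
}

# Seed-and-extend placement of reads against a reference. Exact 32-mer
# seeds from both read ends (forward and reverse complement) propose
# candidate loci; each candidate is verified by full-length mismatch
# counting. The unique minimum-mismatch locus maps at mapq_unique;
# several equally good loci give MAPQ 0 with one chosen uniformly (the
# gametolog ambiguity); no acceptable locus leaves the read unmapped.
# Hard-masked (all-N) regions admit no seeds, which is exactly how a
# masked reference redirects gametologous reads to the surviving copy.
exact_align <- function(reads, reference, mapq_unique = 60L,
                        seed_len = 32L, max_mismatch = 8L) {
  seqs <- load_fasta(reference)
  chrom_str <- vapply(names(seqs), function(ch) as.character(seqs[[ch]]), "")
  chrom_len <- nchar(chrom_str)
  n <- length(reads)
  res <- data.frame(chrom = rep(NA_character_, n), pos = NA_integer_,
                    strand = NA_character_, mapq = 0L, n_matches = 0L,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(res)
  widths <- nchar(reads)
  oriented <- list(
    "+" = reads,
    "-" = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads))))

  acc <- list()
  for (strand in c("+", "-")) {
    orient <- oriented[[strand]]
    for (w in unique(widths)) {
      idx <- which(widths == w)
      sl <- min(seed_len, w)
      for (ss in unique(c(1L, w - sl + 1L))) {
        pd <- Biostrings::PDict(substr(orient[idx], ss, ss + sl - 1L))
        for (chrom in names(seqs)) {
          st <- Biostrings::startIndex(Biostrings::matchPDict(pd, seqs[[chrom]]))
          hit <- which(lengths(st) > 0L)
          if (!length(hit)) next
          acc[[length(acc) + 1L]] <- data.frame(
            read = rep(idx[hit], lengths(st[hit])),
            chrom = chrom,
            pos = unlist(st[hit], use.names = FALSE) - (ss - 1L),
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(acc)) return(res)
  cand <- do.call(rbind, acc)
  cand <- cand[cand$pos >= 1L &
                 cand$pos + widths[cand$read] - 1L <= chrom_len[cand$chrom], ,
               drop = FALSE]
  cand <- cand[!duplicated(paste(cand$read, cand$chrom, cand$pos,
                                 cand$strand)), , drop = FALSE]
  if (nrow(cand) == 0L) return(res)
  ref_str <- substring(chrom_str[cand$chrom], cand$pos,
                       cand$pos + widths[cand$read] - 1L)
  read_str <- ifelse(cand$strand == "+",
                     oriented[["+"]][cand$read],
                     oriented[["-"]][cand$read])
  cand$mm <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                    read_str, ref_str, USE.NAMES = FALSE)
  cand <- cand[cand$mm <= max_mismatch, , drop = FALSE]
  if (nrow(cand) == 0L) return(res)
  for (rows in split(seq_len(nrow(cand)), cand$read)) {
    i <- cand$read[rows[1L]]
    best <- min(cand$mm[rows])
    winners <- rows[cand$mm[rows] == best]
    pick <- if (length(winners) == 1L) winners else
      winners[sample.int(length(winners), 1L)]
    res$chrom[i] <- cand$chrom[pick]
    res$pos[i] <- cand$pos[pick]
    res$strand[i] <- cand$strand[pick]
    res$mapq[i] <- if (length(winners) == 1L) mapq_unique else 0L
    res$n_matches[i] <- length(winners)
  }
  res
}

#' Remap stripped read bundles to a reference
#'
#' By default uses the package's seed-and-extend aligner (no external
#' binaries), writing one coordinate-sorted merged BAM with the original
#' read-group headers and a `ZR:i:1` provenance tag on every remapped
#' record. Alternatively, user-editable command templates run an
#' external aligner per bundle (placeholders `{ref}`, `{fq1}`, `{fq2}`,
#' `{out}`, `{rg}`); the per-group BAMs are then merged.
#'
#' @param bundles a `strip_bundles` list from [strip_reads()].
#' @param reference FASTA path (indexable) to remap against — typically
#'   one side of a [prepare_reference_pair()].
#' @param out_bam merged output BAM path.
#' @param aligner_cmd_template optional external command template that
#'   must produce a BAM at `{out}`.
#' @param sort_cmd_template optional sort command template with `{inp}`
#'   and `{out}` placeholders, run after the aligner.
#' @param seed seed for tie-breaking among equally good placements.
#' @param mapq_unique MAPQ for uniquely placed reads (internal aligner).
#' @return `out_bam`, invisibly.
#' @export
remap_reads <- function(bundles, reference, out_bam,
                        aligner_cmd_template = NULL,
                        sort_cmd_template = NULL,
                        seed = 1L, mapq_unique = 60L) {
  if (!is.null(aligner_cmd_template)) {
    return(remap_external(bundles, reference, out_bam,
                          aligner_cmd_template, sort_cmd_template))
  }
  set.seed(seed)
  dict <- sequence_dictionary(reference)
  seqs <- load_fasta(reference)
  all_rec <- list()
  for (b in bundles) {
    paired <- !is.na(b$fastq_2)
    r1 <- read_fastq(b$fastq_1)
    r2 <- if (paired) read_fastq(b$fastq_2) else NULL
    if (nrow(r1) == 0L) {
      warning("empty bundle for read group ", b$read_group_id, "; skipped")
      next
    }
    a1 <- exact_align(r1$seq, seqs, mapq_unique)
    a2 <- if (paired) exact_align(r2$seq, seqs, mapq_unique) else NULL
    mk <- function(fq, al, mate_al, first) {
      n <- nrow(fq)
      mapped <- !is.na(al$chrom)
      mate_mapped <- if (is.null(mate_al)) rep(FALSE, n) else !is.na(mate_al$chrom)
      neg <- !is.na(al$strand) & al$strand == "-"
      seq_out <- fq$seq
      qual_out <- fq$qual
      if (any(neg)) {
        seq_out[neg] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(fq$seq[neg])))
        qual_out[neg] <- vapply(fq$qual[neg], function(q)
          paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "")
      }
      flag <- rep(0L, n)
      if (!is.null(mate_al)) {
        mate_neg <- if (is.null(mate_al)) rep(FALSE, n) else
          (!is.na(mate_al$strand) & mate_al$strand == "-")
        same <- mapped & mate_mapped & al$chrom == mate_al$chrom
        flag <- FLAG_PAIRED +
          (if (first) FLAG_FIRST else FLAG_SECOND) +
          ifelse(mapped, 0L, FLAG_UNMAPPED) +
          ifelse(mate_mapped, 0L, FLAG_MATE_UNMAPPED) +
          ifelse(neg, FLAG_REVERSE, 0L) +
          ifelse(mate_neg, FLAG_MATE_REVERSE, 0L) +
          ifelse(same, FLAG_PROPER, 0L)
        isize <- rep(0L, n)
        ok <- which(same)
        if (length(ok)) {
          w <- nchar(fq$seq[ok])
          left <- pmin(al$pos[ok], mate_al$pos[ok])
          right <- pmax(al$pos[ok] + w - 1L, mate_al$pos[ok] + w - 1L)
          span <- right - left + 1L
          isize[ok] <- ifelse(al$pos[ok] <= mate_al$pos[ok], span, -span)
        }
        mrnm <- ifelse(mate_mapped, mate_al$chrom, NA_character_)
        mpos <- ifelse(mate_mapped, mate_al$pos, NA_integer_)
      } else {
        flag <- ifelse(mapped, 0L, FLAG_UNMAPPED) +
          ifelse(neg, FLAG_REVERSE, 0L)
        isize <- NA_integer_
        mrnm <- NA_character_
        mpos <- NA_integer_
      }
      data.frame(qname = fq$qname, flag = flag,
                 rname = al$chrom, pos = al$pos,
                 mapq = ifelse(mapped, al$mapq, 0L),
                 cigar = ifelse(mapped, paste0(nchar(fq$seq), "M"),
                                NA_character_),
                 mrnm = mrnm, mpos = mpos, isize = isize,
                 seq = seq_out, qual = qual_out,
                 rg = b$read_group_id, zr = 1L, stringsAsFactors = FALSE)
    }
    all_rec[[length(all_rec) + 1L]] <- mk(r1, a1, a2, TRUE)
    if (paired) all_rec[[length(all_rec) + 1L]] <- mk(r2, a2, a1, FALSE)
    if (!is.na(b$singles) && file.exists(b$singles)) {
      s <- read_fastq(b$singles)
      if (nrow(s) > 0L) {
        all_rec[[length(all_rec) + 1L]] <- mk(s, exact_align(s$seq, seqs,
                                                             mapq_unique),
                                              NULL, TRUE)
      }
    }
  }
  rec <- if (length(all_rec)) do.call(rbind, all_rec) else empty_alignments()
  write_bam(rec, dict, out_bam)
  invisible(out_bam)
}

# external-aligner route: one BAM per bundle via templates, then merged
remap_external <- function(bundles, reference, out_bam,
                           aligner_cmd_template, sort_cmd_template = NULL) {
  dict <- sequence_dictionary(reference)
  parts <- list()
  for (b in bundles) {
    r1 <- read_fastq(b$fastq_1)
    if (nrow(r1) == 0L) {
      warning("empty bundle for read group ", b$read_group_id, "; skipped")
      next
    }
    raw <- tempfile(fileext = ".bam")
    cmd <- fill_template(aligner_cmd_template,
                         list(ref = reference, fq1 = b$fastq_1,
                              fq2 = if (is.na(b$fastq_2)) "" else b$fastq_2,
                              out = raw, rg = b$read_group_id),
                         required = c("ref", "fq1", "out"))
    run_external(cmd)
    if (!is.null(sort_cmd_template)) {
      sorted <- tempfile(fileext = ".bam")
      run_external(fill_template(sort_cmd_template,
                                 list(inp = raw, out = sorted),
                                 required = c("inp", "out")))
      raw <- sorted
    }
    Rsamtools::indexBam(raw)
    part <- read_bam_records(raw)
    part$rg <- b$read_group_id
    part$zr <- 1L
    parts[[length(parts) + 1L]] <- part
  }
  rec <- if (length(parts)) do.call(rbind, parts) else empty_alignments()
  write_bam(rec, dict, out_bam)
  invisible(out_bam)
}

#' Merge remapped sex-chromosome alignments with untouched non-target alignments
#'
#' Partitions by chromosome: alignments on non-target chromosomes come
#' unchanged from the original BAM, alignments on the target (sex)
#' chromosomes come only from the remapped BAM (recognisable by their
#' `ZR` tag). Requires identical sequence dictionaries — which the
#' hard-masking strategy guarantees.
#'
#' @param original_bam the pre-remapping BAM.
#' @param remapped_bam output of [remap_reads()].
#' @param target_chroms chromosomes replaced by the remap.
#' @param out_bam merged, coordinate-sorted, indexed output.
#' @return `out_bam`, invisibly.
#' @export
merge_with_nonsex <- function(original_bam, remapped_bam, target_chroms,
                              out_bam) {
  d1 <- bam_dictionary(original_bam)
  d2 <- bam_dictionary(remapped_bam)
  if (!identical(d1, d2)) {
    stop("sequence dictionaries differ between original and remapped BAMs")
  }
  orig <- read_bam_records(original_bam)
  orig <- orig[is.na(orig$rname) | !(orig$rname %in% target_chroms), ,
               drop = FALSE]
  remap <- read_bam_records(remapped_bam)
  remap <- remap[!is.na(remap$rname) & remap$rname %in% target_chroms, ,
                 drop = FALSE]
  write_bam(rbind(orig, remap), d1, out_bam)
  invisible(out_bam)
}
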