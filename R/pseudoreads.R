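#' Chop a genome assembly into overlapping pseudo-reads
#'
#' Segments of `seg_len` bp are taken every `step` bp along each contig
#' (simulated long reads, ready for alignment to the reference). For a
#' contig of length L >= seg_len, starts run 0, step, 2*step, ... while
#' start + seg_len <= L; when L - seg_len is not a multiple of `step` one
#' final segment anchored at L - seg_len is added so the contig tail is
#' covered. Contigs shorter than `seg_len` are emitted whole. Ordering is
#' deterministic: contig order, then start.
#'
#' @param assembly `DNAStringSet` (or named character vector) of contigs
#' @param seg_len segment length in bp (default 5,000)
#' @param step distance between consecutive segment starts (default 200)
#' @return data.frame with one pseudo-read per row: `name`
#'   (`<contig>:<start>-<start+len>`), `contig`, `start` (0-based),
#'   `length`, `sequence`
#' @export
chop_assembly <- function(assembly, seg_len = 5000L, step = 200L) {
  if (!inherits(assembly, "DNAStringSet"))
    assembly <- Biostrings::DNAStringSet(assembly)
  seg_len <- as.integer(seg_len); step <- as.integer(step)
  stopifnot(seg_len >= step, step >= 1L)
  seqs <- as.character(assembly)
  out <- lapply(names(seqs), function(ct) {
    L <- nchar(seqs[[ct]])
    if (L == 0L) {
      warning(sprintf("contig '%s' is empty; skipped", ct))
      return(NULL)
    }
    if (L < seg_len) {
      starts <- 0L; lens <- L
    } else {
      starts <- seq.int(0L, L - seg_len, by = step)
      last <- L - seg_len
      if (last %% step != 0L) starts <- c(starts, last)
      lens <- rep(seg_len, length(starts))
    }
    data.frame(name = sprintf("%s:%d-%d", ct, starts, starts + lens),
               contig = ct, start = starts, length = lens,
               sequence = substring(seqs[[ct]], starts + 1L, starts + lens),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write pseudo-reads as FASTA
#' @param pseudo_reads output of [chop_assembly()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pseudoreads_fasta <- function(pseudo_reads, path) {
  s <- Biostrings::DNAStringSet(pseudo_reads$sequence)
  names(s) <- pseudo_reads$name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

# Minimal SAM parser: returns a data.frame of mapped records with the
# fields the genotyper needs. SAM is plain tab-separated text; only the
# eleven mandatory columns are read.
read_sam <- function(path_or_lines) {
  lines <- if (length(path_or_lines) == 1L && file.exists(path_or_lines))
    readLines(path_or_lines) else path_or_lines
  rec <- lines[!startsWith(lines, "@")]
  if (!length(rec))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), seq = character()))
  f <- strsplit(rec, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 11L
  if (any(bad)) stop(sprintf("malformed SAM: %d records with < 11 fields", sum(bad)))
  data.frame(qname = vapply(f, `[[`, "", 1L),
             flag = as.integer(vapply(f, `[[`, "", 2L)),
             rname = vapply(f, `[[`, "", 3L),
             pos = as.integer(vapply(f, `[[`, "", 4L)),
             cigar = vapply(f, `[[`, "", 6L),
             seq = vapply(f, `[[`, "", 10L),
             stringsAsFactors = FALSE)
}

# Walk a CIGAR string and return the read base aligned to each requested
# 1-based reference position (NA where the read has a deletion/skip or
# does not reach the position).
cigar_bases_at <- function(pos, cigar, seq, ref_positions) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  out <- rep(NA_character_, length(ref_positions))
  rpos <- pos          # next reference base consumed
  qpos <- 1L           # next query base consumed
  for (i in seq_along(op)) {
    len <- n[i]
    o <- op[i]
    if (o %in% c("M", "=", "X")) {
      hit <- ref_positions >= rpos & ref_positions < rpos + len
      if (any(hit)) {
        off <- ref_positions[hit] - rpos
        out[hit] <- substring(seq, qpos + off, qpos + off)
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (o %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (o %in% c("I", "S")) {
      qpos <- qpos + len
    }                   # H, P consume nothing
  }
  out
}

#' Genotype marker sites from pseudo-read alignments
#'
#' For every marker, collects the aligned base from each covering segment
#' and calls the majority base: mapped to allele 0 if it equals the
#' reference allele, 1 if it equals the alternative allele, `"other"` for
#' any third base. A site with no covering segment, or an exact tie
#' between bases, is called missing -- a conservative rule in keeping with
#' the strictly bi-allelic marker set.
#'
#' @param sam SAM file path or character vector of SAM lines
#' @param markers marker data.frame (`chrom`, `pos`, `ref`, `alt`)
#' @return data.frame per marker: `allele` (`"0"`, `"1"`, `"other"` or NA),
#'   `depth` (covering segments), `agreement` (fraction of covering
#'   segments voting the called base; NA when missing)
#' @export
genotype_from_alignments <- function(sam, markers) {
  aln <- read_sam(sam)
  aln <- aln[bitwAnd(aln$flag, 4L) == 0L & aln$rname != "*", , drop = FALSE]
  votes <- vector("list", nrow(markers))
  for (v in seq_along(votes)) votes[[v]] <- character(0)
  by_chrom <- split(seq_len(nrow(markers)), markers$chrom)
  for (r in seq_len(nrow(aln))) {
    idx <- by_chrom[[aln$rname[r]]]
    if (is.null(idx)) next
    b <- cigar_bases_at(aln$pos[r], aln$cigar[r], aln$seq[r],
                        markers$pos[idx])
    got <- which(!is.na(b))
    for (g in got) votes[[idx[g]]] <- c(votes[[idx[g]]], b[g])
  }
  call_one <- function(v, ref, alt) {
    if (!length(v)) return(c(NA_character_, "0", NA))
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2])
      return(c(NA_character_, as.character(length(v)), NA))
    base <- names(tab)[1]
    allele <- if (base == ref) "0" else if (base == alt) "1" else "other"
    c(allele, as.character(length(v)), as.character(tab[1] / length(v)))
  }
  res <- t(mapply(call_one, votes, markers$ref, markers$alt))
  data.frame(allele = res[, 1],
             depth = as.integer(res[, 2]),
             agreement = as.numeric(res[, 3]),
             stringsAsFactors = FALSE)
}

#' Add an assembly-derived haplotype to the genotype matrix
#'
#' Converts an allele-call track to a haploid sample: `"0"`/`"1"` become
#' allele codes, `"other"` and missing become `NA` (the marker set is
#' strictly bi-allelic, so third bases carry no dosage information).
#'
#' @param gm a `genotype_matrix`
#' @param calls output of [genotype_from_alignments()] over `gm`'s markers
#' @param sample_id name for the new haploid sample
#' @return the extended `genotype_matrix`
#' @export
add_assembly_haplotype <- function(gm, calls, sample_id) {
  stopifnot(nrow(calls) == ncol(gm$dosage))
  al <- ifelse(calls$allele %in% c("0", "1"),
               suppressWarnings(as.integer(calls$allele)), NA_integer_)
  add_haploid_sample(gm, al, sample_id)
}

#' Append the all-reference haplotype of the reference strain
#'
#' The strain whose genome is the alignment reference carries, by
#' definition, the reference allele at every marker; its haplotype (all
#' allele 0) is added to the matrix as a monokaryon sample so the
#' reference nucleus participates in population-structure analysis.
#'
#' @param gm a `genotype_matrix`
#' @param sample_id name for the reference haplotype sample
#' @return the extended `genotype_matrix`
#' @export
reference_haplotype <- function(gm, sample_id = "REF") {
  add_haploid_sample(gm, rep(0L, ncol(gm$dosage)), sample_id)
}
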