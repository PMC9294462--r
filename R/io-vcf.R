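#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Monokaryon samples are written with haploid genotype calls (`0`, `1`,
#' `.`) by default; `haploid_style = "diploid"` emits the
#' homozygous-diploid dialect (`0/0`, `1/1`, `./.`) that read-based joint
#' genotypers produce for haploid samples. Dikaryons are always written as
#' unphased diploid genotypes.
#'
#' @param gm a `genotype_matrix`
#' @param path output file path
#' @param haploid_style `"haploid"` or `"diploid"` coding for monokaryons
#' @param contig_lengths optional named integer vector for `##contig`
#'   header lines; inferred as the max marker position per contig if absent
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path, haploid_style = c("haploid", "diploid"),
                      contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  haploid_style <- match.arg(haploid_style)
  m <- gm$markers
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(m$pos, m$chrom, max)
    contig_lengths <- contig_lengths[unique(m$chrom)]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=karyophase",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(contig_lengths), as.integer(contig_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_chr <- function(d, mono) {
    if (mono) {
      out <- ifelse(is.na(d), ".",
             ifelse(d == MONO_HET, "0/1", as.character(d)))
      if (haploid_style == "diploid")
        out <- ifelse(out %in% c("0", "1"), paste(out, out, sep = "/"), out)
      if (haploid_style == "diploid")
        out[out == "."] <- "./."
      out
    } else {
      ifelse(is.na(d), "./.",
             c("0/0", "0/1", "1/1")[d + 1L])
    }
  }
  cols <- lapply(seq_along(gm$samples), function(i)
    gt_chr(gm$dosage[i, ], gm$role[[i]] == "monokaryon"))
  body <- paste(m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  for (col in cols) body <- paste(body, col, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a joint-genotyped VCF into a genotype matrix
#'
#' Parsing is delegated to \pkg{vcfR}; genotype strings are then mapped to
#' dosages according to the karyotype role of each sample. Haploid calls
#' (`0`/`1`) and the homozygous-diploid dialect (`0/0`/`1/1`) both map to
#' allele codes for monokaryons; a genuinely heterozygous call in a
#' monokaryon is retained as an internal flag that triggers filter rule 5.
#' Multi-allelic SNP records are retained (rule 1 removes them later);
#' non-SNP records (indels, MNPs) are skipped and counted.
#'
#' @param path VCF file (plain text or gzipped)
#' @param metadata data.frame with at least `sample_id` and `role`
#'   (`monokaryon`/`dikaryon`) columns, e.g. from [read_sample_metadata()].
#'   Every metadata sample must be present in the VCF; VCF samples absent
#'   from the metadata are dropped.
#' @return a `genotype_matrix`; the number of skipped non-SNP records is
#'   attached as attribute `n_skipped_non_snp`.
#' @export
read_vcf <- function(path, metadata) {
  stopifnot(all(c("sample_id", "role") %in% names(metadata)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alts <- strsplit(ifelse(is.na(fix$ALT), ".", fix$ALT), ",", fixed = TRUE)
  is_snp <- nchar(fix$REF) == 1L &
    vapply(alts, function(a) all(nchar(a) == 1L & a != "*"), logical(1))
  n_skip <- sum(!is_snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  missing_samples <- setdiff(metadata$sample_id, colnames(gt))
  if (length(missing_samples))
    stop("metadata samples absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt <- gt[is_snp, metadata$sample_id, drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  parse_gt <- function(g, mono) {
    # split on / or |, count non-reference alleles
    g[g %in% c(".", "./.", ".|.", NA)] <- NA
    al <- strsplit(g, "[/|]")
    vapply(seq_along(al), function(i) {
      a <- al[[i]]
      if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a)) return(NA_integer_)
      nonref <- sum(a > 0L)
      if (mono) {
        if (length(a) == 1L) return(min(nonref, 1L))
        if (length(unique(a)) == 1L) return(min(nonref %/% length(a), 1L))
        return(MONO_HET)          # het call in a haploid sample: flagged
      }
      if (length(a) == 1L) return(min(nonref, 1L) * 2L)  # haploid-coded dikaryon: treat as hom
      min(nonref, 2L)
    }, integer(1))
  }
  mono <- metadata$role == "monokaryon"
  dosage <- vapply(seq_len(ncol(gt)),
                   function(j) parse_gt(gt[, j], mono[j]),
                   integer(nrow(gt)))
  if (nrow(gt) == 1L) dosage <- matrix(dosage, nrow = 1L)
  dosage <- t(dosage)
  rownames(dosage) <- metadata$sample_id
  markers <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  out <- genotype_matrix(dosage, markers, metadata$role)
  attr(out, "n_skipped_non_snp") <- n_skip
  out
}

#' Write / read the sample metadata table
#'
#' Tab-separated with columns `sample_id`, `role` (monokaryon | dikaryon),
#' `type` (wild | cultivated | reference), and `dikaryon_link` (for a
#' monokaryon, the id of the dikaryon it was isolated from; for a dikaryon,
#' a comma-separated list of its known constituent monokaryons; `.` when
#' unknown).
#'
#' @param meta data.frame with the four columns above
#' @param path file path
#' @return `path` (write) or the metadata data.frame (read)
#' @export
write_sample_metadata <- function(meta, path) {
  stopifnot(all(c("sample_id", "role", "type", "dikaryon_link") %in% names(meta)))
  m <- meta
  m$dikaryon_link[is.na(m$dikaryon_link) | m$dikaryon_link == ""] <- "."
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "")
  m$dikaryon_link[m$dikaryon_link == "."] <- NA_character_
  m
}
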