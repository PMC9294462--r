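#' Per-marker statistics used by the polymorphic-marker filter
#'
#' Allele counting respects true ploidy: a monokaryon contributes one
#' allele observation per call and a dikaryon two (`convention =
#' "ploidy"`). `convention = "plink"` instead counts every sample as
#' diploid (monokaryon allele a as a/a), reproducing what PLINK computes on
#' the homozygous-diploid VCF dialect. Genotype-class counts treat a
#' monokaryon allele a as the corresponding homozygous class; flagged
#' heterozygous monokaryon calls count in the het class and contribute no
#' alleles to the MAF.
#'
#' @param gm a `genotype_matrix`
#' @param convention `"ploidy"` (default) or `"plink"` allele weighting
#' @return data.frame, one row per marker: `maf`, `missing_rate`,
#'   `n_hom_ref`, `n_hom_alt`, `n_het`, `any_monokaryon_het`. `maf` is `NA`
#'   for all-missing markers.
#' @export
marker_stats <- function(gm, convention = c("ploidy", "plink")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  convention <- match.arg(convention)
  d <- gm$dosage
  if (nrow(d) == 0L || ncol(d) == 0L) stop("empty genotype matrix")
  mono <- gm$role == "monokaryon"
  dm <- d[mono, , drop = FALSE]
  dd <- d[!mono, , drop = FALSE]
  het_flag <- dm == MONO_HET
  mono_valid <- !is.na(dm) & !het_flag
  w_mono <- if (convention == "ploidy") 1 else 2

  alt_count <- colSums(dm * mono_valid * w_mono, na.rm = TRUE) +
    colSums(dd, na.rm = TRUE)
  tot_count <- colSums(mono_valid) * w_mono + 2 * colSums(!is.na(dd))
  p_alt <- ifelse(tot_count > 0, alt_count / tot_count, NA_real_)

  n_hom_ref <- colSums(dm == 0L, na.rm = TRUE) + colSums(dd == 0L, na.rm = TRUE)
  n_hom_alt <- colSums(dm == 1L, na.rm = TRUE) + colSums(dd == 2L, na.rm = TRUE)
  n_het <- colSums(het_flag, na.rm = TRUE) + colSums(dd == 1L, na.rm = TRUE)
  data.frame(
    maf = pmin(p_alt, 1 - p_alt),
    missing_rate = colMeans(is.na(d)),
    n_hom_ref = n_hom_ref,
    n_hom_alt = n_hom_alt,
    n_het = n_het,
    any_monokaryon_het = colSums(het_flag, na.rm = TRUE) > 0L
  )
}

#' Filter markers to an intrapopulation-polymorphic bi-allelic SNP set
#'
#' Retains exactly the markers passing all five rules:
#' \enumerate{
#'   \item bi-allelic SNP (exactly one single-base alternative allele);
#'   \item minor allele frequency strictly greater than `maf_min`;
#'   \item at least one sample homozygous reference AND at least one
#'     homozygous alternative (a monokaryon allele counts as the
#'     homozygous class; missing calls never count);
#'   \item missing rate strictly below `max_missing`;
#'   \item no heterozygous call in any monokaryon sample.
#' }
#' Removal is attributed to the first failing rule in the order 1 to 5;
#' retention itself is order-independent (the rules are a conjunction).
#'
#' @param gm a `genotype_matrix`
#' @param maf_min MAF threshold, exclusive (default 0.05)
#' @param max_missing missing-rate threshold, exclusive (default 0.2)
#' @param convention allele-counting convention, see [marker_stats()]
#' @return list with `gm` (the filtered `genotype_matrix`) and `report`
#'   (class `filter_report`: per-rule removal counts and totals)
#' @export
filter_markers <- function(gm, maf_min = 0.05, max_missing = 0.2,
                           convention = "ploidy") {
  stopifnot(inherits(gm, "genotype_matrix"))
  st <- marker_stats(gm, convention = convention)
  pass <- cbind(
    biallelic_snp = is_biallelic_snp(gm$markers),
    maf           = !is.na(st$maf) & st$maf > maf_min,
    both_homs     = st$n_hom_ref >= 1L & st$n_hom_alt >= 1L,
    missing_rate  = st$missing_rate < max_missing,
    mono_het      = !st$any_monokaryon_het
  )
  keep <- rowSums(pass) == 5L
  first_fail <- apply(!pass, 1L, function(x) if (any(x)) which(x)[1L] else NA_integer_)
  removed_by <- tabulate(first_fail, nbins = 5L)
  names(removed_by) <- colnames(pass)
  report <- structure(list(
    n_input = ncol(gm$dosage),
    n_retained = sum(keep),
    removed_by_rule = as.list(removed_by),
    maf_min = maf_min,
    max_missing = max_missing,
    convention = convention
  ), class = "filter_report")
  list(gm = subset_gm(gm, markers = keep), report = report)
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat(sprintf("marker filter: %d in, %d retained (%.1f%%)\n",
              x$n_input, x$n_retained, 100 * x$n_retained / max(x$n_input, 1)))
  lab <- c("rule 1 (bi-allelic SNP)", "rule 2 (MAF)",
           "rule 3 (both homozygotes)", "rule 4 (missing rate)",
           "rule 5 (monokaryon het)")
  for (i in seq_along(lab))
    cat(sprintf("  removed by %s: %d\n", lab[i], x$removed_by_rule[[i]]))
  invisible(x)
}

#' Export a filter report as JSON
#' @param report a `filter_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-sample quality control: missing and heterozygous proportions
#'
#' Computed over the current (normally post-filter) marker set. The
#' heterozygosity level classifies dikaryons by how diverged their two
#' constituent haplotypes are: after filtering, monokaryons are exactly 0
#' by construction, highly homozygous dikaryons (two near-identical nuclei)
#' sit low, and wide crosses sit high.
#'
#' @param gm a `genotype_matrix`
#' @param het_breaks boundaries between low/medium and medium/high levels
#'   (proportions; defaults 0.05 and 0.30)
#' @return data.frame: `sample_id`, `role`, `missing_proportion`,
#'   `het_proportion`, `het_level` (low/medium/high)
#' @export
sample_qc <- function(gm, het_breaks = c(0.05, 0.30)) {
  stopifnot(inherits(gm, "genotype_matrix"), length(het_breaks) == 2L)
  d <- gm$dosage
  miss <- rowMeans(is.na(d))
  is_het <- (d == 1L & matrix(gm$role == "dikaryon", nrow(d), ncol(d))) |
    d == MONO_HET
  het <- rowSums(is_het, na.rm = TRUE) / pmax(rowSums(!is.na(d)), 1L)
  lvl <- cut(het, breaks = c(-Inf, het_breaks, Inf),
             labels = c("low", "medium", "high"))
  data.frame(sample_id = gm$samples, role = unname(gm$role),
             missing_proportion = unname(miss),
             het_proportion = unname(het),
             het_level = as.character(lvl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker density in genomic windows
#'
#' Tiles each chromosome with fixed-size windows (0-based half-open
#' intervals; the last window of a chromosome is truncated at its length)
#' and reports markers per kb per window, plus the genome-wide density as
#' an attribute. A sliding step smaller than the window size may be given
#' for overlapping windows.
#'
#' @param gm a `genotype_matrix`
#' @param chrom_lengths named integer vector of chromosome lengths (bp)
#' @param window window size in bp (default 500 kb)
#' @param step step between window starts (default = `window`, i.e. tiling)
#' @return data.frame `chrom`, `start`, `end`, `n_markers`, `density`
#'   (markers per kb); attribute `global_density` = total markers / total
#'   genome length in kb
#' @export
density_track <- function(gm, chrom_lengths, window = 5e5, step = window) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(names(chrom_lengths)),
            window >= 1, step >= 1)
  m <- gm$markers
  unknown <- setdiff(unique(m$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("markers on contigs without a stated length: ",
         paste(unknown, collapse = ", "))
  bad <- m$pos > chrom_lengths[m$chrom]
  if (any(bad))
    stop(sprintf("%d markers lie beyond the stated chromosome length", sum(bad)))
  rows <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, max(L - 1L, 0L), by = step)
    ends <- pmin(starts + window, L)
    pos0 <- m$pos[m$chrom == ch] - 1L       # 0-based marker coordinates
    n <- vapply(seq_along(starts), function(i)
      sum(pos0 >= starts[i] & pos0 < ends[i]), integer(1))
    data.frame(chrom = ch, start = starts, end = ends, n_markers = n,
               density = n / ((ends - starts) / 1000))
  })
  out <- do.call(rbind, rows)
  attr(out, "global_density") <- nrow(m) / (sum(chrom_lengths) / 1000)
  out
}

#' Write a density track as BED-graph
#' @param track output of [density_track()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "density")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minor-allele-frequency spectrum
#'
#' Normalised histogram of per-marker MAF on (0, 0.5], the standard
#' diagnostic for how much of the marker set is near-rare versus balanced
#' polymorphism.
#'
#' @param gm a `genotype_matrix`
#' @param bins number of equal-width bins over (0, 0.5]
#' @param convention allele-counting convention, see [marker_stats()]
#' @return data.frame `lower`, `upper`, `proportion` (sums to 1 over
#'   markers with defined MAF)
#' @export
maf_spectrum <- function(gm, bins = 25L, convention = "ploidy") {
  st <- marker_stats(gm, convention = convention)
  maf <- st$maf[!is.na(st$maf)]
  br <- seq(0, 0.5, length.out = bins + 1L)
  h <- graphics::hist(maf, breaks = br, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  data.frame(lower = br[-length(br)], upper = br[-1L],
             proportion = h$counts / max(length(maf), 1L))
}
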