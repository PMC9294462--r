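#' @useDynLib karyophase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Sentinel for a heterozygous call observed in a monokaryon sample. Such a
# call is biologically impossible for a haploid nucleus and marks the site
# for removal by filter rule 5; it is never a valid allele code.
MONO_HET <- -1L

#' Construct a genotype matrix for a mixed monokaryon/dikaryon panel
#'
#' The central container of the pipeline: an ordered marker table plus a
#' samples x markers dosage matrix. Dikaryons (two haploid nuclei per
#' mycelium) carry diploid-style dosages in \{0, 1, 2\}; monokaryons carry
#' haploid allele codes in \{0, 1\}. `NA` is a missing call. A heterozygous
#' call recorded for a monokaryon sample -- impossible for a haploid, but
#' present in raw joint-genotyped VCFs as noise -- is kept as an internal
#' flag so that the marker filter can remove the site.
#'
#' @param dosage integer matrix, samples in rows (rownames = sample ids),
#'   markers in columns. Monokaryon rows in \{0, 1, NA\}, dikaryon rows in
#'   \{0, 1, 2, NA\}.
#' @param markers data.frame with columns `chrom`, `pos` (1-based), `ref`
#'   (single base) and `alt` (comma-separated alternative alleles; exactly
#'   one for a bi-allelic SNP).
#' @param role character vector, one of `"monokaryon"` or `"dikaryon"` per
#'   sample, in row order of `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, markers, role) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "ref", "alt") %in% names(markers)),
            ncol(dosage) == nrow(markers),
            length(role) == nrow(dosage))
  if (is.null(rownames(dosage)))
    stop("dosage must carry sample ids as rownames")
  role <- match.arg(role, c("monokaryon", "dikaryon"), several.ok = TRUE)
  if (length(role) != nrow(dosage))
    role <- rep(role, length.out = nrow(dosage))
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample ids in dosage rownames")
  mono <- role == "monokaryon"
  bad_mono <- dosage[mono, , drop = FALSE]
  if (any(bad_mono > 1L, na.rm = TRUE))
    stop("monokaryon samples cannot carry dosage > 1 (use MONO_HET flag for raw het calls)")
  if (any(dosage[!mono, , drop = FALSE] < 0L, na.rm = TRUE))
    stop("dikaryon dosages must be in {0, 1, 2, NA}")
  if (any(dosage > 2L, na.rm = TRUE))
    stop("dosages must be in {0, 1, 2, NA}")
  markers$pos <- as.integer(markers$pos)
  if (any(markers$pos < 1L)) stop("marker positions are 1-based and must be >= 1")
  structure(list(dosage = dosage,
                 markers = markers,
                 samples = rownames(dosage),
                 role = stats::setNames(role, rownames(dosage))),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  n_mono <- sum(x$role == "monokaryon")
  cat(sprintf("genotype_matrix: %d samples (%d monokaryon, %d dikaryon) x %d markers\n",
              nrow(x$dosage), n_mono, nrow(x$dosage) - n_mono, ncol(x$dosage)))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype matrix by markers and/or samples
#'
#' @param x a `genotype_matrix`
#' @param markers logical/integer index over markers (columns)
#' @param samples logical/integer/character index over samples (rows)
#' @return a new `genotype_matrix`
#' @export
subset_gm <- function(x, markers = NULL, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage; m <- x$markers; r <- x$role
  if (!is.null(markers)) {
    d <- d[, markers, drop = FALSE]
    m <- m[markers, , drop = FALSE]
    rownames(m) <- NULL
  }
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    r <- r[rownames(d)]
  }
  genotype_matrix(d, m, unname(r))
}

#' Append a haploid sample to a genotype matrix
#'
#' Used to add inferred monokaryon haplotypes, assembly-derived haplotypes
#' and the all-reference haplotype of the reference strain as first-class
#' samples alongside the sequenced panel.
#'
#' @param gm a `genotype_matrix`
#' @param alleles integer vector over the marker set, values in \{0, 1, NA\}
#' @param sample_id new sample name; must not collide with an existing one
#' @return the extended `genotype_matrix`
#' @export
add_haploid_sample <- function(gm, alleles, sample_id) {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(alleles) == ncol(gm$dosage))
  if (sample_id %in% gm$samples)
    stop(sprintf("sample id '%s' already present", sample_id))
  if (any(alleles > 1L, na.rm = TRUE))
    stop("haploid alleles must be 0, 1 or NA")
  d <- rbind(gm$dosage, as.integer(alleles))
  rownames(d) <- c(gm$samples, sample_id)
  genotype_matrix(d, gm$markers, c(unname(gm$role), "monokaryon"))
}

is_biallelic_snp <- function(markers) {
  one_alt <- !grepl(",", markers$alt, fixed = TRUE)
  one_alt & nchar(markers$ref) == 1L & nchar(markers$alt) == 1L &
    markers$alt != markers$ref & markers$alt != "."
}

# Run code with a private, seeded RNG stream; the caller's RNG state is
# untouched so simulation seeds never leak into user sessions.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
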