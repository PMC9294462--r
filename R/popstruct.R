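#' Encode a mixed monokaryon/dikaryon panel on a common dosage scale
#'
#' Monokaryon allele a maps to 2a and dikaryon dosage stays as-is, the
#' unique 0..2 joint encoding under which an error-free union dikaryon's
#' row is exactly the arithmetic mean of its two constituent monokaryons'
#' rows -- the property that makes dikaryons sit at the midpoint of their
#' parents in PCA space. This also matches how PLINK sees haploids coded
#' as homozygous diploids.
#'
#' @param gm a `genotype_matrix`
#' @return numeric samples x markers matrix with entries in \{0, 1, 2,
#'   NA\}; flagged heterozygous monokaryon calls (pre-filter noise) map to
#'   NA
#' @export
encode_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  x <- gm$dosage
  x[x == MONO_HET] <- NA_integer_
  mono <- gm$role == "monokaryon"
  x <- x * 1.0
  x[mono, ] <- x[mono, , drop = FALSE] * 2
  x
}

#' Identity-by-state similarity matrix
#'
#' `ibs(i, j)` is the mean over pairwise non-missing markers of
#' `1 - |x_i - x_j| / 2` on the joint 0/1/2 encoding: 1 for identical
#' genotypes, 0.5 for hom vs het, 0 for opposite homozygotes. Pairs with
#' no shared non-missing marker get `NA`.
#'
#' @param gm a `genotype_matrix` (or an already-encoded numeric matrix)
#' @return symmetric samples x samples matrix with unit diagonal
#' @export
ibs_matrix <- function(gm) {
  x <- if (inherits(gm, "genotype_matrix")) encode_genotypes(gm) else gm
  n <- nrow(x)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  # sum_j |xi - xj| over shared markers, via the identity on {0,1,2}:
  # |a-b| = a + b - 2*min(a,b); computed per pair directly (n is small)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      sh <- obs[i, ] & obs[j, ]
      m <- sum(sh)
      out[i, j] <- out[j, i] <-
        if (m == 0L) NA_real_ else 1 - sum(abs(x[i, sh] - x[j, sh])) / (2 * m)
    }
  }
  out
}

#' Write an IBS matrix as square TSV
#' @param ibs matrix from [ibs_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ibs <- function(ibs, path) {
  utils::write.table(ibs, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Principal component analysis of the genotype matrix
#'
#' Standard genotype PCA on the joint encoding: each marker is centred by
#' its mean dosage and scaled by the binomial standard deviation
#' `sqrt(p(1-p))` with `p` the mean allele frequency; zero-variance
#' markers are dropped; missing entries are mean-imputed (zero after
#' centring) before projection. Scores are the projections of the
#' standardised rows onto the eigenvectors of their sample covariance.
#' Because standardisation is an affine map applied marker-wise and
#' projection is linear, a dikaryon row that equals the mean of its two
#' parent rows has scores equal to the mean of their scores on every
#' component, exactly. Signs are fixed per component (largest-magnitude
#' loading positive) for reproducibility.
#'
#' @param gm a `genotype_matrix` or encoded numeric matrix
#' @param n_components number of leading components to return (default 20)
#' @return object of class `kp_pca`: `scores` (samples x C), `eigenvalues`
#'   (length C), `loadings` (markers x C), `explained` (fractions of total
#'   variance), `kept_markers` (indices of non-constant markers used)
#' @export
pca_genotypes <- function(gm, n_components = 20L) {
  x <- if (inherits(gm, "genotype_matrix")) encode_genotypes(gm) else gm
  n <- nrow(x)
  stopifnot(n >= 2L)
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  n_components <- min(as.integer(n_components), n - 1L, length(keep))
  xs <- sweep(x, 2L, 2 * p, "-")
  xs <- sweep(xs, 2L, sqrt(p * (1 - p)), "/")
  xs[is.na(xs)] <- 0
  sv <- svd(xs, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  loadings <- sv$v
  # sign convention: largest-|loading| entry positive per component
  for (c in seq_len(n_components)) {
    s <- sign(loadings[which.max(abs(loadings[, c])), c])
    if (s < 0) { loadings[, c] <- -loadings[, c]; scores[, c] <- -scores[, c] }
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores,
                 eigenvalues = d^2 / (n - 1),
                 loadings = loadings,
                 explained = (d^2 / sum(sv$d^2))[seq_len(n_components)],
                 kept_markers = keep),
            class = "kp_pca")
}

#' @exportS3Method base::print
print.kp_pca <- function(x, ...) {
  cat(sprintf("kp_pca: %d samples x %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1],
              100 * x$explained[min(2, length(x$explained))]))
  invisible(x)
}

#' Write PCA scores and eigenvalues in eigenvec/eigenval convention
#' @param pca a `kp_pca`
#' @param prefix output path prefix; writes `<prefix>.eigenvec` (TSV with
#'   sample ids) and `<prefix>.eigenval`
#' @return the two paths, invisibly
#' @export
write_pca <- function(pca, prefix) {
  ev <- paste0(prefix, ".eigenvec"); el <- paste0(prefix, ".eigenval")
  df <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                   check.names = FALSE)
  utils::write.table(df, ev, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(pca$eigenvalues, digits = 10), el)
  invisible(c(ev, el))
}
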