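#' Midpoint residual of a candidate parent pair in PC space
#'
#' Under the joint encoding, an error-free union dikaryon's PCA score is
#' exactly the mean of its two constituent monokaryons' scores on every
#' component, so the Euclidean distance between the dikaryon's score and
#' the candidate pair's mean score measures how well the pair explains
#' the dikaryon geometrically.
#'
#' @param dik,a,b sample ids (dikaryon and two candidate parents; `a` may
#'   equal `b` for a selfed dikaryon)
#' @param pca a `kp_pca` whose scores include all three samples
#' @param n_components leading components used (default: all computed)
#' @return non-negative scalar distance
#' @export
midpoint_residual <- function(dik, a, b, pca, n_components = NULL) {
  sc <- pca$scores
  for (id in unique(c(dik, a, b)))
    if (!id %in% rownames(sc)) stop(sprintf("sample '%s' has no PCA score", id))
  C <- if (is.null(n_components)) ncol(sc) else min(n_components, ncol(sc))
  v <- sc[dik, 1:C] - (sc[a, 1:C] + sc[b, 1:C]) / 2
  sqrt(sum(v^2))
}

#' Genotype compatibility of a candidate parent pair
#'
#' Fraction of markers, non-missing in the dikaryon and both candidates,
#' where the candidates' allele sum reproduces the dikaryon dosage. The
#' true pair is fully compatible in the error-free union model.
#'
#' @param dik_g dikaryon dosage vector
#' @param a_g,b_g candidate haplotype allele vectors
#' @return fraction in \[0, 1\] (NA when no marker is jointly observed)
#' @export
pair_compatibility <- function(dik_g, a_g, b_g) {
  ok <- !is.na(dik_g) & !is.na(a_g) & !is.na(b_g)
  if (!any(ok)) return(NA_real_)
  mean((a_g[ok] + b_g[ok]) == dik_g[ok])
}

#' Rank candidate parent pairs for a dikaryon
#'
#' Evaluates every unordered pair from the panel (self-pairs included, to
#' cover selfed dikaryons), scoring each by the PCA midpoint residual and
#' by exact genotype compatibility. Pairs are ranked by residual
#' ascending, ties broken by compatibility descending: geometry alone
#' cannot separate mirror-symmetric candidate pairs, and compatibility
#' alone saturates among close relatives, so the two are combined
#' lexicographically rather than through an arbitrary weight.
#'
#' @param dik dikaryon sample id
#' @param panel character vector of candidate haploid sample ids (>= 2)
#' @param gm the `genotype_matrix` holding all samples
#' @param pca a `kp_pca` over (at least) the dikaryon and the panel
#' @param top_n number of top-ranked pairs to return (default 5)
#' @param n_components components for the residual (default: all)
#' @return data.frame of `pedigree_edge` rows: `dikaryon`, `parent_a`,
#'   `parent_b`, `midpoint_residual`, `compatibility`, `rank`
#' @export
infer_parents <- function(dik, panel, gm, pca, top_n = 5L,
                          n_components = NULL) {
  if (length(panel) < 2L) stop("panel must contain at least two haplotypes")
  stopifnot(dik %in% gm$samples, all(panel %in% gm$samples))
  pairs <- cbind(rep(seq_along(panel), times = seq_along(panel)),
                 unlist(lapply(seq_along(panel), seq_len)))
  # (i, j) with j <= i: all unordered pairs incl. self-pairs
  dik_g <- gm$dosage[dik, ]
  res <- apply(pairs, 1L, function(pr) {
    a <- panel[pr[1]]; b <- panel[pr[2]]
    c(midpoint_residual(dik, a, b, pca, n_components),
      pair_compatibility(dik_g, gm$dosage[a, ], gm$dosage[b, ]))
  })
  out <- data.frame(dikaryon = dik,
                    parent_a = panel[pairs[, 2]],
                    parent_b = panel[pairs[, 1]],
                    midpoint_residual = res[1, ],
                    compatibility = res[2, ],
                    stringsAsFactors = FALSE)
  ord <- order(out$midpoint_residual, -out$compatibility)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Identify a dikaryon's un-sequenced parent from a haplotype panel
#'
#' Phases the dikaryon with its known sequenced parent, then ranks the
#' panel by identity-by-state similarity to the inferred second
#' haplotype. When the known parent itself conflicts with the dikaryon
#' beyond `threshold`, a warning flags the pairing as doubtful.
#'
#' @param dik dikaryon sample id
#' @param known_parent sequenced parent sample id
#' @param panel candidate sample ids to search
#' @param gm the `genotype_matrix`
#' @param threshold conflict-rate plausibility bound (default 0.01)
#' @return list: `matches` (data.frame `sample_id`, `ibs`, `rank`),
#'   `phase` (the `kp_phase` result), `plausible_parent` (logical)
#' @export
match_inferred_parent <- function(dik, known_parent, panel, gm,
                                  threshold = 0.01) {
  stopifnot(all(c(dik, known_parent, panel) %in% gm$samples))
  ph <- phase_dikaryon(gm$dosage[dik, ], gm$dosage[known_parent, ])
  if (ph$conflict_rate > threshold)
    warning(sprintf(
      "conflict rate %.3g exceeds %.3g: '%s' is unlikely a true parent of '%s'",
      ph$conflict_rate, threshold, known_parent, dik))
  inf2 <- 2 * ph$inferred                  # joint encoding for a haploid
  ibs_to <- vapply(panel, function(s) {
    x <- 2 * gm$dosage[s, ]
    sh <- !is.na(inf2) & !is.na(x)
    if (!any(sh)) return(NA_real_)
    1 - sum(abs(inf2[sh] - x[sh])) / (2 * sum(sh))
  }, numeric(1))
  ord <- order(-ibs_to)
  matches <- data.frame(sample_id = panel[ord], ibs = ibs_to[ord],
                        rank = seq_along(panel), row.names = NULL,
                        stringsAsFactors = FALSE)
  list(matches = matches, phase = ph,
       plausible_parent = ph$conflict_rate <= threshold)
}

#' Export pedigree edges as a DOT graph
#'
#' One arrow per inferred parent, in the style of a breeding-history
#' module diagram: monokaryon nodes point at the dikaryon they form.
#'
#' @param edges data.frame of pedigree edges (rank-1 rows of
#'   [infer_parents()] results)
#' @param path output `.dot` path
#' @return `path`, invisibly
#' @export
write_pedigree_dot <- function(edges, path) {
  lines <- c("digraph pedigree {", "  rankdir=BT;")
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines,
               sprintf('  "%s" -> "%s";', edges$parent_a[i], edges$dikaryon[i]),
               sprintf('  "%s" -> "%s";', edges$parent_b[i], edges$dikaryon[i]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
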