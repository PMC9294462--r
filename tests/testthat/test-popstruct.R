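test_that("joint encoding makes a union dikaryon the mean of its parents", {
  sim <- bench_sim(seed = 23, n_markers = 500L)
  x <- encode_genotypes(sim$gm)
  for (d in names(sim$truth$dikaryon_parents)[1:5]) {
    pr <- sim$truth$dikaryon_parents[[d]]
    expect_equal(x[d, ], (x[pr[1], ] + x[pr[2], ]) / 2)
  }
})

test_that("IBS matches hand-computed values, is symmetric with unit diagonal", {
  d <- rbind(s1 = c(0L, 1L, 2L, 1L),
             s2 = c(0L, 0L, 2L, 2L),
             s3 = c(2L, 1L, 0L, NA))
  mk <- data.frame(chrom = "c", pos = 1:4 * 10L, ref = "A", alt = "G")
  gm <- genotype_matrix(d, mk, rep("dikaryon", 3))
  ibs <- ibs_matrix(gm)
  expect_equal(unname(diag(ibs)), rep(1, 3))
  expect_equal(ibs, t(ibs))
  expect_equal(ibs["s1", "s2"], 0.75)       # diffs 0,1,0,1 over 4 markers
  expect_equal(ibs["s1", "s3"], 1 - 4 / 6)  # diffs 2,0,2 over 3 shared
  expect_equal(ibs["s2", "s3"], 1 - 5 / 6)
  # opposite homozygotes across the board -> similarity 0
  d2 <- rbind(a = c(0L, 0L), b = c(2L, 2L))
  gm2 <- genotype_matrix(d2, mk[1:2, ], rep("dikaryon", 2))
  expect_equal(ibs_matrix(gm2)["a", "b"], 0)
})

test_that("PCA scores match a dense eigendecomposition oracle", {
  set.seed(61)
  x <- matrix(sample(0:2, 20 * 200, TRUE), 20, 200,
              dimnames = list(sprintf("s%02d", 1:20), NULL))
  pca <- pca_genotypes(x, n_components = 10L)
  # independent oracle: explicit standardisation + eigen of the Gram matrix
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  xs <- sweep(x[, keep], 2, 2 * p[keep])
  xs <- sweep(xs, 2, sqrt(p[keep] * (1 - p[keep])), "/")
  eg <- eigen(tcrossprod(xs), symmetric = TRUE)
  oracle <- eg$vectors[, 1:10] %*% diag(sqrt(pmax(eg$values[1:10], 0)))
  for (c in 1:10) {
    s <- sign(sum(oracle[, c] * pca$scores[, c]))
    expect_lt(max(abs(pca$scores[, c] - s * oracle[, c])), 1e-8)
  }
  expect_equal(pca$eigenvalues, eg$values[1:10] / (20 - 1), tolerance = 1e-10)
  expect_true(all(diff(pca$eigenvalues) <= 1e-9))
})

test_that("two point clusters separate on PC1 with zero within-cluster spread", {
  d <- rbind(matrix(0L, 4, 60), matrix(2L, 4, 60))
  d[, 31:60] <- 2L - d[, 31:60]
  rownames(d) <- sprintf("s%d", 1:8)
  mk <- data.frame(chrom = "c", pos = 1:60 * 10L, ref = "A", alt = "G")
  gm <- genotype_matrix(d, mk, rep("dikaryon", 8))
  pca <- pca_genotypes(gm, n_components = 3L)
  expect_gt(abs(mean(pca$scores[1:4, 1]) - mean(pca$scores[5:8, 1])), 1)
  expect_lt(max(abs(pca$scores[1:4, 1] - mean(pca$scores[1:4, 1]))), 1e-8)
  expect_lt(max(abs(pca$scores[5:8, 1] - mean(pca$scores[5:8, 1]))), 1e-8)
})

test_that("every union dikaryon scores at the midpoint of its parents", {
  sim <- bench_sim(seed = 29)
  gm <- filter_markers(sim$gm)$gm
  pca <- pca_genotypes(gm, n_components = 20L)
  for (d in names(sim$truth$dikaryon_parents)) {
    pr <- sim$truth$dikaryon_parents[[d]]
    delta <- pca$scores[d, ] -
      (pca$scores[pr[1], ] + pca$scores[pr[2], ]) / 2
    expect_lt(max(abs(delta)), 1e-8)
  }
})

test_that("EM log-likelihood is non-decreasing and K = 1 hits the closed form", {
  sim <- bench_sim(seed = 37, n_markers = 800L, n_monokaryons_per_pop = 10L,
                   n_admixed_monokaryons = 3L, crosses = 5L,
                   missing_rate = 0.05)
  gm <- filter_markers(sim$gm)$gm
  for (K in c(1L, 2L, 4L)) {
    fit <- admixture_em(gm, K, seed = 3, n_starts = 2)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8), info = paste("K =", K))
    expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)),
                 tolerance = 1e-12)
    expect_true(all(fit$Q >= 0) && all(fit$F >= 0 & fit$F <= 1))
  }
  # K = 1 closed form: Q = 1, f_j = observed allele frequency,
  # loglik = binomial log-likelihood at the MLE
  fit1 <- admixture_em(gm, 1L, seed = 3, n_starts = 1)
  gn <- karyophase:::allele_counts(gm)
  f_mle <- colSums(gn$G) / colSums(gn$N)
  expect_equal(unname(fit1$F[1, ]), f_mle, tolerance = 1e-5)
  expect_true(all(fit1$Q == 1))
  fm <- pmin(pmax(f_mle, 1e-12), 1 - 1e-12)
  ll_mle <- sum(t(gn$G) * log(fm) + t(gn$N - gn$G) * log(1 - fm))
  expect_equal(fit1$loglik, ll_mle, tolerance = 1e-6)
})

test_that("ancestry recovery on the benchmark design beats 0.05 MAE", {
  sim <- bench_sim(seed = 43)
  gm <- filter_markers(sim$gm)$gm
  mono <- gm$samples[gm$role == "monokaryon"]
  fit <- admixture_em(gm, 3L, seed = 2, n_starts = 3)
  qm <- q_mae(fit$Q[mono, ], sim$truth$true_Q[mono, ])
  expect_lt(qm$mae, 0.05)
})

test_that("cross-validation guards degenerate masking and selects informatively", {
  sim <- bench_sim(seed = 47, n_markers = 600L, n_monokaryons_per_pop = 12L,
                   n_admixed_monokaryons = 0L, crosses = 0L)
  gm <- filter_markers(sim$gm)$gm
  # deterministic under seed
  e1 <- cv_error(gm, 2L, seed = 5)
  e2 <- cv_error(gm, 2L, seed = 5)
  expect_identical(e1, e2)
  # noiseless K = 1 population: cv error approximates binomial variance
  cfg1 <- sim_config(n_ancestral_pops = 1L, divergence_F = 1e-9,
                     n_monokaryons_per_pop = 40L, n_admixed_monokaryons = 0L,
                     n_markers = 800L, crosses = list(), seed = 53L)
  sim1 <- simulate_population(cfg1)
  gm1 <- filter_markers(sim1$gm)$gm
  st <- marker_stats(gm1)
  p <- st$maf  # frequencies folded; variance is polarity-invariant
  # within-population binomial variance up to O(1/n) estimation corrections
  expect_equal(cv_error(gm1, 1L, seed = 5),
               mean(p * (1 - p)), tolerance = 0.1)
  expect_error(cv_error(subset_gm(gm1, markers = 1:2), 1L, folds = 500L),
               "not enough")
})

test_that("choose_K reports the full table over the candidate range", {
  sim <- bench_sim(seed = 59, n_markers = 400L, n_monokaryons_per_pop = 8L,
                   n_admixed_monokaryons = 0L, crosses = 0L)
  gm <- filter_markers(sim$gm)$gm
  ks <- choose_K(gm, K_range = 2:4, seed = 1)
  expect_identical(nrow(ks$table), 3L)
  expect_identical(ks$table$K, 2:4)
  expect_true(ks$best_K %in% 2:4)
  expect_equal(min(ks$table$cv_error),
               ks$table$cv_error[ks$table$K == ks$best_K])
})

test_that("PLINK-parity ploidy mode treats monokaryons as diploid", {
  gm <- toy_gm()
  gn_h <- karyophase:::allele_counts(gm, "haploid")
  gn_p <- karyophase:::allele_counts(gm, "plink")
  mono <- gm$role == "monokaryon"
  expect_true(all(gn_h$N[mono, ][!is.na(gm$dosage[mono, ])] == 1))
  expect_true(all(gn_p$N[mono, ][!is.na(gm$dosage[mono, ])] == 2))
  expect_equal(gn_p$G[mono, ], gn_h$G[mono, ] * 2)
})
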