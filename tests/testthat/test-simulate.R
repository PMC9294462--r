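test_that("identical configuration produces byte-identical artifacts", {
  cfg <- sim_config(n_monokaryons_per_pop = 6L, n_admixed_monokaryons = 2L,
                    n_markers = 300L, crosses = 4L,
                    genotype_error_rate = 0.01, missing_rate = 0.05,
                    seed = 123L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_population(cfg), d1)
  p2 <- write_simulation(simulate_population(cfg), d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  # a different seed changes the VCF
  cfg2 <- sim_config(n_monokaryons_per_pop = 6L, n_admixed_monokaryons = 2L,
                     n_markers = 300L, crosses = 4L,
                     genotype_error_rate = 0.01, missing_rate = 0.05,
                     seed = 124L)
  d3 <- withr::local_tempdir()
  p3 <- write_simulation(simulate_population(cfg2), d3)
  expect_false(identical(readLines(p1[["vcf"]]), readLines(p3[["vcf"]])))
})

test_that("union law: error-free dikaryon dosage is the sum of its parents", {
  sim <- bench_sim(seed = 5, n_markers = 1000L)
  for (d in names(sim$truth$dikaryon_parents)) {
    pr <- sim$truth$dikaryon_parents[[d]]
    expect_identical(unname(sim$gm$dosage[d, ]),
                     unname(sim$truth$haplotypes[pr[1], ] +
                              sim$truth$haplotypes[pr[2], ]))
  }
})

test_that("a selfing cross yields an everywhere-homozygous dikaryon", {
  cfg <- sim_config(n_monokaryons_per_pop = 2L, n_admixed_monokaryons = 0L,
                    n_markers = 500L, crosses = list(c("M001", "M001")),
                    seed = 2L)
  sim <- simulate_population(cfg)
  qc <- sample_qc(sim$gm)
  expect_equal(qc$het_proportion[qc$sample_id == "D01"], 0)
})

test_that("no-drift limit: sample allele frequencies match the ancestral draw", {
  cfg <- sim_config(n_ancestral_pops = 1L, divergence_F = 1e-12,
                    n_monokaryons_per_pop = 400L, n_admixed_monokaryons = 0L,
                    n_markers = 400L, crosses = list(), seed = 9L)
  sim <- simulate_population(cfg)
  freq <- colMeans(sim$truth$haplotypes)
  p0 <- sim$truth$p0
  se <- sqrt(p0 * (1 - p0) / 400)
  # per-marker deviations behave like binomial noise: ~99.7% within 3 SE
  expect_gt(mean(abs(freq - p0) <= 3 * se), 0.98)
  # and the average absolute deviation matches the half-normal mean
  expect_equal(mean(abs(freq - p0)), mean(sqrt(2 / pi) * se), tolerance = 0.1)
})

test_that("per-population frequencies match binomial sampling error under drift", {
  cfg <- sim_config(n_ancestral_pops = 3L, divergence_F = 0.3,
                    n_monokaryons_per_pop = 40L, n_admixed_monokaryons = 0L,
                    n_markers = 5000L, crosses = list(), seed = 17L)
  sim <- simulate_population(cfg)
  for (k in 1:3) {
    rows <- which(rowSums(sim$truth$true_Q == 1) == 1 &
                    sim$truth$true_Q[, k] == 1)
    realized <- colMeans(sim$truth$haplotypes[rows, ])
    f <- sim$truth$ancestral_freqs[k, ]
    expected_mad <- mean(sqrt(2 / pi) * sqrt(f * (1 - f) / length(rows)))
    expect_equal(mean(abs(realized - f)), expected_mad, tolerance = 0.05)
  }
})

test_that("realized MAF distribution tracks the configured ancestral range", {
  cfg <- sim_config(n_ancestral_pops = 1L, divergence_F = 1e-12,
                    n_monokaryons_per_pop = 300L, n_admixed_monokaryons = 0L,
                    n_markers = 5000L, crosses = list(),
                    ancestral_maf_range = c(0.1, 0.4), seed = 21L)
  sim <- simulate_population(cfg)
  realized_maf <- pmin(colMeans(sim$truth$haplotypes),
                       1 - colMeans(sim$truth$haplotypes))
  target_maf <- pmin(sim$truth$p0, 1 - sim$truth$p0)
  ks <- suppressWarnings(stats::ks.test(realized_maf, target_maf))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("error and missingness injection hit their configured rates", {
  cfg <- sim_config(n_monokaryons_per_pop = 30L, n_admixed_monokaryons = 0L,
                    n_markers = 4000L, crosses = 5L,
                    genotype_error_rate = 0.02, missing_rate = 0.1, seed = 4L)
  sim <- simulate_population(cfg)
  expect_equal(mean(is.na(sim$gm$dosage)), 0.1, tolerance = 0.01)
  mono_rows <- sim$gm$samples[sim$gm$role == "monokaryon"]
  obs <- sim$gm$dosage[mono_rows, ]
  tru <- sim$truth$haplotypes[mono_rows, ]
  flipped <- mean(obs != tru, na.rm = TRUE)
  expect_equal(flipped, 0.02, tolerance = 0.005)
})

test_that("crosses referencing unknown haplotypes are rejected", {
  cfg <- sim_config(n_monokaryons_per_pop = 2L, n_admixed_monokaryons = 0L,
                    n_markers = 50L, crosses = list(c("M001", "M999")),
                    seed = 1L)
  expect_error(simulate_population(cfg), "unknown")
})

test_that("per-sample missingness inflation spreads samples in QC space", {
  infl <- c(M001 = 0.3)
  cfg <- sim_config(n_monokaryons_per_pop = 5L, n_admixed_monokaryons = 0L,
                    n_markers = 2000L, crosses = list(), missing_rate = 0.01,
                    sample_missing_inflation = infl, seed = 8L)
  sim <- simulate_population(cfg)
  qc <- sample_qc(sim$gm)
  m1 <- qc$missing_proportion[qc$sample_id == "M001"]
  rest <- qc$missing_proportion[qc$sample_id != "M001"]
  expect_gt(m1, 0.25)
  expect_true(all(rest < 0.05))
})

test_that("assembly simulation substitutes exactly the alternative alleles", {
  toy <- simulate_toy_genome(n_chrom = 1L, chrom_len = 6000L,
                             n_markers = 12L, seed = 3L)
  # all-reference haplotype: assembly identical to the reference
  asm0 <- simulate_assembly(toy$reference, toy$markers,
                            rep(0L, nrow(toy$markers)))
  expect_identical(as.character(asm0$assembly), as.character(toy$reference))
  # one substitution: exactly one differing base
  al <- rep(0L, nrow(toy$markers)); al[5] <- 1L
  asm1 <- simulate_assembly(toy$reference, toy$markers, al)
  ref_chars <- strsplit(as.character(toy$reference)[[1]], "")[[1]]
  asm_chars <- strsplit(as.character(asm1$assembly)[[1]], "")[[1]]
  diff <- which(ref_chars != asm_chars)
  expect_identical(diff, toy$markers$pos[5])
  expect_identical(asm_chars[diff], toy$markers$alt[5])
  # out-of-bounds marker position is a coordinate error
  bad <- toy$markers; bad$pos[1] <- 7000L
  expect_error(simulate_assembly(toy$reference, bad, al), "bounds")
})
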