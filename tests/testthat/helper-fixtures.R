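# Shared fixtures and independent oracles for the test-suite.
# All fixtures are built in code; nothing is read from disk.

# A small hand-specified panel: 2 monokaryons + 2 dikaryons, 6 markers.
toy_gm <- function() {
  dosage <- rbind(
    M1 = c(0L, 1L, 0L, 1L, NA, 0L),
    M2 = c(1L, 0L, 0L, 1L, 1L, 0L),
    D1 = c(1L, 1L, 0L, 2L, 1L, 0L),
    D2 = c(2L, 0L, 0L, 1L, NA, 0L))
  markers <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L, 60L),
                        ref = c("A", "C", "G", "T", "A", "C"),
                        alt = c("G", "T", "A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  genotype_matrix(dosage, markers,
                  c("monokaryon", "monokaryon", "dikaryon", "dikaryon"))
}

# Random genotype matrix with multi-allelic markers, missingness and
# occasional heterozygous monokaryon calls -- raw-VCF-like input for the
# filter oracle.
random_raw_gm <- function(n_samples = 10L, n_markers = 50L, seed = 1L,
                          p_multi = 0.1, p_missing = 0.1, p_mono_het = 0.03) {
  set.seed(seed)
  role <- sample(c("monokaryon", "dikaryon"), n_samples, replace = TRUE)
  role[1:2] <- c("monokaryon", "dikaryon")     # ensure both present
  dosage <- matrix(NA_integer_, n_samples, n_markers)
  for (j in seq_len(n_markers)) {
    p <- stats::runif(1, 0.02, 0.8)
    for (i in seq_len(n_samples)) {
      if (stats::runif(1) < p_missing) next
      if (role[i] == "monokaryon") {
        dosage[i, j] <- if (stats::runif(1) < p_mono_het) karyophase:::MONO_HET
                        else stats::rbinom(1, 1, p)
      } else {
        dosage[i, j] <- stats::rbinom(1, 2, p)
      }
    }
  }
  rownames(dosage) <- sprintf("S%02d", seq_len(n_samples))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_markers, TRUE)
  alt <- vapply(seq_len(n_markers), function(j) {
    alts <- sample(setdiff(bases, ref[j]),
                   if (stats::runif(1) < p_multi) 2L else 1L)
    paste(alts, collapse = ",")
  }, character(1))
  markers <- data.frame(chrom = "chr1", pos = seq_len(n_markers) * 100L,
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(dosage, markers, role)
}

# Independent brute-force checker of the five marker-filter predicates,
# written entry-by-entry with explicit loops (no shared code with the
# implementation).
brute_force_filter <- function(gm, maf_min = 0.05, max_missing = 0.2) {
  keep <- logical(ncol(gm$dosage))
  for (j in seq_len(ncol(gm$dosage))) {
    mk <- gm$markers[j, ]
    alts <- strsplit(mk$alt, ",")[[1]]
    rule1 <- length(alts) == 1L && nchar(mk$ref) == 1L &&
      nchar(alts) == 1L && alts != mk$ref
    alt_n <- 0; tot_n <- 0
    n_hom_ref <- 0; n_hom_alt <- 0
    mono_het <- FALSE
    n_miss <- 0
    for (i in seq_len(nrow(gm$dosage))) {
      g <- gm$dosage[i, j]
      mono <- gm$role[[i]] == "monokaryon"
      if (is.na(g)) { n_miss <- n_miss + 1; next }
      if (mono && g == karyophase:::MONO_HET) { mono_het <- TRUE; next }
      if (mono) {
        alt_n <- alt_n + g; tot_n <- tot_n + 1
        if (g == 0) n_hom_ref <- n_hom_ref + 1 else n_hom_alt <- n_hom_alt + 1
      } else {
        alt_n <- alt_n + g; tot_n <- tot_n + 2
        if (g == 0) n_hom_ref <- n_hom_ref + 1
        if (g == 2) n_hom_alt <- n_hom_alt + 1
      }
    }
    p <- if (tot_n > 0) alt_n / tot_n else NA_real_
    maf <- if (is.na(p)) NA_real_ else min(p, 1 - p)
    rule2 <- !is.na(maf) && maf > maf_min
    rule3 <- n_hom_ref >= 1 && n_hom_alt >= 1
    rule4 <- (n_miss / nrow(gm$dosage)) < max_missing
    rule5 <- !mono_het
    keep[j] <- rule1 && rule2 && rule3 && rule4 && rule5
  }
  keep
}

# Benchmark population of the admixture / pedigree experiments.
bench_sim <- function(seed, ...) simulate_population(sim_config(seed = seed, ...))
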