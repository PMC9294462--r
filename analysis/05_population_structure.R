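#!/usr/bin/env Rscript
# Stage 5 -- population structure: IBS relatedness, PCA, admixture with
# cross-validated selection of the number of ancestral components.
#
# K selection runs on the monokaryon haplotype panel: union dikaryons
# duplicate their parents' haplotypes, and that relatedness keeps
# improving held-out prediction as K grows, so the combined panel has no
# CV minimum at the true K (see the methods vignette). PCA runs on the
# combined panel, where the dikaryon-midpoint geometry lives.

suppressPackageStartupMessages(library(karyophase))

meta <- read_sample_metadata("results/run/input/samples.tsv")
gm <- read_vcf("results/run/snpset.vcf", meta)
truth <- jsonlite::read_json("results/run/input/truth.json",
                             simplifyVector = TRUE)

ibs <- ibs_matrix(gm)
write_ibs(ibs, "results/run/ibs.tsv")
dik <- gm$samples[gm$role == "dikaryon"]
cat(sprintf("IBS: mean within-panel %.3f; parent-dikaryon pairs reach %.3f\n",
            mean(ibs[upper.tri(ibs)]),
            max(vapply(dik, function(d)
              max(ibs[d, unlist(truth$dikaryon_parents[[d]])]), numeric(1)))))

pca <- pca_genotypes(gm, n_components = 20L)
write_pca(pca, "results/run/pca")
print(pca)
res <- vapply(dik, function(d) {
  pr <- unlist(truth$dikaryon_parents[[d]])
  max(abs(pca$scores[d, ] - (pca$scores[pr[1], ] + pca$scores[pr[2], ]) / 2))
}, numeric(1))
cat(sprintf("dikaryon midpoint residual, worst of %d: %.2e (exact property)\n",
            length(res), max(res)))

mono_panel <- subset_gm(gm, samples = which(gm$role == "monokaryon"))
ks <- choose_K(mono_panel, K_range = 2:6, seed = 42L)
write.table(ks$table, "results/run/cv_error.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ks$table, row.names = FALSE, digits = 4)
cat("selected K =", ks$best_K, "\n")

fit <- admixture_em(gm, ks$best_K, seed = 42L)
write_q_matrix(fit, sprintf("results/run/admixture.%d.Q", ks$best_K))
print(fit)
true_Q <- truth$true_Q
rownames(true_Q) <- truth$monokaryon_ids
mae <- q_mae(fit$Q[truth$monokaryon_ids, ], true_Q)$mae
cat(sprintf("monokaryon ancestry MAE vs truth (best label order): %.4f\n", mae))
non_admixed <- sum(apply(fit$Q, 1, max) > 0.999)
cat(sprintf("non-admixed samples (>99.9%% single component): %d of %d\n",
            non_admixed, nrow(fit$Q)))
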