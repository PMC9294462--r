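#!/usr/bin/env Rscript
# Stage 6 -- pedigree inference: recover each dikaryon's parent pair from
# the monokaryon panel by PCA midpoint geometry + genotype compatibility,
# and demonstrate identification of an un-sequenced parent by
# phase-then-IBS matching.

suppressPackageStartupMessages(library(karyophase))

meta <- read_sample_metadata("results/run/input/samples.tsv")
gm <- read_vcf("results/run/snpset.vcf", meta)
truth <- jsonlite::read_json("results/run/input/truth.json",
                             simplifyVector = TRUE)

pca <- pca_genotypes(gm, n_components = 20L)
panel <- gm$samples[gm$role == "monokaryon"]
diks <- gm$samples[gm$role == "dikaryon"]

edges <- do.call(rbind, lapply(diks, function(d)
  infer_parents(d, panel, gm, pca, top_n = 1L)))
write.table(edges, "results/run/pedigree.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_pedigree_dot(edges, "results/run/pedigree.dot")

hits <- vapply(seq_len(nrow(edges)), function(i)
  setequal(c(edges$parent_a[i], edges$parent_b[i]),
           unlist(truth$dikaryon_parents[[edges$dikaryon[i]]])), logical(1))
cat(sprintf("rank-1 parent-pair recovery: %d/%d (compatibility all %.3f)\n",
            sum(hits), length(hits), min(edges$compatibility)))

# un-sequenced-parent identification: withhold one parent, phase with the
# other, rank the panel by IBS to the inferred haplotype
d <- diks[1]
pr <- unlist(truth$dikaryon_parents[[d]])
m <- match_inferred_parent(d, pr[1], setdiff(panel, pr[1]), gm)
cat(sprintf("dikaryon %s phased with %s: top match %s (IBS %.3f; truth %s)\n",
            d, pr[1], m$matches$sample_id[1], m$matches$ibs[1], pr[2]))
write.table(m$matches[1:5, ], "results/run/inferred_parent_matches.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
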