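#!/usr/bin/env Rscript
# Stage 1 -- generate the benchmark population and its file artifacts.
#
# The design mirrors the study system: monokaryon haplotypes drawn from 3
# ancestral genetic components under Balding-Nichols drift (F = 0.3), 120
# monokaryons of which 10% are admixed, and 20 dikaryons formed as unions
# of two monokaryon haplotypes (protoplast-derived monokaryons are the
# dikaryon's own nuclei, so no recombination is involved). Outputs: VCF,
# sample metadata TSV, truth JSON under results/run/input, plus a toy
# reference genome and one haplotype-substituted assembly with its truth
# alignments for the assembly-integration stage.

suppressPackageStartupMessages(library(karyophase))
dir.create("results/run", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 42L)
sim <- simulate_population(cfg)
paths <- write_simulation(sim, "results/run/input")
cat("population:", nrow(sim$gm$dosage), "samples x",
    ncol(sim$gm$dosage), "markers\n")
cat("wrote:", paste(basename(paths), collapse = ", "), "\n")

# toy genome + one assembly for the pseudo-read round trip
toy <- simulate_toy_genome(n_chrom = 2L, chrom_len = 12000L,
                           n_markers = 30L, seed = 42L)
set.seed(42)
hap <- sample(0:1, nrow(toy$markers), replace = TRUE)
asm <- simulate_assembly(toy$reference, toy$markers, hap)
Biostrings::writeXStringSet(toy$reference, "results/run/input/toy_reference.fa")
Biostrings::writeXStringSet(asm$assembly, "results/run/input/toy_assembly.fa")
writeLines(asm$sam, "results/run/input/toy_assembly.sam")
write.table(cbind(toy$markers, allele = hap),
            "results/run/input/toy_truth_haplotype.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("toy assembly:", length(asm$sam), "SAM lines,",
    sum(hap), "alternative alleles substituted\n")
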