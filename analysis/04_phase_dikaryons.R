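#!/usr/bin/env Rscript
# Stage 4 -- phase every dikaryon with its sequenced monokaryon and add
# the inferred un-sequenced haplotypes to the panel.
#
# For each (dikaryon, monokaryon) link in the metadata, heterozygous
# dikaryon genotypes donate the complementary allele to the second
# nucleus; homozygous genotypes force both nuclei. The inferred haplotype
# joins the matrix as a new haploid sample, mirroring the construction of
# an expanded monokaryon population from sequenced + inferred haplotypes.

suppressPackageStartupMessages(library(karyophase))

meta <- read_sample_metadata("results/run/input/samples.tsv")
gm <- read_vcf("results/run/snpset.vcf", meta)

pairs <- karyophase:::phaseable_pairs(meta)
cat("phaseable dikaryon-monokaryon pairs:", nrow(pairs), "\n")
ph <- phase_panel(gm, pairs)

summ <- data.frame(
  dikaryon = names(ph$phase),
  n_phased = vapply(ph$phase, `[[`, numeric(1), "n_phased"),
  n_conflicts = vapply(ph$phase, `[[`, numeric(1), "n_conflicts"),
  conflict_rate = vapply(ph$phase, `[[`, numeric(1), "conflict_rate"))
write.table(summ, "results/run/phasing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ, row.names = FALSE, digits = 3)
cat(sprintf("max conflict rate: %.4g (error-free input phases conflict-free)\n",
            max(summ$conflict_rate)))

write_vcf(ph$gm, "results/run/snpset_with_inferred.vcf")
cat("panel grown to", nrow(ph$gm$dosage), "samples (",
    sum(grepl("inferred", ph$gm$samples)), "inferred haplotypes )\n")
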