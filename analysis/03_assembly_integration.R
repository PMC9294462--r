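#!/usr/bin/env Rscript
# Stage 3 -- integrate a genome assembly into the marker set.
#
# Chops the toy assembly into 5-kb pseudo-reads at 200-bp steps, genotypes
# the marker sites from the truth alignments by majority vote, verifies
# the calls against the generating haplotype, and appends the
# assembly-derived haplotype plus the all-reference haplotype of the
# reference strain to the genotype matrix.

suppressPackageStartupMessages(library(karyophase))

asm <- Biostrings::readDNAStringSet("results/run/input/toy_assembly.fa")
truth <- read.table("results/run/input/toy_truth_haplotype.tsv",
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
markers <- truth[, c("chrom", "pos", "ref", "alt")]

pr <- chop_assembly(asm)                    # defaults: 5,000 bp / 200 bp
write_pseudoreads_fasta(pr, "results/run/pseudoreads.fa")
cat("pseudo-reads:", nrow(pr), "segments from",
    length(unique(pr$contig)), "contigs\n")

calls <- genotype_from_alignments("results/run/input/toy_assembly.sam", markers)
cat(sprintf("covered markers: %d/%d, mean depth %.1f\n",
            sum(calls$depth > 0), nrow(calls), mean(calls$depth)))
agree <- sum(as.integer(calls$allele) == truth$allele, na.rm = TRUE)
cat(sprintf("calls matching the generating haplotype: %d/%d\n",
            agree, sum(!is.na(calls$allele))))
stopifnot(agree == nrow(calls))             # exact round trip

# attach to a small genotype panel built over the same toy markers
set.seed(7)
panel <- matrix(sample(0:1, 4 * nrow(markers), TRUE), 4,
                dimnames = list(sprintf("M%02d", 1:4), NULL))
gm <- genotype_matrix(panel, markers, rep("monokaryon", 4))
gm <- add_assembly_haplotype(gm, calls, "ASM1")
gm <- reference_haplotype(gm, "KREF")
cat("panel after integration:", nrow(gm$dosage), "samples (",
    paste(gm$samples, collapse = ", "), ")\n")
write_vcf(gm, "results/run/toy_panel_with_assembly.vcf")
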