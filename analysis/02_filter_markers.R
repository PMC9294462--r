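#!/usr/bin/env Rscript
# Stage 2 -- build the polymorphic marker set.
#
# Reads the joint-genotyped VCF back from disk (exercising the same I/O
# path a real study would use), applies the five-rule filter, and writes
# the retained SNP set, the per-rule removal report, per-sample QC and
# the 500-kb marker-density track.

suppressPackageStartupMessages(library(karyophase))

meta <- read_sample_metadata("results/run/input/samples.tsv")
gm <- read_vcf("results/run/input/population.vcf", meta)
cat("input:", ncol(gm$dosage), "markers,",
    attr(gm, "n_skipped_non_snp"), "non-SNP records skipped\n")

fl <- filter_markers(gm)
print(fl$report)
write_vcf(fl$gm, "results/run/snpset.vcf")
write_filter_report(fl$report, "results/run/filter_report.json")

qc <- sample_qc(fl$gm)
write.table(qc, "results/run/sample_qc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("heterozygosity levels:\n")
print(table(qc$role, qc$het_level))

# density in 500-kb windows on a toy chromosome scale: the markers sit on
# two chromosomes at 100-bp spacing, so windows are uniformly dense
lens <- tapply(fl$gm$markers$pos, fl$gm$markers$chrom, max) + 100
tr <- density_track(fl$gm, lens, window = 5e5)
write_bedgraph(tr, "results/run/marker_density.bedgraph")
cat(sprintf("global marker density: %.2f markers/kb\n",
            attr(tr, "global_density")))

sp <- maf_spectrum(fl$gm, bins = 25L)
write.table(sp, "results/run/maf_spectrum.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("MAF spectrum mass in (0.05, 0.5]:", sum(sp$proportion), "\n")
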