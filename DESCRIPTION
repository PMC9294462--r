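Package: karyophase
Title: Dikaryon-Monokaryon Haplotype Phasing and Population Structure for
    Fungal Breeding Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of dikaryotic fungi and
    their constituent monokaryons, as used in cross-breeding studies of
    cultivated mushrooms such as Flammulina filiformis. Builds polymorphic
    bi-allelic SNP marker sets from joint-genotyped VCFs with a five-rule
    filter, integrates genome assemblies by chopping them into overlapping
    pseudo-reads and genotyping marker sites from their alignments, phases
    dikaryon genotypes against a sequenced monokaryon haplotype to infer the
    un-sequenced haplotype, and re-implements the population-structure stack
    (identity-by-state relatedness, genotype PCA with joint haploid/dikaryotic
    encoding, and the admixture likelihood with block EM and cross-validated
    selection of the number of ancestral components). Includes a synthetic
    population generator (Balding-Nichols ancestral components, dikaryons as
    unions of two monokaryon haplotypes, genotyping error and missingness,
    toy assemblies with truth alignments) so the whole pipeline is testable
    against known truth, and midpoint-based pedigree inference that ranks
    candidate parent pairs by PCA geometry and genotype compatibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
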