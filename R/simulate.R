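#' Configuration for the synthetic dikaryon/monokaryon population generator
#'
#' The generator emulates the study design this package targets: a panel of
#' wild and cultivated strains in which monokaryon haplotypes descend from
#' K ancestral genetic components (Balding-Nichols drift around an
#' ancestral frequency), some individuals are admixed, and each dikaryon is
#' exactly the union of two monokaryon haplotypes -- no recombination,
#' because protoplast-derived monokaryons are the dikaryon's own two
#' nuclei. Defaults encode the standard benchmark population used
#' throughout the test-suite: 3 ancestral components with drift F = 0.3,
#' 120 monokaryons of which 10% are admixed, 20 union dikaryons, and 5,000
#' markers.
#'
#' @param n_ancestral_pops number of ancestral components K (>= 1)
#' @param divergence_F Balding-Nichols drift coefficient per population, in
#'   (0, 1); recycled to length K. Population-k frequencies are Beta
#'   distributed with mean p0 and variance F p0 (1 - p0).
#' @param n_monokaryons_per_pop non-admixed monokaryons drawn from each
#'   component
#' @param n_admixed_monokaryons monokaryons with Dirichlet(0.5) ancestry
#'   vectors across all K components
#' @param n_markers number of SNP markers
#' @param ancestral_maf_range range of the ancestral minor allele
#'   frequency p0, drawn uniformly; allele polarity (which allele is
#'   minor) is randomised per marker
#' @param crosses list of length-2 character vectors of monokaryon ids
#'   defining dikaryons, or a single integer n meaning "n random crosses
#'   between distinct monokaryons" (drawn under the seed)
#' @param genotype_error_rate per-call allele-flip probability, applied to
#'   haploid calls and (as a single-step hom/het perturbation) to dikaryon
#'   genotype classes
#' @param missing_rate i.i.d. per-entry masking probability
#' @param sample_missing_inflation optional named vector of per-sample
#'   additional masking probabilities (to spread samples in missingness QC
#'   space)
#' @param seed integer; fully determines the output
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_ancestral_pops = 3L,
                       divergence_F = 0.3,
                       n_monokaryons_per_pop = 36L,
                       n_admixed_monokaryons = 12L,
                       n_markers = 5000L,
                       ancestral_maf_range = c(0.05, 0.5),
                       crosses = 20L,
                       genotype_error_rate = 0,
                       missing_rate = 0,
                       sample_missing_inflation = NULL,
                       seed = 1L) {
  cfg <- list(n_ancestral_pops = as.integer(n_ancestral_pops),
              divergence_F = rep_len(divergence_F, n_ancestral_pops),
              n_monokaryons_per_pop = as.integer(n_monokaryons_per_pop),
              n_admixed_monokaryons = as.integer(n_admixed_monokaryons),
              n_markers = as.integer(n_markers),
              ancestral_maf_range = ancestral_maf_range,
              crosses = crosses,
              genotype_error_rate = genotype_error_rate,
              missing_rate = missing_rate,
              sample_missing_inflation = sample_missing_inflation,
              seed = as.integer(seed))
  stopifnot(cfg$n_ancestral_pops >= 1L,
            all(cfg$divergence_F > 0 & cfg$divergence_F < 1),
            cfg$n_monokaryons_per_pop >= 1L,
            cfg$n_admixed_monokaryons >= 0L,
            cfg$n_markers >= 1L,
            length(cfg$ancestral_maf_range) == 2L,
            cfg$ancestral_maf_range[1] > 0,
            cfg$ancestral_maf_range[2] <= 0.5,
            cfg$ancestral_maf_range[1] <= cfg$ancestral_maf_range[2],
            cfg$genotype_error_rate >= 0, cfg$genotype_error_rate < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Simulate a dikaryon/monokaryon population with known truth
#'
#' Draws ancestral frequencies per marker, population frequencies under
#' the Balding-Nichols model, monokaryon haplotypes allele-wise Bernoulli
#' from each individual's mixture frequency, and dikaryon genotypes as the
#' multiset union of their two parent haplotypes. Genotyping error and
#' missingness are then injected into the *observed* matrix; the returned
#' truth set keeps the error-free haplotypes, the true ancestry matrix Q
#' and the ancestral frequency profiles.
#'
#' @param config a [sim_config()]
#' @return list of class `kp_simulation`: `gm` (observed
#'   `genotype_matrix`), `meta` (sample metadata data.frame), `truth`
#'   (list: `p0` ancestral frequency per marker, `ancestral_freqs` K x
#'   markers drifted component profiles,
#'   `true_Q` monokaryons x K, `haplotypes` error-free monokaryon allele
#'   matrix, `dikaryon_parents` named list id -> c(parent, parent),
#'   `markers` marker table)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    K <- config$n_ancestral_pops
    J <- config$n_markers
    n_pure <- config$n_monokaryons_per_pop * K
    n_adm <- config$n_admixed_monokaryons
    N <- n_pure + n_adm

    # ancestral MAF and allele polarity
    p0 <- stats::runif(J, config$ancestral_maf_range[1],
                       config$ancestral_maf_range[2])
    flip <- stats::runif(J) < 0.5
    p0 <- ifelse(flip, 1 - p0, p0)

    # Balding-Nichols population frequencies: Beta(p0 (1-F)/F, (1-p0)(1-F)/F)
    popf <- matrix(NA_real_, K, J)
    for (k in seq_len(K)) {
      F_k <- config$divergence_F[k]
      if (F_k < 1e-9) popf[k, ] <- p0
      else popf[k, ] <- stats::rbeta(J, p0 * (1 - F_k) / F_k,
                                     (1 - p0) * (1 - F_k) / F_k)
    }

    Q <- matrix(0, N, K)
    pop_of <- rep(seq_len(K), each = config$n_monokaryons_per_pop)
    Q[cbind(seq_len(n_pure), pop_of)] <- 1
    if (n_adm > 0)
      for (i in seq_len(n_adm))
        Q[n_pure + i, ] <- rdirichlet1(K, 0.5)
    mono_ids <- sprintf("M%03d", seq_len(N))
    rownames(Q) <- mono_ids

    mixf <- Q %*% popf                     # N x J individual allele frequencies
    hap <- matrix(as.integer(stats::runif(N * J) < mixf), N, J,
                  dimnames = list(mono_ids, NULL))

    crosses <- config$crosses
    if (is.numeric(crosses) && length(crosses) == 1L) {
      n_cross <- as.integer(crosses)
      crosses <- lapply(seq_len(n_cross), function(i)
        sample(mono_ids, 2L, replace = FALSE))
    }
    dik_ids <- sprintf("D%02d", seq_along(crosses))
    for (cr in crosses) {
      if (!all(cr %in% mono_ids))
        stop("cross references unknown haplotype id(s): ",
             paste(setdiff(unlist(crosses), mono_ids), collapse = ", "))
      if (length(cr) != 2L) stop("each cross must name exactly two haplotypes")
    }
    dik_true <- t(vapply(crosses, function(cr)
      hap[cr[1], ] + hap[cr[2], ], integer(J)))
    if (length(crosses) == 1L) dik_true <- matrix(dik_true, nrow = 1L)
    rownames(dik_true) <- dik_ids

    # observed copies: allele-flip error on haploid calls, single-step
    # hom<->het perturbation on dikaryon genotype classes
    e <- config$genotype_error_rate
    hap_obs <- hap
    dik_obs <- dik_true
    if (e > 0) {
      fl <- matrix(stats::runif(N * J) < e, N, J)
      hap_obs[fl] <- 1L - hap_obs[fl]
      fl2 <- matrix(stats::runif(nrow(dik_true) * J) < e, nrow(dik_true), J)
      pert <- dik_obs
      hom0 <- fl2 & dik_obs == 0L
      hom2 <- fl2 & dik_obs == 2L
      het <- fl2 & dik_obs == 1L
      pert[hom0] <- 1L
      pert[hom2] <- 1L
      up <- het & matrix(stats::runif(length(het)) < 0.5, nrow(het))
      pert[het] <- 0L
      pert[up] <- 2L
      dik_obs <- pert
    }

    dosage <- rbind(hap_obs, dik_obs)
    role <- c(rep("monokaryon", N), rep("dikaryon", length(crosses)))
    mr <- config$missing_rate
    rates <- rep(mr, nrow(dosage))
    names(rates) <- rownames(dosage)
    if (!is.null(config$sample_missing_inflation)) {
      infl <- config$sample_missing_inflation
      rates[names(infl)] <- rates[names(infl)] + infl
    }
    if (any(rates > 0)) {
      mask <- matrix(stats::runif(length(dosage)) <
                       rates[row(dosage)], nrow(dosage))
      dosage[mask] <- NA_integer_
    }

    # toy marker map: markers spread over two chromosomes, 100 bp apart
    half <- ceiling(J / 2)
    chrom <- rep(c("chr1", "chr2"), times = c(half, J - half))
    pos <- c(seq_len(half), seq_len(J - half)) * 100L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, J, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    markers <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE)

    gm <- genotype_matrix(dosage, markers, role)
    link_of_mono <- rep(NA_character_, N)
    names(link_of_mono) <- mono_ids
    for (i in seq_along(crosses))
      for (p in crosses[[i]])
        link_of_mono[p] <- if (is.na(link_of_mono[p])) dik_ids[i] else
          paste(link_of_mono[p], dik_ids[i], sep = ",")
    meta <- data.frame(
      sample_id = c(mono_ids, dik_ids),
      role = role,
      type = c(ifelse(pop_of == 1, "cultivated", "wild")[seq_len(n_pure)],
               rep("wild", n_adm),
               rep("cultivated", length(crosses)))[seq_len(N + length(crosses))],
      dikaryon_link = c(unname(link_of_mono),
                        vapply(crosses, paste, character(1), collapse = ",")),
      stringsAsFactors = FALSE)

    parents <- stats::setNames(crosses, dik_ids)
    structure(list(gm = gm, meta = meta,
                   truth = list(p0 = p0,
                                ancestral_freqs = popf,
                                true_Q = Q,
                                haplotypes = hap,
                                dikaryon_true = dik_true,
                                dikaryon_parents = parents,
                                markers = markers)),
              class = "kp_simulation")
  })
}

#' @exportS3Method base::print
print.kp_simulation <- function(x, ...) {
  cat(sprintf("kp_simulation: %d monokaryons + %d dikaryons, %d markers\n",
              nrow(x$truth$haplotypes), length(x$truth$dikaryon_parents),
              ncol(x$gm$dosage)))
  invisible(x)
}

#' Write all artifacts of a simulated population to disk
#'
#' Emits the observed genotypes as VCF 4.2, the sample metadata as TSV and
#' the truth set as JSON, giving every downstream stage file-based inputs
#' identical in shape to a real study.
#'
#' @param sim a `kp_simulation`
#' @param dir output directory (created if needed)
#' @param haploid_style monokaryon VCF dialect, see [write_vcf()]
#' @return named character vector of the paths written
#' @export
write_simulation <- function(sim, dir, haploid_style = "haploid") {
  stopifnot(inherits(sim, "kp_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "population.vcf"),
             meta = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$gm, paths[["vcf"]], haploid_style = haploid_style)
  write_sample_metadata(sim$meta, paths[["meta"]])
  tr <- sim$truth
  jsonlite::write_json(
    list(ancestral_freqs = tr$ancestral_freqs,
         monokaryon_ids = rownames(tr$true_Q),
         true_Q = tr$true_Q,
         haplotypes = tr$haplotypes,
         dikaryon_parents = tr$dikaryon_parents),
    paths[["truth"]], digits = NA)
  paths
}

#' Generate a toy reference genome with marker positions
#'
#' @param n_chrom number of chromosomes
#' @param chrom_len length of each chromosome in bp
#' @param n_markers total SNP markers, placed uniformly without collision
#' @param seed RNG seed
#' @return list: `reference` (DNAStringSet), `markers` (marker data.frame)
#' @export
simulate_toy_genome <- function(n_chrom = 2L, chrom_len = 12000L,
                                n_markers = 30L, seed = 1L) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n_chrom), function(i)
      paste(sample(bases, chrom_len, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("chr%d", seq_len(n_chrom))
    per <- diff(round(seq(0, n_markers, length.out = n_chrom + 1L)))
    markers <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      pos <- sort(sample(seq_len(chrom_len), per[i]))
      ref <- substring(seqs[i], pos, pos)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
      data.frame(chrom = names(seqs)[i], pos = pos, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    }))
    rownames(markers) <- NULL
    list(reference = Biostrings::DNAStringSet(seqs), markers = markers)
  })
}

#' Build a haploid assembly from a reference and a marker haplotype
#'
#' The assembly equals the reference with the haplotype's alternative
#' alleles substituted at marker positions (substitutions only, no
#' structural change), so assembly coordinates coincide with reference
#' coordinates and the true alignment of every chopped segment is known by
#' construction. The truth SAM contains one perfect-match alignment record
#' per pseudo-read segment.
#'
#' @param reference `DNAStringSet` (or named character) reference contigs
#' @param markers marker data.frame (`chrom`, `pos`, `ref`, `alt`)
#' @param alleles integer vector over markers, 0 = reference allele,
#'   1 = alternative allele, NA treated as reference
#' @param seg_len,step chopping geometry forwarded to [chop_assembly()]
#' @return list: `assembly` (DNAStringSet), `sam` (character vector of SAM
#'   lines, header included), `pseudo_reads` (the chopped segment table)
#' @export
simulate_assembly <- function(reference, markers, alleles,
                              seg_len = 5000L, step = 200L) {
  if (!inherits(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  seqs <- as.character(reference)
  stopifnot(length(alleles) == nrow(markers),
            all(markers$chrom %in% names(seqs)))
  if (any(markers$pos < 1L | markers$pos > nchar(seqs)[match(markers$chrom, names(seqs))]))
    stop("marker position outside reference bounds")
  ref_base <- substring(seqs[markers$chrom], markers$pos, markers$pos)
  if (!all(ref_base == markers$ref))
    stop("marker ref alleles disagree with the reference sequence")
  sub <- which(!is.na(alleles) & alleles == 1L)
  for (i in sub) {
    ch <- markers$chrom[i]
    substring(seqs[ch], markers$pos[i], markers$pos[i]) <- markers$alt[i]
  }
  assembly <- Biostrings::DNAStringSet(seqs)
  pr <- chop_assembly(assembly, seg_len = seg_len, step = step)
  sam <- truth_sam(pr, nchar(seqs))
  list(assembly = assembly, sam = sam, pseudo_reads = pr)
}

# Emit perfect-match SAM records for pseudo-reads whose true placement is
# known (assembly coordinates == reference coordinates).
truth_sam <- function(pseudo_reads, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  rec <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                 pseudo_reads$name, pseudo_reads$contig,
                 pseudo_reads$start + 1L, pseudo_reads$length,
                 pseudo_reads$sequence)
  c(hdr, rec)
}
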