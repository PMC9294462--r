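#' Assemble a pipeline run configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Either `vcf` +
#' `metadata` paths or a [sim_config()] (for a fully synthetic run) must
#' be supplied.
#'
#' @param vcf path to the multi-sample VCF (ignored when `simulate` given)
#' @param metadata path to the sample metadata TSV
#' @param simulate optional `sim_config`; when present the run starts by
#'   generating the population
#' @param out_dir output directory for all artifacts
#' @param maf_min,max_missing marker-filter thresholds
#' @param conflict_threshold phasing plausibility bound
#' @param K_range candidate numbers of ancestral components
#' @param n_components PCA components
#' @param folds CV folds for K selection (default 5)
#' @param seed master seed, recorded in the manifest
#' @param stages character subset of
#'   `c("filter", "phase", "structure", "pedigree")`
#' @return a validated `run_config` list
#' @export
run_config <- function(vcf = NULL, metadata = NULL, simulate = NULL,
                       out_dir = "karyophase_run",
                       maf_min = 0.05, max_missing = 0.2,
                       conflict_threshold = 0.01,
                       K_range = 2:6, n_components = 20L, folds = 5L,
                       seed = 1L,
                       stages = c("filter", "phase", "structure", "pedigree")) {
  stopifnot(maf_min >= 0, maf_min < 0.5, max_missing > 0, max_missing <= 1,
            conflict_threshold >= 0, all(K_range >= 1), n_components >= 1,
            folds >= 2)
  if (is.null(simulate) && (is.null(vcf) || is.null(metadata)))
    stop("either 'simulate' or both 'vcf' and 'metadata' must be given")
  structure(list(vcf = vcf, metadata = metadata, simulate = simulate,
                 out_dir = out_dir, maf_min = maf_min,
                 max_missing = max_missing,
                 conflict_threshold = conflict_threshold,
                 K_range = K_range, n_components = as.integer(n_components),
                 folds = as.integer(folds), seed = as.integer(seed),
                 stages = stages),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes marker filtering, dikaryon phasing, population structure
#' (IBS, PCA, cross-validated admixture) and pedigree inference in order,
#' writing every artifact plus a JSON manifest (seeds, thresholds,
#' per-stage counts) under the configured output directory. A re-run with
#' the same configuration reproduces identical outputs.
#'
#' @param config a [run_config()]
#' @return list of in-memory results (`gm`, `report`, `qc`, `phase`,
#'   `ibs`, `pca`, `admixture`, `K_selection`, `pedigree`, `manifest`),
#'   invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   thresholds = list(maf_min = config$maf_min,
                                     max_missing = config$max_missing,
                                     conflict_threshold = config$conflict_threshold),
                   K_range = config$K_range,
                   n_components = config$n_components,
                   folds = config$folds,
                   stages = config$stages, counts = list())

  if (!is.null(config$simulate)) {
    sim <- simulate_population(config$simulate)
    write_simulation(sim, file.path(config$out_dir, "input"))
    gm <- sim$gm; meta <- sim$meta
  } else {
    if (!file.exists(config$metadata))
      stop("metadata file not found: ", config$metadata)
    if (!file.exists(config$vcf))
      stop("VCF file not found: ", config$vcf)
    meta <- read_sample_metadata(config$metadata)
    gm <- read_vcf(config$vcf, meta)
  }
  manifest$counts$input <- list(samples = nrow(gm$dosage),
                                markers = ncol(gm$dosage))
  out <- list()

  if ("filter" %in% config$stages) {
    fl <- filter_markers(gm, maf_min = config$maf_min,
                         max_missing = config$max_missing)
    gm <- fl$gm
    write_filter_report(fl$report, file.path(config$out_dir, "filter_report.json"))
    write_vcf(gm, file.path(config$out_dir, "snpset.vcf"))
    qc <- sample_qc(gm)
    utils::write.table(qc, file.path(config$out_dir, "sample_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$filter <- list(retained = fl$report$n_retained)
    out$report <- fl$report; out$qc <- qc
  }

  if ("phase" %in% config$stages) {
    pairs <- phaseable_pairs(meta)
    if (nrow(pairs)) {
      ph <- phase_panel(gm, pairs)
      gm <- ph$gm
      ph_sum <- data.frame(
        dikaryon = names(ph$phase),
        conflict_rate = vapply(ph$phase, `[[`, numeric(1), "conflict_rate"),
        n_phased = vapply(ph$phase, `[[`, numeric(1), "n_phased"))
      utils::write.table(ph_sum, file.path(config$out_dir, "phasing.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$phase <- ph$phase
    }
    manifest$counts$phase <- list(pairs = nrow(pairs))
  }

  if ("structure" %in% config$stages) {
    ibs <- ibs_matrix(gm)
    write_ibs(ibs, file.path(config$out_dir, "ibs.tsv"))
    pca <- pca_genotypes(gm, n_components = config$n_components)
    write_pca(pca, file.path(config$out_dir, "pca"))
    ks <- choose_K(gm, K_range = config$K_range, folds = config$folds,
                   seed = config$seed)
    utils::write.table(ks$table, file.path(config$out_dir, "cv_error.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- admixture_em(gm, ks$best_K, seed = config$seed)
    write_q_matrix(fit, file.path(config$out_dir,
                                  sprintf("admixture.%d.Q", ks$best_K)))
    manifest$counts$structure <- list(best_K = ks$best_K)
    out$ibs <- ibs; out$pca <- pca; out$K_selection <- ks; out$admixture <- fit
  }

  if ("pedigree" %in% config$stages && !is.null(out$pca)) {
    mono_ids <- gm$samples[gm$role == "monokaryon"]
    dik_ids <- gm$samples[gm$role == "dikaryon"]
    if (length(mono_ids) >= 2L && length(dik_ids) >= 1L) {
      edges <- do.call(rbind, lapply(dik_ids, function(d)
        infer_parents(d, mono_ids, gm, out$pca, top_n = 1L)))
      utils::write.table(edges, file.path(config$out_dir, "pedigree.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_pedigree_dot(edges, file.path(config$out_dir, "pedigree.dot"))
      manifest$counts$pedigree <- list(edges = nrow(edges))
      out$pedigree <- edges
    }
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$gm <- gm
  out$manifest <- manifest
  invisible(out)
}

# (dikaryon, sequenced monokaryon) pairs derivable from metadata links
phaseable_pairs <- function(meta) {
  mono <- meta[meta$role == "monokaryon" & !is.na(meta$dikaryon_link), ,
               drop = FALSE]
  if (!nrow(mono))
    return(data.frame(dikaryon = character(), monokaryon = character()))
  pairs <- do.call(rbind, lapply(seq_len(nrow(mono)), function(i) {
    diks <- strsplit(mono$dikaryon_link[i], ",", fixed = TRUE)[[1]]
    data.frame(dikaryon = diks, monokaryon = mono$sample_id[i],
               stringsAsFactors = FALSE)
  }))
  # one sequenced monokaryon per dikaryon is enough; keep the first
  pairs[!duplicated(pairs$dikaryon), , drop = FALSE]
}
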