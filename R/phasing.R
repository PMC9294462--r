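#' Phase a dikaryon against one sequenced monokaryon haplotype
#'
#' The dikaryon carries exactly the two haploid nuclei it was formed from,
#' so given one of them every marker is resolved by a deterministic truth
#' table: a heterozygous dikaryon genotype donates the complementary
#' allele to the other nucleus; a homozygous genotype forces both nuclei
#' to that allele (a mismatching monokaryon allele there is a conflict --
#' genotyping error or a wrong pairing -- and the site is emitted
#' missing); sites uninformative for the second haplotype (heterozygous
#' dikaryon, missing monokaryon) and missing dikaryon calls stay missing.
#'
#' @param dik integer vector of dikaryon dosages in \{0, 1, 2, NA\}
#' @param mono integer vector of monokaryon alleles in \{0, 1, NA\}, same
#'   marker order
#' @return object of class `kp_phase`: `inferred` (allele vector of the
#'   un-sequenced haplotype), counts `n_phased`, `n_conflicts`,
#'   `n_uninformative`, `n_missing`, and `conflict_rate` =
#'   conflicts / (phased + conflicts)
#' @export
phase_dikaryon <- function(dik, mono) {
  if (length(dik) != length(mono))
    stop("dikaryon and monokaryon vectors cover different marker sets")
  dik <- as.integer(dik); mono <- as.integer(mono)
  inferred <- rep(NA_integer_, length(dik))
  status <- rep("missing", length(dik))

  het <- !is.na(dik) & dik == 1L
  hom <- !is.na(dik) & dik != 1L
  hom_allele <- dik %/% 2L                    # 0 -> 0, 2 -> 1

  i <- het & !is.na(mono)                     # complementary allele
  inferred[i] <- 1L - mono[i]
  status[i] <- "phased"
  i <- het & is.na(mono)
  status[i] <- "uninformative"
  i <- hom & !is.na(mono) & mono == hom_allele
  inferred[i] <- hom_allele[i]
  status[i] <- "phased"
  i <- hom & !is.na(mono) & mono != hom_allele
  status[i] <- "conflict"                     # inferred stays missing
  i <- hom & is.na(mono)                      # hom forces both haplotypes
  inferred[i] <- hom_allele[i]
  status[i] <- "phased"

  n <- table(factor(status, levels = c("phased", "conflict",
                                       "uninformative", "missing")))
  denom <- n[["phased"]] + n[["conflict"]]
  structure(list(inferred = inferred,
                 n_phased = n[["phased"]],
                 n_conflicts = n[["conflict"]],
                 n_uninformative = n[["uninformative"]],
                 n_missing = n[["missing"]],
                 conflict_rate = if (denom > 0) n[["conflict"]] / denom else 0),
            class = "kp_phase")
}

#' @exportS3Method base::print
print.kp_phase <- function(x, ...) {
  cat(sprintf(
    "kp_phase: %d phased, %d conflicts (rate %.4g), %d uninformative, %d missing\n",
    x$n_phased, x$n_conflicts, x$conflict_rate, x$n_uninformative, x$n_missing))
  invisible(x)
}

#' Reconstruct a dikaryon genotype vector from two haplotypes
#'
#' The exact inverse of phasing: with both constituent monokaryons
#' sequenced, the dikaryon dosage at every marker is simply the sum of the
#' two alleles (missing where either haplotype is missing).
#'
#' @param a,b integer allele vectors in \{0, 1, NA\}, same marker order
#' @return integer dosage vector in \{0, 1, 2, NA\}
#' @export
reconstruct_dikaryon <- function(a, b) {
  if (length(a) != length(b)) stop("haplotypes cover different marker sets")
  as.integer(a) + as.integer(b)
}

#' Is a monokaryon a plausible constituent of a dikaryon?
#'
#' Phases the dikaryon with the candidate and accepts the pairing when the
#' conflict rate (homozygous dikaryon sites where the candidate carries
#' the other allele) does not exceed `threshold`. A true constituent
#' conflicts only through genotyping error; an unrelated haplotype
#' conflicts at roughly the allele-mismatch rate of homozygous sites.
#'
#' @param dik dikaryon dosage vector
#' @param mono candidate monokaryon allele vector
#' @param threshold maximum tolerated conflict rate (default 0.01)
#' @return list: `plausible` (logical), `phase` (the `kp_phase` result)
#' @export
pairing_plausibility <- function(dik, mono, threshold = 0.01) {
  ph <- phase_dikaryon(dik, mono)
  list(plausible = ph$conflict_rate <= threshold, phase = ph)
}

#' Phase every linked dikaryon in a panel and append inferred haplotypes
#'
#' Applies [phase_dikaryon()] to each (dikaryon, sequenced monokaryon)
#' pair and adds each inferred un-sequenced haplotype to the matrix as a
#' new haploid sample named `<dikaryon>.inferred`.
#'
#' @param gm a `genotype_matrix`
#' @param pairs data.frame with columns `dikaryon` and `monokaryon`
#'   (sample ids); e.g. derived from the metadata `dikaryon_link` column
#' @return list: `gm` (extended matrix), `phase` (named list of
#'   `kp_phase` results per dikaryon)
#' @export
phase_panel <- function(gm, pairs) {
  stopifnot(all(c("dikaryon", "monokaryon") %in% names(pairs)))
  results <- list()
  for (i in seq_len(nrow(pairs))) {
    d_id <- pairs$dikaryon[i]; m_id <- pairs$monokaryon[i]
    if (!all(c(d_id, m_id) %in% gm$samples))
      stop(sprintf("unknown sample in pair (%s, %s)", d_id, m_id))
    ph <- phase_dikaryon(gm$dosage[d_id, ], gm$dosage[m_id, ])
    results[[d_id]] <- ph
    gm <- add_haploid_sample(gm, ph$inferred, paste0(d_id, ".inferred"))
  }
  list(gm = gm, phase = results)
}
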