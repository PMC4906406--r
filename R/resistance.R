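# Resistance-mechanism selection logic: relative abundance of candidate
# alterations, the emergent / increasing / carried-forward rules,
# innate-vs-acquired timing, mechanism categories and the MET FISH rule.

#' Relative abundance of an alteration within a sample
#'
#' Abundance relative to total ctDNA content, so longitudinal changes
#' reflect clonal selection rather than fluctuating tumour burden. For a
#' SNV this is its (copy-number-aware) VAF divided by the raw truncal
#' VAF of the sample; for a gene-level SCNA it is the normalized copy
#' number, which is already expressed per contributing tumour cell. An
#' undetected alteration has abundance 0 with `detected = FALSE`.
#'
#' @param type `"SNV"` or `"SCNA"`.
#' @param vaf SNV allele fraction (ignored for SCNA).
#' @param truncal_vaf Raw truncal anchor VAF of the sample.
#' @param normalized_cn SCNA normalized copy number (ignored for SNV).
#' @param detected Was the alteration detected in this sample?
#' @return One-row tibble: `abundance`, `detected`.
#' @export
relative_abundance <- function(type, vaf = NA_real_, truncal_vaf = NA_real_,
                               normalized_cn = NA_real_, detected = TRUE) {
  if (!detected) {
    return(tibble(abundance = 0, detected = FALSE))
  }
  ab <- switch(type,
    SNV = {
      if (is.na(truncal_vaf) || truncal_vaf <= 0) {
        abort_validation("SNV relative abundance needs a truncal ctDNA anchor")
      }
      vaf / truncal_vaf
    },
    SCNA = normalized_cn,
    abort_validation(sprintf("unknown alteration type '%s'", type))
  )
  tibble(abundance = ab, detected = TRUE)
}

#' Call putative resistance mechanisms for one patient
#'
#' An alteration is a putative resistance mechanism when it is
#' (1) emergent — absent in pretreatment plasma but present at
#' progression — or (2) increasing — its relative abundance (see
#' [relative_abundance()]) rises from pretreatment to progression.
#' Two carry-forward cases keep pre-existing alterations on the list
#' when progression data cannot rule them out: a pretreatment SCNA
#' whose progression copy-number analysis is inconclusive (activating
#' VAF below the ctDNA adequacy gate), and a pretreatment SNV with no
#' detectable ctDNA at progression. The treatment target itself (T790M
#' and the activating EGFR mutation) is excluded from the candidate
#' set, as is the truncal anchor.
#'
#' @param pre_variants,prog_variants Germline-filtered variant tibbles
#'   for the pretreatment and progression samples.
#' @param pre_scna,prog_scna [call_scna()] tibbles for the two samples
#'   (may be `NULL` when depth data is unavailable).
#' @param pre_estimate,prog_estimate [estimate_ctdna_fraction()] rows.
#' @param fold_change Minimal abundance fold change counted as an
#'   increase (default 1, i.e. any strict increase).
#' @param ctdna_gate_vaf Adequacy gate for conclusive SCNA analysis.
#' @param scna_genes Genes whose copy-number gains are eligible
#'   resistance mechanisms. Defaults to the receptor-kinase genes the
#'   copy-number index is calibrated for (EGFR, ERBB2, MET); gains
#'   called in other genes are ignored as candidates.
#' @param patient_id Carried into the output.
#' @return Tibble of resistance calls: `patient_id`, `alteration`,
#'   `gene`, `type`, `evidence`, `pre_abundance`, `post_abundance`.
#' @export
call_resistance <- function(pre_variants, prog_variants,
                            pre_scna = NULL, prog_scna = NULL,
                            pre_estimate = NULL, prog_estimate = NULL,
                            fold_change = 1, ctdna_gate_vaf = 0.02,
                            scna_genes = c("EGFR", "ERBB2", "MET"),
                            patient_id = NA_character_) {
  pre_estimate <- pre_estimate %||% estimate_ctdna_fraction(pre_variants, pre_scna)
  prog_estimate <- prog_estimate %||% estimate_ctdna_fraction(prog_variants, prog_scna)
  empty <- tibble(
    patient_id = character(0), alteration = character(0), gene = character(0),
    type = character(0), evidence = character(0),
    pre_abundance = numeric(0), post_abundance = numeric(0)
  )
  calls <- list()

  excluded_classes <- c("T790M", "activating", "truncal_TP53")
  snv_universe <- bind_rows(
    pre_variants %>% mutate(.tp = "pre"),
    prog_variants %>% mutate(.tp = "prog")
  ) %>%
    filter(
      !.data$class %in% excluded_classes,
      .data$effect == "nonsynonymous", !.data$blacklisted
    ) %>%
    distinct(.data$gene, .data$variant)

  prog_ctdna_detectable <- !is.na(prog_estimate$ctdna_fraction) &&
    prog_estimate$ctdna_fraction > 0
  snv_ab <- function(variants, est, gene, variant) {
    row <- variants %>%
      filter(.data$gene == .env$gene, .data$variant == .env$variant,
        .data$alt_reads > 0 | .data$vaf > 0)
    if (nrow(row) == 0 || is.na(est$raw_truncal_vaf) ||
      est$raw_truncal_vaf <= 0) {
      return(tibble(abundance = 0, detected = nrow(row) > 0))
    }
    relative_abundance("SNV", vaf = max(row$vaf),
      truncal_vaf = est$raw_truncal_vaf)
  }
  for (i in seq_len(nrow(snv_universe))) {
    g <- snv_universe$gene[i]
    v <- snv_universe$variant[i]
    pre <- snv_ab(pre_variants, pre_estimate, g, v)
    prog <- snv_ab(prog_variants, prog_estimate, g, v)
    evidence <- NULL
    if (!pre$detected && prog$detected) {
      evidence <- "emergent"
    } else if (pre$detected && prog$detected &&
      prog$abundance > fold_change * pre$abundance) {
      evidence <- "increasing"
    } else if (pre$detected && !prog_ctdna_detectable) {
      evidence <- "carried_forward"
    }
    if (!is.null(evidence)) {
      calls[[length(calls) + 1]] <- tibble(
        patient_id = patient_id, alteration = v, gene = g, type = "SNV",
        evidence = evidence, pre_abundance = pre$abundance,
        post_abundance = prog$abundance
      )
    }
  }

  if (!is.null(pre_scna) || !is.null(prog_scna)) {
    candidate_genes <- intersect(
      union(
        if (!is.null(pre_scna)) pre_scna$gene[pre_scna$significant] else character(0),
        if (!is.null(prog_scna)) prog_scna$gene[prog_scna$significant] else character(0)
      ),
      scna_genes
    )
    prog_conclusive <- !is.na(prog_estimate$raw_truncal_vaf) &&
      prog_estimate$raw_truncal_vaf >= ctdna_gate_vaf
    for (g in candidate_genes) {
      pre_row <- if (!is.null(pre_scna)) pre_scna %>% filter(.data$gene == g)
      prog_row <- if (!is.null(prog_scna)) prog_scna %>% filter(.data$gene == g)
      pre_sig <- !is.null(pre_row) && nrow(pre_row) == 1 && pre_row$significant
      prog_sig <- !is.null(prog_row) && nrow(prog_row) == 1 && prog_row$significant
      pre_ab <- if (pre_sig && !is.na(pre_row$normalized_cn)) pre_row$normalized_cn else 0
      prog_ab <- if (prog_sig && !is.na(prog_row$normalized_cn)) prog_row$normalized_cn else 0
      evidence <- NULL
      if (!pre_sig && prog_sig) {
        evidence <- "emergent"
      } else if (pre_sig && prog_sig && prog_ab > fold_change * pre_ab) {
        evidence <- "increasing"
      } else if (pre_sig && !prog_conclusive) {
        evidence <- "carried_forward"
      }
      if (!is.null(evidence)) {
        calls[[length(calls) + 1]] <- tibble(
          patient_id = patient_id, alteration = paste(g, "SCNA"), gene = g,
          type = "SCNA", evidence = evidence, pre_abundance = pre_ab,
          post_abundance = prog_ab
        )
      }
    }
  }
  if (length(calls) == 0) empty else bind_rows(calls) %>% arrange(.data$alteration)
}

#' Classify resistance timing from progression-free survival
#'
#' Progression in under 3 months is innate resistance; longer is
#' acquired. The boundary (exactly 3.0 months, with 30.44 days per
#' month) is assigned to acquired.
#'
#' @param pfs_days Progression-free survival in days (>= 0).
#' @param split_months Boundary in months (default 3).
#' @return `"innate"` or `"acquired"` (vectorized).
#' @export
#' @examples
#' classify_timing(c(60, 120))
classify_timing <- function(pfs_days, split_months = 3) {
  if (any(pfs_days < 0)) abort_validation("pfs_days must be >= 0")
  ifelse(pfs_days / 30.44 < split_months, "innate", "acquired")
}

#' Categorize a patient's resistance mechanisms
#'
#' @param calls [call_resistance()] tibble for one patient.
#' @return `"SCNA_only"`, `"SCNA_plus_SNV"`, `"SNV_only"` or `"none"`.
#' @export
categorize_mechanisms <- function(calls) {
  types <- unique(calls$type)
  if (length(types) == 0) {
    "none"
  } else if (setequal(types, "SCNA")) {
    "SCNA_only"
  } else if (setequal(types, "SNV")) {
    "SNV_only"
  } else {
    "SCNA_plus_SNV"
  }
}

#' MET FISH positivity
#'
#' Tissue criteria for MET amplification: gene-to-centromere (MET/CEP7)
#' ratio at least 2.0, or mean MET signals per tumour cell nucleus at
#' least 6, or at least 10% of tumour cells with 15+ MET signals or
#' large clusters. Any single criterion suffices.
#'
#' @param met_cep7_ratio MET/CEP7 ratio.
#' @param mean_met_signals Mean MET signals per nucleus.
#' @param pct_cells_high Percent of cells with >= 15 signals/clusters.
#' @return `"positive"` or `"negative"` (vectorized).
#' @export
classify_met_fish <- function(met_cep7_ratio, mean_met_signals, pct_cells_high) {
  if (any(c(met_cep7_ratio, mean_met_signals, pct_cells_high) < 0)) {
    abort_validation("FISH inputs must be non-negative")
  }
  ifelse(
    met_cep7_ratio >= 2.0 | mean_met_signals >= 6 | pct_cells_high >= 10,
    "positive", "negative"
  )
}
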