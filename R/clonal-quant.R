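# Variant-level clonal quantification: germline filtering, ctDNA
# fraction estimation, copy-number correction of the activating-driver
# VAF, the binomial limit-of-detection bound, and the
# T790M:activating-mutation ratio with censoring.

#' Filter putative germline variants
#'
#' Plasma-only profiling (no matched germline) removes SNPs by three
#' rules: (1) VAF windows around heterozygous (~50%) and homozygous
#' (~100%) germline frequencies, applied only while the tumour fraction
#' is below `suspend_at` (at very high ctDNA burden a somatic variant
#' can legitimately reach 50%); (2) variants catalogued in a population
#' database (the `blacklisted` flag); (3) restriction to nonsynonymous
#' substitutions. Retained rows carry a `filter_reason` of `"retained"`;
#' set `keep_all = TRUE` to keep removed rows with their reason.
#'
#' @param variants Variant tibble (needs `vaf`, `effect`, `blacklisted`).
#' @param ctdna_fraction Estimated tumour fraction f of the sample
#'   (`NA` treated as low, i.e. windows active).
#' @param het_window Heterozygous-germline VAF window (default
#'   `c(0.40, 0.60)`).
#' @param hom_min Homozygous-germline VAF floor (default 0.90).
#' @param suspend_at Tumour fraction at or above which the VAF windows
#'   are suspended (default 0.40).
#' @param keep_all Return removed rows too, with `filter_reason`.
#' @return Tibble of somatic candidate variants.
#' @export
filter_germline <- function(variants, ctdna_fraction = NA_real_,
                            het_window = c(0.40, 0.60), hom_min = 0.90,
                            suspend_at = 0.40, keep_all = FALSE) {
  check_columns(variants, c("vaf", "effect", "blacklisted"), "variants")
  windows_active <- is.na(ctdna_fraction) || ctdna_fraction < suspend_at
  out <- variants %>%
    mutate(filter_reason = case_when(
      .data$blacklisted ~ "population_blacklist",
      .data$effect != "nonsynonymous" ~ "not_nonsynonymous",
      windows_active & .data$vaf >= het_window[1] & .data$vaf <= het_window[2] ~
        "germline_het_window",
      windows_active & .data$vaf >= hom_min ~ "germline_hom_window",
      TRUE ~ "retained"
    ))
  if (keep_all) out else filter(out, .data$filter_reason == "retained")
}

#' Copy-number-corrected activating-mutation VAF
#'
#' When the activating driver's gene carries a significant copy-number
#' gain, its raw VAF overstates clonal abundance because the amplified
#' allele is over-represented in plasma. Under the model that the
#' amplified copies carry the activating mutation, the raw VAF is
#' `f * CN / (2 r)`, so the heterozygous-equivalent VAF the sample
#' would show without amplification is `raw * r / CN` (which doubles to
#' the tumour fraction f). Without a significant gain the raw VAF is
#' returned unchanged.
#'
#' @param raw_vaf Observed VAF of the activating mutation.
#' @param relative_depth Linear relative depth r of the gene.
#' @param normalized_cn Normalized copy number CN of the gene.
#' @param significant Is the gene's copy-number call significant?
#' @return Corrected VAF.
#' @export
#' @examples
#' corrected_activating_vaf(0.5263, 1.9, 20, significant = TRUE) # 0.05
corrected_activating_vaf <- function(raw_vaf, relative_depth, normalized_cn,
                                     significant = TRUE) {
  if (!isTRUE(significant)) {
    return(raw_vaf)
  }
  if (any(normalized_cn <= 0)) abort_validation("normalized_cn must be > 0")
  raw_vaf * relative_depth / normalized_cn
}

#' Estimate the ctDNA fraction of a sample
#'
#' Uses a truncal TP53 mutation when present (truncal in NSCLC, so its
#' VAF reflects all tumour cells): `f = min(1, 2 * VAF)` under the
#' heterozygous-clonal assumption. Otherwise falls back to the
#' EGFR-activating mutation, corrected for excess EGFR coverage when a
#' significant EGFR gain is called; the correction and fraction are
#' solved jointly with the mixture model, giving the closed form
#' `f = 1 + r * (raw - 1)` for a fully mutant amplified gene. With
#' neither variant class available the source is `"none"` and `f` is
#' `NA`.
#'
#' @param variants Variant tibble for one sample (`class`, `vaf`).
#' @param scna_calls Optional [call_scna()] tibble for the sample (used
#'   for the EGFR correction).
#' @param mode `"double_vaf"` (default; f = 2 * VAF) or `"raw_vaf"`
#'   (f = VAF, for workflows that treat %ctDNA and VAF as synonyms).
#' @return One-row tibble: `ctdna_fraction`, `raw_truncal_vaf`, `source`.
#' @export
estimate_ctdna_fraction <- function(variants, scna_calls = NULL,
                                    mode = c("double_vaf", "raw_vaf")) {
  mode <- match.arg(mode)
  mult <- if (mode == "double_vaf") 2 else 1
  detected <- variants %>% filter(.data$alt_reads > 0 | .data$vaf > 0)
  tp53 <- detected %>% filter(.data$class == "truncal_TP53")
  if (nrow(tp53) > 0) {
    v <- max(tp53$vaf)
    return(tibble(
      ctdna_fraction = min(1, mult * v), raw_truncal_vaf = v,
      source = "TP53_truncal"
    ))
  }
  act <- detected %>% filter(.data$class == "activating")
  if (nrow(act) > 0) {
    raw <- max(act$vaf)
    corr <- raw
    egfr <- if (!is.null(scna_calls)) {
      scna_calls %>% filter(.data$gene == "EGFR", .data$significant)
    }
    if (!is.null(egfr) && nrow(egfr) == 1 && is.finite(egfr$relative_depth)) {
      r <- egfr$relative_depth
      # joint solution of f = 2 raw r / CN and CN = 2 + 2 (r - 1) / f
      f <- min(1, max(0, 1 + r * (raw - 1)))
      corr <- f / mult
      return(tibble(
        ctdna_fraction = f, raw_truncal_vaf = raw,
        source = "EGFR_activating_corrected"
      ))
    }
    return(tibble(
      ctdna_fraction = min(1, mult * corr), raw_truncal_vaf = raw,
      source = "EGFR_activating_corrected"
    ))
  }
  tibble(
    ctdna_fraction = NA_real_, raw_truncal_vaf = NA_real_, source = "none"
  )
}

#' Binomial limit-of-detection VAF bound
#'
#' The smallest allele fraction `v` at which a variant would be
#' observed with at least `min_supporting_reads` supporting reads with
#' probability >= `confidence`, under a binomial read-count model at
#' the sequenced depth of the locus. For a single supporting read the
#' closed form is `v = 1 - (1 - confidence)^(1/depth)`; otherwise the
#' bound is solved by bisection on the monotone binomial tail.
#'
#' @param depth Read depth at the locus (> 0).
#' @param min_supporting_reads Required supporting reads s (default 2).
#' @param confidence Detection probability (default 0.95).
#' @param tol Bisection tolerance on v.
#' @return The VAF bound.
#' @export
#' @examples
#' lod_vaf(3000, min_supporting_reads = 1) # 1 - 0.05^(1/3000)
lod_vaf <- function(depth, min_supporting_reads = 2, confidence = 0.95,
                    tol = 1e-12) {
  stopifnot(min_supporting_reads >= 1, confidence > 0, confidence < 1)
  if (any(depth <= 0)) abort_validation("depth must be > 0")
  depth <- round(depth)
  s <- min_supporting_reads
  if (s == 1) {
    return(1 - (1 - confidence)^(1 / depth))
  }
  vapply(depth, function(n) {
    if (n < s) {
      return(1) # cannot reach s reads reliably below depth s
    }
    tail_prob <- function(v) pbinom(s - 1, n, v, lower.tail = FALSE)
    lo <- 0
    hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (tail_prob(mid) >= confidence) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

#' T790M : activating-mutation ratio for one sample
#'
#' The ratio of the gatekeeper resistance mutation's VAF to the
#' (copy-number-corrected) activating mutation's VAF tracks the share
#' of the tumour carried by the T790M subclone. When T790M is not
#' detected, its VAF is censored at the lower of (1) the binomial
#' limit-of-detection bound at the T790M locus depth and (2) the
#' corrected activating VAF (equivalent to assuming a ratio of 1), so a
#' censored ratio is an upper bound and never exceeds 1. Samples are
#' grouped `low`/`high` at `cutpoint` (default 0.5).
#'
#' @param variants Variant tibble for one sample.
#' @param scna_calls Optional [call_scna()] tibble for the sample.
#' @param cutpoint Ratio grouping threshold (default 0.5).
#' @param min_supporting_reads Passed to [lod_vaf()] for censoring.
#' @return One-row tibble: `vaf_t790m`, `vaf_activating_corrected`,
#'   `ratio`, `censored`, `group`.
#' @export
t790m_ratio <- function(variants, scna_calls = NULL, cutpoint = 0.5,
                        min_supporting_reads = 2) {
  act <- variants %>%
    filter(.data$class == "activating", .data$alt_reads > 0 | .data$vaf > 0)
  if (nrow(act) == 0) {
    abort_validation("no activating mutation detected: ratio not evaluable")
  }
  raw_act <- max(act$vaf)
  egfr <- if (!is.null(scna_calls)) {
    scna_calls %>% filter(.data$gene == "EGFR", .data$significant)
  }
  act_corr <- if (!is.null(egfr) && nrow(egfr) == 1 &&
    is.finite(egfr$normalized_cn %||% NA_real_) && !is.na(egfr$normalized_cn)) {
    corrected_activating_vaf(raw_act, egfr$relative_depth, egfr$normalized_cn)
  } else {
    raw_act
  }
  t790m <- variants %>% filter(.data$class == "T790M")
  detected <- nrow(t790m) > 0 && any(t790m$alt_reads > 0 | t790m$vaf > 0)
  if (detected) {
    v_t <- max(t790m$vaf[t790m$alt_reads > 0 | t790m$vaf > 0])
    censored <- FALSE
  } else {
    locus_depth <- if (nrow(t790m) > 0 && !is.na(t790m$depth[1])) {
      t790m$depth[1]
    } else {
      act$depth[which.max(act$vaf)] # same-gene capture depth as proxy
    }
    lod <- lod_vaf(locus_depth, min_supporting_reads = min_supporting_reads)
    v_t <- min(lod, act_corr)
    censored <- TRUE
  }
  ratio <- v_t / act_corr
  tibble(
    vaf_t790m = v_t, vaf_activating_corrected = act_corr, ratio = ratio,
    censored = censored, group = ifelse(ratio <= cutpoint, "low", "high")
  )
}

#' Ratio trajectory across a patient's timepoints
#'
#' Computes the T790M:activating ratio at every evaluable timepoint and
#' the signed percent change between pretreatment and progression.
#' Eligibility mirrors the clonal-selection analysis: T790M must be
#' detected pretreatment and the activating mutation at both endpoints;
#' patients whose progression activating VAF falls below
#' `activating_floor` are flagged not evaluable (the change cannot be
#' measured accurately).
#'
#' @param patient_variants Variant tibble for one patient (all
#'   timepoints; needs `timepoint`).
#' @param scna_by_sample Optional named list of [call_scna()] tibbles,
#'   keyed by `sample_id`.
#' @param activating_floor Progression activating-VAF evaluability
#'   floor (default 0.003, i.e. 0.3%).
#' @param ... Passed to [t790m_ratio()].
#' @return List with `per_timepoint` (tibble of ratios), `pct_change`,
#'   `direction` (`decreased`/`increased`/`unchanged`) and `evaluable`.
#' @export
ratio_trajectory <- function(patient_variants, scna_by_sample = NULL,
                             activating_floor = 0.003, ...) {
  tps <- patient_variants %>%
    distinct(.data$timepoint, .data$sample_id, .data$day) %>%
    arrange(.data$day)
  per_tp <- purrr::map_dfr(seq_len(nrow(tps)), function(i) {
    v <- patient_variants %>% filter(.data$sample_id == tps$sample_id[i])
    sc <- scna_by_sample[[tps$sample_id[i]]]
    res <- tryCatch(t790m_ratio(v, scna_calls = sc, ...),
      ctdnaprof_validation_error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble())
    }
    dplyr::bind_cols(tps[i, ], res)
  })
  need <- c("pretreatment", "progression")
  if (!all(need %in% per_tp$timepoint)) {
    return(list(
      per_timepoint = per_tp, pct_change = NA_real_,
      direction = NA_character_, evaluable = FALSE,
      reason = "missing endpoint"
    ))
  }
  pre <- per_tp %>% filter(.data$timepoint == "pretreatment")
  prog <- per_tp %>% filter(.data$timepoint == "progression")
  pre_t790m_detected <- !pre$censored
  prog_act <- prog$vaf_activating_corrected
  evaluable <- pre_t790m_detected && prog_act >= activating_floor
  pct <- 100 * (prog$ratio - pre$ratio) / pre$ratio
  list(
    per_timepoint = per_tp,
    pct_change = if (evaluable) pct else NA_real_,
    direction = if (!evaluable) {
      NA_character_
    } else if (pct < 0) {
      "decreased"
    } else if (pct > 0) "increased" else "unchanged",
    evaluable = evaluable,
    reason = if (evaluable) NA_character_ else if (!pre_t790m_detected) {
      "T790M not detected pretreatment"
    } else {
      "progression activating VAF below evaluability floor"
    }
  )
}

#' ROC-optimal ratio cut-point for predicting partial response
#'
#' Scans midpoints between consecutive sorted unique baseline ratios
#' and returns the candidate maximizing Youden's J (sensitivity +
#' specificity - 1) for predicting partial response, where a high
#' baseline T790M:activating ratio predicts response to a
#' T790M-selective inhibitor. Ties take the smallest candidate.
#'
#' @param ratios Baseline ratio per patient.
#' @param response Logical (or 0/1) partial-response indicator
#'   (>= 30% target-lesion shrinkage).
#' @return List: `cutpoint`, `youden_j`, and the candidate grid.
#' @export
#' @examples
#' roc_cutpoint(c(0.2, 0.3, 0.9, 1.0), c(0, 0, 1, 1)) # cutpoint 0.6
roc_cutpoint <- function(ratios, response) {
  response <- as.logical(response)
  stopifnot(length(ratios) == length(response))
  if (length(unique(response)) < 2) {
    abort_validation("need at least one responder and one non-responder")
  }
  u <- sort(unique(ratios))
  if (length(u) < 2) abort_validation("need at least two distinct ratios")
  candidates <- (head(u, -1) + tail(u, -1)) / 2
  j <- vapply(candidates, function(t) {
    pred <- ratios >= t
    sens <- sum(pred & response) / sum(response)
    spec <- sum(!pred & !response) / sum(!response)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1] # smallest candidate wins ties
  list(cutpoint = candidates[best], youden_j = j[best],
    candidates = candidates, j = j)
}
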