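# End-to-end orchestration over a study bundle: germline filtering,
# per-sample copy-number calls and ctDNA estimates, ratio
# trajectories, and resistance-mechanism calls per patient.

#' Profile resistance mechanisms across a study bundle
#'
#' Runs the full analysis chain for every patient with both a
#' pretreatment and a progression sample: fits (or reuses) the
#' healthy-control depth model, filters putative germline variants,
#' estimates each sample's ctDNA fraction, calls gene-level
#' copy-number alterations, computes the T790M:activating ratio
#' trajectory, applies the resistance rules, and classifies timing
#' from progression-free survival.
#'
#' @param bundle A [load_study()] result (or an equivalent list built
#'   in code with the same components).
#' @param model Optional pre-fitted `control_model`; fitted from the
#'   bundle's control cohort when `NULL`.
#' @param ctdna_gate_vaf Adequacy gate for conclusive SCNA analysis.
#' @param fold_change Minimal abundance fold change for "increasing".
#' @param split_months Innate/acquired PFS boundary in months.
#' @return List of tibbles: `estimates` (per sample), `scna_calls`
#'   (per sample x gene), `ratios` (per patient), `mechanisms`
#'   (resistance calls with timing and category), and the fitted
#'   `model`.
#' @export
profile_resistance <- function(bundle, model = NULL, ctdna_gate_vaf = 0.02,
                               fold_change = 1, split_months = 3) {
  selector <- bundle$selector
  model <- model %||% fit_control_model(bundle$control_depths, selector)
  variants <- bundle$variants
  if (is.null(variants)) abort_validation("bundle has no variant table")

  sample_ids <- unique(variants$sample_id)
  per_sample <- purrr::map(setNames(sample_ids, sample_ids), function(sid) {
    v <- variants %>% filter(.data$sample_id == sid)
    est0 <- estimate_ctdna_fraction(v)
    vf <- filter_germline(v, ctdna_fraction = est0$ctdna_fraction)
    sc <- NULL
    if (!is.null(bundle$patient_depths) &&
      sid %in% bundle$patient_depths$sample_id) {
      row <- bundle$patient_depths %>% filter(.data$sample_id == sid)
      sc0 <- call_scna(row, model, selector,
        ctdna_gate_vaf = ctdna_gate_vaf,
        truncal_vaf = est0$raw_truncal_vaf
      )
      est <- estimate_ctdna_fraction(vf, scna_calls = sc0)
      sc <- call_scna(row, model, selector,
        ctdna_gate_vaf = ctdna_gate_vaf,
        truncal_vaf = est$raw_truncal_vaf,
        ctdna_fraction = if (!is.na(est$ctdna_fraction) &&
          est$ctdna_fraction > 0) {
          est$ctdna_fraction
        } else {
          NULL
        }
      )
    } else {
      est <- estimate_ctdna_fraction(vf)
    }
    list(variants = vf, estimate = est, scna = sc)
  })

  estimates <- purrr::imap_dfr(per_sample, function(x, sid) {
    x$estimate %>% mutate(sample_id = sid)
  }) %>% select("sample_id", dplyr::everything())
  scna_calls <- purrr::map_dfr(per_sample, "scna")

  patients <- variants %>%
    distinct(.data$patient_id, .data$sample_id, .data$timepoint, .data$day)
  pids <- unique(patients$patient_id)

  ratios <- list()
  mechanisms <- list()
  for (pid in pids) {
    tp <- patients %>% filter(.data$patient_id == pid)
    pre_id <- tp$sample_id[tp$timepoint == "pretreatment"]
    prog_id <- tp$sample_id[tp$timepoint == "progression"]
    if (length(pre_id) != 1 || length(prog_id) != 1) next
    pv <- variants %>% filter(.data$patient_id == pid)
    scna_by_sample <- purrr::map(
      setNames(tp$sample_id, tp$sample_id),
      ~ per_sample[[.x]]$scna
    )
    traj <- ratio_trajectory(pv, scna_by_sample = scna_by_sample)
    ratios[[pid]] <- tibble(
      patient_id = pid,
      pre_ratio = traj$per_timepoint$ratio[
        traj$per_timepoint$timepoint == "pretreatment"
      ][1] %||% NA_real_,
      progression_ratio = traj$per_timepoint$ratio[
        traj$per_timepoint$timepoint == "progression"
      ][1] %||% NA_real_,
      pct_change = traj$pct_change, direction = traj$direction,
      evaluable = traj$evaluable
    )
    mech <- call_resistance(
      pre_variants = per_sample[[pre_id]]$variants,
      prog_variants = per_sample[[prog_id]]$variants,
      pre_scna = per_sample[[pre_id]]$scna,
      prog_scna = per_sample[[prog_id]]$scna,
      pre_estimate = per_sample[[pre_id]]$estimate,
      prog_estimate = per_sample[[prog_id]]$estimate,
      fold_change = fold_change, ctdna_gate_vaf = ctdna_gate_vaf,
      patient_id = pid
    )
    mech$category <- categorize_mechanisms(mech)
    if (!is.null(bundle$patients) && pid %in% bundle$patients$patient_id) {
      pfs <- bundle$patients$pfs_days[bundle$patients$patient_id == pid]
      mech$timing <- if (!is.na(pfs)) {
        classify_timing(pfs, split_months = split_months)
      } else {
        NA_character_
      }
    } else {
      mech$timing <- NA_character_
    }
    mechanisms[[pid]] <- mech
  }

  list(
    estimates = estimates,
    scna_calls = scna_calls,
    ratios = bind_rows(ratios),
    mechanisms = bind_rows(mechanisms),
    model = model
  )
}
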