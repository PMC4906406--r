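# Longitudinal patient scenarios for exercising the clonal-ratio and
# resistance-rule stages. Each scenario plants a known ground truth
# (mechanism labels) so rule recovery can be measured.

.scenarios <- c(
  "t790m_depletion", "emergent_met", "increasing_snv",
  "mixed_mechanisms", "null"
)

#' Default scenario parameters
#'
#' Tumour fractions and clonal fractions used by [gen_patient_series()].
#' The depletion scenario is parameterized so the gatekeeper-mutant
#' subclone falls from ~85% of the tumour before treatment to ~25% at
#' progression (a median ratio drop well above 50%), emulating strong
#' negative selection of that subclone by a mutant-selective inhibitor.
#'
#' @return Named list of parameters.
#' @export
scenario_params <- function() {
  list(
    f_pre = 0.10, f_on = 0.03, f_prog = 0.12,
    t790m_cf_pre = c(0.75, 0.95), t790m_cf_prog = c(0.15, 0.35),
    t790m_cf_stable = c(0.75, 0.95),
    met_cn_pre = 4, met_cn_prog = 9,
    snv_cf_pre = 0.15, snv_cf_prog = 0.70,
    pfs_days = c(50, 300), best_response = c(-60, 20)
  )
}

#' Generate a longitudinal synthetic patient
#'
#' Produces pretreatment, on-treatment and progression plasma samples
#' for one patient under a named clonal-evolution scenario:
#'
#' * `t790m_depletion` — the T790M subclone shrinks under therapy while
#'   the activating mutation persists; no resistance alteration planted.
#' * `emergent_met` — no MET gain before treatment; a MET copy-number
#'   event appears at progression.
#' * `increasing_snv` — a PIK3CA subclonal mutation rises in relative
#'   abundance from pretreatment to progression.
#' * `mixed_mechanisms` — a pre-existing MET gain increases and a KRAS
#'   mutation emerges at progression.
#' * `null` — stable clonal composition; nothing satisfies the
#'   resistance rules.
#'
#' @param scenario One of the scenario names above.
#' @param params List as from [scenario_params()] (entries may be
#'   overridden).
#' @param seed Integer seed for this patient.
#' @param config A [sim_config()] describing selector/noise; its
#'   `genes` must include EGFR, MET, TP53 and PIK3CA/KRAS.
#' @param selector Optional pre-built selector (saves rebuilding in
#'   cohort loops); must match `config$genes`.
#' @param patient_id Identifier for the patient.
#' @param include_depths If `FALSE`, skip depth-row generation (the
#'   variant series alone supports ratio analyses).
#' @return List with `patient`, `timepoints`, `variants`, `depths`
#'   (possibly `NULL`) and `truth` (planted mechanism labels).
#' @export
gen_patient_series <- function(scenario, params = scenario_params(),
                               seed = 1L, config = sim_config(seed = seed),
                               selector = NULL, patient_id = "P1",
                               include_depths = TRUE) {
  if (!scenario %in% .scenarios) {
    abort_validation(sprintf(
      "unknown scenario '%s' (expected one of: %s)",
      scenario, paste(.scenarios, collapse = ", ")
    ))
  }
  p <- utils::modifyList(scenario_params(), params)
  selector <- selector %||% gen_selector(config$genes, seed = config$seed)

  draws <- withr::with_seed(derive_seed(seed, paste0("patient_", patient_id)), {
    list(
      cf_pre = runif(1, p$t790m_cf_pre[1], p$t790m_cf_pre[2]),
      cf_prog = runif(1, p$t790m_cf_prog[1], p$t790m_cf_prog[2]),
      cf_stable = runif(1, p$t790m_cf_stable[1], p$t790m_cf_stable[2]),
      pfs = round(runif(1, p$pfs_days[1], p$pfs_days[2])),
      br = runif(1, p$best_response[1], p$best_response[2])
    )
  })
  t790m_cf <- switch(scenario,
    t790m_depletion = c(draws$cf_pre, mean(c(draws$cf_pre, draws$cf_prog)), draws$cf_prog),
    rep(draws$cf_stable, 3)
  )
  met_cn <- switch(scenario,
    emergent_met = c(2, 2, p$met_cn_prog),
    mixed_mechanisms = c(p$met_cn_pre, p$met_cn_pre, p$met_cn_prog),
    c(2, 2, 2)
  )
  snv <- switch(scenario,
    increasing_snv = list(
      gene = "PIK3CA", variant = "PIK3CA E545K", cf = c(p$snv_cf_pre, p$snv_cf_pre, p$snv_cf_prog)
    ),
    mixed_mechanisms = list(
      gene = "KRAS", variant = "KRAS G12A", cf = c(0, 0, p$snv_cf_prog)
    ),
    NULL
  )

  fractions <- c(p$f_pre, p$f_on, p$f_prog)
  labels <- c("pretreatment", "on_treatment", "progression")
  days <- c(0, 21, max(draws$pfs, 42))

  out <- purrr::map(1:3, function(k) {
    vars <- tibble(
      gene = c("EGFR", "EGFR", "TP53"),
      variant = c("EGFR L858R", "EGFR T790M", "TP53 R175H"),
      class = c("activating", "T790M", "truncal_TP53"),
      clone_fraction = c(1, t790m_cf[k], 1),
      mutant_copies = 1
    )
    if (!is.null(snv) && snv$cf[k] > 0) {
      vars <- bind_rows(vars, tibble(
        gene = snv$gene, variant = snv$variant, class = "other",
        clone_fraction = snv$cf[k], mutant_copies = 1
      ))
    }
    prof <- tumour_profile(
      cn_events = c(MET = met_cn[k]),
      variants = vars
    )
    sid <- sprintf("%s_%s", patient_id, labels[k])
    smp <- gen_tumour_sample(selector, prof, fractions[k], config,
      sample_id = sid, sample_seed = derive_seed(seed, sid)
    )
    if (!include_depths) smp$depths <- NULL
    smp$variants <- smp$variants %>%
      mutate(patient_id = .env$patient_id, timepoint = labels[k], day = days[k]) %>%
      select(
        "sample_id", "patient_id", "timepoint", "day", "gene", "variant",
        "class", "vaf", "depth", "alt_reads", "effect", "blacklisted",
        "expected_vaf"
      )
    smp
  })

  truth <- switch(scenario,
    emergent_met = tibble(
      alteration = "MET SCNA", gene = "MET", type = "SCNA", evidence = "emergent"
    ),
    increasing_snv = tibble(
      alteration = "PIK3CA E545K", gene = "PIK3CA", type = "SNV",
      evidence = "increasing"
    ),
    mixed_mechanisms = tibble(
      alteration = c("MET SCNA", "KRAS G12A"), gene = c("MET", "KRAS"),
      type = c("SCNA", "SNV"), evidence = c("increasing", "emergent")
    ),
    tibble(
      alteration = character(0), gene = character(0), type = character(0),
      evidence = character(0)
    )
  )

  list(
    patient = tibble(
      patient_id = patient_id, pfs_days = draws$pfs, progression_event = TRUE,
      best_response_pct = draws$br, met_fish_status = "unknown"
    ),
    timepoints = tibble(
      label = labels, day = days,
      sample_id = sprintf("%s_%s", patient_id, labels)
    ),
    variants = bind_rows(purrr::map(out, "variants")),
    depths = if (include_depths) bind_rows(purrr::map(out, "depths")),
    truth = truth,
    scenario = scenario,
    tumour_fractions = setNames(fractions, labels)
  )
}
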