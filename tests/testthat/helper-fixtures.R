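# Shared fixtures, memoised so the control-model fit is paid once per run.

.fixture_cache <- new.env(parent = emptyenv())

# default-configuration study: selector, control cohort, fitted model
fx_study <- function(seed = 1L, n_controls = 27L) {
  key <- sprintf("study_%d_%d", seed, n_controls)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(seed = seed, n_controls = n_controls)
    sel <- gen_selector(cfg$genes, seed = seed)
    ctrl <- gen_control_cohort(sel, cfg)
    model <- suppressWarnings(fit_control_model(ctrl, sel))
    .fixture_cache[[key]] <- list(
      cfg = cfg, selector = sel, controls = ctrl, model = model
    )
  }
  .fixture_cache[[key]]
}

# cohort with held-out controls: fit on the first `n_fit`, return the rest
fx_heldout <- function(seed = 1L, n_fit = 27L, n_held = 200L) {
  key <- sprintf("held_%d_%d_%d", seed, n_fit, n_held)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(seed = seed, n_controls = n_fit + n_held)
    sel <- gen_selector(cfg$genes, seed = seed)
    all <- gen_control_cohort(sel, cfg)
    ids <- unique(all$sample_id)
    fit <- dplyr::filter(all, sample_id %in% ids[seq_len(n_fit)])
    held <- dplyr::filter(all, sample_id %in% ids[-seq_len(n_fit)])
    model <- suppressWarnings(fit_control_model(fit, sel))
    .fixture_cache[[key]] <- list(
      cfg = cfg, selector = sel, fit_depths = fit, held_depths = held,
      model = model
    )
  }
  .fixture_cache[[key]]
}

# spike grid for a single-gene amplification profile, memoised
fx_spike <- function(gene, cn, seed = 1L, fractions = spike_fractions()) {
  key <- sprintf("spike_%s_%g_%d_%s", gene, cn, seed,
    paste(fractions, collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    st <- fx_study(seed = seed)
    design <- spike_design(
      fractions = fractions,
      backgrounds = unique(st$controls$sample_id),
      profile = tumour_profile(cn_events = stats::setNames(cn, gene)),
      genes_under_test = stats::setNames(cn, gene),
      seed = seed
    )
    .fixture_cache[[key]] <- run_spike_grid(
      design, st$model, st$controls, st$selector, st$cfg
    )
  }
  .fixture_cache[[key]]
}

# minimal on-disk study for I/O tests
fx_study_files <- function(dir) {
  sel <- tibble::tibble(
    region_id = c("TP53|1", "TP53|2", "EGFR|1"),
    gene = c("TP53", "TP53", "EGFR"),
    chrom = c("chr17", "chr17", "chr7"),
    start = c(100L, 500L, 900L), end = c(200L, 650L, 1100L),
    autosomal = TRUE
  )
  write_selector(sel, file.path(dir, "selector.bed"))
  write_depths(
    tibble::tibble(
      sample_id = "S1", region_id = sel$region_id, depth = c(100, 200, 400)
    ),
    file.path(dir, "depths.tsv"), region_order = sel$region_id
  )
  readr::write_tsv(
    tibble::tibble(
      sample_id = "S1", patient_id = "P1", timepoint = "pretreatment",
      day = 0, gene = "TP53", variant = "TP53 R175H", class = "truncal_TP53",
      vaf = 0.1, depth = 1000, alt_reads = 100, effect = "nonsynonymous"
    ),
    file.path(dir, "variants.tsv")
  )
  readr::write_tsv(
    tibble::tibble(
      patient_id = "P1", pfs_days = 120, progression_event = TRUE,
      best_response_pct = -35, met_fish_status = "unknown"
    ),
    file.path(dir, "patients.tsv")
  )
  invisible(sel)
}
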