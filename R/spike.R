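# In-silico spike-in benchmark: mixing tumour depth profiles into
# healthy-control backgrounds at defined ctDNA fractions and measuring
# sensitivity / specificity of the copy-number caller.

#' The dilution series used by the spike benchmark
#'
#' Twelve ctDNA percentages spanning 0.1% to 10%.
#'
#' @return Numeric vector of percentages.
#' @export
spike_fractions <- function() {
  c(0.1, 0.3, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 2.5, 5, 10)
}

#' Mix a tumour depth profile into a control background
#'
#' Both depth rows are first scaled to their own autosomal median
#' (genome-equivalent equalization, so a deeply sequenced tumour does
#' not contribute more genomes than intended), mixed linearly at
#' fraction `f`, and rescaled to the control's original autosomal
#' median, preserving the quantity the copy-number index consumes.
#' Optional variant rows have alt reads re-drawn binomially at the
#' mixed depth with the mixture-weighted expected VAF.
#'
#' @param control_row,tumour_row Depth tibbles (`region_id`, `depth`)
#'   on the same selector.
#' @param fraction Tumour fraction f between 0 and 1.
#' @param selector Selector tibble.
#' @param control_variants,tumour_variants Optional variant tibbles
#'   (need `gene`, `variant`, `class`, `vaf`).
#' @param seed Seed for the variant re-draw.
#' @return List with `depths` (mixed row) and `variants` (or `NULL`).
#' @export
mix_sample <- function(control_row, tumour_row, fraction, selector,
                       control_variants = NULL, tumour_variants = NULL,
                       seed = 1L) {
  f <- fraction
  stopifnot(f >= 0, f <= 1)
  cd <- control_row$depth[match(selector$region_id, control_row$region_id)]
  td <- tumour_row$depth[match(selector$region_id, tumour_row$region_id)]
  if (anyNA(cd) || anyNA(td)) {
    abort_validation("depth rows do not match the selector")
  }
  auto <- selector$autosomal
  cmed <- median(cd[auto])
  tmed <- median(td[auto])
  if (cmed <= 0 || tmed <= 0) abort_validation("zero autosomal median depth")
  mixed_rel <- (1 - f) * cd / cmed + f * td / tmed
  # rescale so the mixed sample keeps the control's autosomal median
  mixed_rel <- mixed_rel / median(mixed_rel[auto])
  sid <- if ("sample_id" %in% names(control_row)) {
    sprintf("%s_f%g", control_row$sample_id[1], 100 * f)
  } else {
    sprintf("mix_f%g", 100 * f)
  }
  depths <- tibble(
    sample_id = sid, region_id = selector$region_id,
    depth = mixed_rel * cmed
  )
  variants <- NULL
  if (!is.null(tumour_variants)) {
    tv <- tumour_variants
    first_region <- selector$region_id[match(tv$gene, selector$gene)]
    mix_depth <- round(depths$depth[match(first_region, depths$region_id)])
    ctrl_vaf <- if (is.null(control_variants)) 0 else {
      cv <- control_variants
      m <- match(paste(tv$gene, tv$variant), paste(cv$gene, cv$variant))
      ifelse(is.na(m), 0, cv$vaf[m])
    }
    # mixture-weighted expected VAF in genome-equivalent space
    rel_c <- cd[match(first_region, selector$region_id)] / cmed
    rel_t <- td[match(first_region, selector$region_id)] / tmed
    mix_vaf <- ((1 - f) * rel_c * ctrl_vaf + f * rel_t * tv$vaf) /
      ((1 - f) * rel_c + f * rel_t)
    variants <- withr::with_seed(derive_seed(seed, sid), {
      alt <- rbinom(length(mix_depth), mix_depth, pmin(pmax(mix_vaf, 0), 1))
      tibble(
        sample_id = sid, gene = tv$gene, variant = tv$variant,
        class = tv$class, depth = as.numeric(mix_depth),
        alt_reads = as.numeric(alt),
        vaf = ifelse(mix_depth > 0, alt / mix_depth, 0),
        effect = "nonsynonymous", blacklisted = FALSE
      )
    })
  }
  list(depths = depths, variants = variants)
}

#' Build a spike benchmark design
#'
#' @param fractions ctDNA percentages in (0, 100].
#' @param backgrounds Character vector of background control sample ids.
#' @param profile [tumour_profile()] to spike.
#' @param genes_under_test Named numeric vector gene -> true copy
#'   number (truth labels for scoring).
#' @param seed Integer seed.
#' @return A `spike_design` list.
#' @export
spike_design <- function(fractions = spike_fractions(), backgrounds,
                         profile, genes_under_test, seed = 1L) {
  if (any(fractions <= 0 | fractions > 100)) {
    abort_validation("fractions must be percentages in (0, 100]")
  }
  if (length(backgrounds) == 0) abort_validation("at least one background")
  structure(
    list(
      fractions = fractions, backgrounds = backgrounds, profile = profile,
      genes_under_test = genes_under_test, seed = as.integer(seed)
    ),
    class = "spike_design"
  )
}

#' Run the spike benchmark grid
#'
#' Generates a pure-tumour depth row from the design's profile, mixes
#' it into every background at every fraction, scores each mixed sample
#' with [call_scna()] against the supplied control model, and records
#' the per-gene index and detection flag with truth labels. The record
#' count is `|backgrounds| x |fractions| x |genes under test|`.
#'
#' @param design A [spike_design()].
#' @param model [fit_control_model()] fitted on the backgrounds' cohort.
#' @param control_depths Long depth tibble holding the background rows.
#' @param selector Selector tibble.
#' @param config [sim_config()] for the tumour row's noise model.
#' @return A `spike_result` tibble: one row per (background, fraction,
#'   gene) with `index`, `threshold`, `detected`, `true_cn`, `spiked`.
#' @export
run_spike_grid <- function(design, model, control_depths, selector,
                           config = sim_config(seed = design$seed)) {
  tumour <- gen_tumour_sample(
    selector, design$profile,
    tumour_fraction = 1, config,
    sample_id = "SPIKE_TUMOUR",
    sample_seed = derive_seed(design$seed, "spike_tumour")
  )
  genes <- names(design$genes_under_test)
  grid <- tidyr::expand_grid(
    background = design$backgrounds, fraction_pct = design$fractions
  )
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    bg <- grid$background[i]
    fr <- grid$fraction_pct[i]
    ctrl <- control_depths %>% filter(.data$sample_id == bg)
    mixed <- mix_sample(ctrl, tumour$depths, fr / 100, selector,
      seed = derive_seed(design$seed, sprintf("%s_%g", bg, fr))
    )
    calls <- call_scna(mixed$depths, model, selector)
    calls %>%
      filter(.data$gene %in% genes) %>%
      mutate(background = bg, fraction_pct = fr)
  })
  res %>%
    mutate(
      detected = .data$significant,
      true_cn = design$genes_under_test[.data$gene],
      spiked = TRUE
    ) %>%
    select(
      "background", "fraction_pct", "gene", "index", "threshold",
      "detected", "true_cn", "spiked"
    ) %>%
    structure(class = c("spike_result", class(tibble())))
}

#' Score unspiked control samples against a model
#'
#' Used to measure specificity: each control is called with
#' [call_scna()] and per-gene detection flags recorded.
#'
#' @param control_depths Long depth tibble of (held-out) controls.
#' @param model A fitted `control_model`.
#' @param selector Selector tibble.
#' @param genes Genes to report (default: all model genes).
#' @return Tibble: `sample_id`, `gene`, `index`, `detected`.
#' @export
score_controls <- function(control_depths, model, selector, genes = NULL) {
  control_depths %>%
    dplyr::group_split(.data$sample_id) %>%
    purrr::map_dfr(function(s) {
      call_scna(s, model, selector) %>%
        mutate(sample_id = s$sample_id[1])
    }) %>%
    filter(if (is.null(genes)) TRUE else .data$gene %in% genes) %>%
    mutate(detected = .data$significant) %>%
    select("sample_id", "gene", "index", "detected")
}

#' Sensitivity and specificity of spike detection
#'
#' Sensitivity per gene and fraction bin is the share of spiked samples
#' detected; specificity is one minus the per-gene false-positive rate
#' on unspiked controls. Exact binomial confidence intervals are
#' attached; empty bins yield `NA` metrics with a flag.
#'
#' @param spike_results [run_spike_grid()] output.
#' @param control_results [score_controls()] output (for specificity);
#'   may be `NULL`.
#' @param bins Optional numeric breaks for fraction bins (percent); by
#'   default each distinct fraction is its own bin.
#' @param conf_level Confidence level for the binomial intervals.
#' @return Tibble per gene (and per bin for sensitivity) with
#'   `metric`, `value` (percent), `n`, `ci_lo`, `ci_hi`, `empty`.
#' @export
sensitivity_specificity <- function(spike_results, control_results = NULL,
                                    bins = NULL, conf_level = 0.95) {
  binom_ci <- function(x, n) {
    if (n == 0) {
      return(c(NA_real_, NA_real_))
    }
    ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
    100 * as.numeric(ci)
  }
  sr <- spike_results %>%
    mutate(bin = if (is.null(bins)) {
      as.character(.data$fraction_pct)
    } else {
      as.character(cut(.data$fraction_pct, breaks = bins, include.lowest = TRUE))
    })
  sens <- sr %>%
    group_by(.data$gene, .data$bin) %>%
    summarise(
      n = dplyr::n(), x = sum(.data$detected), .groups = "drop"
    ) %>%
    mutate(
      metric = "sensitivity",
      value = ifelse(.data$n > 0, 100 * .data$x / .data$n, NA_real_),
      ci_lo = purrr::map2_dbl(.data$x, .data$n, ~ binom_ci(.x, .y)[1]),
      ci_hi = purrr::map2_dbl(.data$x, .data$n, ~ binom_ci(.x, .y)[2]),
      empty = .data$n == 0
    )
  out <- sens
  if (!is.null(control_results)) {
    spec <- control_results %>%
      group_by(.data$gene) %>%
      summarise(n = dplyr::n(), fp = sum(.data$detected), .groups = "drop") %>%
      mutate(
        metric = "specificity", bin = NA_character_,
        value = ifelse(.data$n > 0, 100 * (1 - .data$fp / .data$n), NA_real_),
        ci_lo = purrr::map2_dbl(.data$n - .data$fp, .data$n, ~ binom_ci(.x, .y)[1]),
        ci_hi = purrr::map2_dbl(.data$n - .data$fp, .data$n, ~ binom_ci(.x, .y)[2]),
        empty = .data$n == 0
      ) %>%
      select(-"fp")
    out <- bind_rows(
      sens %>% select(-"x"),
      spec
    )
  } else {
    out <- sens %>% select(-"x")
  }
  out %>% select("gene", "metric", "bin", "value", "n", "ci_lo", "ci_hi", "empty")
}
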