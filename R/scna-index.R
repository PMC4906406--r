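# Depth-based gene-level copy-number statistic: selector-median
# normalization, control-model fitting, per-region z-scores, the
# gene-level copy-number index, empirical threshold calibration and
# normalized copy number.

#' Normalize a depth vector to the selector-wide autosomal median
#'
#' Divides each region's depth by the sample's median depth over
#' autosomal regions and log2-transforms the ratio, removing
#' sample-to-sample differences in total sequencing depth. Regions with
#' zero depth map to `-Inf` and are flagged `excluded` so downstream
#' stages drop them explicitly rather than silently.
#'
#' @param depth_row Tibble with `region_id` and `depth` for one sample.
#' @param selector Selector tibble.
#' @return Tibble with `region_id`, `log2_norm`, `excluded`.
#' @export
#' @examples
#' sel <- gen_selector(c(TP53 = 3L), seed = 1)
#' normalize_depth(tibble::tibble(region_id = sel$region_id,
#'                                depth = c(100, 200, 400)), sel)
normalize_depth <- function(depth_row, selector) {
  check_columns(depth_row, c("region_id", "depth"), "depth_row")
  d <- depth_row$depth[match(selector$region_id, depth_row$region_id)]
  if (anyNA(d)) {
    abort_validation("depth_row does not cover every selector region")
  }
  auto <- selector$autosomal
  med <- median(d[auto & d >= 0])
  if (!is.finite(med) || med <= 0) {
    abort_validation("all autosomal depths are zero; cannot normalize")
  }
  zero <- d == 0
  tibble(
    region_id = selector$region_id,
    log2_norm = ifelse(zero, -Inf, log2(d / med)),
    excluded = zero
  )
}

#' Calibrate a detection threshold from control index values
#'
#' Candidate thresholds are the sorted unique index values observed in
#' controls plus a sentinel just above the maximum; the detection rule
#' is `C >= t`. Returns the smallest candidate whose in-control
#' false-positive rate is below `alpha`. When no finite candidate
#' qualifies the sentinel is returned with attribute `sentinel = TRUE`.
#'
#' @param values Numeric control index values (>= 2).
#' @param alpha Target false-positive rate (default 0.05).
#' @return Numeric threshold with logical attribute `sentinel`.
#' @export
#' @examples
#' calibrate_threshold(0.1 * (1:27)) # 2.7: FPR 1/27 < 0.05
calibrate_threshold <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort_validation("no control index values")
  n <- length(values)
  sentinel <- max(values) + 1e-8
  candidates <- c(sort(unique(values)), sentinel)
  fpr <- vapply(candidates, function(t) sum(values >= t) / n, numeric(1))
  ok <- which(fpr < alpha)
  t <- candidates[ok[1]]
  attr(t, "sentinel") <- ok[1] == length(candidates)
  t
}

#' Fit the healthy-control depth model
#'
#' Learns, for every selector region, the mean and standard deviation of
#' normalized log2 depth across a cohort of healthy-control plasma
#' samples, records a Shapiro-Wilk normality p-value per region as QC
#' metadata (not used to exclude regions by default), excludes
#' zero-variance regions, and calibrates a per-gene copy-number-index
#' threshold at the requested in-control false-positive rate. Genes
#' whose regions are all excluded are marked uncallable.
#'
#' @param control_depths Long depth tibble of the control cohort.
#' @param selector Selector tibble.
#' @param alpha Target false-positive rate for threshold calibration.
#' @return A `control_model` object.
#' @export
fit_control_model <- function(control_depths, selector, alpha = 0.05) {
  samples <- unique(control_depths$sample_id)
  if (length(samples) < 2) {
    abort_validation("at least 2 control samples are required")
  }
  norm <- control_depths %>%
    group_by(.data$sample_id) %>%
    dplyr::group_modify(~ normalize_depth(.x, selector)) %>%
    ungroup()
  if (any(norm$excluded)) {
    warn(sprintf(
      "%d zero-depth control measurements excluded from model fitting",
      sum(norm$excluded)
    ))
  }
  regions <- norm %>%
    filter(!.data$excluded) %>%
    group_by(.data$region_id) %>%
    summarise(
      n = dplyr::n(),
      mu = mean(.data$log2_norm),
      sigma = sd(.data$log2_norm),
      sw_pvalue = if (dplyr::n() >= 3 && sd(.data$log2_norm) > 0) {
        shapiro.test(.data$log2_norm)$p.value
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    mutate(excluded = !is.finite(.data$sigma) | .data$sigma <= 0 |
      .data$n < length(samples))
  regions <- selector %>%
    select("region_id", "gene", "autosomal") %>%
    left_join(regions, by = "region_id") %>%
    mutate(excluded = .data$excluded | is.na(.data$n))
  if (any(regions$excluded)) {
    warn(sprintf(
      "%d region(s) excluded (zero variance or missing control coverage)",
      sum(regions$excluded)
    ))
  }
  model <- structure(
    list(
      regions = regions, genes = NULL, n_controls = length(samples),
      alpha = alpha, control_indices = NULL
    ),
    class = "control_model"
  )
  # in-sample control indices drive the empirical threshold calibration
  idx <- norm %>%
    dplyr::group_split(.data$sample_id) %>%
    purrr::map_dfr(function(s) {
      z <- region_zscores(s, model)
      gene_index_table(z, model) %>%
        mutate(sample_id = s$sample_id[1])
    })
  genes <- idx %>%
    group_by(.data$gene) %>%
    summarise(
      n_regions = .data$n_regions[1],
      threshold = if (all(is.na(.data$index))) NA_real_ else {
        as.numeric(calibrate_threshold(.data$index, alpha = alpha))
      },
      sentinel = if (all(is.na(.data$index))) NA else {
        attr(calibrate_threshold(.data$index, alpha = alpha), "sentinel")
      },
      .groups = "drop"
    ) %>%
    mutate(uncallable = is.na(.data$threshold))
  model$genes <- genes
  model$control_indices <- idx %>% select("sample_id", "gene", "index")
  model
}

#' @export
print.control_model <- function(x, ...) {
  cat("<control_model>\n")
  cat("  controls:", x$n_controls, " regions:", nrow(x$regions),
    sprintf("(%d excluded)", sum(x$regions$excluded)), "\n")
  cat("  alpha:", x$alpha, "\n")
  gs <- x$genes %>% filter(!.data$uncallable)
  cat("  thresholds:", paste(sprintf("%s=%.3g", gs$gene, gs$threshold),
    collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_control_model Per-region parameters as a tibble
#'   (`region_id`, `gene`, `mu`, `sigma`, `sw_pvalue`, `excluded`).
#' @param x A `control_model`.
#' @param ... Unused.
#' @export
tidy.control_model <- function(x, ...) {
  x$regions %>%
    select("region_id", "gene", "mu", "sigma", "sw_pvalue", "excluded")
}

#' @describeIn fit_control_model One-row model summary.
#' @export
glance.control_model <- function(x, ...) {
  tibble(
    n_controls = x$n_controls,
    n_regions = nrow(x$regions),
    n_excluded = sum(x$regions$excluded),
    n_genes = nrow(x$genes),
    n_uncallable = sum(x$genes$uncallable),
    alpha = x$alpha
  )
}

#' Per-region depth z-scores for one sample
#'
#' `z_i = (d_i - mu_i) / sigma_i` over regions included in the control
#' model; excluded regions are absent from the output.
#'
#' @param normalized Output of [normalize_depth()] for one sample.
#' @param model A [fit_control_model()] result.
#' @return Tibble with `region_id`, `gene`, `z`.
#' @export
region_zscores <- function(normalized, model) {
  reg <- model$regions %>% filter(!.data$excluded)
  m <- match(reg$region_id, normalized$region_id)
  if (anyNA(m)) {
    abort_validation("sample regions do not match the control model")
  }
  keep <- !normalized$excluded[m]
  tibble(
    region_id = reg$region_id[keep],
    gene = reg$gene[keep],
    z = (normalized$log2_norm[m][keep] - reg$mu[keep]) / reg$sigma[keep]
  )
}

# per-gene index over a z-score tibble (internal; vectorized over genes)
gene_index_table <- function(zscores, model) {
  idx <- zscores %>%
    group_by(.data$gene) %>%
    summarise(
      n_regions = dplyr::n(),
      index = sum(.data$z) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  model$regions %>%
    distinct(.data$gene) %>%
    left_join(idx, by = "gene") %>%
    mutate(n_regions = tidyr::replace_na(.data$n_regions, 0L))
}

#' Gene-level copy-number index
#'
#' The index for gene g is the sum of its per-region depth z-scores
#' divided by the square root of the number of contributing regions —
#' an unweighted z-combination in the style of Stouffer's method, except
#' that regions of one gene are not assumed independent, so detection
#' thresholds are calibrated empirically on controls rather than taken
#' from the normal distribution.
#'
#' @param zscores Output of [region_zscores()].
#' @param gene Gene symbol.
#' @param model A `control_model` (used to detect uncallable genes).
#' @return Numeric index value.
#' @export
#' @examples
#' # four regions at z = 1 give index 4 / sqrt(4) = 2
copy_number_index <- function(zscores, gene, model = NULL) {
  z <- zscores$z[zscores$gene == gene]
  if (length(z) == 0) {
    if (!is.null(model) &&
      isTRUE(model$genes$uncallable[model$genes$gene == gene])) {
      abort_validation(sprintf("gene %s is uncallable (no included regions)", gene))
    }
    abort_validation(sprintf("no z-scores for gene %s", gene))
  }
  sum(z) / sqrt(length(z))
}

#' Estimate mean copy number from relative depth and ctDNA fraction
#'
#' Inverts the two-population mixture r = (1 - f) + f * CN / 2 that
#' links the observed linear relative depth r of a gene to the mean
#' copy number CN among tumour cells contributing DNA to plasma:
#' CN = 2 + 2 * (r - 1) / f, clipped below at zero. When the gain is
#' subclonal, the reported value is the average over contributing cells
#' and therefore underestimates the level within the subclone.
#'
#' @param relative_depth Linear mean depth ratio of the gene (diploid = 1).
#' @param ctdna_fraction Tumour genome-equivalent fraction f (> 0).
#' @return Estimated copies (>= 0).
#' @export
#' @examples
#' normalized_copy_number(1.275, 0.05) # 13 copies
normalized_copy_number <- function(relative_depth, ctdna_fraction) {
  if (any(ctdna_fraction <= 0)) {
    abort_validation("ctdna_fraction must be > 0 to estimate copy number")
  }
  pmax(0, 2 + 2 * (relative_depth - 1) / ctdna_fraction)
}

#' Call gene-level copy-number alterations for one sample
#'
#' Normalizes the sample's depth row, computes per-region z-scores
#' against the control model, aggregates them into per-gene copy-number
#' indexes, and flags genes whose index reaches the calibrated
#' threshold. The linear relative depth (arithmetic mean of per-region
#' linear ratios) is reported for every gene; normalized copy number is
#' computed only for significant calls when a ctDNA fraction is
#' supplied. Samples whose truncal/activating raw VAF falls below
#' `ctdna_gate_vaf` are marked inconclusive (calls are still reported).
#'
#' Large negative indexes (copy-number loss) are reported descriptively
#' but never flagged significant: thresholds are calibrated for gains.
#'
#' @param depth_row Tibble (`region_id`, `depth`) for one sample; a
#'   `sample_id` column, if present, is carried through.
#' @param model A [fit_control_model()] result.
#' @param selector Selector tibble.
#' @param ctdna_gate_vaf Raw-VAF adequacy gate (default 0.02).
#' @param truncal_vaf Raw truncal/activating VAF used for the gate, or
#'   `NA` when unknown.
#' @param ctdna_fraction Tumour genome-equivalent fraction f, or `NULL`.
#' @return Tibble with one row per callable gene: `sample_id`, `gene`,
#'   `n_regions`, `index`, `threshold`, `significant`,
#'   `relative_depth`, `conclusive`, `normalized_cn`.
#' @export
call_scna <- function(depth_row, model, selector, ctdna_gate_vaf = 0.02,
                      truncal_vaf = NA_real_, ctdna_fraction = NULL) {
  sid <- if ("sample_id" %in% names(depth_row)) depth_row$sample_id[1] else NA_character_
  norm <- normalize_depth(depth_row, selector)
  z <- region_zscores(norm, model)
  idx <- gene_index_table(z, model)
  reg <- model$regions %>% filter(!.data$excluded)
  m <- match(reg$region_id, norm$region_id)
  # depth ratio relative to the control expectation for each region, so
  # fixed capture-efficiency differences between regions cancel
  rel <- tibble(gene = reg$gene, ratio = 2^(norm$log2_norm[m] - reg$mu)) %>%
    filter(is.finite(.data$ratio)) %>%
    group_by(.data$gene) %>%
    summarise(relative_depth = mean(.data$ratio), .groups = "drop")
  conclusive <- if (is.na(truncal_vaf)) NA else truncal_vaf >= ctdna_gate_vaf
  out <- idx %>%
    left_join(model$genes %>% select("gene", "threshold", "uncallable"),
      by = "gene"
    ) %>%
    left_join(rel, by = "gene") %>%
    mutate(
      sample_id = sid,
      significant = !.data$uncallable & !is.na(.data$index) &
        .data$index >= .data$threshold,
      conclusive = conclusive,
      normalized_cn = ifelse(
        .data$significant & !is.null(ctdna_fraction) &
          !is.na(.data$relative_depth),
        if (is.null(ctdna_fraction)) NA_real_ else {
          normalized_copy_number(.data$relative_depth, ctdna_fraction)
        },
        NA_real_
      )
    ) %>%
    select(
      "sample_id", "gene", "n_regions", "index", "threshold", "significant",
      "relative_depth", "conclusive", "normalized_cn"
    )
  out
}
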