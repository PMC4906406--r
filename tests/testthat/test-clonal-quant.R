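mk_variant <- function(class = "other", vaf = 0.05, depth = 5000,
                       gene = "KRAS", variant = "KRAS G12A",
                       effect = "nonsynonymous", blacklisted = FALSE) {
  tibble::tibble(
    sample_id = "S1", patient_id = "P1", timepoint = "pretreatment", day = 0,
    gene = gene, variant = variant, class = class, vaf = vaf, depth = depth,
    alt_reads = round(vaf * depth), effect = effect, blacklisted = blacklisted
  )
}

test_that("germline filtering applies windows, blacklist and effect rules", {
  v <- dplyr::bind_rows(
    mk_variant(vaf = 0.50),                                  # het window
    mk_variant(vaf = 0.95),                                  # hom window
    mk_variant(vaf = 0.03, effect = "synonymous"),           # effect rule
    mk_variant(vaf = 0.03, blacklisted = TRUE),              # catalogue
    mk_variant(vaf = 0.03, variant = "KRAS Q61H")            # somatic
  )
  kept <- filter_germline(v, ctdna_fraction = 0.05)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$variant, "KRAS Q61H")
  reasons <- filter_germline(v, ctdna_fraction = 0.05, keep_all = TRUE)
  expect_setequal(
    reasons$filter_reason,
    c("germline_het_window", "germline_hom_window", "not_nonsynonymous",
      "population_blacklist", "retained")
  )
  # at very high tumour fraction the VAF windows are suspended
  high <- filter_germline(mk_variant(vaf = 0.50), ctdna_fraction = 0.95)
  expect_equal(nrow(high), 1)
})

test_that("ctDNA fraction prefers truncal TP53 then corrected activating", {
  tp53 <- mk_variant(
    class = "truncal_TP53", vaf = 0.12, gene = "TP53",
    variant = "TP53 R175H"
  )
  est <- estimate_ctdna_fraction(tp53)
  expect_equal(est$ctdna_fraction, 0.24)
  expect_equal(est$raw_truncal_vaf, 0.12)
  expect_equal(est$source, "TP53_truncal")
  # EGFR-activating fallback with copy-number correction: the worked
  # mixture example f = 0.1, CN = 20, r = 1.9 gives raw VAF 0.5263
  act <- mk_variant(
    class = "activating", vaf = 0.5263, gene = "EGFR",
    variant = "EGFR L858R"
  )
  scna <- tibble::tibble(
    sample_id = "S1", gene = "EGFR", n_regions = 12L, index = 9,
    threshold = 2.58, significant = TRUE, relative_depth = 1.9,
    conclusive = TRUE, normalized_cn = 20
  )
  est2 <- estimate_ctdna_fraction(act, scna_calls = scna)
  expect_equal(est2$ctdna_fraction, 0.1, tolerance = 1e-3)
  expect_equal(est2$source, "EGFR_activating_corrected")
  # no gain: fraction doubles the raw VAF
  est3 <- estimate_ctdna_fraction(mk_variant(class = "activating", vaf = 0.04))
  expect_equal(est3$ctdna_fraction, 0.08)
  # neither class present
  est4 <- estimate_ctdna_fraction(mk_variant(class = "other"))
  expect_equal(est4$source, "none")
  expect_true(is.na(est4$ctdna_fraction))
})

test_that("activating-VAF correction inverts the amplification model", {
  expect_equal(corrected_activating_vaf(0.5263, 1.9, 20), 0.05, tolerance = 1e-4)
  # without a significant gain the correction is the identity
  expect_equal(corrected_activating_vaf(0.10, 1.0, 2, significant = FALSE), 0.10)
  expect_equal(corrected_activating_vaf(0.07, 1.4, 6, significant = FALSE), 0.07)
  # round-trip: forward-simulated raw VAF at (f, CN) corrects back to f/2
  for (f in c(0.02, 0.1, 0.3)) {
    for (cn in c(4, 13, 20)) {
      r <- (1 - f) + f * cn / 2
      raw <- f * cn / (2 * r)
      expect_equal(corrected_activating_vaf(raw, r, cn), f / 2,
        tolerance = 1e-12)
    }
  }
  expect_error(corrected_activating_vaf(0.1, 1.5, 0),
    class = "ctdnaprof_validation_error"
  )
})

test_that("the binomial LOD bound matches closed form and an oracle", {
  # closed form at s = 1 against an independent numeric solver
  for (depth in c(300, 3000, 12000)) {
    closed <- lod_vaf(depth, min_supporting_reads = 1)
    oracle <- stats::uniroot(
      function(v) 1 - pbinom(0, depth, v) - 0.95,
      c(1e-12, 0.5), tol = 1e-15
    )$root
    expect_equal(closed, oracle, tolerance = 1e-9)
  }
  expect_equal(lod_vaf(3000, 1), 1 - 0.05^(1 / 3000), tolerance = 1e-12)
  # s = 2 bisection against a brute-force grid scan
  grid <- seq(1e-5, 5e-3, by = 1e-6)
  tail2 <- 1 - pbinom(1, 3000, grid)
  scan <- grid[which(tail2 >= 0.95)[1]]
  expect_equal(lod_vaf(3000, 2), scan, tolerance = 1e-3)
  # monotone: deeper sequencing lowers the bound, more reads raise it
  expect_true(all(diff(lod_vaf(c(500, 1000, 5000, 20000), 1)) < 0))
  expect_gt(lod_vaf(3000, 2), lod_vaf(3000, 1))
  expect_gt(lod_vaf(3000, 3), lod_vaf(3000, 2))
  expect_error(lod_vaf(0), class = "ctdnaprof_validation_error")
})

test_that("ratio computation, censoring and grouping follow the rules", {
  act <- mk_variant(
    class = "activating", vaf = 0.25, gene = "EGFR", variant = "EGFR L858R",
    depth = 3000
  )
  t790m <- mk_variant(
    class = "T790M", vaf = 0.10, gene = "EGFR", variant = "EGFR T790M",
    depth = 3000
  )
  res <- t790m_ratio(dplyr::bind_rows(act, t790m))
  expect_equal(res$ratio, 0.4)
  expect_equal(res$group, "low")
  expect_false(res$censored)
  # equal VAFs sit exactly at ratio 1, in the high group
  eq <- t790m_ratio(dplyr::bind_rows(
    act, mk_variant(class = "T790M", vaf = 0.25, gene = "EGFR",
      variant = "EGFR T790M", depth = 3000)
  ))
  expect_equal(eq$ratio, 1)
  expect_equal(eq$group, "high")
  # undetected T790M: VAF censored at min(LOD, activating VAF)
  low_act <- mk_variant(
    class = "activating", vaf = 0.0005, gene = "EGFR",
    variant = "EGFR L858R", depth = 3000
  )
  cens <- t790m_ratio(low_act, min_supporting_reads = 1)
  expect_true(cens$censored)
  expect_equal(cens$vaf_t790m, 0.0005) # LOD ~ 0.000998 is larger
  expect_equal(cens$ratio, 1)
  # censored ratios are upper bounds, never above 1
  for (av in c(0.0002, 0.002, 0.02, 0.2)) {
    r <- t790m_ratio(
      mk_variant(class = "activating", vaf = av, gene = "EGFR",
        variant = "EGFR L858R", depth = 4000),
      min_supporting_reads = 2
    )
    expect_lte(r$ratio, 1)
    expect_true(r$censored)
  }
  expect_error(t790m_ratio(mk_variant(class = "other")),
    class = "ctdnaprof_validation_error"
  )
})

test_that("trajectories report signed change and eligibility rules", {
  mk_tp <- function(tp, day, act_vaf, t790m_vaf, sid) {
    dplyr::bind_rows(
      mk_variant(class = "activating", vaf = act_vaf, gene = "EGFR",
        variant = "EGFR L858R", depth = 4000),
      mk_variant(class = "T790M", vaf = t790m_vaf, gene = "EGFR",
        variant = "EGFR T790M", depth = 4000)
    ) |>
      dplyr::mutate(timepoint = tp, day = day, sample_id = sid)
  }
  pv <- dplyr::bind_rows(
    mk_tp("pretreatment", 0, 0.10, 0.08, "a"),
    mk_tp("progression", 120, 0.10, 0.04, "b")
  )
  traj <- ratio_trajectory(pv)
  expect_true(traj$evaluable)
  expect_equal(traj$pct_change, -50)
  expect_equal(traj$direction, "decreased")
  # identical ratios: zero change
  flat <- ratio_trajectory(dplyr::bind_rows(
    mk_tp("pretreatment", 0, 0.10, 0.05, "a"),
    mk_tp("progression", 120, 0.20, 0.10, "b")
  ))
  expect_equal(flat$pct_change, 0)
  expect_equal(flat$direction, "unchanged")
  # a very low progression activating VAF blocks evaluation
  low <- ratio_trajectory(dplyr::bind_rows(
    mk_tp("pretreatment", 0, 0.10, 0.08, "a"),
    mk_tp("progression", 120, 0.002, 0.001, "b")
  ))
  expect_false(low$evaluable)
  expect_match(low$reason, "floor")
  # missing endpoint
  half <- ratio_trajectory(mk_tp("pretreatment", 0, 0.1, 0.08, "a"))
  expect_false(half$evaluable)
})

test_that("depletion simulations show falling ratios in most replicates", {
  cfg <- sim_config(seed = 17)
  sel <- gen_selector(cfg$genes, seed = 17)
  drops <- vapply(1:60, function(i) {
    ps <- gen_patient_series("t790m_depletion",
      seed = i, config = cfg,
      selector = sel, include_depths = FALSE, patient_id = paste0("D", i)
    )
    traj <- ratio_trajectory(ps$variants)
    isTRUE(traj$direction == "decreased")
  }, logical(1))
  expect_gte(mean(drops), 0.95)
})

test_that("the ROC cut-point maximizes Youden's J deterministically", {
  res <- roc_cutpoint(c(0.2, 0.3, 0.9, 1.0), c(0, 0, 1, 1))
  expect_equal(res$cutpoint, 0.6)
  expect_equal(res$youden_j, 1)
  # ties resolve to the smallest candidate; verify against enumeration
  ratios <- c(0.1, 0.2, 0.3, 0.4)
  resp <- c(1, 0, 1, 0)
  res2 <- roc_cutpoint(ratios, resp)
  j_all <- vapply(res2$candidates, function(t) {
    pred <- ratios >= t
    sum(pred & resp == 1) / 2 + sum(!pred & resp == 0) / 2 - 1
  }, numeric(1))
  expect_equal(res2$cutpoint, min(res2$candidates[j_all == max(j_all)]))
  # cohort shaped like the study: low-ratio non-responders around 0.3,
  # high-ratio responders around 0.9 recover a cut-point near 0.5
  set.seed(42)
  lows <- pmin(pmax(rnorm(12, 0.30, 0.10), 0.02), 0.45)
  highs <- pmin(pmax(rnorm(29, 0.90, 0.20), 0.55), 1.6)
  res3 <- roc_cutpoint(c(lows, highs), c(rep(0, 12), rep(1, 29)))
  expect_gt(res3$cutpoint, 0.3)
  expect_lt(res3$cutpoint, 0.7)
  expect_error(roc_cutpoint(c(0.1, 0.2), c(1, 1)),
    class = "ctdnaprof_validation_error"
  )
})
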