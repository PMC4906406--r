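mk_v <- function(gene, variant, vaf, class = "other", depth = 5000,
                 sid = "S1", tp = "pretreatment") {
  tibble::tibble(
    sample_id = sid, patient_id = "P1", timepoint = tp, day = 0,
    gene = gene, variant = variant, class = class, vaf = vaf, depth = depth,
    alt_reads = round(vaf * depth), effect = "nonsynonymous",
    blacklisted = FALSE
  )
}

mk_scna <- function(gene, significant, cn = NA_real_, r = NA_real_) {
  tibble::tibble(
    sample_id = "S", gene = gene, n_regions = 10L,
    index = ifelse(significant, 8, 0), threshold = 3,
    significant = significant, relative_depth = r, conclusive = TRUE,
    normalized_cn = cn
  )
}

test_that("relative abundance normalizes against the truncal anchor", {
  snv <- relative_abundance("SNV", vaf = 0.05, truncal_vaf = 0.10)
  expect_equal(snv$abundance, 0.5)
  scna <- relative_abundance("SCNA", normalized_cn = 6)
  expect_equal(scna$abundance, 6)
  absent <- relative_abundance("SNV", detected = FALSE)
  expect_equal(absent$abundance, 0)
  expect_false(absent$detected)
  expect_error(relative_abundance("SNV", vaf = 0.05),
    class = "ctdnaprof_validation_error"
  )
})

test_that("resistance rules catch emergent, increasing and carried-forward", {
  anchors <- function(sid, tp, tp53 = 0.10, act = 0.12) dplyr::bind_rows(
    mk_v("TP53", "TP53 R175H", tp53, "truncal_TP53", sid = sid, tp = tp),
    mk_v("EGFR", "EGFR L858R", act, "activating", sid = sid, tp = tp),
    mk_v("EGFR", "EGFR T790M", act * 0.8, "T790M", sid = sid, tp = tp)
  )
  # increasing MET gain (normalized CN 4 -> 9) plus emergent PIK3CA SNV
  pre <- anchors("pre", "pretreatment")
  prog <- dplyr::bind_rows(
    anchors("prog", "progression"),
    mk_v("PIK3CA", "PIK3CA E545K", 0.03, sid = "prog", tp = "progression")
  )
  calls <- call_resistance(
    pre_variants = pre, prog_variants = prog,
    pre_scna = mk_scna("MET", TRUE, cn = 4, r = 1.2),
    prog_scna = mk_scna("MET", TRUE, cn = 9, r = 1.5),
    patient_id = "P1"
  )
  expect_setequal(calls$alteration, c("MET SCNA", "PIK3CA E545K"))
  met <- dplyr::filter(calls, gene == "MET")
  expect_equal(met$evidence, "increasing")
  expect_equal(met$pre_abundance, 4)
  expect_equal(met$post_abundance, 9)
  pik <- dplyr::filter(calls, gene == "PIK3CA")
  expect_equal(pik$evidence, "emergent")
  expect_equal(pik$pre_abundance, 0)
  # the treatment target and the truncal anchor are never candidates
  expect_false(any(calls$gene == "TP53"))
  expect_false(any(grepl("T790M|L858R", calls$alteration)))
  # pre-existing SCNA with inconclusive progression ctDNA carries forward
  carried <- call_resistance(
    pre_variants = pre,
    prog_variants = anchors("prog", "progression", tp53 = 0.01, act = 0.01),
    pre_scna = mk_scna("MET", TRUE, cn = 6, r = 1.3),
    prog_scna = mk_scna("MET", FALSE),
    patient_id = "P1"
  )
  expect_equal(
    dplyr::filter(carried, type == "SCNA")$evidence, "carried_forward"
  )
  # pre-existing SNV with no detectable ctDNA at progression carries forward
  snv_pre <- dplyr::bind_rows(pre, mk_v("CDKN2A", "CDKN2A D74A", 0.05,
    sid = "pre", tp = "pretreatment"))
  no_ctdna_prog <- mk_v("EGFR", "EGFR L858R", 0, "activating",
    sid = "prog", tp = "progression")
  carried2 <- call_resistance(
    pre_variants = snv_pre, prog_variants = no_ctdna_prog[0, ],
    patient_id = "P1"
  )
  expect_equal(
    dplyr::filter(carried2, gene == "CDKN2A")$evidence, "carried_forward"
  )
  # a stable alteration is not called
  none <- call_resistance(
    pre_variants = pre, prog_variants = anchors("prog", "progression"),
    pre_scna = mk_scna("MET", TRUE, cn = 6, r = 1.3),
    prog_scna = mk_scna("MET", TRUE, cn = 6, r = 1.3),
    patient_id = "P1"
  )
  expect_equal(nrow(none), 0)
})

test_that("timing splits at three months with the boundary to acquired", {
  expect_equal(classify_timing(60), "innate")
  expect_equal(classify_timing(120), "acquired")
  expect_equal(classify_timing(3 * 30.44), "acquired") # exact boundary
  expect_equal(classify_timing(3 * 30.44 - 0.01), "innate")
  expect_error(classify_timing(-1), class = "ctdnaprof_validation_error")
})

test_that("mechanism categories map alteration sets, order-invariant", {
  scna <- tibble::tibble(type = "SCNA", alteration = "MET SCNA")
  snv <- tibble::tibble(type = "SNV", alteration = "KRAS G12A")
  expect_equal(categorize_mechanisms(scna), "SCNA_only")
  expect_equal(categorize_mechanisms(snv), "SNV_only")
  expect_equal(categorize_mechanisms(dplyr::bind_rows(scna, snv)), "SCNA_plus_SNV")
  expect_equal(categorize_mechanisms(dplyr::bind_rows(snv, scna)), "SCNA_plus_SNV")
  expect_equal(categorize_mechanisms(scna[0, ]), "none")
})

test_that("MET FISH positivity uses any single criterion", {
  expect_equal(classify_met_fish(2.1, 3.0, 0), "positive")
  expect_equal(classify_met_fish(1.2, 7.0, 0), "positive")
  expect_equal(classify_met_fish(1.0, 2.0, 12), "positive")
  expect_equal(classify_met_fish(1.0, 2.0, 0), "negative")
  expect_error(classify_met_fish(-1, 0, 0), class = "ctdnaprof_validation_error")
})

test_that("planted mechanisms are recovered on simulated cohorts", {
  st <- fx_study(seed = 1)
  scenarios <- c("emergent_met", "increasing_snv", "mixed_mechanisms", "null")
  n_per <- 12
  results <- purrr::map_dfr(scenarios, function(sc) {
    purrr::map_dfr(seq_len(n_per), function(i) {
      ps <- gen_patient_series(sc,
        seed = 1000 + i, config = st$cfg, selector = st$selector,
        patient_id = sprintf("%s_%d", sc, i)
      )
      per_sample <- lapply(
        split(ps$depths, ps$depths$sample_id),
        function(d) {
          sid <- d$sample_id[1]
          v <- dplyr::filter(ps$variants, sample_id == sid)
          est <- estimate_ctdna_fraction(v)
          list(
            est = est,
            scna = call_scna(d, st$model, st$selector,
              truncal_vaf = est$raw_truncal_vaf,
              ctdna_fraction = est$ctdna_fraction
            )
          )
        }
      )
      pre_id <- ps$timepoints$sample_id[1]
      prog_id <- ps$timepoints$sample_id[3]
      calls <- call_resistance(
        pre_variants = dplyr::filter(ps$variants, sample_id == pre_id),
        prog_variants = dplyr::filter(ps$variants, sample_id == prog_id),
        pre_scna = per_sample[[pre_id]]$scna,
        prog_scna = per_sample[[prog_id]]$scna,
        pre_estimate = per_sample[[pre_id]]$est,
        prog_estimate = per_sample[[prog_id]]$est,
        patient_id = ps$patient$patient_id
      )
      tibble::tibble(
        scenario = sc,
        n_true = nrow(ps$truth),
        n_called = nrow(calls),
        n_correct = sum(paste(calls$gene, calls$type) %in%
          paste(ps$truth$gene, ps$truth$type)),
        n_snv_null = if (sc == "null") sum(calls$type == "SNV") else 0L
      )
    })
  })
  precision <- sum(results$n_correct) / sum(results$n_called)
  recall <- sum(results$n_correct) / sum(results$n_true)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # the null scenario plants nothing: the only possible calls are
  # copy-number false positives at the calibrated per-gene rate, and
  # no spurious SNV ever appears (binomial sampling cannot invent reads)
  null_calls <- results$n_called[results$scenario == "null"]
  expect_lte(mean(null_calls), 3 * 0.06 * 2 + 0.25)
  expect_equal(sum(results$n_snv_null), 0)
})

test_that("cohort comparison delegates to rank-sum and log-rank", {
  # identical response vectors: no group difference
  pats <- tibble::tibble(
    patient_id = as.character(1:10),
    group = rep(c("a", "b"), each = 5),
    pfs_days = rep(c(90, 120, 150, 180, 210), 2),
    progression_event = TRUE,
    best_response_pct = rep(c(-30, -20, -10, 0, 10), 2)
  )
  cc <- suppressWarnings(cohort_compare(pats, "group"))
  expect_equal(cc$response_p, 1, tolerance = 1e-9)
  expect_false(cc$underpowered)
  expect_equal(nrow(cc$summary), 2)
  # a strong planted PFS difference is detected in most replicates
  rejections <- vapply(1:20, function(i) {
    set.seed(3000 + i)
    sim <- tibble::tibble(
      patient_id = as.character(1:49),
      group = c(rep("MET_pos", 16), rep("MET_neg", 33)),
      pfs_days = c(
        stats::rexp(16, rate = 1 / (2 * 30.44)),
        stats::rexp(33, rate = 1 / (6 * 30.44))
      ),
      progression_event = TRUE,
      best_response_pct = c(
        stats::rnorm(16, -13.8, 25), stats::rnorm(33, -36.5, 25)
      )
    )
    suppressWarnings(cohort_compare(sim, "group"))$logrank_p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
  # single-member groups: summaries only, tests flagged underpowered
  single <- pats[c(1, 6), ]
  cc2 <- cohort_compare(single, "group")
  expect_true(cc2$underpowered)
  expect_true(is.na(cc2$response_p))
})
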