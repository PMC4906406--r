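# Synthetic-cohort generator.
#
# Emulates the statistical structure the depth-based copy-number caller
# assumes: a multi-region capture selector, healthy-control plasma
# samples whose per-region depths are log-normal around a fixed
# per-region capture efficiency, tumour-bearing plasma samples whose
# depth follows the two-population mixture (1 - f) + f * CN/2, and
# variant alt-read counts that are binomial at the realized depth.

# approximate genomic anchors so synthetic coordinates look plausible
.gene_anchors <- c(
  EGFR = 55000000, MET = 116000000, ERBB2 = 39000000, TP53 = 7500000,
  KRAS = 25000000, PIK3CA = 178000000, RB1 = 48000000, ALK = 29000000,
  BRAF = 140000000, RET = 43000000, ROS1 = 117000000, PTEN = 89000000,
  MYC = 127000000, NF1 = 31000000, STK11 = 1200000, KEAP1 = 10500000,
  CDKN2A = 21900000, SMAD4 = 51000000, CTNNB1 = 41000000,
  NTRK1 = 156000000
)
.gene_chroms <- c(
  EGFR = "chr7", MET = "chr7", ERBB2 = "chr17", TP53 = "chr17",
  KRAS = "chr12", PIK3CA = "chr3", RB1 = "chr13", ALK = "chr2",
  BRAF = "chr7", RET = "chr10", ROS1 = "chr6", PTEN = "chr10",
  MYC = "chr8", NF1 = "chr17", STK11 = "chr19", KEAP1 = "chr19",
  CDKN2A = "chr9", SMAD4 = "chr18", CTNNB1 = "chr3", NTRK1 = "chr1"
)

# default synthetic selector: the genes of interest plus enough
# background regions that an amplified gene stays a small minority of
# the selector, as in a real multi-gene panel (otherwise the
# selector-wide median normalization absorbs part of its own signal)
.default_genes <- c(
  EGFR = 12L, MET = 10L, ERBB2 = 8L, TP53 = 5L, KRAS = 4L, PIK3CA = 6L,
  ALK = 8L, BRAF = 6L, RET = 6L, ROS1 = 8L, RB1 = 5L, PTEN = 4L,
  MYC = 4L, NF1 = 5L, STK11 = 4L, KEAP1 = 4L, CDKN2A = 3L, SMAD4 = 4L,
  CTNNB1 = 3L, NTRK1 = 6L
)

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic cohort generator. Defaults mirror
#' the study conditions the pipeline was designed for: 27 healthy-control
#' plasma samples sequenced to a mean depth of ~5,500x over a multi-gene
#' selector, with per-region log2 normalized depth noise of sd 0.10.
#'
#' @param n_controls Number of healthy-control samples (>= 2).
#' @param mean_depth Mean sequencing depth in reads.
#' @param sigma_log2 Standard deviation of per-region log2 normalized
#'   depth (multiplicative log-normal noise).
#' @param genes Named integer vector: regions per gene.
#' @param capture_bias_sd Log2 sd of the fixed per-region capture
#'   efficiencies (drawn once per selector, shared by all samples).
#' @param overdispersion Beta-binomial overdispersion rho for alt reads;
#'   0 (default) means plain binomial sampling.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
sim_config <- function(n_controls = 27, mean_depth = 5500, sigma_log2 = 0.10,
                       genes = .default_genes,
                       capture_bias_sd = 0.25, overdispersion = 0,
                       seed = 1L) {
  stopifnot(n_controls >= 2, sigma_log2 > 0, length(genes) >= 1)
  if (is.null(names(genes)) || any(names(genes) == "")) {
    abort_validation("genes must be a named vector of region counts")
  }
  if (any(genes < 1)) abort_validation("every gene needs >= 1 region")
  structure(
    list(
      n_controls = as.integer(n_controls), mean_depth = mean_depth,
      sigma_log2 = sigma_log2, genes = genes,
      capture_bias_sd = capture_bias_sd, overdispersion = overdispersion,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic capture selector
#'
#' Lays out the requested number of non-overlapping regions per gene at
#' plausible genomic positions; deterministic for a given seed. Genes
#' without a known anchor get sequential synthetic chromosomes.
#'
#' @param genes Named integer vector of regions per gene.
#' @param seed Integer seed.
#' @return A selector tibble (see [read_selector()] for columns).
#' @export
#' @examples
#' gen_selector(c(MET = 10L, EGFR = 12L, TP53 = 5L), seed = 1)
gen_selector <- function(genes, seed = 1L) {
  if (length(genes) == 0) abort_validation("empty gene list")
  if (any(genes < 1)) abort_validation("region count must be >= 1")
  withr::with_seed(derive_seed(seed, "selector"), {
    rows <- purrr::imap(genes, function(n_reg, gene) {
      anchor <- if (gene %in% names(.gene_anchors)) {
        .gene_anchors[[gene]]
      } else {
        1e6 + 5e6 * (abs(derive_seed(0L, gene)) %% 100)
      }
      chrom <- if (gene %in% names(.gene_chroms)) {
        .gene_chroms[[gene]]
      } else {
        paste0("chr", 1 + (abs(derive_seed(0L, gene)) %% 12))
      }
      len <- sample(150:600, n_reg, replace = TRUE)
      gap <- sample(500:5000, n_reg, replace = TRUE)
      start <- anchor + cumsum(gap) + c(0, cumsum(len))[seq_len(n_reg)]
      tibble(
        region_id = sprintf("%s|%d", gene, seq_len(n_reg)),
        gene = gene, chrom = chrom,
        start = as.integer(start), end = as.integer(start + len)
      )
    })
    bind_rows(rows) %>%
      mutate(autosomal = !.data$chrom %in% c("chrX", "chrY")) %>%
      validate_selector(context = "gen_selector")
  })
}

# fixed per-region capture efficiencies, deterministic in (selector, config)
region_efficiencies <- function(selector, config) {
  withr::with_seed(derive_seed(config$seed, "efficiency"), {
    eff <- 2^rnorm(nrow(selector), mean = 0, sd = config$capture_bias_sd)
    setNames(eff, selector$region_id)
  })
}

# one sample's raw depth vector: mean_depth * e_i * rel_i * 2^(sigma*eps)
.sample_depths <- function(selector, config, eff, rel, sample_seed) {
  withr::with_seed(sample_seed, {
    noise <- 2^(config$sigma_log2 * rnorm(nrow(selector)))
    unname(config$mean_depth * eff[selector$region_id] * rel * noise)
  })
}

#' Generate a healthy-control depth cohort
#'
#' Per-region depth is `mean_depth * e_i * 2^(sigma_log2 * eps)` with a
#' fixed per-region capture efficiency `e_i` (shared by every sample
#' generated under the same config) and standard-normal `eps`, so that
#' after median normalization the per-region log2 depths are normal with
#' sd `sigma_log2`.
#'
#' @param selector Selector tibble.
#' @param config A [sim_config()].
#' @return Long depth tibble (`sample_id`, `region_id`, `depth`).
#' @export
gen_control_cohort <- function(selector, config) {
  if (config$n_controls < 2) abort_validation("n_controls must be >= 2")
  eff <- region_efficiencies(selector, config)
  purrr::map_dfr(seq_len(config$n_controls), function(s) {
    d <- .sample_depths(
      selector, config, eff, rel = 1,
      sample_seed = derive_seed(config$seed, paste0("control_", s))
    )
    tibble(
      sample_id = sprintf("CTRL%03d", s),
      region_id = selector$region_id, depth = d
    )
  })
}

#' Describe a synthetic tumour
#'
#' A tumour profile is the genomic state mixed into plasma: gene total
#' copy numbers (diploid = 2) and a variant table giving, per variant,
#' the fraction of tumour cells carrying it (`clone_fraction`, truncal
#' = 1) and the number of mutant copies per carrying cell.
#'
#' @param cn_events Named numeric vector gene -> total copy number.
#' @param variants Tibble with columns `gene`, `variant`, `class`,
#'   `clone_fraction`, `mutant_copies` (the last defaults to 1 if
#'   absent); may be `NULL` for a copy-number-only profile.
#' @return A `tumour_profile` list.
#' @export
#' @examples
#' tumour_profile(cn_events = c(MET = 13))
tumour_profile <- function(cn_events = numeric(0), variants = NULL) {
  if (any(cn_events < 0)) abort_validation("copy number must be >= 0")
  if (!is.null(variants)) {
    check_columns(variants, c("gene", "variant", "class", "clone_fraction"),
      context = "tumour_profile variants"
    )
    if (!"mutant_copies" %in% names(variants)) variants$mutant_copies <- 1
    if (any(variants$clone_fraction <= 0 | variants$clone_fraction > 1)) {
      abort_validation("clone_fraction must be in (0, 1]")
    }
  }
  structure(list(cn_events = cn_events, variants = variants),
    class = "tumour_profile"
  )
}

#' Generate one tumour-bearing plasma sample
#'
#' Depth follows the two-population mixture: relative depth in gene g is
#' `(1 - f) + f * CN_g / 2`, multiplied by the control noise model.
#' Variant allele fractions follow the same mixture at the allele level
#' (a heterozygous truncal variant in a copy-neutral gene has expected
#' VAF `f/2`) and alt reads are drawn binomially at the realized depth
#' of the variant's first selector region.
#'
#' @param selector Selector tibble.
#' @param profile A [tumour_profile()].
#' @param tumour_fraction Tumour genome-equivalent fraction f between
#'   0 and 1.
#' @param config A [sim_config()].
#' @param sample_id Sample identifier for the output rows.
#' @param sample_seed Optional explicit seed for this sample's noise.
#' @return List with `depths` (long tibble) and `variants` (tibble of
#'   variant calls, possibly empty).
#' @export
gen_tumour_sample <- function(selector, profile, tumour_fraction, config,
                              sample_id = "TUMOUR1", sample_seed = NULL) {
  f <- tumour_fraction
  stopifnot(f >= 0, f <= 1)
  if (any(profile$cn_events < 0)) abort_validation("copy number must be >= 0")
  cn <- profile$cn_events
  cn_of <- function(g) ifelse(g %in% names(cn), unname(cn[g]), 2)
  rel <- (1 - f) + f * cn_of(selector$gene) / 2
  eff <- region_efficiencies(selector, config)
  seed1 <- sample_seed %||% derive_seed(config$seed, paste0("tumour_", sample_id))
  depths <- tibble(
    sample_id = sample_id, region_id = selector$region_id,
    depth = .sample_depths(selector, config, eff, rel, seed1)
  )
  variants <- NULL
  if (!is.null(profile$variants) && nrow(profile$variants) > 0) {
    pv <- profile$variants
    gene_rel <- rel[match(pv$gene, selector$gene)] # first region's rel = gene rel
    # mutant allele fraction among all alleles contributed to plasma
    exp_vaf <- f * pv$clone_fraction * pv$mutant_copies / (2 * gene_rel)
    first_region <- selector$region_id[match(pv$gene, selector$gene)]
    locus_depth <- round(depths$depth[match(first_region, depths$region_id)])
    variants <- withr::with_seed(derive_seed(seed1, "altreads"), {
      alt <- .draw_alt_reads(locus_depth, exp_vaf, config$overdispersion)
      tibble(
        sample_id = sample_id, gene = pv$gene, variant = pv$variant,
        class = pv$class, depth = as.numeric(locus_depth),
        alt_reads = as.numeric(alt),
        vaf = ifelse(locus_depth > 0, alt / locus_depth, 0),
        effect = "nonsynonymous", blacklisted = FALSE,
        expected_vaf = exp_vaf
      )
    })
  }
  list(depths = depths, variants = variants)
}

# binomial (or beta-binomial when rho > 0) alt-read sampling
.draw_alt_reads <- function(depth, vaf, rho = 0) {
  vaf <- pmin(pmax(vaf, 0), 1)
  if (rho <= 0) {
    return(rbinom(length(depth), size = depth, prob = vaf))
  }
  a <- vaf * (1 - rho) / rho
  b <- (1 - vaf) * (1 - rho) / rho
  p <- stats::rbeta(length(depth), pmax(a, 1e-9), pmax(b, 1e-9))
  rbinom(length(depth), size = depth, prob = p)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
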