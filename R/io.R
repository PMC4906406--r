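#' Read a capture selector from a BED file
#'
#' The selector is the set of non-contiguous genomic regions targeted by
#' the capture panel. The expected format is BED4 with 0-based half-open
#' coordinates and a name field of the form `"GENE|region_idx"` (a bare
#' gene symbol is also accepted; region ids are then made unique per gene).
#'
#' @param path Path to a BED4 file.
#' @return A tibble with columns `region_id`, `gene`, `chrom`, `start`,
#'   `end` (0-based half-open) and `autosomal`.
#' @export
read_selector <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  name <- as.character(gr$name)
  if (anyNA(name) || any(name == "")) {
    abort_format(sprintf("%s: BED name (gene) field is required", path))
  }
  gene <- sub("\\|.*$", "", name)
  region_id <- ifelse(grepl("\\|", name), name,
    paste(name, stats::ave(seq_along(name), name, FUN = seq_along), sep = "|")
  )
  sel <- tibble(
    region_id = region_id,
    gene = gene,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # back to BED 0-based
    end = GenomicRanges::end(gr)
  ) %>%
    mutate(autosomal = !.data$chrom %in% c("chrX", "chrY", "X", "Y", "chrM", "MT"))
  validate_selector(sel, context = path)
}

#' Validate a selector tibble
#'
#' Checks the selector invariants: positive-length regions, unique region
#' ids, one gene per region, and no overlapping regions on a chromosome.
#'
#' @param selector Selector tibble as from [read_selector()].
#' @param context Character used in error messages (e.g. a file name).
#' @return The validated selector, invisibly usable in pipes.
#' @export
validate_selector <- function(selector, context = "selector") {
  check_columns(selector, c("region_id", "gene", "chrom", "start", "end", "autosomal"),
    context = context
  )
  if (any(selector$start >= selector$end)) {
    abort_validation(sprintf("%s: regions with start >= end", context))
  }
  if (anyDuplicated(selector$region_id)) {
    abort_validation(sprintf("%s: duplicated region_id", context))
  }
  ovl <- selector %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(overlaps = .data$start < dplyr::lag(as.numeric(.data$end), default = -Inf)) %>%
    ungroup() %>%
    filter(.data$overlaps)
  if (nrow(ovl) > 0) {
    abort_validation(sprintf(
      "%s: overlapping regions on %s (e.g. %s)",
      context, paste(unique(ovl$chrom), collapse = ","), ovl$region_id[1]
    ))
  }
  as_tibble(selector)
}

#' Write a selector to BED4
#'
#' @param selector Selector tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selector <- function(selector, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = selector$chrom,
    ranges = IRanges::IRanges(start = selector$start + 1L, end = selector$end),
    name = selector$region_id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a per-region depth matrix
#'
#' The on-disk layout is one row per selector region and one column per
#' sample: a `region_id` column followed by sample columns holding mean
#' read depth. Empty cells are explicit missing measurements (`NA`);
#' zero is a real measured depth.
#'
#' @param path Path to a TSV file.
#' @return A long tibble with columns `sample_id`, `region_id`, `depth`.
#' @export
read_depths <- function(path) {
  header <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE))
  if (!"region_id" %in% header) {
    abort_format(sprintf("%s: missing required column(s): region_id", path))
  }
  wide <- readr::read_tsv(path, col_types = readr::cols(
    region_id = readr::col_character(), .default = readr::col_double()
  ))
  if (ncol(wide) < 2) {
    abort_format(sprintf("%s: no sample columns", path))
  }
  long <- tidyr::pivot_longer(wide, -"region_id",
    names_to = "sample_id", values_to = "depth"
  ) %>%
    select("sample_id", "region_id", "depth")
  bad <- which(!is.na(long$depth) & long$depth < 0)
  if (length(bad) > 0) {
    abort_validation(sprintf("%s: negative depth for %s / %s", path,
      long$sample_id[bad[1]], long$region_id[bad[1]]))
  }
  long
}

#' Write a long depth tibble as a region-by-sample TSV
#'
#' @param depths Long tibble (`sample_id`, `region_id`, `depth`).
#' @param path Output path.
#' @param region_order Optional character vector fixing region row order.
#' @return `path`, invisibly.
#' @export
write_depths <- function(depths, path, region_order = NULL) {
  wide <- tidyr::pivot_wider(depths,
    id_cols = "region_id", names_from = "sample_id", values_from = "depth"
  )
  if (!is.null(region_order)) {
    wide <- wide[match(region_order, wide$region_id), , drop = FALSE]
  }
  readr::write_tsv(wide, path, na = "")
  invisible(path)
}

.timepoint_levels <- c("pretreatment", "on_treatment", "progression")
.variant_classes <- c("activating", "T790M", "truncal_TP53", "other")
.effect_levels <- c("nonsynonymous", "synonymous", "other")

#' Read a variant call table
#'
#' Expected columns: `sample_id`, `patient_id`, `timepoint`, `day`,
#' `gene`, `variant`, `class`, `vaf`, `depth`, `alt_reads`, `effect`.
#' Variant rows are validated against the container invariants
#' (0 <= VAF <= 1, alt reads <= depth, VAF consistent with
#' alt_reads/depth to 1e-6, known timepoint labels).
#'
#' @param path Path to a TSV file.
#' @param blacklist Optional blacklist tibble (see [read_blacklist()]);
#'   when given, a `blacklisted` flag is attached by gene+variant match.
#' @return A tibble of validated variant calls.
#' @export
read_variants <- function(path, blacklist = NULL) {
  v <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), patient_id = readr::col_character(),
    timepoint = readr::col_character(), day = readr::col_double(),
    gene = readr::col_character(), variant = readr::col_character(),
    class = readr::col_character(), vaf = readr::col_double(),
    depth = readr::col_double(), alt_reads = readr::col_double(),
    effect = readr::col_character()
  ))
  check_columns(v, c(
    "sample_id", "patient_id", "timepoint", "day", "gene", "variant",
    "class", "vaf", "depth", "alt_reads", "effect"
  ), context = path)
  validate_variants(v, context = path)
  v$blacklisted <- if (is.null(blacklist)) {
    FALSE
  } else {
    paste(v$gene, v$variant) %in% paste(blacklist$gene, blacklist$variant)
  }
  v
}

#' Validate a variant table against its invariants
#'
#' @param variants Variant tibble.
#' @param context Character for error messages.
#' @return The validated tibble, invisibly usable in pipes.
#' @export
validate_variants <- function(variants, context = "variants") {
  bad_tp <- !variants$timepoint %in% .timepoint_levels
  if (any(bad_tp)) {
    abort_validation(sprintf(
      "%s: unknown timepoint label '%s' (row %d)",
      context, variants$timepoint[which(bad_tp)[1]], which(bad_tp)[1]
    ))
  }
  if (any(variants$vaf < 0 | variants$vaf > 1, na.rm = TRUE)) {
    abort_validation(sprintf("%s: vaf outside [0, 1]", context))
  }
  bad_ar <- which(variants$alt_reads > variants$depth)
  if (length(bad_ar) > 0) {
    abort_validation(sprintf(
      "%s: alt_reads > depth (row %d: %s %s)",
      context, bad_ar[1], variants$gene[bad_ar[1]], variants$variant[bad_ar[1]]
    ))
  }
  have_both <- !is.na(variants$vaf) & !is.na(variants$alt_reads) &
    !is.na(variants$depth) & variants$depth > 0
  incons <- which(have_both &
    abs(variants$vaf - variants$alt_reads / variants$depth) > 1e-6)
  if (length(incons) > 0) {
    abort_validation(sprintf(
      "%s: vaf inconsistent with alt_reads/depth (row %d)", context, incons[1]
    ))
  }
  as_tibble(variants)
}

#' Read patient metadata
#'
#' Expected columns: `patient_id`, `pfs_days`, `progression_event`,
#' `best_response_pct` (signed percent change of the target-lesion sum,
#' RECIST convention: negative = shrinkage), `met_fish_status`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of patient records.
#' @export
read_patients <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(), pfs_days = readr::col_double(),
    progression_event = readr::col_logical(),
    best_response_pct = readr::col_double(),
    met_fish_status = readr::col_character()
  ))
  check_columns(p, c(
    "patient_id", "pfs_days", "progression_event", "best_response_pct",
    "met_fish_status"
  ), context = path)
  if (any(p$pfs_days < 0, na.rm = TRUE)) {
    abort_validation(sprintf("%s: negative pfs_days", path))
  }
  p
}

#' Read a population-variant blacklist
#'
#' A table of catalogued population variants (e.g. from a population
#' allele-frequency database) used to remove residual germline SNPs.
#' Accepts either `gene` + `variant` columns or `chrom`, `pos`, `ref`,
#' `alt` (in which case `gene`/`variant` are synthesised from them).
#'
#' @param path Path to a TSV file.
#' @return A tibble with at least `gene` and `variant` columns.
#' @export
read_blacklist <- function(path) {
  b <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (all(c("gene", "variant") %in% names(b))) {
    return(b)
  }
  check_columns(b, c("chrom", "pos", "ref", "alt"), context = path)
  b %>% mutate(
    gene = .data$chrom,
    variant = paste0(.data$pos, .data$ref, ">", .data$alt)
  )
}

#' Load a full study bundle from disk
#'
#' Reads the selector, control and patient depth matrices, variant table,
#' patient metadata and blacklist, validates all cross-references and
#' returns a single validated container for the pipeline.
#'
#' @param selector_bed Path to the selector BED file.
#' @param control_depths Path to the healthy-control depth TSV.
#' @param patient_depths Path to the patient depth TSV (may be `NULL`).
#' @param variants Path to the variant TSV (may be `NULL`).
#' @param patients Path to the patient metadata TSV (may be `NULL`).
#' @param blacklist Path to the blacklist TSV (may be `NULL`).
#' @return A `study_bundle` object (list with tibble components).
#' @export
load_study <- function(selector_bed, control_depths, patient_depths = NULL,
                       variants = NULL, patients = NULL, blacklist = NULL) {
  sel <- read_selector(selector_bed)
  ctrl <- read_depths(control_depths)
  check_regions <- function(d, context) {
    unknown <- setdiff(unique(d$region_id), sel$region_id)
    if (length(unknown) > 0) {
      abort_validation(sprintf(
        "%s: region_id not in selector: %s", context, unknown[1]
      ))
    }
    if (!setequal(unique(d$region_id), sel$region_id)) {
      abort_validation(sprintf("%s: does not cover every selector region", context))
    }
  }
  check_regions(ctrl, control_depths)
  pat_depths <- if (!is.null(patient_depths)) {
    d <- read_depths(patient_depths)
    check_regions(d, patient_depths)
    d
  }
  bl <- if (!is.null(blacklist)) read_blacklist(blacklist)
  vars <- if (!is.null(variants)) read_variants(variants, blacklist = bl)
  pats <- if (!is.null(patients)) read_patients(patients)
  if (!is.null(vars) && !is.null(pat_depths)) {
    orphan <- setdiff(unique(vars$sample_id), unique(pat_depths$sample_id))
    if (length(orphan) > 0) {
      warn(sprintf(
        "variant sample(s) without a depth column: %s",
        paste(orphan, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      selector = sel, control_depths = ctrl, patient_depths = pat_depths,
      variants = vars, patients = pats, blacklist = bl
    ),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  cat("  selector:", nrow(x$selector), "regions,",
    length(unique(x$selector$gene)), "genes\n")
  cat("  controls:", length(unique(x$control_depths$sample_id)), "samples\n")
  if (!is.null(x$patient_depths)) {
    cat("  patient samples:", length(unique(x$patient_depths$sample_id)), "\n")
  }
  if (!is.null(x$variants)) cat("  variant rows:", nrow(x$variants), "\n")
  if (!is.null(x$patients)) cat("  patients:", nrow(x$patients), "\n")
  invisible(x)
}

#' Write pipeline results and a run manifest
#'
#' Emits deterministic, column-stable TSVs for gene-level copy-number
#' calls and ctDNA estimates plus a `manifest.json` recording the seed,
#' a hash of the configuration and package versions. Writing the same
#' inputs twice produces byte-identical files.
#'
#' @param scna_calls Tibble of gene copy-number calls (may have 0 rows).
#' @param estimates Tibble of ctDNA estimates (may be `NULL`).
#' @param dir Output directory (created if absent).
#' @param seed Integer seed recorded in the manifest.
#' @param config List of configuration values (hashed into the manifest).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(scna_calls, estimates = NULL, dir, seed = NA_integer_,
                          config = list()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory %s", dir))
  }
  paths <- character(0)
  cn_cols <- c(
    "sample_id", "gene", "n_regions", "index", "threshold", "significant",
    "relative_depth", "conclusive", "normalized_cn"
  )
  cn <- as_tibble(scna_calls)
  for (cc in setdiff(cn_cols, names(cn))) cn[[cc]] <- NA
  cn <- cn[, cn_cols, drop = FALSE]
  p1 <- file.path(dir, "scna_calls.tsv")
  readr::write_tsv(cn, p1, na = "")
  paths <- c(paths, p1)
  if (!is.null(estimates)) {
    p2 <- file.path(dir, "ctdna_estimates.tsv")
    readr::write_tsv(as_tibble(estimates), p2, na = "")
    paths <- c(paths, p2)
  }
  manifest <- list(
    seed = if (is.na(seed)) NULL else as.integer(seed),
    config_hash = rlang::hash(config),
    package = "ctdnaprof",
    version = as.character(packageVersion("ctdnaprof"))
  )
  pm <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pm))
}
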