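# Patient-level orchestration and cohort-level percent formatting.

#' Format a cohort proportion the way the screen reports it
#'
#' Renders `100 * numerator / denominator` to two significant digits:
#' values of 10% or more are rounded to the nearest integer percent;
#' values below 10% keep one decimal, truncated toward zero (so 1/57 is
#' "1.7%", not "1.8%"). Zero renders as "0%".
#'
#' @param numerator,denominator non-negative integers with
#'   `numerator <= denominator`, `denominator > 0`.
#' @return a string like `"31%"` or `"1.7%"`.
#' @examples
#' format_percent(16, 52)  # "31%"
#' format_percent(1, 57)   # "1.7%"
#' format_percent(1, 52)   # "1.9%"
#' @export
format_percent <- function(numerator, denominator) {
  if (denominator <= 0) stopf("denominator must be > 0")
  if (numerator < 0 || numerator > denominator)
    stopf("numerator must be in [0, denominator]")
  pct <- 100 * numerator / denominator
  if (pct == 0) return("0%")
  if (pct < 10) sprintf("%.1f%%", floor(pct * 10 + 1e-9) / 10)
  else sprintf("%d%%", as.integer(round_half_away(pct)))
}

default_patient_params <- function() {
  list(min_depth = 20, normal_cn = 2, ccf_cap = 1.5, default_cn = NULL,
       k_max = 6, families = MIX_FAMILIES, n_restarts = 10,
       presence_threshold = 0.10,
       hyper_threshold = 500, capture_mb = 30,
       mmr_genes = c("MLH1", "MSH2", "MSH6", "PMS2"),
       ct = ct_params())
}

read_meta_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("sample" %in% names(df) && !"sample_id" %in% names(df))
    names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "timepoint", "purity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("metadata %s missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (any(df$purity <= 0 | df$purity > 1)) stopf("purity outside (0, 1]")
  df
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

resolve_inputs <- function(config) {
  cfg <- config
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading a YAML config requires the yaml package")
    cfg <- yaml::read_yaml(config)
  }
  if (!is.null(cfg$meta) && is.character(cfg$meta)) {
    if (!file.exists(cfg$meta)) stopf("missing metadata file: %s", cfg$meta)
    cfg$meta <- read_meta_tsv(cfg$meta)
  }
  cfg$meta <- cfg$meta[order(cfg$meta$timepoint), , drop = FALSE]
  ntp <- nrow(cfg$meta)
  check_paths <- function(paths, what) {
    for (p in paths) if (!file.exists(p)) stopf("missing %s file: %s", what, p)
  }
  if (is.null(cfg$variants)) {
    check_paths(cfg$vcf, "VCF")
    if (length(cfg$vcf) != ntp) stopf("need one VCF per timepoint")
    cfg$variants <- lapply(seq_len(ntp), function(t)
      read_somatic_vcf(cfg$vcf[t], cfg$meta$sample_id[t]))
  }
  if (is.null(cfg$segments)) {
    check_paths(cfg$seg, "SEG")
    if (length(cfg$seg) != ntp) stopf("need one SEG per timepoint")
    cfg$segments <- lapply(cfg$seg, read_segments)
  }
  if (is.null(cfg$depths) && !is.null(cfg$depth)) {
    check_paths(cfg$depth, "depth")
    cfg$depths <- lapply(cfg$depth, read.delim, stringsAsFactors = FALSE)
  }
  if (is.null(cfg$breakpoints) && !is.null(cfg$bedpe)) {
    check_paths(cfg$bedpe, "BEDPE")
    cfg$breakpoints <- lapply(seq_along(cfg$bedpe), function(t)
      read_breakpoints(cfg$bedpe[t], cfg$meta$sample_id[t]))
  }
  cfg
}

#' Run the full longitudinal analysis for one patient
#'
#' Stages, in order: CCF matrix assembly, mixture clustering with BIC
#' model selection, trajectory classification, per-timepoint spectra and
#' hypermutation screening, and (when breakpoints are provided)
#' chromothripsis calling with double-minute candidates. A stage error
#' aborts with the stage name. Deterministic for a given config and seed.
#'
#' @param config a list (or path to a YAML file) with either file inputs —
#'   `vcf`, `seg`, optional `depth` and `bedpe` (one path per timepoint,
#'   ordered), `meta` (path or data.frame) — or in-memory inputs
#'   (`variants`, `segments`, `depths`, `breakpoints`, `meta`); plus an
#'   optional `params` list overriding `min_depth`, `k_max`, `families`,
#'   `n_restarts`, `presence_threshold`, `hyper_threshold`, `capture_mb`,
#'   `mmr_genes`, `ct` (see [ct_params()]), `normal_cn`, `ccf_cap`,
#'   `default_cn`.
#' @param seed integer seed for the mixture fit.
#' @return object of class `patient_report`.
#' @export
run_patient <- function(config, seed = 1) {
  cfg <- stage("inputs", resolve_inputs(config))
  params <- utils::modifyList(default_patient_params(), cfg$params %||% list())
  metas <- cfg$meta
  ntp <- nrow(metas)

  ccf <- stage("clonality", assemble_ccf_matrix(
    cfg$variants, cfg$segments, metas,
    min_depth = params$min_depth, depths_by_timepoint = cfg$depths,
    normal_cn = params$normal_cn, ccf_cap = params$ccf_cap,
    default_cn = params$default_cn))

  fit <- stage("clustering", select_model(
    ccf, k_max = params$k_max, families = params$families, seed = seed,
    n_restarts = params$n_restarts))

  clusters <- stage("classification",
                    classify_clusters(fit, params$presence_threshold))

  spectra <- stage("signatures", lapply(seq_len(ntp), function(t) {
    sp <- mutation_spectrum(cfg$variants[[t]])
    hy <- flag_hypermutation(cfg$variants[[t]],
                             threshold = params$hyper_threshold,
                             capture_mb = params$capture_mb,
                             mmr_genes = params$mmr_genes)
    list(sample_id = metas$sample_id[t], spectrum = sp, hypermutation = hy)
  }))

  ct_calls <- if (!is.null(cfg$breakpoints)) {
    stage("chromothripsis", lapply(seq_len(ntp), function(t)
      call_chromothripsis(cfg$segments[[t]], cfg$breakpoints[[t]],
                          sample_id = metas$sample_id[t], params = params$ct)))
  } else NULL

  structure(list(
    meta = metas, ccf = ccf, fit = fit, clusters = clusters,
    spectra = spectra, chromothripsis = ct_calls,
    provenance = list(package = "longevol",
                      version = as.character(packageVersion("longevol")),
                      seed = seed, params = params)),
    class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("Patient report: %d timepoints, %d unique mutations\n",
              nrow(x$meta), nrow(x$ccf$values)))
  cat(sprintf("  selected mixture: k = %d (%s), BIC = %.1f\n",
              x$fit$k, x$fit$family, x$fit$bic))
  cat("  clusters:\n")
  print(x$clusters)
  for (s in x$spectra)
    cat(sprintf("  %s: %d SNVs, C>T %s, hypermutated: %s\n",
                s$sample_id, s$spectrum$n_snv,
                ifelse(is.na(s$spectrum$ct_fraction), "NA",
                       sprintf("%d%%", as.integer(round_half_away(
                         100 * s$spectrum$ct_fraction)))),
                s$hypermutation$is_hypermutated))
  invisible(x)
}

# plain-list view of a report for deterministic JSON serialization
patient_report_json <- function(x) {
  list(
    meta = x$meta,
    ccf = as.data.frame(x$ccf),
    mixture = list(k = x$fit$k, family = x$fit$family,
                   loglik = x$fit$loglik, bic = x$fit$bic,
                   n_params = x$fit$n_params, n = x$fit$n,
                   weights = as.numeric(x$fit$weights)),
    clusters = x$clusters,
    spectra = lapply(x$spectra, function(s) list(
      sample_id = s$sample_id,
      counts6 = as.list(s$spectrum$counts6),
      n_snv = s$spectrum$n_snv,
      ct_fraction = s$spectrum$ct_fraction,
      ct_percent = if (is.na(s$spectrum$ct_fraction)) NA else
        as.integer(round_half_away(100 * s$spectrum$ct_fraction)),
      hypermutation = list(
        coding_snv_count = s$hypermutation$coding_snv_count,
        mut_per_mb = s$hypermutation$mut_per_mb,
        is_hypermutated = s$hypermutation$is_hypermutated,
        mmr_hits = s$hypermutation$mmr_hits[
          c("gene", "chrom", "pos", "ref", "alt", "effect")]))),
    chromothripsis = if (is.null(x$chromothripsis)) NULL else
      lapply(x$chromothripsis, function(calls) lapply(calls, function(cl) list(
        sample_id = cl$sample_id, chroms = cl$chroms,
        event_type = cl$event_type, n_inter_links = cl$n_inter_links,
        n_dm_candidates = length(cl$dm_candidates),
        features = cl$features))),
    provenance = x$provenance)
}
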