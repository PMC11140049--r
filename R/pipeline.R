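#' Build a validated MR run configuration
#'
#' Bundles datasets and thresholds for [run_mr()]/[run_reverse()]. Datasets
#' may be given as canonical tibbles or as file paths (read through
#' [read_summary_stats()]/[read_ld_matrix()]). All thresholds are echoed
#' verbatim into the run report for provenance; unknown arguments are an
#' error rather than silently ignored.
#'
#' @param exposure,outcome Summary-statistics tibbles or file paths.
#' @param ld LD matrix (or path) covering the exposure's candidate
#'   instruments.
#' @param exposure_name,outcome_name Trait labels used in reports.
#' @param p_threshold Exposure instrument p-value threshold (default 5e-8).
#' @param clump_r2,clump_kb Clumping parameters (defaults 0.001, 10000).
#' @param f_min Minimum instrument F-statistic (default 10).
#' @param outcome_p_exclusion Drop instruments with outcome p below this
#'   (default 5e-8); `NA` disables the exclusion.
#' @param eaf_ambiguity_band Palindromic EAF ambiguity band (default 0.08).
#' @param ivw_mode IVW gate: `"auto"`, `"fixed"`, `"random"`.
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param seed Integer seed for the seeded components (required).
#' @param ... Unknown keys: always an error (typo guard).
#' @return List of class `"mr_run_config"`.
#' @export
mr_config <- function(exposure, outcome, ld,
                      exposure_name = "exposure", outcome_name = "outcome",
                      p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                      f_min = 10, outcome_p_exclusion = 5e-8,
                      eaf_ambiguity_band = 0.08, ivw_mode = "auto",
                      n_boot = 1000, seed = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(paste0("unknown configuration key(s): ",
                 paste(names(extra), collapse = ", ")))
  }
  if (is.character(exposure)) exposure <- read_summary_stats(exposure)
  if (is.character(outcome)) outcome <- read_summary_stats(outcome)
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  stopifnot(
    p_threshold > 0, p_threshold < 1, clump_r2 > 0, clump_r2 <= 1,
    clump_kb > 0, f_min > 0,
    is.na(outcome_p_exclusion) || (outcome_p_exclusion > 0 && outcome_p_exclusion < 1),
    eaf_ambiguity_band >= 0, eaf_ambiguity_band < 0.5,
    ivw_mode %in% c("auto", "fixed", "random"), n_boot >= 0
  )
  if (is.null(seed)) abort("mr_config requires a seed")
  structure(list(
    exposure = exposure, outcome = outcome, ld = ld,
    exposure_name = exposure_name, outcome_name = outcome_name,
    p_threshold = p_threshold, clump_r2 = clump_r2, clump_kb = clump_kb,
    f_min = f_min, outcome_p_exclusion = outcome_p_exclusion,
    eaf_ambiguity_band = eaf_ambiguity_band, ivw_mode = ivw_mode,
    n_boot = n_boot, seed = as.integer(seed)
  ), class = "mr_run_config")
}

#' Run a complete two-sample MR analysis
#'
#' Executes the full battery: instrument selection (p-value threshold,
#' clumping, F filter, outcome-association exclusion), harmonization, the
#' estimator suite (IVW with the Q gate, maximum likelihood, weighted
#' median, MR-Egger), and the sensitivity analyses (Cochran's Q, Egger
#' intercept, leave-one-out, funnel and scatter data). With fewer than three
#' surviving instruments the run degrades to IVW/ML with a warning. Two runs
#' with identical configuration (including seed) produce identical reports.
#'
#' @param config An [mr_config()].
#' @return List of class `"mr_report"`: trait names, `instruments`,
#'   `harmonized`, `estimates`, `heterogeneity`, `pleiotropy`, `loo`,
#'   `funnel`, `scatter`, per-stage `audit` counts, the echoed `settings`,
#'   `seed`, `version`, and `config_hash`.
#' @export
run_mr <- function(config) {
  stopifnot(inherits(config, "mr_run_config"))
  inst <- select_instruments(
    config$exposure, config$ld,
    p_threshold = config$p_threshold, clump_r2 = config$clump_r2,
    clump_kb = config$clump_kb, f_min = config$f_min,
    outcome = if (is.na(config$outcome_p_exclusion)) NULL else config$outcome,
    outcome_p_exclusion = if (is.na(config$outcome_p_exclusion)) 5e-8 else config$outcome_p_exclusion
  )
  h <- harmonize(inst, config$outcome,
                 eaf_ambiguity_band = config$eaf_ambiguity_band,
                 exposure_name = config$exposure_name,
                 outcome_name = config$outcome_name)
  he <- harmonized_effects(h)
  audit <- c(attr(inst, "audit"),
             harmonization_dropped = nrow(h) - nrow(he),
             analyzed = nrow(he))
  if (nrow(he) == 0) abort("no instruments survived selection and harmonization")
  estimates <- mr_all(he, ivw_mode = config$ivw_mode,
                      n_boot = config$n_boot, seed = config$seed)
  enough <- nrow(he) >= 3
  report <- list(
    exposure_name = config$exposure_name,
    outcome_name = config$outcome_name,
    instruments = inst,
    harmonized = h,
    estimates = estimates,
    heterogeneity = if (nrow(he) >= 2) cochran_q(he) else NULL,
    pleiotropy = if (enough) pleiotropy_test(he) else NULL,
    loo = if (enough) leave_one_out(he, mode = config$ivw_mode) else NULL,
    funnel = funnel_data(he),
    scatter = scatter_data(he, estimates),
    audit = audit,
    settings = config_settings(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("mrflow")),
    config_hash = rlang::hash(config_settings(config))
  )
  structure(report, class = "mr_report")
}

# Threshold/provenance echo (everything but the data tables).
config_settings <- function(config) {
  tibble(
    key = c("exposure_name", "outcome_name", "p_threshold", "clump_r2",
            "clump_kb", "f_min", "outcome_p_exclusion", "eaf_ambiguity_band",
            "ivw_mode", "n_boot", "seed"),
    value = as.character(c(config$exposure_name, config$outcome_name,
                           config$p_threshold, config$clump_r2, config$clump_kb,
                           config$f_min, config$outcome_p_exclusion,
                           config$eaf_ambiguity_band, config$ivw_mode,
                           config$n_boot, config$seed))
  )
}

#' Run the reverse-direction MR analysis
#'
#' Identical machinery to [run_mr()] with exposure and outcome roles
#' swapped; `ld` must cover the (reverse) exposure's candidate instruments.
#' The typical use is a batch over several outcomes, one report per trait,
#' summarized with [mr_report_table()].
#'
#' @inheritParams run_mr
#' @param ld Optional replacement LD matrix for the swapped exposure;
#'   defaults to the matrix already in `config`.
#' @return An `"mr_report"` for the swapped direction.
#' @export
run_reverse <- function(config, ld = NULL) {
  stopifnot(inherits(config, "mr_run_config"))
  swapped <- mr_config(
    exposure = config$outcome, outcome = config$exposure,
    ld = ld %||% config$ld,
    exposure_name = config$outcome_name, outcome_name = config$exposure_name,
    p_threshold = config$p_threshold, clump_r2 = config$clump_r2,
    clump_kb = config$clump_kb, f_min = config$f_min,
    outcome_p_exclusion = config$outcome_p_exclusion,
    eaf_ambiguity_band = config$eaf_ambiguity_band,
    ivw_mode = config$ivw_mode, n_boot = config$n_boot, seed = config$seed
  )
  run_mr(swapped)
}

#' One-row-per-analysis summary table from a list of reports
#'
#' The shape of a multi-trait results table: one row per report with the
#' headline IVW estimate and the heterogeneity/pleiotropy columns.
#'
#' @param reports List of `"mr_report"` objects.
#' @return Tibble, one row per report.
#' @export
mr_report_table <- function(reports) {
  purrr::map_dfr(reports, glance.mr_report)
}

#' Meta-analyze cohort-level MR estimates
#'
#' Pools per-cohort estimates (from a manifest tibble with `study` plus
#' `beta`/`se`, or `or`/`or_ci_low`/`or_ci_high`) with [meta_pool()] and
#' returns the forest-plot-ready table alongside the pooled results.
#'
#' @param estimates Cohort estimate tibble; rows are validated and a
#'   malformed row is reported by number.
#' @param model Pooling model passed to [meta_pool()].
#' @return List of class `"mr_meta_report"`: `studies` (per-cohort rows with
#'   OR-scale columns), `pooled` (the [meta_pool()] row), `forest` (studies
#'   plus pooled rows stacked for plotting).
#' @export
run_meta <- function(estimates, model = "auto") {
  if (!"beta" %in% names(estimates) && "or" %in% names(estimates)) {
    bad <- which(!(estimates$or > 0 & estimates$or_ci_low > 0 &
                     estimates$or_ci_high > estimates$or_ci_low))
    if (length(bad)) abort(paste0("malformed OR row(s): ", paste(bad, collapse = ", ")))
    estimates <- dplyr::bind_cols(
      estimates, or_to_beta(estimates$or, estimates$or_ci_low, estimates$or_ci_high))
  }
  bad <- which(!is.finite(estimates$beta) | !is.finite(estimates$se) | estimates$se <= 0)
  if (length(bad)) abort(paste0("malformed estimate row(s): ", paste(bad, collapse = ", ")))
  if (!"study" %in% names(estimates)) {
    estimates$study <- paste0("study_", seq_len(nrow(estimates)))
  }
  pooled <- meta_pool(estimates, model = model)
  studies <- dplyr::mutate(
    estimates,
    or = exp(.data$beta),
    or_ci_low = exp(.data$beta - Z95 * .data$se),
    or_ci_high = exp(.data$beta + Z95 * .data$se),
    weight_fixed = (1 / .data$se^2) / sum(1 / .data$se^2) * 100
  )
  forest <- dplyr::bind_rows(
    dplyr::select(studies, "study", "beta", "se", "or", "or_ci_low", "or_ci_high"),
    tibble(study = paste0("Pooled (", pooled$model, ")"),
           beta = pooled$beta, se = pooled$se, or = pooled$or,
           or_ci_low = pooled$or_ci_low, or_ci_high = pooled$or_ci_high)
  )
  structure(list(studies = studies, pooled = pooled, forest = forest),
            class = "mr_meta_report")
}

#' Write a run report as a set of TSV tables
#'
#' Emits machine-precision tables plus a human table with OR-scale numbers
#' rounded to two decimals, so publication-style display and exact
#' re-testing coexist. Identical reports produce byte-identical files.
#'
#' @param report An `"mr_report"`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_mr_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x)) readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  w(report$estimates, "estimates.tsv")
  human <- dplyr::transmute(
    report$estimates,
    exposure = report$exposure_name, outcome = report$outcome_name,
    method = .data$method, n_snp = .data$n_snp,
    or = sprintf("%.2f", .data$or),
    or_95ci = sprintf("%.2f-%.2f", .data$or_ci_low, .data$or_ci_high),
    pval = sprintf("%.3g", .data$pval)
  )
  w(human, "estimates_rounded.tsv")
  w(as_tibble(report$harmonized), "harmonized.tsv")
  if (!is.null(report$heterogeneity)) {
    sens <- tibble(
      exposure = report$exposure_name, outcome = report$outcome_name,
      q = report$heterogeneity$q, q_df = report$heterogeneity$df,
      q_pval = report$heterogeneity$pval,
      egger_intercept = if (is.null(report$pleiotropy)) NA_real_ else report$pleiotropy$intercept,
      intercept_se = if (is.null(report$pleiotropy)) NA_real_ else report$pleiotropy$se,
      intercept_pval = if (is.null(report$pleiotropy)) NA_real_ else report$pleiotropy$pval
    )
    w(sens, "sensitivity.tsv")
  }
  if (!is.null(report$loo)) w(as_tibble(report$loo), "leave_one_out.tsv")
  w(report$funnel, "funnel.tsv")
  w(report$scatter$points, "scatter_points.tsv")
  w(report$scatter$lines, "scatter_lines.tsv")
  w(tibble(stage = names(report$audit), count = as.integer(report$audit)), "audit.tsv")
  prov <- dplyr::bind_rows(
    report$settings,
    tibble(key = c("package_version", "config_hash"),
           value = c(report$version, report$config_hash))
  )
  w(prov, "config.tsv")
  invisible(dir)
}

#' @method print mr_report
#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s\n", x$exposure_name, x$outcome_name))
  cat(sprintf("Instruments analyzed: %d (of %d input SNPs)\n",
              x$audit[["analyzed"]], x$audit[["n_input"]]))
  print(dplyr::select(x$estimates, "method", "n_snp", "or",
                      "or_ci_low", "or_ci_high", "pval"))
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Cochran's Q = %.3f (df %d, p = %.3g)",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$pval))
    if (!is.null(x$pleiotropy)) {
      cat(sprintf("; Egger intercept = %.4f (p = %.3g)",
                  x$pleiotropy$intercept, x$pleiotropy$pval))
    }
    cat("\n")
  }
  invisible(x)
}
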