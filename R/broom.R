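#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR run report
#'
#' @param x An `"mr_report"`.
#' @param ... Unused.
#' @return The estimate tibble (one row per method) with trait labels.
#' @method tidy mr_report
#' @export
tidy.mr_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(exposure = x$exposure_name, outcome = x$outcome_name),
    x$estimates
  )
}

#' One-row summary of an MR run report
#'
#' The row shape of a multi-trait results table: trait labels, instrument
#' count, the headline IVW estimate, and the heterogeneity/pleiotropy
#' diagnostics.
#'
#' @inheritParams tidy.mr_report
#' @return One-row tibble.
#' @method glance mr_report
#' @export
glance.mr_report <- function(x, ...) {
  ivw <- x$estimates[startsWith(x$estimates$method, "ivw"), ][1, ]
  tibble(
    exposure = x$exposure_name,
    outcome = x$outcome_name,
    n_snp = ivw$n_snp,
    method = ivw$method,
    beta = ivw$beta, se = ivw$se,
    or = ivw$or, or_ci_low = ivw$or_ci_low, or_ci_high = ivw$or_ci_high,
    pval = ivw$pval,
    q = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$q,
    q_pval = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$pval,
    egger_intercept = if (is.null(x$pleiotropy)) NA_real_ else x$pleiotropy$intercept,
    intercept_pval = if (is.null(x$pleiotropy)) NA_real_ else x$pleiotropy$pval
  )
}

#' Tidy an MR-Egger fit
#'
#' @param x An `"mr_egger"` object.
#' @param ... Unused.
#' @return Two-row tibble: the slope and intercept terms.
#' @method tidy mr_egger
#' @export
tidy.mr_egger <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "slope", estimate = x$slope$beta, se = x$slope$se,
           pval = x$slope$pval),
    tibble(term = "intercept", estimate = x$intercept$intercept,
           se = x$intercept$se, pval = x$intercept$pval)
  )
}

#' Tidy a meta-analysis report
#'
#' @param x An `"mr_meta_report"`.
#' @param ... Unused.
#' @return The forest table (per-study rows plus the pooled row).
#' @method tidy mr_meta_report
#' @export
tidy.mr_meta_report <- function(x, ...) x$forest

#' One-row summary of a meta-analysis report
#'
#' @inheritParams tidy.mr_meta_report
#' @return The pooled [meta_pool()] row.
#' @method glance mr_meta_report
#' @export
glance.mr_meta_report <- function(x, ...) x$pooled
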