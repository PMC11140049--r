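#' Two-step mediation MR
#'
#' Combines three MR estimates — exposure-to-mediator (`beta_em`),
#' mediator-to-outcome (`beta_mo`), and the total exposure-to-outcome effect
#' (`beta_total`) — into the indirect effect `beta_em * beta_mo` and the
#' mediated proportion `indirect / beta_total`, with first-order
#' delta-method standard errors:
#' `se_indirect = sqrt(beta_em^2 * se_mo^2 + beta_mo^2 * se_em^2)` and
#' `se_proportion = sqrt(se_indirect^2 / beta_total^2 +
#'   indirect^2 * se_total^2 / beta_total^4)`, treating the indirect and
#' total estimates as independent. 95% CIs use the normal multiplier.
#'
#' @param beta_em,se_em Exposure-to-mediator effect and SE (log scale for
#'   binary traits).
#' @param beta_mo,se_mo Mediator-to-outcome effect and SE.
#' @param beta_total,se_total Total exposure-to-outcome effect and SE.
#' @return One-row tibble of class `"mr_mediation"`: the six inputs,
#'   `indirect`, `indirect_se`, `indirect_ci_low/high`, `proportion`,
#'   `proportion_se`, `proportion_ci_low/high`.
#' @export
two_step_mediation <- function(beta_em, se_em, beta_mo, se_mo, beta_total, se_total) {
  if (any(c(se_em, se_mo, se_total) <= 0)) abort("standard errors must be positive")
  if (abs(beta_total) < 1e-12) {
    abort("mediated proportion undefined: total effect is (numerically) zero")
  }
  indirect <- beta_em * beta_mo
  indirect_se <- sqrt(beta_em^2 * se_mo^2 + beta_mo^2 * se_em^2)
  proportion <- indirect / beta_total
  proportion_se <- sqrt(indirect_se^2 / beta_total^2 +
                          indirect^2 * se_total^2 / beta_total^4)
  out <- tibble(
    beta_em = beta_em, se_em = se_em,
    beta_mo = beta_mo, se_mo = se_mo,
    beta_total = beta_total, se_total = se_total,
    indirect = indirect, indirect_se = indirect_se,
    indirect_ci_low = indirect - Z95 * indirect_se,
    indirect_ci_high = indirect + Z95 * indirect_se,
    proportion = proportion, proportion_se = proportion_se,
    proportion_ci_low = proportion - Z95 * proportion_se,
    proportion_ci_high = proportion + Z95 * proportion_se
  )
  structure(out, class = c("mr_mediation", class(out)))
}

#' Mediated proportion from printed odds ratios
#'
#' Reconstructs the mediated proportion from odds ratios as reported in
#' publications: `ln(or_em) * ln(or_mo) / ln(or_total)`. Useful for checking
#' published two-step mediation results from their printed step ORs.
#'
#' @param or_em,or_mo,or_total Step and total odds ratios (> 0,
#'   `or_total != 1`).
#' @return The mediated proportion (fraction, not percent).
#' @export
mediated_proportion_from_ors <- function(or_em, or_mo, or_total) {
  stopifnot(all(c(or_em, or_mo, or_total) > 0))
  if (any(or_total == 1)) abort("mediated proportion undefined: total OR is 1")
  log(or_em) * log(or_mo) / log(or_total)
}

#' Screen a mediator panel by two-step mediation MR
#'
#' For each candidate mediator, runs the exposure-to-mediator MR (using the
#' supplied exposure instruments) and the mediator-to-outcome MR
#' (instrumenting the mediator at `mediator_p_threshold`, default 1e-5 as
#' used for sparse mediator GWAS), then combines both with the total effect
#' into a [two_step_mediation()] result. A mediator is retained when both
#' step p-values fall below `alpha` and the indirect effect is
#' direction-concordant with the total effect. No multiplicity correction is
#' applied by default (`p_adjust = "none"`), matching raw-p screening;
#' `"bonferroni"`/`"BH"` are available.
#'
#' @param exposure_instruments Selected exposure instrument tibble.
#' @param mediators Named list of mediator summary-statistics tibbles.
#' @param outcome Outcome summary-statistics tibble.
#' @param total Total-effect estimate row (e.g. `mr_ivw(...)` on the
#'   exposure-outcome harmonized set).
#' @param ld Optional LD matrix for clumping mediator instruments; `NULL`
#'   skips clumping (instruments assumed independent).
#' @param mediator_p_threshold Instrument threshold for the
#'   mediator-to-outcome step (default 1e-5).
#' @param f_min Minimum instrument F for mediator instruments (default 10).
#' @param alpha Per-step significance level for retention (default 0.05).
#' @param p_adjust Multiplicity correction applied to each step's p-values
#'   before the `alpha` screen: `"none"` (default), `"bonferroni"`, `"BH"`.
#' @return Tibble with one row per screened mediator: `mediator`, step
#'   estimates/SEs/p-values, the [two_step_mediation()] columns, and
#'   `retained`. Mediators with no usable instruments are skipped and
#'   counted in the `"audit"` attribute.
#' @export
screen_mediators <- function(exposure_instruments, mediators, outcome, total,
                             ld = NULL, mediator_p_threshold = 1e-5, f_min = 10,
                             alpha = 0.05, p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.list(mediators))
  skipped <- character(0)
  rows <- purrr::imap(mediators, function(med, nm) {
    h_em <- harmonized_effects(harmonize(exposure_instruments, med))
    if (nrow(h_em) == 0) {
      skipped <<- c(skipped, nm)
      inform(paste0("mediator '", nm, "' skipped: no exposure instruments found in its GWAS"))
      return(NULL)
    }
    step1 <- mr_ivw(h_em)
    inst_m <- filter_weak(select_by_pvalue(med, mediator_p_threshold), f_min = f_min)
    if (!is.null(ld)) inst_m <- clump(inst_m, ld)
    # the exposure's own instruments must not instrument the mediator step
    inst_m <- dplyr::filter(inst_m, !.data$snp_id %in% exposure_instruments$snp_id)
    h_mo <- harmonized_effects(harmonize(inst_m, outcome))
    if (nrow(h_mo) == 0) {
      skipped <<- c(skipped, nm)
      inform(paste0("mediator '", nm, "' skipped: zero usable instruments"))
      return(NULL)
    }
    step2 <- mr_ivw(h_mo)
    med_row <- two_step_mediation(step1$beta, step1$se, step2$beta, step2$se,
                                  total$beta, total$se)
    dplyr::bind_cols(
      tibble(mediator = nm, n_snp_em = step1$n_snp, p_em = step1$pval,
             n_snp_mo = step2$n_snp, p_mo = step2$pval),
      med_row
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out)) {
    p_em <- stats::p.adjust(out$p_em, method = if (p_adjust == "BH") "BH" else p_adjust)
    p_mo <- stats::p.adjust(out$p_mo, method = if (p_adjust == "BH") "BH" else p_adjust)
    out$retained <- p_em < alpha & p_mo < alpha &
      sign(out$indirect) == sign(out$beta_total)
    out <- dplyr::arrange(out, dplyr::desc(.data$retained), .data$p_em * .data$p_mo)
  }
  attr(out, "audit") <- c(n_panel = length(mediators), skipped = length(skipped),
                          screened = nrow(out),
                          retained = if (nrow(out)) sum(out$retained) else 0L)
  attr(out, "skipped") <- skipped
  out
}
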