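#' Cochran's Q heterogeneity test for the IVW model
#'
#' `Q = sum(w_j * (ratio_j - beta_ivw)^2)` over per-SNP Wald ratios with
#' first-order weights `w_j = beta_exp_j^2 / se_out_j^2`, where `beta_ivw`
#' is the fixed-effect IVW estimate; `df = J - 1` and the p-value is the
#' chi-square survival probability. Large Q signals heterogeneity across
#' instruments, the trigger for random-effects IVW.
#'
#' @inheritParams mr_ivw
#' @return One-row tibble: `q`, `df`, `pval`.
#' @export
cochran_q <- function(h) {
  h <- h_effects(h, min_snp = 2L, caller = "cochran_q")
  w <- h$beta_exp^2 / h$se_out^2
  ratio <- h$beta_out / h$beta_exp
  beta_ivw <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta_ivw)^2)
  df <- nrow(h) - 1L
  tibble(q = q, df = df, pval = min(max(stats::pchisq(q, df, lower.tail = FALSE),
                                        .Machine$double.xmin), 1))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Packages the intercept of [mr_egger()]: a nonzero intercept estimates the
#' average directional pleiotropic effect across instruments.
#'
#' @inheritParams mr_ivw
#' @return One-row tibble: `intercept`, `se`, `pval`, `n_snp`.
#' @export
pleiotropy_test <- function(h) {
  mr_egger(h)$intercept
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each SNP in turn, plus the full-set
#' estimate labelled `"All"`. A single SNP whose exclusion moves the estimate
#' markedly (or flips significance) indicates an estimate driven by that
#' instrument. The fixed/random gate is re-evaluated per subset and recorded
#' in `model_note`.
#'
#' @inheritParams mr_ivw
#' @param mode IVW gating mode applied to every subset (default `"auto"`).
#' @return Tibble of class `"mr_loo"`: one row per excluded SNP
#'   (`excluded = snp_id`) plus the `"All"` row, each with the estimate
#'   columns of [mr_ivw()].
#' @export
leave_one_out <- function(h, mode = "auto") {
  h <- h_effects(h, min_snp = 3L, caller = "leave_one_out")
  rows <- purrr::map(seq_len(nrow(h)), function(i) {
    dplyr::bind_cols(tibble(excluded = h$snp_id[i]), mr_ivw(h[-i, ], mode = mode))
  })
  out <- dplyr::bind_rows(
    dplyr::bind_rows(rows),
    dplyr::bind_cols(tibble(excluded = "All"), mr_ivw(h, mode = mode))
  )
  structure(out, class = c("mr_loo", class(out)))
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precision (`1/se`); asymmetry about the
#' pooled estimate suggests directional pleiotropy. Returns the numeric
#' table only — rendering is left to [plot_mr_funnel()] or the caller.
#'
#' @inheritParams mr_ivw
#' @return Tibble: `snp_id`, `ratio`, `se`, `precision`.
#' @export
funnel_data <- function(h) {
  h <- h_effects(h, min_snp = 1L, caller = "funnel_data")
  r <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  tibble(snp_id = h$snp_id, ratio = r$beta, se = r$se, precision = 1 / r$se)
}

#' Scatter-plot data
#'
#' Per-SNP effect pairs (exposure orientation forced positive, as in the
#' conventional scatter display) plus one fitted line per estimate row:
#' slope = the method's causal estimate, intercept = the Egger intercept for
#' `method = "egger"` and 0 otherwise.
#'
#' @inheritParams mr_ivw
#' @param estimates Estimate tibble, e.g. from [mr_all()].
#' @return List with tibbles `points` (`snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`) and `lines` (`method`, `intercept`, `slope`).
#' @export
scatter_data <- function(h, estimates) {
  h <- h_effects(h, min_snp = 1L, caller = "scatter_data")
  s <- ifelse(h$beta_exp < 0, -1, 1)
  points <- tibble(
    snp_id = h$snp_id,
    beta_exp = h$beta_exp * s,
    se_exp = h$se_exp,
    beta_out = h$beta_out * s,
    se_out = h$se_out
  )
  intercepts <- rep(0, nrow(estimates))
  if ("egger" %in% estimates$method && nrow(h) >= 3) {
    intercepts[estimates$method == "egger"] <- mr_egger(h)$intercept$intercept
  }
  lines <- tibble(method = estimates$method, intercept = intercepts,
                  slope = estimates$beta)
  list(points = points, lines = lines)
}
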