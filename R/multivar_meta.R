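#' Multivariable MR by weighted regression
#'
#' Jointly regresses harmonized outcome effects on several exposures' effect
#' columns (no intercept) with weights `1/se_out^2`, giving each exposure's
#' direct effect conditional on the others. SEs use multiplicative
#' overdispersion scaling `sqrt(max(Q/(J-k), 1))`, as in random-effects IVW;
#' with a single exposure the result reduces to univariable IVW.
#'
#' @param data Tibble with one row per SNP: columns `beta_<name>` (and
#'   optionally `se_<name>`) for each exposure, plus `beta_out`, `se_out`.
#'   Complete cases only — rows with any missing exposure beta are an error.
#' @param exposures Character vector of exposure names; defaults to every
#'   `beta_<name>` column except `beta_out`.
#' @return Estimate tibble, one row per exposure (`method = "mvmr_ivw"`,
#'   `exposure` column first); p-values from a two-sided normal reference.
#' @export
mvmr_ivw <- function(data, exposures = NULL) {
  if (is.null(exposures)) {
    bcols <- setdiff(grep("^beta_", names(data), value = TRUE), "beta_out")
    exposures <- sub("^beta_", "", bcols)
  }
  stopifnot(length(exposures) >= 1)
  cols <- paste0("beta_", exposures)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing exposure column(s): ", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[, cols, drop = FALSE])
  colnames(X) <- exposures
  if (anyNA(X) || anyNA(data$beta_out) || anyNA(data$se_out)) {
    abort("multivariable MR requires complete cases (no missing effects)")
  }
  J <- nrow(X)
  k <- ncol(X)
  if (J < k + 1) abort(sprintf("need at least %d SNPs for %d exposures; got %d", k + 1, k, J))
  fit <- wls_fit(X, data$beta_out, 1 / data$se_out^2)
  inflate2 <- max(fit$sigma2, 1)
  coefs <- unname(fit$coef)
  purrr::map_dfr(seq_len(k), function(i) {
    se <- unname(sqrt(fit$V[i, i] * inflate2))
    dplyr::bind_cols(
      tibble(exposure = exposures[i]),
      new_mr_estimate("mvmr_ivw", J, coefs[i], se, p_normal(coefs[i] / se),
                      sprintf("k = %d exposures; dispersion = %.3g", k, fit$sigma2))
    )
  })
}

#' Assemble a multivariable-MR input table
#'
#' Builds the complete-case SNP-by-exposure effect table from several
#' exposure summary datasets and one outcome: each exposure's instruments
#' are selected (p-value threshold, F filter), the union is re-clumped
#' jointly using the smallest per-SNP p-value across exposures, and every
#' dataset is aligned to a common reference allele per SNP (the orientation
#' of the first exposure dataset carrying it). SNPs missing from any dataset
#' or dropped in harmonization are excluded.
#'
#' @param exposures Named list of exposure summary-statistics tibbles.
#' @param outcome Outcome summary-statistics tibble.
#' @param ld LD matrix covering the union of candidate instruments.
#' @param p_threshold,clump_r2,clump_kb,f_min Instrument-selection settings
#'   (see [select_instruments()]).
#' @return Tibble with `snp_id`, `beta_<name>`/`se_<name>` per exposure,
#'   `beta_out`, `se_out`, ready for [mvmr_ivw()].
#' @export
mvmr_assemble <- function(exposures, outcome, ld, p_threshold = 5e-8,
                          clump_r2 = 0.001, clump_kb = 10000, f_min = 10) {
  stopifnot(is.list(exposures), length(exposures) >= 2, !is.null(names(exposures)))
  selected <- purrr::map(exposures, function(ex) {
    filter_weak(select_by_pvalue(ex, p_threshold), f_min = f_min)
  })
  # reference rows: first dataset carrying each union SNP, with the smallest
  # cross-exposure p-value attached for the joint re-clump
  ref <- dplyr::bind_rows(selected) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom), pos = dplyr::first(.data$pos),
      effect_allele = dplyr::first(.data$effect_allele),
      other_allele = dplyr::first(.data$other_allele),
      eaf = dplyr::first(.data$eaf), beta = dplyr::first(.data$beta),
      se = dplyr::first(.data$se), pval = min(.data$pval),
      n = dplyr::first(.data$n), .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  ref <- clump(ref, ld, clump_r2 = clump_r2, clump_kb = clump_kb)
  out <- tibble(snp_id = ref$snp_id)
  for (nm in names(exposures)) {
    hx <- harmonized_effects(harmonize(ref, exposures[[nm]]))
    idx <- match(out$snp_id, hx$snp_id)
    out[[paste0("beta_", nm)]] <- hx$beta_out[idx]
    out[[paste0("se_", nm)]] <- hx$se_out[idx]
  }
  hy <- harmonized_effects(harmonize(ref, outcome))
  idx <- match(out$snp_id, hy$snp_id)
  out$beta_out <- hy$beta_out[idx]
  out$se_out <- hy$se_out[idx]
  stats::na.omit(out)
}

#' Inverse-variance meta-analysis of cohort estimates
#'
#' Pools per-cohort causal estimates with fixed-effect weights `1/se^2` and
#' DerSimonian-Laird random-effects weights `1/(se^2 + tau2)`, where
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`. `model =
#' "auto"` selects fixed effects when the heterogeneity p-value exceeds
#' 0.05, random effects otherwise; both pooled results are always reported.
#'
#' @param estimates Tibble with columns `beta` and `se`, or `or`,
#'   `or_ci_low`, `or_ci_high` (auto-converted to the log-odds scale); an
#'   optional `study` column labels cohorts.
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @return One-row tibble: `k`, `model`, pooled `beta`/`se`/CI/`pval`
#'   (selected model, OR scale included), `q`, `q_df`, `q_pval`, `i2`
#'   (percent), `tau2` (0 under the fixed model), `tau2_dl`, and
#'   `beta_fixed`/`se_fixed`/`beta_random`/`se_random`.
#' @export
meta_pool <- function(estimates, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  if (!"beta" %in% names(estimates) && "or" %in% names(estimates)) {
    conv <- or_to_beta(estimates$or, estimates$or_ci_low, estimates$or_ci_high)
    estimates <- dplyr::bind_cols(estimates, conv)
  }
  stopifnot(all(c("beta", "se") %in% names(estimates)))
  k <- nrow(estimates)
  if (k < 2) abort("meta-analysis requires at least 2 studies")
  if (any(estimates$se <= 0)) abort("study standard errors must be positive")
  b <- estimates$beta
  w <- 1 / estimates$se^2
  beta_f <- sum(w * b) / sum(w)
  se_f <- sqrt(1 / sum(w))
  q <- sum(w * (b - beta_f)^2)
  q_df <- k - 1L
  q_pval <- min(max(stats::pchisq(q, q_df, lower.tail = FALSE), .Machine$double.xmin), 1)
  i2 <- max(0, (q - q_df) / q) * 100
  tau2_dl <- max(0, (q - q_df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (estimates$se^2 + tau2_dl)
  beta_r <- sum(wr * b) / sum(wr)
  se_r <- sqrt(1 / sum(wr))
  use_random <- switch(model, fixed = FALSE, random = TRUE, auto = q_pval < 0.05)
  beta <- if (use_random) beta_r else beta_f
  se <- if (use_random) se_r else se_f
  dplyr::bind_cols(
    tibble(k = as.integer(k), model = if (use_random) "random" else "fixed"),
    new_mr_estimate("meta", k, beta, se, p_normal(beta / se),
                    sprintf("%s-effects (Q p = %.3g)",
                            if (use_random) "random" else "fixed", q_pval))[, -(1:2)],
    tibble(q = q, q_df = q_df, q_pval = q_pval, i2 = i2,
           tau2 = if (use_random) tau2_dl else 0, tau2_dl = tau2_dl,
           beta_fixed = beta_f, se_fixed = se_f,
           beta_random = beta_r, se_random = se_r)
  )
}
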