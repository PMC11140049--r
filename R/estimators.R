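#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate: outcome effect divided by exposure
#' effect. The default standard error is the first-order delta-method
#' approximation `se_out / |beta_exp|`; the second-order variant adds the
#' exposure-uncertainty term
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#'
#' @param beta_exp,se_exp Exposure effect and standard error.
#' @param beta_out,se_out Outcome effect and standard error.
#' @param second_order Use the second-order delta-method SE? Default `FALSE`.
#' @return Tibble with columns `beta`, `se` (vectorized over inputs).
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, second_order = FALSE) {
  if (any(beta_exp == 0)) abort("wald_ratio undefined for beta_exp = 0")
  if (any(se_exp <= 0) || any(se_out <= 0)) abort("standard errors must be positive")
  beta <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  tibble(beta = beta, se = se)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Combines per-SNP Wald ratios with first-order inverse-variance weights —
#' equivalently, weighted least squares of outcome on exposure effects
#' through the origin with weights `1/se_out^2`. The fixed-effect SE is
#' `sqrt(1/sum(beta_exp^2/se_out^2))`; the random-effects (multiplicative
#' overdispersion) SE inflates it by `sqrt(max(Q/(J-1), 1))`. `mode = "auto"`
#' applies the Cochran's Q gate: random effects when the heterogeneity
#' p-value is below 0.05, fixed effects otherwise.
#'
#' @param h Harmonized set (see [harmonize()]) or a tibble with columns
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param mode `"auto"` (default), `"fixed"`, or `"random"`.
#' @return One-row estimate tibble (`method`, `n_snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `or`, `or_ci_low`, `or_ci_high`,
#'   `model_note`); p-values use a two-sided normal reference.
#' @export
mr_ivw <- function(h, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  h <- h_effects(h, min_snp = 1L, caller = "mr_ivw")
  w <- 1 / h$se_out^2
  sw <- sum(h$beta_exp^2 * w)
  beta <- sum(h$beta_exp * h$beta_out * w) / sw
  se_fixed <- sqrt(1 / sw)
  J <- nrow(h)
  if (J >= 2) {
    het <- cochran_q(h)
    inflate <- sqrt(max(het$q / het$df, 1))
    use_random <- switch(mode,
      fixed = FALSE,
      random = TRUE,
      auto = het$pval < 0.05
    )
  } else {
    het <- tibble(q = NA_real_, df = NA_integer_, pval = NA_real_)
    inflate <- 1
    use_random <- FALSE
  }
  se <- if (use_random) se_fixed * inflate else se_fixed
  note <- if (J < 2) {
    "fixed-effects (single SNP)"
  } else {
    sprintf("%s-effects (Q p = %.3g)", if (use_random) "random" else "fixed", het$pval)
  }
  new_mr_estimate(if (use_random) "ivw_random" else "ivw_fixed",
                  J, beta, se, p_normal(beta / se), note)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept, after orienting every SNP to a positive exposure effect
#' (both betas sign-flipped where needed) and weighting by `1/se_out^2`. The
#' slope estimates the causal effect under the InSIDE assumption; a nonzero
#' intercept indicates directional horizontal pleiotropy. Coefficient SEs use
#' the weighted-regression residual dispersion with `J - 2` degrees of
#' freedom, and p-values a two-sided t reference on `J - 2` df.
#'
#' @inheritParams mr_ivw
#' @return List of class `"mr_egger"`: `$slope`, a one-row estimate tibble
#'   (`method = "egger"`), and `$intercept`, a one-row tibble with columns
#'   `intercept`, `se`, `pval`, `n_snp`.
#' @export
mr_egger <- function(h) {
  h <- h_effects(h, min_snp = 3L, caller = "mr_egger")
  s <- ifelse(h$beta_exp < 0, -1, 1)
  x <- h$beta_exp * s
  y <- h$beta_out * s
  w <- 1 / h$se_out^2
  J <- length(x)
  fit <- wls_fit(cbind(`(Intercept)` = 1, x = x), y, w)
  se <- unname(sqrt(diag(fit$V) * fit$sigma2))
  b <- unname(fit$coef)
  slope <- new_mr_estimate("egger", J, b[2], se[2], p_t(b[2] / se[2], J - 2))
  intercept <- tibble(
    intercept = b[1],
    se = se[1],
    pval = p_t(b[1] / se[1], J - 2),
    n_snp = as.integer(J)
  )
  structure(list(slope = slope, intercept = intercept), class = "mr_egger")
}

# Weighted least squares via explicit normal equations; returns coefficients,
# unscaled covariance (X'WX)^-1, and the residual dispersion estimate.
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  A <- XtW %*% X
  qa <- qr(A)
  if (qa$rank < ncol(X)) {
    abort(paste0("rank-deficient weighted regression; collinear column(s): ",
                 paste(colnames(X)[qa$pivot[seq(qa$rank + 1, ncol(X))]], collapse = ", ")))
  }
  V <- solve(A)
  coef <- drop(V %*% (XtW %*% y))
  r <- y - drop(X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sum(w * r^2) / df else NA_real_
  list(coef = coef, V = V, sigma2 = sigma2, df = df, q = sum(w * r^2))
}

#' Weighted median estimate
#'
#' The weighted median of the per-SNP Wald ratios, using first-order
#' inverse-variance weights and linear interpolation of the weighted
#' empirical distribution at cumulative standardized weight 0.5. Consistent
#' when instruments carrying less than half the total weight are invalid.
#' The SE comes from a seeded parametric bootstrap: exposure and outcome
#' effects are resampled from normal distributions centred on the observed
#' values with their reported SEs and the estimator recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE (default 1000). `n_boot = 0`
#'   returns the point estimate with `NA` SE/CI/p, for simulation loops that
#'   only need the estimate.
#' @param seed Integer seed for the bootstrap (required when `n_boot > 0`);
#'   applied in a local RNG scope.
#' @return One-row estimate tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  h <- h_effects(h, min_snp = 3L, caller = "mr_weighted_median")
  ratios <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  w <- 1 / ratios$se^2
  beta <- weighted_quantile(ratios$beta, w, 0.5)
  J <- nrow(h)
  if (n_boot == 0) {
    return(new_mr_estimate("weighted_median", J, beta, NA_real_, NA_real_,
                           "point estimate only (n_boot = 0)"))
  }
  if (is.null(seed)) abort("mr_weighted_median requires a seed when n_boot > 0")
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      be <- stats::rnorm(J, h$beta_exp, h$se_exp)
      bo <- stats::rnorm(J, h$beta_out, h$se_out)
      ok <- be != 0
      weighted_quantile(bo[ok] / be[ok], (be[ok] / h$se_out[ok])^2, 0.5)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", J, beta, se, p_normal(beta / se),
                  sprintf("bootstrap SE (%d reps, seed %d)", n_boot, as.integer(seed)))
}

#' Maximum-likelihood estimate
#'
#' Maximizes the bivariate-normal likelihood in which each observed pair
#' `(beta_exp_j, beta_out_j)` is independent normal around `(g_j, beta * g_j)`
#' with the reported SEs. The per-SNP true effects `g_j` are profiled out in
#' closed form, leaving the one-dimensional profile objective
#' `sum((beta_out - beta * beta_exp)^2 / (se_out^2 + beta^2 * se_exp^2)) / 2`,
#' minimized numerically; the SE comes from the observed information
#' (numerical second derivative at the optimum). Equals IVW in the limit of
#' exactly measured exposure effects.
#'
#' @inheritParams mr_ivw
#' @return One-row estimate tibble (`method = "max_likelihood"`).
#' @export
mr_max_likelihood <- function(h) {
  h <- h_effects(h, min_snp = 1L, caller = "mr_max_likelihood")
  nll <- function(b) {
    sum((h$beta_out - b * h$beta_exp)^2 / (h$se_out^2 + b^2 * h$se_exp^2)) / 2
  }
  ivw <- mr_ivw(h, mode = "fixed")
  half <- max(1, 100 * ivw$se)
  opt <- stats::optimize(nll, interval = ivw$beta + c(-half, half), tol = 1e-10)
  beta <- opt$minimum
  eps <- 1e-5 * (1 + abs(beta))
  info <- (nll(beta + eps) - 2 * opt$objective + nll(beta - eps)) / eps^2
  if (!is.finite(info) || info <= 0) {
    abort(sprintf("maximum-likelihood estimation did not converge (beta = %.4g, curvature = %.4g)",
                  beta, info))
  }
  se <- 1 / sqrt(info)
  new_mr_estimate("max_likelihood", nrow(h), beta, se, p_normal(beta / se))
}

#' Run the full estimator suite on a harmonized set
#'
#' Computes IVW (with the Cochran's Q fixed/random gate), maximum likelihood,
#' weighted median, and MR-Egger, in that order. With fewer than three
#' usable instruments the estimators that need at least three (weighted
#' median, MR-Egger) are skipped with a warning, mirroring a degraded
#' pipeline run.
#'
#' @inheritParams mr_weighted_median
#' @param ivw_mode IVW gating mode (see [mr_ivw()]).
#' @return Estimate tibble, one row per method.
#' @export
mr_all <- function(h, ivw_mode = "auto", n_boot = 1000, seed = NULL) {
  he <- h_effects(h, min_snp = 1L, caller = "mr_all")
  res <- list(mr_ivw(he, mode = ivw_mode), mr_max_likelihood(he))
  if (nrow(he) >= 3) {
    res <- c(res, list(mr_weighted_median(he, n_boot = n_boot, seed = seed),
                       mr_egger(he)$slope))
  } else {
    warn(sprintf("only %d instrument(s): skipping weighted median and MR-Egger", nrow(he)))
  }
  dplyr::bind_rows(res)
}
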