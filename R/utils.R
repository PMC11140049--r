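# 95% normal quantile fixed to 6 decimals so reports are bit-reproducible
# across BLAS/libm builds.
Z95 <- 1.959964

#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Assemble the canonical one-row estimate tibble shared by every estimator.
# `pval` is computed by the caller (normal for IVW/ML/WM, t for Egger).
new_mr_estimate <- function(method, n_snp, beta, se, pval, model_note = NA_character_) {
  tibble(
    method = method,
    n_snp = as.integer(n_snp),
    beta = beta,
    se = se,
    ci_low = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    pval = pval,
    or = exp(beta),
    or_ci_low = exp(beta - Z95 * se),
    or_ci_high = exp(beta + Z95 * se),
    model_note = model_note
  )
}

# Two-sided p from a normal reference; clamped into (0, 1].
p_normal <- function(z) pmin(pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin), 1)

# Two-sided p from a t reference.
p_t <- function(t, df) pmin(pmax(2 * stats::pt(-abs(t), df = df), .Machine$double.xmin), 1)

# Linear interpolation of a weighted empirical quantile at probability p.
# Weights are standardized; evaluation points are midpoints of the cumulative
# weight steps, so an unweighted call reproduces the ordinary median.
weighted_quantile <- function(x, w, p = 0.5) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  stats::approx(cum, x, xout = p, rule = 2, ties = "ordered")$y
}

# Convert an odds ratio with 95% CI to (beta, se) on the log-odds scale.
or_to_beta <- function(or, ci_low, ci_high) {
  stopifnot(all(or > 0), all(ci_low > 0), all(ci_high > ci_low))
  tibble(beta = log(or), se = (log(ci_high) - log(ci_low)) / (2 * Z95))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
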