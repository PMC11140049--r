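test_that("Wald ratio arithmetic and delta-method SEs", {
  r <- wald_ratio(0.1, 0.02, 0.05, 0.02)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.2)

  r0 <- wald_ratio(0.2, 0.01, 0, 0.05)
  expect_equal(r0$beta, 0)
  expect_equal(r0$se, 0.05 / 0.2)

  # sign-invariance of the SE
  expect_equal(wald_ratio(-0.1, 0.02, 0.05, 0.02)$se, 0.2)

  # second-order SE equals the delta-method expression evaluated directly
  r2 <- wald_ratio(0.1, 0.02, 0.05, 0.02, second_order = TRUE)
  expect_equal(r2$se, sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))

  expect_error(wald_ratio(0, 0.02, 0.05, 0.02), "beta_exp")
})

test_that("IVW reduces correctly in degenerate cases", {
  h1 <- make_h(0.2, 0.04, se_out = 0.01)
  est <- mr_ivw(h1)
  expect_equal(est$beta, 0.2)           # single SNP: the Wald ratio
  expect_equal(est$se, 0.01 / 0.2)
  expect_equal(est$n_snp, 1L)
  expect_equal(est$or, exp(est$beta))

  h2 <- make_h(c(1, 1), c(0.1, 0.3), se_out = 1)
  expect_equal(mr_ivw(h2, mode = "fixed")$beta, 0.2)  # equal weights: plain mean

  expect_error(mr_ivw(make_h(numeric(0), numeric(0))), "at least 1")
})

test_that("IVW equals a weighted regression through the origin (independent oracle)", {
  for (seed in c(21, 22, 23)) {
    h <- random_h(50, seed)
    fit <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
    sm <- summary(fit)
    est_f <- mr_ivw(h, mode = "fixed")
    expect_equal(est_f$beta, unname(coef(fit)), tolerance = 1e-10)
    expect_equal(est_f$se, unname(sm$coefficients[1, 2] / sm$sigma), tolerance = 1e-10)
    est_r <- mr_ivw(h, mode = "random")
    expect_equal(est_r$se,
                 unname(sm$coefficients[1, 2] / min(sm$sigma, 1)), tolerance = 1e-10)
    expect_gte(est_r$se, est_f$se)  # multiplicative inflation floored at 1
  }
})

test_that("the fixed/random Q-gate picks the model the heterogeneity p dictates", {
  h_hom <- make_h(rep(1, 5), rep(0.3, 5), se_out = 1)      # identical ratios
  expect_equal(mr_ivw(h_hom, mode = "auto")$method, "ivw_fixed")
  h_het <- make_h(rep(1, 5), c(-3, -1.5, 0.1, 1.4, 3.2), se_out = 0.1)
  expect_lt(cochran_q(h_het)$pval, 0.05)
  auto <- mr_ivw(h_het, mode = "auto")
  expect_equal(auto$method, "ivw_random")
  expect_equal(auto$se, mr_ivw(h_het, mode = "random")$se)
})

test_that("MR-Egger recovers exact lines and matches weighted least squares", {
  g <- seq(0.05, 0.5, length.out = 10)
  h <- make_h(g, 0.05 + 0.3 * g, se_out = 0.02)
  fit <- mr_egger(h)
  expect_equal(fit$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$intercept$intercept, 0.05, tolerance = 1e-12)

  # zero-intercept construction
  h0 <- make_h(g, 0.3 * g, se_out = 0.02)
  expect_equal(mr_egger(h0)$intercept$intercept, 0, tolerance = 1e-12)

  for (seed in c(31, 32)) {
    h <- random_h(30, seed)
    s <- sign(h$beta_exp)
    lm_fit <- lm(I(beta_out * s) ~ I(beta_exp * s), data = h,
                 weights = 1 / h$se_out^2)
    sm <- summary(lm_fit)$coefficients
    fit <- mr_egger(h)
    expect_equal(fit$slope$beta, unname(sm[2, 1]), tolerance = 1e-10)
    expect_equal(fit$slope$se, unname(sm[2, 2]), tolerance = 1e-10)
    expect_equal(fit$slope$pval, unname(sm[2, 4]), tolerance = 1e-10)
    expect_equal(fit$intercept$intercept, unname(sm[1, 1]), tolerance = 1e-10)
    expect_equal(fit$intercept$se, unname(sm[1, 2]), tolerance = 1e-10)
    expect_equal(fit$intercept$pval, unname(sm[1, 4]), tolerance = 1e-10)
  }
  expect_error(mr_egger(make_h(c(1, 1), c(1, 1))), "at least 3")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  h <- make_h(c(1, 1, 1), c(0.1, 0.2, 0.9), se_out = 1)
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.2)

  # one SNP carrying ~90% of total weight dominates
  h2 <- make_h(c(1, 1, 1), c(0.1, 0.4, 0.9), se_out = c(0.3, 0.1, 0.3))
  w <- 1 / c(0.3, 0.1, 0.3)^2
  expect_gt(w[2] / sum(w), 0.8)
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta, 0.4)

  # estimate always lies inside the ratio range
  for (seed in 41:45) {
    h <- random_h(15, seed)
    est <- mr_weighted_median(h, n_boot = 0)$beta
    ratios <- h$beta_out / h$beta_exp
    expect_gte(est, min(ratios))
    expect_lte(est, max(ratios))
  }

  # bootstrap SE is seeded and reproducible
  h <- random_h(20, 46)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_equal(a$se, b$se)
  expect_true(is.finite(a$se) && a$se > 0)
})

test_that("maximum likelihood matches proportional data, the IVW limit, and a grid search", {
  g <- seq(0.05, 0.5, length.out = 8)
  h <- make_h(g, 0.3 * g, se_out = 0.05)
  expect_equal(mr_max_likelihood(h)$beta, 0.3, tolerance = 1e-8)

  # vanishing exposure-side noise: ML converges to IVW
  h_lim <- random_h(25, 51, se_exp_range = c(1e-8, 1e-8))
  expect_equal(mr_max_likelihood(h_lim)$beta, mr_ivw(h_lim, mode = "fixed")$beta,
               tolerance = 1e-6)

  # profile likelihood at the optimum beats a dense grid
  h <- random_h(10, 52)
  nll <- function(b) sum((h$beta_out - b * h$beta_exp)^2 /
                           (h$se_out^2 + b^2 * h$se_exp^2)) / 2
  opt <- mr_max_likelihood(h)$beta
  grid <- seq(opt - 0.5, opt + 0.5, length.out = 1e4)
  expect_lte(nll(opt), min(vapply(grid, nll, numeric(1))) + 1e-9)
})

test_that("estimators are order-invariant and scale equivariantly in the outcome", {
  h <- random_h(20, 61)
  perm <- withr::with_seed(62, sample.int(20))
  hp <- h[perm, ]
  expect_equal(mr_ivw(hp)$beta, mr_ivw(h)$beta)
  expect_equal(mr_egger(hp)$slope$beta, mr_egger(h)$slope$beta)
  expect_equal(mr_weighted_median(hp, n_boot = 0)$beta,
               mr_weighted_median(h, n_boot = 0)$beta)

  cc <- 2.5
  hs <- dplyr::mutate(h, beta_out = beta_out * cc, se_out = se_out * cc)
  for (f in list(function(x) mr_ivw(x, mode = "fixed"),
                 function(x) mr_ivw(x, mode = "random"),
                 function(x) mr_egger(x)$slope,
                 function(x) mr_weighted_median(x, n_boot = 0),
                 mr_max_likelihood)) {
    a <- f(h); b <- f(hs)
    expect_equal(b$beta, cc * a$beta, tolerance = 1e-6)
    if (is.finite(a$se)) expect_equal(b$se, cc * a$se, tolerance = 1e-6)
  }
})

test_that("mr_all runs the suite and degrades gracefully under 3 instruments", {
  h <- random_h(12, 71)
  est <- mr_all(h, seed = 5, n_boot = 50)
  expect_setequal(est$method,
                  c("ivw_fixed", "max_likelihood", "weighted_median", "egger"))
  expect_true(all(est$ci_low < est$ci_high))
  expect_equal(est$or, exp(est$beta))

  h2 <- random_h(2, 72)
  expect_warning(est2 <- mr_all(h2, seed = 5), "skipping")
  expect_setequal(est2$method, c("ivw_fixed", "max_likelihood"))
})
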