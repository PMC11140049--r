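mvmr_data <- function(J, k, seed, betas = NULL, noise = TRUE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(J * k, 0, 0.1), J, k)
    if (is.null(betas)) betas <- seq(0.05, by = 0.05, length.out = k)
    se_out <- runif(J, 0.005, 0.05)
    mu <- drop(X %*% betas)
    d <- tibble::tibble(snp_id = sprintf("rs%03d", 1:J),
                        beta_out = if (noise) rnorm(J, mu, se_out) else mu,
                        se_out = se_out)
    for (i in seq_len(k)) d[[paste0("beta_x", i)]] <- X[, i]
    d
  })
}

test_that("single-exposure MVMR reduces to univariable IVW", {
  d <- mvmr_data(20, 1, seed = 1)
  h <- make_h(d$beta_x1, d$beta_out, se_out = d$se_out)
  mv <- mvmr_ivw(d, exposures = "x1")
  ivw_r <- mr_ivw(h, mode = "random")
  ivw_f <- mr_ivw(h, mode = "fixed")
  expect_equal(mv$beta, ivw_f$beta, tolerance = 1e-12)
  # same multiplicative-floor dispersion as random-effects IVW
  expect_equal(mv$se, ivw_r$se, tolerance = 1e-12)
})

test_that("MVMR recovers noiseless multi-exposure constructions exactly", {
  d <- mvmr_data(30, 2, seed = 2, betas = c(0.08, 0.2), noise = FALSE)
  mv <- mvmr_ivw(d, exposures = c("x1", "x2"))
  expect_equal(mv$beta, c(0.08, 0.2), tolerance = 1e-10)

  # orthogonal exposure columns: each coefficient equals its own-column fit
  X <- withr::with_seed(3, {
    q <- qr.Q(qr(matrix(rnorm(40), 20, 2))) * 0.3
    q
  })
  d2 <- tibble::tibble(snp_id = sprintf("rs%03d", 1:20),
                       beta_out = drop(X %*% c(0.1, -0.25)),
                       se_out = rep(0.02, 20),
                       beta_x1 = X[, 1], beta_x2 = X[, 2])
  mv2 <- mvmr_ivw(d2)
  uni1 <- mr_ivw(make_h(X[, 1], d2$beta_out, se_out = 0.02), mode = "fixed")
  uni2 <- mr_ivw(make_h(X[, 2], d2$beta_out, se_out = 0.02), mode = "fixed")
  expect_equal(mv2$beta, c(uni1$beta, uni2$beta), tolerance = 1e-10)
})

test_that("MVMR coefficients match a weighted-regression oracle to 1e-10", {
  for (seed in c(4, 5, 6)) {
    k <- 4
    d <- mvmr_data(40, k, seed = seed)
    cols <- paste0("beta_x", 1:k)
    fit <- lm(reformulate(c("0", cols), response = "beta_out"), data = d,
              weights = 1 / d$se_out^2)
    sm <- summary(fit)
    mv <- mvmr_ivw(d)
    expect_equal(mv$beta, unname(coef(fit)), tolerance = 1e-10)
    oracle_se <- unname(sm$coefficients[, 2] / sm$sigma * max(sm$sigma, 1))
    expect_equal(mv$se, oracle_se, tolerance = 1e-10)
  }
})

test_that("rank-deficient MVMR designs raise a collinearity error", {
  d <- mvmr_data(20, 2, seed = 7)
  d$beta_x2 <- 2 * d$beta_x1
  expect_error(mvmr_ivw(d), "collinear")
  expect_error(mvmr_ivw(d[1:2, ], exposures = c("x1", "x2")), "at least 3")
  d2 <- mvmr_data(20, 2, seed = 8)
  d2$beta_x1[3] <- NA
  expect_error(mvmr_ivw(d2), "complete cases")
})

test_that("mvmr_assemble builds complete-case joint instrument tables", {
  simA <- simulate_two_sample(sim_config(seed = 21, n_snp = 40, gamma_sd = 0.15,
                                         n_exp = 2e5, palindromic_frac = 0))
  # second exposure: same SNP universe, different effects
  simB <- simulate_two_sample(sim_config(seed = 22, n_snp = 40, gamma_sd = 0.15,
                                         n_exp = 2e5, palindromic_frac = 0))
  expB <- simB$exposure
  expB$snp_id <- simA$exposure$snp_id
  expB$chrom <- simA$exposure$chrom
  expB$pos <- simA$exposure$pos
  tab <- mvmr_assemble(list(a = simA$exposure, b = expB), simA$outcome,
                       simA$ld, p_threshold = 5e-6)
  expect_true(all(c("beta_a", "se_a", "beta_b", "se_b", "beta_out", "se_out")
                  %in% names(tab)))
  expect_false(anyNA(tab))
  expect_gt(nrow(tab), 3)
  mv <- mvmr_ivw(tab, exposures = c("a", "b"))
  expect_equal(nrow(mv), 2L)
})

test_that("meta-analysis matches hand arithmetic on the two-study case", {
  est <- tibble::tibble(beta = c(0, 2), se = c(1, 1))
  m <- meta_pool(est, model = "fixed")
  expect_equal(m$beta, 1)
  expect_equal(m$se, 1 / sqrt(2))
  expect_equal(m$q, 2)
  expect_equal(m$tau2_dl, 1)  # (Q - 1) / (sum w - sum w^2 / sum w) = 1/1

  ident <- tibble::tibble(beta = rep(0.1, 3), se = rep(0.05, 3))
  mi <- meta_pool(ident)
  expect_equal(mi$beta, 0.1)
  expect_equal(mi$q, 0)
  expect_equal(mi$i2, 0)
  expect_equal(mi$tau2, 0)
  expect_equal(mi$model, "fixed")

  expect_error(meta_pool(ident[1, ]), "at least 2")
})

test_that("meta-analysis agrees with metafor for fixed and DL random effects", {
  skip_if_not_installed("metafor")
  for (seed in c(11, 12)) {
    est <- withr::with_seed(seed, tibble::tibble(beta = rnorm(5, 0.1, 0.15),
                                                 se = runif(5, 0.02, 0.2)))
    m <- meta_pool(est)
    fe <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
    dl <- metafor::rma(yi = est$beta, sei = est$se, method = "DL")
    expect_equal(m$beta_fixed, unname(coef(fe)), tolerance = 1e-10)
    expect_equal(m$se_fixed, unname(fe$se), tolerance = 1e-10)
    expect_equal(m$beta_random, unname(coef(dl)), tolerance = 1e-10)
    expect_equal(m$se_random, unname(dl$se), tolerance = 1e-10)
    expect_equal(m$tau2_dl, unname(dl$tau2), tolerance = 1e-10)
    expect_equal(m$q, unname(fe$QE), tolerance = 1e-10)
  }
})

test_that("meta-analysis invariants: permutation, pooled bounds, I2 floor", {
  est <- withr::with_seed(13, tibble::tibble(beta = rnorm(6, 0, 0.3),
                                             se = runif(6, 0.05, 0.3)))
  m <- meta_pool(est)
  mp <- meta_pool(est[withr::with_seed(14, sample.int(6)), ])
  expect_equal(mp$beta, m$beta)
  expect_gte(m$beta, min(est$beta))
  expect_lte(m$beta, max(est$beta))
  # fixed pooled variance never exceeds the best study variance
  expect_lte(m$se_fixed^2, min(est$se^2))
  if (m$q <= m$q_df) expect_equal(m$i2, 0)

  # OR-with-CI input converts to beta/se and pools identically
  or_in <- dplyr::transmute(est, or = exp(beta),
                            or_ci_low = exp(beta - 1.959964 * se),
                            or_ci_high = exp(beta + 1.959964 * se))
  expect_equal(meta_pool(or_in)$beta, m$beta, tolerance = 1e-10)
})
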