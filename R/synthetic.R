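#' Pleiotropy models for the synthetic generator
#'
#' `pleiotropy_none()` makes every instrument valid. `pleiotropy_balanced()`
#' gives invalid instruments direct outcome effects drawn from
#' `N(0, sd^2)` — zero on average, satisfying InSIDE. With
#' `pleiotropy_directional()` invalid instruments receive `mean + N(0, sd^2)`
#' applied in each SNP's exposure-increasing orientation (the effective
#' direct effect is `sign(g_j) * (mean + noise)`), which is how a shared
#' directional pathway manifests after harmonization orients instruments:
#' it biases IVW while leaving a majority-valid weighted median consistent.
#'
#' @param mean Mean direct effect on invalid instruments (directional only).
#' @param sd SD of the direct effects.
#' @return A pleiotropy specification list.
#' @export
pleiotropy_none <- function() list(type = "none", mean = 0, sd = 0)

#' @rdname pleiotropy_none
#' @export
pleiotropy_balanced <- function(sd) {
  stopifnot(sd >= 0)
  list(type = "balanced", mean = 0, sd = sd)
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_directional <- function(mean, sd) {
  stopifnot(sd >= 0)
  list(type = "directional", mean = mean, sd = sd)
}

#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults emulate the anorexia-nervosa-to-sepsis setting the package's
#' examples revolve around: a causal log-odds effect of 0.077 (odds ratio
#' 1.08), an exposure GWAS of ~72,500 subjects and an outcome GWAS of
#' ~463,000. Per-SNP standard errors follow the standard
#' `1/sqrt(2 * maf * (1 - maf) * n)` approximation.
#'
#' @param n_snp Number of candidate SNPs (overridden to
#'   `n_blocks * block_size` when `ld_blocks` is given).
#' @param n_exp,n_out Effective GWAS sample sizes.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5\].
#' @param beta_true Causal effect on the log-odds scale.
#' @param gamma_sd SD of true instrument effects `g_j ~ N(0, gamma_sd^2)`.
#' @param pleiotropy A [pleiotropy_none()]-family specification.
#' @param prop_invalid Fraction of instruments given pleiotropic effects.
#' @param ld_blocks `NULL` (all SNPs independent) or
#'   `list(n_blocks =, block_size =, within_r2 =)` for block-diagonal LD.
#' @param palindromic_frac Fraction of SNPs given A/T or C/G alleles.
#' @param seed Integer seed; required, and fully determines the output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_snp = 50, n_exp = 72500, n_out = 462918,
                       maf_range = c(0.05, 0.5), beta_true = 0.077,
                       gamma_sd = 0.1, pleiotropy = pleiotropy_none(),
                       prop_invalid = 0, ld_blocks = NULL,
                       palindromic_frac = 0.1, seed = NULL) {
  stopifnot(
    n_snp >= 1, n_exp > 0, n_out > 0,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    gamma_sd >= 0, prop_invalid >= 0, prop_invalid < 1,
    palindromic_frac >= 0, palindromic_frac <= 1,
    is.list(pleiotropy), pleiotropy$type %in% c("none", "balanced", "directional")
  )
  if (!is.null(ld_blocks)) {
    stopifnot(all(c("n_blocks", "block_size", "within_r2") %in% names(ld_blocks)),
              ld_blocks$within_r2 >= 0, ld_blocks$within_r2 <= 1)
    n_snp <- ld_blocks$n_blocks * ld_blocks$block_size
  }
  structure(list(
    n_snp = as.integer(n_snp), n_exp = n_exp, n_out = n_out,
    maf_range = maf_range, beta_true = beta_true, gamma_sd = gamma_sd,
    pleiotropy = pleiotropy, prop_invalid = prop_invalid,
    ld_blocks = ld_blocks, palindromic_frac = palindromic_frac,
    seed = seed
  ), class = "sim_config")
}

.pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
.nonpal_pairs <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulate paired two-sample GWAS summary statistics with known truth
#'
#' Generates exposure and outcome summary-statistics tables under the model
#' the two-sample estimators assume: true instrument effects
#' `g_j ~ N(0, gamma_sd^2)`; observed exposure effects
#' `N(g_j, se_exp_j^2)`; observed outcome effects
#' `N(beta_true * g_j + alpha_j, se_out_j^2)` with `alpha_j` from the
#' configured pleiotropy model on the invalid subset; SEs from the
#' `1/sqrt(2 * maf * (1 - maf) * n)` approximation; two-sided normal
#' p-values. LD is emitted at the r-squared summary level as a
#' block-diagonal matrix (blocks placed well apart so only within-block
#' pairs fall inside a clumping window).
#'
#' @param config A [sim_config()]; its `seed` must be set and fully
#'   determines the output.
#' @return List of class `"mr_sim"`: `exposure` and `outcome`
#'   summary-statistics tibbles, `ld` matrix, and `truth` (a list with
#'   `beta_true` and a per-SNP tibble of `g`, `alpha`, `valid`, `block`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) abort("sim_config$seed must be set: simulations take no implicit seed")
  withr::with_seed(as.integer(config$seed), {
    n <- config$n_snp
    snp_id <- sprintf("rs%06d", seq_len(n))
    if (is.null(config$ld_blocks)) {
      block <- seq_len(n)
      within_r2 <- 0
    } else {
      block <- rep(seq_len(config$ld_blocks$n_blocks), each = config$ld_blocks$block_size)
      within_r2 <- config$ld_blocks$within_r2
    }
    chrom <- as.character(((block - 1L) %% 22L) + 1L)
    # same-chromosome blocks sit 20 Mb apart: outside any clumping window
    pos <- 1e6 + ((block - 1L) %/% 22L) * 2e7 +
      (seq_len(n) - match(block, block)) * 1000

    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    pal <- stats::runif(n) < config$palindromic_frac
    pick <- ifelse(pal, sample.int(4L, n, replace = TRUE),
                   sample.int(8L, n, replace = TRUE))
    alleles <- t(vapply(seq_len(n), function(i) {
      if (pal[i]) .pal_pairs[[pick[i]]] else .nonpal_pairs[[pick[i]]]
    }, character(2)))

    g <- stats::rnorm(n, 0, config$gamma_sd)
    n_invalid <- round(config$prop_invalid * n)
    valid <- rep(TRUE, n)
    if (n_invalid > 0) valid[sample.int(n, n_invalid)] <- FALSE
    alpha <- numeric(n)
    pl <- config$pleiotropy
    if (pl$type == "balanced") {
      alpha[!valid] <- stats::rnorm(n_invalid, 0, pl$sd)
    } else if (pl$type == "directional") {
      alpha[!valid] <- sign(g[!valid]) * (pl$mean + stats::rnorm(n_invalid, 0, pl$sd))
    }

    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exp)
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * config$n_out)
    beta_exp <- stats::rnorm(n, g, se_exp)
    beta_out <- stats::rnorm(n, config$beta_true * g + alpha, se_out)

    mk <- function(beta, se, nn) tibble(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = maf, beta = beta, se = se,
      pval = p_normal(beta / se), n = nn
    )
    ld <- diag(n)
    if (within_r2 > 0) {
      same <- outer(block, block, `==`)
      ld[same] <- within_r2
      diag(ld) <- 1
    }
    dimnames(ld) <- list(snp_id, snp_id)
    structure(list(
      exposure = mk(beta_exp, se_exp, config$n_exp),
      outcome = mk(beta_out, se_out, config$n_out),
      ld = as_ld_matrix(ld),
      truth = list(beta_true = config$beta_true,
                   snps = tibble(snp_id = snp_id, g = g, alpha = alpha,
                                 valid = valid, block = block),
                   config = config)
    ), class = "mr_sim")
  })
}

#' Simulate linked exposure-mediator-outcome summary statistics
#'
#' Realizes the exposure -> mediator -> outcome chain behind two-step
#' mediation MR. The exposure's instruments carry effect `a` on the mediator
#' and total effect `c_direct + a * b` on the outcome; the mediator's own
#' instruments carry effect `b` on the outcome. The true mediated proportion
#' `a * b / (a * b + c_direct)` is recorded in the truth object.
#'
#' @param a Exposure-to-mediator effect.
#' @param b Mediator-to-outcome effect.
#' @param c_direct Direct (unmediated) exposure-to-outcome effect.
#' @param n_snp_exp,n_snp_med Instrument counts for exposure and mediator.
#' @param n_exp,n_med,n_out GWAS sample sizes for the three traits.
#' @param maf_range,gamma_sd As in [sim_config()].
#' @param seed Integer seed (required).
#' @return List of class `"mr_sim_mediation"`: `exposure`, `mediator`,
#'   `outcome` summary tibbles (the mediator and outcome tables contain both
#'   SNP sets), `exposure_snps`, `mediator_snps`, and `truth` (a list with
#'   `a`, `b`, `c_direct`, `total = a*b + c_direct`, `proportion`).
#' @export
simulate_mediation_triplet <- function(a, b, c_direct,
                                       n_snp_exp = 30, n_snp_med = 30,
                                       n_exp = 72500, n_med = 50000, n_out = 462918,
                                       maf_range = c(0.1, 0.4), gamma_sd = 0.1,
                                       seed = NULL) {
  if (is.null(seed)) abort("simulate_mediation_triplet requires a seed")
  withr::with_seed(as.integer(seed), {
    n <- n_snp_exp + n_snp_med
    is_exp <- seq_len(n) <= n_snp_exp
    snp_id <- sprintf("rs%06d", seq_len(n))
    chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
    pos <- 1e6 + ((seq_len(n) - 1L) %/% 22L) * 2e7
    maf <- stats::runif(n, maf_range[1], maf_range[2])
    pick <- sample.int(8L, n, replace = TRUE)
    ea <- vapply(pick, function(p) .nonpal_pairs[[p]][1], character(1))
    oa <- vapply(pick, function(p) .nonpal_pairs[[p]][2], character(1))
    g <- stats::rnorm(n, 0, gamma_sd)

    total <- c_direct + a * b
    mean_med <- ifelse(is_exp, a * g, g)
    mean_out <- ifelse(is_exp, total * g, b * g)

    mk <- function(means, nn, keep = rep(TRUE, n)) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * nn)
      beta <- stats::rnorm(n, means, se)
      tibble(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = maf,
             beta = beta, se = se, pval = p_normal(beta / se), n = nn)[keep, ]
    }
    structure(list(
      exposure = mk(ifelse(is_exp, g, 0), n_exp),
      mediator = mk(mean_med, n_med),
      outcome = mk(mean_out, n_out),
      exposure_snps = snp_id[is_exp],
      mediator_snps = snp_id[!is_exp],
      truth = list(a = a, b = b, c_direct = c_direct, total = total,
                   proportion = a * b / total)
    ), class = "mr_sim_mediation")
  })
}
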