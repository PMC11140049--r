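# Shared fixture builders. Everything is generated in code; no stored data.

# A valid random summary-statistics tibble with mixed allele types,
# occasional missing EAF, and scientific-notation-scale p-values.
random_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                  c("A", "T"), c("C", "G"), c("AT", "A"))
    pick <- sample(seq_along(pairs), n, replace = TRUE)
    beta <- rnorm(n, 0, 0.2)
    se <- runif(n, 0.001, 0.1)
    tibble::tibble(
      snp_id = sprintf("rs%05d", sample.int(99999, n)),
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(2e8, n),
      effect_allele = vapply(pick, function(p) pairs[[p]][1], character(1)),
      other_allele = vapply(pick, function(p) pairs[[p]][2], character(1)),
      eaf = ifelse(runif(n) < 0.1, NA_real_, runif(n, 0.01, 0.99)),
      beta = beta,
      se = se,
      pval = pmin(pmax(2 * pnorm(-abs(beta / se)), 1e-300), 1),
      n = ifelse(runif(n) < 0.2, NA_real_, sample.int(5e5, n))
    )
  })
}

# Minimal harmonized-effects tibble for estimator tests.
make_h <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.02,
                   snp_id = sprintf("rs%03d", seq_along(beta_exp))) {
  tibble::tibble(
    snp_id = snp_id,
    beta_exp = beta_exp,
    se_exp = rep_len(se_exp, length(beta_exp)),
    beta_out = beta_out,
    se_out = rep_len(se_out, length(beta_exp)),
    action = "aligned"
  )
}

# Random harmonized set drawn from the estimating model.
random_h <- function(J, seed, beta = 0.1, gamma_sd = 0.1,
                     se_exp_range = c(0.005, 0.02), se_out_range = c(0.005, 0.05)) {
  withr::with_seed(seed, {
    g <- rnorm(J, 0, gamma_sd)
    se_e <- runif(J, se_exp_range[1], se_exp_range[2])
    se_o <- runif(J, se_out_range[1], se_out_range[2])
    make_h(rnorm(J, g, se_e), rnorm(J, beta * g, se_o), se_e, se_o)
  })
}

# Exhaustive greedy clumping oracle: repeated scans over the remaining set,
# no index bookkeeping shared with the implementation.
clump_oracle <- function(tbl, ld, clump_r2 = 0.001, clump_kb = 10000) {
  remaining <- tbl[order(tbl$pval, tbl$chrom, tbl$pos, tbl$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    kept <- c(kept, top$snp_id)
    drop <- remaining$chrom == top$chrom &
      abs(remaining$pos - top$pos) <= clump_kb * 1000 &
      ld[remaining$snp_id, top$snp_id] >= clump_r2
    drop[1] <- TRUE
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}

# Random blocked candidate set plus LD matrix for clumping tests.
random_ld_instance <- function(seed, n_blocks = 3, block_size = 10) {
  r2 <- withr::with_seed(seed + 90000, runif(1, 0.1, 0.9))
  sim <- simulate_two_sample(sim_config(
    seed = seed, gamma_sd = 0.15, n_exp = 2e5,
    ld_blocks = list(n_blocks = n_blocks, block_size = block_size,
                     within_r2 = r2),
    palindromic_frac = 0
  ))
  list(tbl = sim$exposure, ld = sim$ld)
}

# Mirror a record's allele representation: swap alleles, flip beta and EAF.
mirror_records <- function(tbl, rows = seq_len(nrow(tbl))) {
  tbl[rows, c("effect_allele", "other_allele")] <-
    tbl[rows, c("other_allele", "effect_allele")]
  tbl$beta[rows] <- -tbl$beta[rows]
  tbl$eaf[rows] <- 1 - tbl$eaf[rows]
  tbl
}
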