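test_that("palindromic detection covers complements and indels", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("g", "c"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("AT", "A"))
  expect_equal(is_palindromic(c("A", "A"), c("T", "C")), c(TRUE, FALSE))
})

base_instrument <- function(ea = "A", oa = "G", beta = 0.10, eaf = 0.3) {
  tibble::tibble(snp_id = "rs1", chrom = "1", pos = 1000L,
                 effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = 0.02, pval = 1e-10, n = 1e5)
}
base_outcome <- function(ea = "A", oa = "G", beta = 0.05, eaf = 0.3) {
  tibble::tibble(snp_id = "rs1", chrom = "1", pos = 1000L,
                 effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = 0.03, pval = 0.01, n = 4e5)
}

test_that("swapped and strand-flipped alleles are aligned with sign corrections", {
  h <- harmonize(base_instrument(), base_outcome("G", "A", beta = 0.05, eaf = 0.7))
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.3)

  # same orientation: untouched
  h2 <- harmonize(base_instrument(), base_outcome())
  expect_equal(h2$action, "aligned")
  expect_equal(h2$beta_out, 0.05)

  # other strand, same orientation (A/G reported as T/C)
  h3 <- harmonize(base_instrument(), base_outcome("T", "C"))
  expect_equal(h3$action, "aligned")
  expect_equal(h3$beta_out, 0.05)

  # other strand, swapped (A/G reported as C/T)
  h4 <- harmonize(base_instrument(), base_outcome("C", "T", eaf = 0.7))
  expect_equal(h4$action, "flipped")
  expect_equal(h4$beta_out, -0.05)

  # irreconcilable allele sets are dropped, never silently kept
  h5 <- harmonize(base_instrument(), base_outcome("A", "C"))
  expect_equal(h5$action, "dropped_incompatible")
  expect_true(is.na(h5$beta_out))

  h6 <- harmonize(base_instrument(), base_outcome("C", "A", eaf = 0.7)[0, ])
  expect_equal(h6$action, "dropped_missing")
})

test_that("palindromic SNPs are oriented by EAF or dropped when ambiguous", {
  # frequencies agree (both rare): keep current orientation
  h <- harmonize(base_instrument("A", "T", eaf = 0.10),
                 base_outcome("A", "T", eaf = 0.12))
  expect_equal(h$action, "palindromic_inferred")
  expect_equal(h$beta_out, 0.05)

  # frequencies disagree: the outcome is on the other strand, flip
  h2 <- harmonize(base_instrument("A", "T", eaf = 0.10),
                  base_outcome("A", "T", beta = 0.05, eaf = 0.88))
  expect_equal(h2$action, "palindromic_inferred")
  expect_equal(h2$beta_out, -0.05)
  expect_equal(h2$eaf_out, 0.12)

  # EAF in the ambiguity band: dropped
  h3 <- harmonize(base_instrument("A", "T", eaf = 0.10),
                  base_outcome("A", "T", eaf = 0.50))
  expect_equal(h3$action, "dropped_palindromic")
  h4 <- harmonize(base_instrument("A", "T", eaf = 0.43),
                  base_outcome("A", "T", eaf = 0.10))
  expect_equal(h4$action, "dropped_palindromic")

  # missing EAF on a palindromic SNP: conservative drop
  h5 <- harmonize(base_instrument("A", "T", eaf = NA),
                  base_outcome("A", "T", eaf = 0.10))
  expect_equal(h5$action, "dropped_palindromic")

  # band is configurable
  h6 <- harmonize(base_instrument("A", "T", eaf = 0.43),
                  base_outcome("A", "T", eaf = 0.44), eaf_ambiguity_band = 0.05)
  expect_equal(h6$action, "palindromic_inferred")
})

test_that("harmonization is idempotent and accounts for every instrument", {
  sim <- simulate_two_sample(sim_config(seed = 11, n_snp = 40, gamma_sd = 0.15,
                                        n_exp = 2e5, palindromic_frac = 0.4))
  # scramble outcome representations so harmonization has real work to do
  out <- mirror_records(sim$outcome, rows = seq(1, 40, by = 2))
  h <- harmonize(sim$exposure, out)
  expect_equal(nrow(h), nrow(sim$exposure))
  retained <- harmonized_effects(h)
  expect_equal(nrow(retained) + sum(startsWith(h$action, "dropped")), nrow(h))

  # rebuild an outcome dataset from the harmonized table and re-harmonize
  out2 <- dplyr::transmute(retained,
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf_out, beta = beta_out, se = se_out,
    pval = 0.5, n = 4e5)
  exp2 <- dplyr::transmute(retained,
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf_exp, beta = beta_exp, se = se_exp,
    pval = 1e-10, n = 1e5)
  h2 <- harmonize(exp2, out2)
  keep2 <- harmonized_effects(h2)
  expect_equal(keep2$beta_out, retained$beta_out)
  expect_true(all(h2$action[!startsWith(h2$action, "dropped")] %in%
                    c("aligned", "palindromic_inferred")))
})

test_that("estimates are invariant to mirrored allele encodings", {
  sim <- simulate_two_sample(sim_config(seed = 12, n_snp = 30, gamma_sd = 0.15,
                                        n_exp = 2e5, palindromic_frac = 0))
  h_ref <- harmonized_effects(harmonize(sim$exposure, sim$outcome))

  # mirror outcome rows: identical harmonized effects up to the action tag
  out_m <- mirror_records(sim$outcome, rows = seq(1, 30, by = 3))
  h_m <- harmonized_effects(harmonize(sim$exposure, out_m))
  expect_equal(h_m$beta_out, h_ref$beta_out)
  expect_equal(h_m$eaf_out, h_ref$eaf_out)

  # mirror exposure rows: harmonized set differs by orientation only,
  # so every downstream estimator agrees
  exp_m <- mirror_records(sim$exposure, rows = seq(2, 30, by = 3))
  h_e <- harmonized_effects(harmonize(exp_m, sim$outcome))
  expect_equal(mr_ivw(h_e)$beta, mr_ivw(h_ref)$beta)
  expect_equal(mr_egger(h_e)$slope$beta, mr_egger(h_ref)$slope$beta)
  expect_equal(mr_max_likelihood(h_e)$beta, mr_max_likelihood(h_ref)$beta)
  expect_equal(mr_weighted_median(h_e, n_boot = 0)$beta,
               mr_weighted_median(h_ref, n_boot = 0)$beta)
})
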