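#' Is an allele pair palindromic?
#'
#' A biallelic SNP is palindromic when its two alleles are strand
#' complements of each other ({A,T} or {C,G}), so allele labels alone cannot
#' resolve which strand a dataset reports. Multi-base (indel) alleles cannot
#' be assessed and return `FALSE`.
#'
#' @param a1,a2 Allele character vectors.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1)
  a2 <- toupper(a2)
  single <- nchar(a1) == 1L & nchar(a2) == 1L
  single & allele_complement(a1) == a2
}

# Strand complement; multi-base alleles are complemented base-wise (not
# reverse-complemented: GWAS allele columns are not oriented sequences).
allele_complement <- function(a) chartr("ACGT", "TGCA", a)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each instrument's outcome record to the exposure's effect allele,
#' resolving swapped allele labels (sign-flipping the outcome beta and
#' mirroring its EAF), strand flips (complementing outcome alleles before
#' matching), and palindromic ambiguity. Palindromic SNPs are oriented by
#' effect-allele frequency when both EAFs are available and informative
#' (outside `0.5 +/- eaf_ambiguity_band`); otherwise they are dropped.
#' Instruments absent from the outcome dataset are dropped, mirroring the
#' manual removal of variants not identified in the outcome GWAS.
#'
#' Every instrument appears exactly once in the result, with its `action`:
#' `aligned`, `flipped`, `palindromic_inferred`, `dropped_palindromic`,
#' `dropped_missing`, or `dropped_incompatible` (irreconcilable allele sets).
#'
#' @param instruments Exposure instrument tibble (canonical columns).
#' @param outcome Outcome summary-statistics tibble.
#' @param eaf_ambiguity_band Half-width of the frequency band around 0.5
#'   within which a palindromic SNP's strand cannot be inferred (default
#'   0.08, i.e. drop when either EAF lies in \[0.42, 0.58\]).
#' @param exposure_name,outcome_name Labels carried into reports.
#' @return A tibble of class `"mr_harmonized"` with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele` (exposure orientation),
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#'   `action`. Dropped rows keep `NA` outcome effects. Use
#'   [harmonized_effects()] for the retained rows.
#' @export
harmonize <- function(instruments, outcome, eaf_ambiguity_band = 0.08,
                      exposure_name = "exposure", outcome_name = "outcome") {
  stopifnot(eaf_ambiguity_band >= 0, eaf_ambiguity_band < 0.5)
  out_idx <- match(instruments$snp_id, outcome$snp_id)

  n <- nrow(instruments)
  action <- character(n)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    j <- out_idx[i]
    if (is.na(j)) {
      action[i] <- "dropped_missing"
      next
    }
    ea_e <- toupper(instruments$effect_allele[i])
    oa_e <- toupper(instruments$other_allele[i])
    ea_o <- toupper(outcome$effect_allele[j])
    oa_o <- toupper(outcome$other_allele[j])
    b <- outcome$beta[j]
    s <- outcome$se[j]
    f <- outcome$eaf[j]

    if (is_palindromic(ea_e, oa_e)) {
      if (!((ea_o == ea_e && oa_o == oa_e) || (ea_o == oa_e && oa_o == ea_e))) {
        action[i] <- "dropped_incompatible"
        next
      }
      # label orientation first: put the outcome's effect allele on the
      # exposure's effect allele, then let EAF decide the strand
      if (ea_o == oa_e) {
        b <- -b
        f <- 1 - f
      }
      fe <- instruments$eaf[i]
      band <- c(0.5 - eaf_ambiguity_band, 0.5 + eaf_ambiguity_band)
      informative <- !is.na(fe) && !is.na(f) &&
        (fe < band[1] || fe > band[2]) && (f < band[1] || f > band[2])
      if (!informative) {
        action[i] <- "dropped_palindromic"
        next
      }
      if ((fe < 0.5) != (f < 0.5)) {  # frequencies disagree: other strand
        b <- -b
        f <- 1 - f
      }
      action[i] <- "palindromic_inferred"
    } else {
      if (ea_o == ea_e && oa_o == oa_e) {
        action[i] <- "aligned"
      } else if (ea_o == oa_e && oa_o == ea_e) {
        action[i] <- "flipped"
        b <- -b
        f <- 1 - f
      } else if (nchar(ea_o) == 1L && nchar(oa_o) == 1L &&
                 allele_complement(ea_o) == ea_e && allele_complement(oa_o) == oa_e) {
        action[i] <- "aligned"  # reported on the other strand
      } else if (nchar(ea_o) == 1L && nchar(oa_o) == 1L &&
                 allele_complement(ea_o) == oa_e && allele_complement(oa_o) == ea_e) {
        action[i] <- "flipped"
        b <- -b
        f <- 1 - f
      } else {
        action[i] <- "dropped_incompatible"
        next
      }
    }
    beta_out[i] <- b
    se_out[i] <- s
    eaf_out[i] <- f
  }

  out <- tibble(
    snp_id = instruments$snp_id,
    chrom = instruments$chrom,
    pos = instruments$pos,
    effect_allele = toupper(instruments$effect_allele),
    other_allele = toupper(instruments$other_allele),
    beta_exp = instruments$beta,
    se_exp = instruments$se,
    beta_out = beta_out,
    se_out = se_out,
    eaf_exp = instruments$eaf,
    eaf_out = eaf_out,
    action = action
  )
  structure(out,
            exposure_name = exposure_name,
            outcome_name = outcome_name,
            class = c("mr_harmonized", class(out)))
}

#' Retained rows of a harmonized set
#'
#' @param h An `"mr_harmonized"` tibble (or any tibble with the harmonized
#'   columns; rows with `action` starting with `"dropped"` are excluded).
#' @return Tibble of rows usable for estimation.
#' @export
harmonized_effects <- function(h) {
  keep <- !startsWith(h$action, "dropped")
  h[keep, , drop = FALSE]
}

# Coerce estimator input: accept a full harmonized set or a plain tibble of
# effect columns; drop unusable rows; enforce a minimum SNP count.
h_effects <- function(h, min_snp = 1L, caller = "estimator") {
  if (!is.null(h[["action"]])) h <- harmonized_effects(h)
  stopifnot(all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(h)))
  if (any(h$se_exp <= 0) || any(h$se_out <= 0)) abort("standard errors must be positive")
  if (nrow(h) < min_snp) {
    abort(paste0(caller, " requires at least ", min_snp,
                 " harmonized SNP(s); got ", nrow(h)))
  }
  h
}
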