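#' Filter summary statistics by association p-value
#'
#' Retains exactly the records with `pval` strictly below the threshold,
#' preserving input order. Conventional thresholds are genome-wide
#' significance 5e-8, the relaxed 5e-6 used when few independent hits exist,
#' and 1e-5 for sparse mediator GWAS.
#'
#' @param tbl Summary-statistics tibble.
#' @param p_threshold Strict upper bound on `pval`, in (0, 1).
#' @return The retained rows.
#' @export
select_by_pvalue <- function(tbl, p_threshold) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold < 1)
  dplyr::filter(tbl, .data$pval < p_threshold)
}

#' Instrument-strength F-statistic
#'
#' The per-SNP approximation `F = beta^2 / se^2`; values below ~10 flag weak
#' instruments. Sign-invariant in `beta` and always non-negative.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) abort("se must be positive")
  (beta / se)^2
}

#' Remove weak instruments by F-statistic
#'
#' @param tbl Summary-statistics tibble.
#' @param f_min Minimum F retained (boundary inclusive). Default 10.
#' @return The rows with `f_statistic(beta, se) >= f_min`.
#' @export
filter_weak <- function(tbl, f_min = 10) {
  stopifnot(f_min > 0)
  dplyr::filter(tbl, f_statistic(.data$beta, .data$se) >= f_min)
}

#' Greedy LD clumping
#'
#' Selects approximately independent index SNPs: records are ranked by
#' ascending p-value (ties broken by chromosome, position, then SNP id, so
#' the result is independent of input row order) and the best remaining SNP
#' repeatedly retained while discarding all unselected SNPs on the same
#' chromosome within `clump_kb` kilobases whose r-squared with it reaches
#' `clump_r2`. The defaults are the conventional 10,000 kb window with
#' r-squared < 0.001.
#'
#' @param tbl Summary-statistics tibble; every `snp_id` must appear in `ld`.
#' @param ld LD matrix over (at least) the candidate SNPs.
#' @param clump_r2 Discard threshold on r-squared, in (0, 1].
#' @param clump_kb Window half-width in kilobases.
#' @return The retained index SNPs in original input order, with an
#'   `"clumped_by"` attribute naming, for each discarded SNP, the index SNP
#'   that removed it.
#' @export
clump <- function(tbl, ld, clump_r2 = 0.001, clump_kb = 10000) {
  stopifnot(clump_r2 > 0, clump_r2 <= 1, clump_kb > 0)
  missing_ids <- setdiff(tbl$snp_id, rownames(ld))
  if (length(missing_ids)) {
    abort(paste0("SNP(s) absent from LD matrix: ",
                 paste(utils::head(missing_ids, 10L), collapse = ", ")))
  }
  if (nrow(tbl) == 0) return(tbl)
  ord <- order(tbl$pval, tbl$chrom, tbl$pos, tbl$snp_id)
  state <- rep(NA_character_, nrow(tbl))  # NA = undecided; "" = index; else remover id
  for (i in ord) {
    if (!is.na(state[i])) next
    state[i] <- ""
    near <- is.na(state) &
      tbl$chrom == tbl$chrom[i] &
      abs(tbl$pos - tbl$pos[i]) <= clump_kb * 1000 &
      ld[tbl$snp_id, tbl$snp_id[i]] >= clump_r2
    state[near] <- tbl$snp_id[i]
  }
  keep <- state == ""
  out <- tbl[keep, , drop = FALSE]
  attr(out, "clumped_by") <- stats::setNames(state[!keep], tbl$snp_id[!keep])
  out
}

#' Select independent, strong instruments for an exposure
#'
#' Runs the full instrument-selection cascade in the conventional order:
#' p-value threshold, greedy LD clumping, F-statistic filter, and (optionally)
#' exclusion of SNPs strongly associated with the outcome. Per-stage removal
#' counts are recorded in the `"audit"` attribute and always sum to
#' `n_input - n_retained`.
#'
#' @param tbl Exposure summary-statistics tibble.
#' @param ld LD matrix covering the candidates that survive the p-value step.
#' @param p_threshold Exposure association threshold (default 5e-8).
#' @param clump_r2,clump_kb Clumping parameters (defaults 0.001, 10000 kb).
#' @param f_min Minimum instrument F-statistic (default 10).
#' @param outcome Optional outcome summary-statistics tibble; instruments
#'   whose outcome association p-value falls below `outcome_p_exclusion` are
#'   removed so retained variants are exposure-specific.
#' @param outcome_p_exclusion Threshold for the outcome-association exclusion
#'   (default 5e-8).
#' @return Tibble of retained instruments with attribute `"audit"` (named
#'   integer vector: `n_input`, `fail_pvalue`, `clumped`, `weak`,
#'   `outcome_associated`, `retained`).
#' @export
select_instruments <- function(tbl, ld, p_threshold = 5e-8, clump_r2 = 0.001,
                               clump_kb = 10000, f_min = 10,
                               outcome = NULL, outcome_p_exclusion = 5e-8) {
  n_input <- nrow(tbl)
  s1 <- select_by_pvalue(tbl, p_threshold)
  s2 <- clump(s1, ld, clump_r2 = clump_r2, clump_kb = clump_kb)
  s3 <- filter_weak(s2, f_min = f_min)
  if (!is.null(outcome)) {
    assoc <- outcome$snp_id[outcome$pval < outcome_p_exclusion]
    s4 <- dplyr::filter(s3, !.data$snp_id %in% assoc)
  } else {
    s4 <- s3
  }
  audit <- c(
    n_input = n_input,
    fail_pvalue = n_input - nrow(s1),
    clumped = nrow(s1) - nrow(s2),
    weak = nrow(s2) - nrow(s3),
    outcome_associated = nrow(s3) - nrow(s4),
    retained = nrow(s4)
  )
  attr(s4, "audit") <- audit
  attr(s4, "clumped_by") <- attr(s2, "clumped_by")
  s4
}
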