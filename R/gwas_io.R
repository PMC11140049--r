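#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-separated summary-statistics table (one row per SNP)
#' into the canonical tibble used throughout the package. The delimiter is
#' auto-detected from the header line. Columns are matched against the
#' canonical header `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` (`N` and
#' `EAF` optional); files with other column names are handled through
#' `column_map`.
#'
#' Validation enforces the per-record invariants: `se > 0`, `pval` in (0, 1],
#' `eaf` missing or in \[0, 1\], effect allele distinct from other allele,
#' unique SNP identifiers, and non-missing `beta`/`se`/`pval`. In `"strict"`
#' mode any violation is an error naming the offending rows; in `"lenient"`
#' mode violating rows are dropped and the count reported via a message and
#' the `"n_dropped"` attribute.
#'
#' @param path Path to a TSV/CSV file with a header row. Missing EAF is
#'   encoded as `NA`; p-values may use scientific notation; alleles are
#'   upper-cased on read.
#' @param column_map Optional named character vector mapping canonical names
#'   (either internal names such as `"beta"` or file-style names such as
#'   `"BETA"`) to the column names actually present in the file, e.g.
#'   `c(beta = "Effect", se = "StdErr")`.
#' @param mode `"strict"` (default) or `"lenient"` invariant handling.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` (row order preserved).
#' @seealso [write_summary_stats()], [read_ld_matrix()]
#' @export
read_summary_stats <- function(path, column_map = NULL, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("summary-statistics file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("NA", ""),
    progress = FALSE,
    show_col_types = FALSE
  )
  tbl <- map_columns(raw, column_map)
  tbl <- dplyr::mutate(
    tbl,
    pos = as.numeric(.data$pos),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pval = as.numeric(.data$pval),
    n = as.numeric(.data$n),
    effect_allele = toupper(.data$effect_allele),
    other_allele = toupper(.data$other_allele)
  )
  validate_summary_stats(tbl, mode = mode)
}

# Canonical internal names and the file-header aliases accepted for each.
.canonical_cols <- c(
  snp_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
  other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
  pval = "P", n = "N"
)
.optional_cols <- c("eaf", "n")

map_columns <- function(raw, column_map) {
  want <- .canonical_cols
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    keys <- names(column_map)
    # accept either internal ("beta") or file-style ("BETA") keys
    internal <- ifelse(keys %in% names(want), keys,
                       names(want)[match(toupper(keys), want)])
    if (anyNA(internal)) {
      abort(paste0("unknown column_map keys: ",
                   paste(keys[is.na(internal)], collapse = ", ")))
    }
    want[internal] <- column_map
  }
  found <- match(want, names(raw))
  # fall back: header already uses internal names
  found[is.na(found)] <- match(names(want)[is.na(found)], names(raw))
  missing_req <- names(want)[is.na(found) & !names(want) %in% .optional_cols]
  if (length(missing_req)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(want[missing_req], collapse = ", ")))
  }
  out <- tibble(.rows = nrow(raw))
  for (i in seq_along(want)) {
    nm <- names(want)[i]
    out[[nm]] <- if (is.na(found[i])) NA_character_ else raw[[found[i]]]
  }
  out
}

#' Validate a summary-statistics tibble against the record invariants
#'
#' @param tbl Tibble with the canonical columns (see [read_summary_stats()]).
#' @param mode `"strict"` errors on the first violation; `"lenient"` drops
#'   violating rows, messaging the count.
#' @return The validated tibble (with attribute `"n_dropped"` in lenient mode).
#' @export
validate_summary_stats <- function(tbl, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  bad <- !is.finite(tbl$beta) | !is.finite(tbl$se) | tbl$se <= 0 |
    !is.finite(tbl$pval) | tbl$pval <= 0 | tbl$pval > 1 |
    (!is.na(tbl$eaf) & (tbl$eaf < 0 | tbl$eaf > 1)) |
    is.na(tbl$snp_id) | is.na(tbl$effect_allele) | is.na(tbl$other_allele) |
    tbl$effect_allele == tbl$other_allele
  dup <- duplicated(tbl$snp_id)
  if (mode == "strict") {
    if (any(bad)) {
      abort(paste0("invalid summary-statistics row(s): ",
                   paste(utils::head(which(bad), 5L), collapse = ", "),
                   " (snp: ", paste(utils::head(tbl$snp_id[bad], 5L), collapse = ", "), ")"))
    }
    if (any(dup)) {
      abort(paste0("duplicated snp_id: ",
                   paste(unique(tbl$snp_id[dup]), collapse = ", ")))
    }
    tbl
  } else {
    drop <- bad | dup
    if (any(drop)) inform(paste0("dropped ", sum(drop), " invalid row(s)"))
    out <- tbl[!drop, , drop = FALSE]
    attr(out, "n_dropped") <- sum(drop)
    out
  }
}

#' Write summary statistics to the canonical tab-separated format
#'
#' Writes the canonical header `SNP CHR POS EA OA EAF BETA SE P N`. Numeric
#' fields are written with full round-trip precision, so
#' `read_summary_stats(write_summary_stats(x))` reproduces `x` exactly.
#'
#' @param tbl Summary-statistics tibble (canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(tbl, path) {
  out <- tbl[, names(.canonical_cols)]
  names(out) <- unname(.canonical_cols)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a labeled LD (r-squared) matrix
#'
#' Expects a square tab-separated matrix whose first column and header carry
#' SNP identifiers. Validates symmetry (tolerance 1e-8), a unit diagonal, and
#' entries in \[0, 1\].
#'
#' @param path Path to the labeled square TSV.
#' @return A numeric matrix of pairwise r-squared values with SNP ids as
#'   dimnames, class `"ld_matrix"`.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  as_ld_matrix(m)
}

#' Validate a numeric matrix as an LD matrix
#'
#' @param m Square numeric matrix of r-squared values with SNP-id dimnames.
#' @return `m` with class `"ld_matrix"`.
#' @export
as_ld_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("LD matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m))) abort("LD matrix must carry SNP-id dimnames")
  if (!identical(rownames(m), colnames(m))) abort("LD matrix row/column labels disagree")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    abort("LD r-squared values must lie in [0, 1]")
  }
  if (max(abs(m - t(m))) > 1e-8) abort("LD matrix is asymmetric beyond tolerance 1e-8")
  if (any(abs(diag(m) - 1) > 0)) abort("LD matrix diagonal must be exactly 1")
  m <- (m + t(m)) / 2  # kill sub-tolerance asymmetry so downstream lookups agree
  diag(m) <- 1
  class(m) <- c("ld_matrix", class(m))
  m
}

#' Write an LD matrix in the labeled square TSV format
#'
#' @param m LD matrix (as from [as_ld_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  out <- as_tibble(unclass(m), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(SNP = rownames(m)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
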