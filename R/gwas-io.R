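# Reading, validating and writing GWAS summary-statistics tables.

CANONICAL_FIELDS <- c("snp_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pval", "n")

#' Default column map for summary-statistics tables
#'
#' A column map translates the canonical field names used throughout the
#' package to the column headers of a particular source file (FinnGen,
#' Olink pQTL exports and similar all differ). The default is the identity
#' mapping on the canonical names.
#'
#' @param ... Named overrides, e.g. `snp_id = "rsid"`, `pval = "p"`.
#' @return Named character vector mapping canonical names to source headers.
#' @examples
#' columnMap(snp_id = "rsid", pval = "p_value")
#' @export
columnMap <- function(...) {
  m <- stats::setNames(CANONICAL_FIELDS, CANONICAL_FIELDS)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), CANONICAL_FIELDS)
    if (length(bad)) {
      stop("unknown canonical field(s): ", paste(bad, collapse = ", "))
    }
    m[names(over)] <- over
  }
  m
}

# Row-wise validation used by readSummaryStats and the simulators' output
# checks. Returns the first failing reason code per row ("" = valid).
.validateRows <- function(d) {
  reason <- rep("", nrow(d))
  flag <- function(cond, code) {
    cond[is.na(cond)] <- TRUE
    reason <<- ifelse(reason == "" & cond, code, reason)
  }
  flag(is.na(d$snp_id) | d$snp_id == "", "missing_snp_id")
  flag(nchar(d$effect_allele) > 1 | nchar(d$other_allele) > 1, "indel")
  flag(!(d$effect_allele %in% VALID_BASES) |
       !(d$other_allele %in% VALID_BASES), "invalid_allele")
  flag(d$effect_allele == d$other_allele, "allele_identical")
  flag(is.na(d$se) | d$se <= 0, "nonpositive_se")
  flag(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1), "eaf_out_of_range")
  flag(is.na(d$pval) | d$pval < 0 | d$pval > 1, "invalid_pval")
  flag(is.na(d$n) | d$n <= 0, "nonpositive_n")
  flag(is.na(d$pos) | d$pos < 1, "invalid_pos")
  reason
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a delimited text file with a header row, renames columns through a
#' [columnMap()], uppercases alleles, floors p-values of exactly 0 to
#' `1e-300`, and drops rows violating the record invariants (biallelic
#' single-base alleles, `se > 0`, `eaf` in `[0, 1]`, `pval` in `(0, 1]`,
#' `n > 0`, `pos >= 1`). Every dropped row is logged with exactly one
#' reason code; the log is attached as attribute `"drop_log"`.
#'
#' @param path Path to a delimited text file.
#' @param colmap A [columnMap()]; fields absent from the file must still be
#'   mapped — a missing mapped column is an error. `eaf` may be `NA` in the
#'   data (needed only to orient palindromic SNPs).
#' @param sep Field separator (default tab; use `","` for CSV).
#' @param na Strings to treat as missing.
#' @return A `data.frame` of validated records in canonical columns plus a
#'   `palindromic` logical column; attributes `drop_log` (data.frame of
#'   `snp_id`, `reason`) and `n_dropped`.
#' @export
readSummaryStats <- function(path, colmap = columnMap(), sep = "\t",
                             na = c("NA", "", "nan", ".")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           na.strings = na, data.table = FALSE,
                           colClasses = list(character = unname(
                             colmap[c("snp_id", "chrom", "effect_allele",
                                      "other_allele")])))
  missing_cols <- setdiff(unname(colmap), names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  d <- raw[, unname(colmap)]
  names(d) <- names(colmap)
  d$snp_id <- as.character(d$snp_id)
  d$chrom <- as.character(d$chrom)
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  # p = 0 floors to 1e-300 so downstream log/quantile operations stay finite
  zero_p <- !is.na(d$pval) & d$pval == 0
  d$pval[zero_p] <- 1e-300

  reason <- .validateRows(d)
  keep <- reason == ""
  drop_log <- data.frame(snp_id = d$snp_id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("no valid rows in ", path, " (", nrow(drop_log), " dropped)")
  }
  d$pos <- as.integer(d$pos)
  d$palindromic <- isPalindromic(d$effect_allele, d$other_allele)
  rownames(d) <- NULL
  if (nrow(drop_log)) {
    message(nrow(drop_log), " row(s) dropped while reading ", basename(path))
  }
  attr(d, "drop_log") <- drop_log
  attr(d, "n_dropped") <- nrow(drop_log)
  d
}

#' Write an analysis report or summary-statistics table
#'
#' Tab-separated output with a header and stable column order; numeric
#' values are written at full precision so that a write/read round trip
#' reproduces them to at least 12 significant digits.
#'
#' @param records A non-empty `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeResultsTable <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("refusing to write an empty table")
  ok <- tryCatch({
    data.table::fwrite(records, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}
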