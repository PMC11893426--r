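# Instrument selection: p-value screening, LD clumping, instrument
# strength, and LD-proxy lookup.

#' Select SNPs below a p-value threshold
#'
#' @param stats Summary-statistics `data.frame` (see [readSummaryStats()]).
#' @param p_threshold Strict upper bound on `pval`, in (0, 1).
#' @return The rows with `pval < p_threshold`, input order preserved.
#' @export
selectByPvalue <- function(stats, p_threshold = 1e-5) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  stats[stats$pval < p_threshold, , drop = FALSE]
}

#' Per-SNP instrument strength
#'
#' The two-sample approximation `F = (beta/se)^2`, i.e. the squared
#' Z-statistic. `F >= 10` is the conventional weak-instrument floor.
#'
#' @param beta,se Effect and standard error vectors.
#' @return Numeric vector of F statistics.
#' @examples
#' fStatistic(0.1, 0.01) # 100
#' @export
fStatistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be > 0")
  (beta / se)^2
}

#' Greedy LD clumping
#'
#' PLINK-style greedy selection: candidates are ranked by ascending p-value
#' (ties broken by SNP id for determinism); the best remaining SNP is kept
#' and all others on the same chromosome within `window_kb` with
#' `r^2 > r2_max` against it are removed; repeat until exhausted.
#'
#' @param candidates Summary-statistics `data.frame` with `snp_id`, `chrom`,
#'   `pos`, `pval`.
#' @param ld Square r-squared matrix with SNP ids as dimnames covering all
#'   candidates (see [simulateLDMatrix()]).
#' @param r2_max Maximum allowed r-squared between kept SNPs (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @return The kept rows, sorted by (p-value, id). The result is invariant
#'   to the input order of `candidates`.
#' @export
ldClump <- function(candidates, ld, r2_max = 0.001, window_kb = 10000) {
  if (nrow(candidates) == 0L) return(candidates)
  missing_ids <- setdiff(candidates$snp_id, rownames(ld))
  if (length(missing_ids)) {
    stop("candidate SNP(s) absent from LD matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  ord <- order(candidates$pval, candidates$snp_id)
  d <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(d))
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    same_chr <- alive & d$chrom == d$chrom[i]
    near <- same_chr & abs(d$pos - d$pos[i]) <= window_kb * 1000
    r2 <- ld[d$snp_id[i], d$snp_id]
    hit <- near & r2 > r2_max
    hit[i] <- FALSE
    alive[hit] <- FALSE
    alive[i] <- FALSE
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter instruments on strength
#'
#' Annotates records with their F statistic and keeps those with
#' `F >= f_min`. Idempotent.
#'
#' @param stats Summary-statistics `data.frame`.
#' @param f_min Minimum per-SNP F (default 10).
#' @return `stats` rows with `f_stat` column, weak instruments removed; the
#'   removed rows are attached as attribute `"weak"`.
#' @export
filterByStrength <- function(stats, f_min = 10) {
  f <- fStatistic(stats$beta, stats$se)
  out <- stats[f >= f_min, , drop = FALSE]
  out$f_stat <- f[f >= f_min]
  attr(out, "weak") <- stats$snp_id[f < f_min]
  rownames(out) <- NULL
  out
}

#' Find an LD proxy for a missing SNP
#'
#' Returns the pool SNP with the highest r-squared to `missing_id` among
#' those exceeding `r2_min` (strict). Ties are broken by smaller p-value,
#' then lexicographic id.
#'
#' @param missing_id SNP id absent from the outcome data.
#' @param ld Square r-squared matrix including `missing_id`.
#' @param pool Summary-statistics `data.frame` of available SNPs.
#' @param r2_min Strict lower bound on proxy r-squared (default 0.8).
#' @return A one-row `data.frame` (the proxy, with `proxy_r2` column), or
#'   `NULL` when no pool SNP qualifies.
#' @export
findProxy <- function(missing_id, ld, pool, r2_min = 0.8) {
  if (!missing_id %in% rownames(ld)) {
    stop("SNP absent from LD matrix: ", missing_id)
  }
  pool <- pool[pool$snp_id != missing_id & pool$snp_id %in% colnames(ld), ,
               drop = FALSE]
  if (nrow(pool) == 0L) return(NULL)
  r2 <- ld[missing_id, pool$snp_id]
  elig <- r2 > r2_min
  if (!any(elig)) return(NULL)
  cand <- pool[elig, , drop = FALSE]
  cand$proxy_r2 <- r2[elig]
  cand <- cand[order(-cand$proxy_r2, cand$pval, cand$snp_id), , drop = FALSE]
  out <- cand[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full instrument-selection step
#'
#' Convenience wrapper: p-value screen, optional LD clumping, optional
#' strength filter — the selection the pipeline applies per exposure.
#'
#' @param stats Summary-statistics `data.frame`.
#' @param p_threshold Instrument p-value threshold (default 1e-5).
#' @param ld Optional LD matrix; clumping is skipped when `NULL`.
#' @param r2_max,window_kb Clumping parameters.
#' @param f_min Minimum per-SNP F; `NA` disables the strength filter.
#' @return Selected instrument rows (with `f_stat` when filtered).
#' @export
selectInstruments <- function(stats, p_threshold = 1e-5, ld = NULL,
                              r2_max = 0.001, window_kb = 10000,
                              f_min = 10) {
  sel <- selectByPvalue(stats, p_threshold)
  if (!is.null(ld) && nrow(sel) > 0L) {
    sel <- ldClump(sel, ld, r2_max = r2_max, window_kb = window_kb)
  }
  if (!is.na(f_min) && nrow(sel) > 0L) {
    sel <- filterByStrength(sel, f_min)
  }
  sel
}
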