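# Allele-specific harmonization of exposure and outcome associations.

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so their orientation
#' cannot be resolved from the alleles alone.
#'
#' @param a1,a2 Allele vectors (single bases).
#' @return Logical vector.
#' @examples
#' isPalindromic("A", "T") # TRUE
#' isPalindromic("A", "G") # FALSE
#' @export
isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome effect to the exposure's effect allele. Allele swaps
#' negate the outcome beta and complement its frequency; strand flips
#' complement the outcome alleles first. Palindromic SNPs are oriented by
#' comparing which side of 0.5 the two effect-allele frequencies fall on,
#' and dropped as ambiguous when either frequency lies within `eaf_window`
#' of 0.5 (or is missing).
#'
#' @param exp,out Single records (one-row `data.frame` or list) with fields
#'   `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`.
#' @param eaf_window Half-width of the palindrome ambiguity zone around an
#'   allele frequency of 0.5 (default 0.08, i.e. drop when eaf is in
#'   (0.42, 0.58)).
#' @param keep_palindromes Keep palindromic SNPs inside the ambiguity zone
#'   (still frequency-oriented; for sensitivity reruns).
#' @return One-row `data.frame` with `snp_id`, `bx`, `sx`, `by`, `sy`,
#'   `eaf_x`, `eaf_y`, `action` (`unchanged`, `sign_flipped`,
#'   `strand_flipped`, `dropped`), `drop_reason`.
#' @export
harmonizePair <- function(exp, out, eaf_window = 0.08,
                          keep_palindromes = FALSE) {
  if (exp$snp_id != out$snp_id) {
    stop("snp_id mismatch: ", exp$snp_id, " vs ", out$snp_id)
  }
  e1 <- exp$effect_allele; e2 <- exp$other_allele
  o1 <- out$effect_allele; o2 <- out$other_allele
  by <- out$beta; eaf_y <- out$eaf
  action <- NA_character_; reason <- ""

  res <- function(action, reason = "") {
    data.frame(snp_id = exp$snp_id,
               bx = exp$beta, sx = exp$se, by = by, sy = out$se,
               eaf_x = exp$eaf, eaf_y = eaf_y,
               action = action, drop_reason = reason,
               stringsAsFactors = FALSE)
  }

  if (isPalindromic(e1, e2)) {
    if (!setequal(c(o1, o2), c(e1, e2))) {
      return(res("dropped", "allele_mismatch"))
    }
    if (is.na(exp$eaf) || is.na(eaf_y)) {
      return(res("dropped", "palindrome_missing_eaf"))
    }
    # report on the exposure's effect-allele label first
    swapped <- o1 != e1
    if (swapped) {
      by <- -by; eaf_y <- 1 - eaf_y
    }
    ambiguous <- min(abs(exp$eaf - 0.5), abs(eaf_y - 0.5)) < eaf_window
    if (ambiguous && !keep_palindromes) {
      return(res("dropped", "ambiguous_palindrome"))
    }
    # frequencies on opposite sides of 0.5 imply opposite strand labels
    if ((exp$eaf - 0.5) * (eaf_y - 0.5) < 0) {
      by <- -by; eaf_y <- 1 - eaf_y
      swapped <- !swapped
    }
    return(res(if (swapped) "sign_flipped" else "unchanged"))
  }

  if (setequal(c(o1, o2), c(e1, e2))) {
    if (o1 == e1) return(res("unchanged"))
    by <- -by
    eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
    return(res("sign_flipped"))
  }

  c1 <- complementAllele(o1); c2 <- complementAllele(o2)
  if (setequal(c(c1, c2), c(e1, e2))) {
    if (c1 != e1) {
      by <- -by
      eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
    }
    return(res("strand_flipped"))
  }
  res("dropped", "allele_mismatch")
}

#' Harmonize an instrument set against outcome summary statistics
#'
#' Inner-joins exposure instruments with the outcome table on `snp_id`
#' (optionally substituting LD proxies for instruments missing from the
#' outcome), applies [harmonizePair()] per SNP, and assembles a
#' [HarmonizedSet-class] with a complete drop log.
#'
#' @param exp_instruments Instrument rows for the exposure.
#' @param out_stats Outcome summary-statistics `data.frame`.
#' @param exposure,outcome Trait names stored in the result.
#' @param eaf_window,keep_palindromes Passed to [harmonizePair()].
#' @param allow_proxies Substitute proxies for instruments absent from the
#'   outcome (default `FALSE`). A proxy replaces the instrument wholesale
#'   and must be present in `proxy_pool` (exposure stats) and `out_stats`.
#' @param ld LD matrix for proxy search (required when `allow_proxies`).
#' @param proxy_pool Exposure summary statistics to draw proxies from.
#' @param proxy_r2 Strict r-squared floor for proxies (default 0.8).
#' @return A [HarmonizedSet-class].
#' @export
harmonizeSets <- function(exp_instruments, out_stats,
                          exposure = "exposure", outcome = "outcome",
                          eaf_window = 0.08, keep_palindromes = FALSE,
                          allow_proxies = FALSE, ld = NULL,
                          proxy_pool = NULL, proxy_r2 = 0.8) {
  if (nrow(exp_instruments) == 0L) stop("empty instrument set")
  exp_instruments <- exp_instruments[!duplicated(exp_instruments$snp_id), ,
                                     drop = FALSE]
  drops <- data.frame(snp_id = character(), reason = character(),
                      stringsAsFactors = FALSE)

  present <- exp_instruments$snp_id %in% out_stats$snp_id
  if (allow_proxies && any(!present)) {
    if (is.null(ld) || is.null(proxy_pool)) {
      stop("allow_proxies requires `ld` and `proxy_pool`")
    }
    for (id in exp_instruments$snp_id[!present]) {
      pool <- proxy_pool[proxy_pool$snp_id %in% out_stats$snp_id &
                           !(proxy_pool$snp_id %in% exp_instruments$snp_id), ,
                         drop = FALSE]
      pr <- if (id %in% rownames(ld)) findProxy(id, ld, pool, proxy_r2) else NULL
      if (is.null(pr)) {
        drops <- rbind(drops, data.frame(snp_id = id, reason = "no_proxy"))
      } else {
        pr$proxy_r2 <- NULL
        exp_instruments <- rbind(
          exp_instruments[, names(pr), drop = FALSE][
            exp_instruments$snp_id != id, , drop = FALSE], pr)
        drops <- rbind(drops,
                       data.frame(snp_id = id,
                                  reason = paste0("proxied_by:", pr$snp_id)))
      }
    }
    present <- exp_instruments$snp_id %in% out_stats$snp_id
  }
  if (any(!present)) {
    drops <- rbind(drops, data.frame(snp_id = exp_instruments$snp_id[!present],
                                     reason = "absent_from_outcome"))
    exp_instruments <- exp_instruments[present, , drop = FALSE]
  }
  if (nrow(exp_instruments) == 0L) {
    stop("no instrument SNPs present in the outcome data (",
         nrow(drops), " dropped); check SNP id conventions")
  }

  rows <- vector("list", nrow(exp_instruments))
  for (i in seq_len(nrow(exp_instruments))) {
    e <- exp_instruments[i, , drop = FALSE]
    o <- out_stats[match(e$snp_id, out_stats$snp_id), , drop = FALSE]
    rows[[i]] <- harmonizePair(e, o, eaf_window = eaf_window,
                               keep_palindromes = keep_palindromes)
  }
  h <- do.call(rbind, rows)
  dropped <- h$action == "dropped"
  if (any(dropped)) {
    drops <- rbind(drops, data.frame(snp_id = h$snp_id[dropped],
                                     reason = h$drop_reason[dropped]))
  }
  kept <- h[!dropped, setdiff(names(h), "drop_reason"), drop = FALSE]
  rownames(kept) <- NULL
  new("HarmonizedSet", exposure = exposure, outcome = outcome,
      data = kept, drops = drops)
}
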