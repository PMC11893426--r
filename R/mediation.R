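# Two-step mediation: product-of-coefficients indirect effects with
# delta-method standard errors and mediation/suppression classification.

#' Product-of-coefficients mediation effect
#'
#' The indirect effect of an exposure on an outcome through a mediator:
#' the product of the exposure-to-mediator effect (A) and the
#' mediator-to-outcome effect (B).
#'
#' @param a_b Direct effect A (exposure on mediator).
#' @param b_b Direct effect B (mediator on outcome). Vectorized.
#' @return `a_b * b_b`.
#' @examples
#' mediationEffect(-0.0787, -0.2124) # 0.0167 to 4 d.p.
#' @export
mediationEffect <- function(a_b, b_b) a_b * b_b

#' Delta-method SE of a mediation effect
#'
#' Exact standard deviation of the product of two independent normal
#' estimators, including the second-order cross term:
#' `sqrt(a^2 sb^2 + b^2 sa^2 + sa^2 sb^2)`.
#'
#' @param a_b,a_se Direct effect A and its SE.
#' @param b_b,b_se Direct effect B and its SE. Vectorized.
#' @return Standard error of `a_b * b_b`.
#' @examples
#' deltaSE(-0.0787, 0.0321, -0.2124, 0.1002) # 0.0109 to 4 d.p.
#' @export
deltaSE <- function(a_b, a_se, b_b, b_se) {
  if (any(a_se < 0) || any(b_se < 0)) stop("standard errors must be >= 0")
  sqrt(a_b^2 * b_se^2 + b_b^2 * a_se^2 + a_se^2 * b_se^2)
}

#' Summarize a mediation analysis
#'
#' Combines a total effect (exposure on outcome) with the two direct
#' effects of a candidate mediator into the full mediation summary:
#' indirect effect, delta-method SE, two-sided normal p, mediation
#' proportion as a percentage with its confidence interval (the indirect
#' effect's Wald interval scaled by the total effect, which is treated as
#' fixed), and the mediation-versus-suppression label — `suppression` when
#' the indirect effect opposes the sign of the total effect.
#'
#' @param total_b,total_se Total effect of exposure on outcome (log-odds)
#'   and SE. `total_b` must be nonzero.
#' @param a_b,a_se Direct effect A (exposure on mediator).
#' @param b_b,b_se Direct effect B (mediator on outcome). All vectorized.
#' @param exposure,mediator,outcome Names carried into the output.
#' @param level Confidence level (default 0.95).
#' @return `data.frame` with one row per mediator: effects, `med_b`,
#'   `med_se`, `med_p`, `prop_pct`, `prop_lo`, `prop_hi`, `label`.
#' @examples
#' mediationSummary(1.1979, 0.3238, -0.0787, 0.0321, -0.2124, 0.1002)
#' @export
mediationSummary <- function(total_b, total_se, a_b, a_se, b_b, b_se,
                             exposure = "exposure", mediator = "mediator",
                             outcome = "outcome", level = 0.95) {
  if (any(total_b == 0)) stop("total effect must be nonzero")
  med_b <- mediationEffect(a_b, b_b)
  med_se <- deltaSE(a_b, a_se, b_b, b_se)
  med_p <- normalP(med_b, med_se)
  z <- zQuantile(level)
  prop <- 100 * med_b / total_b
  b1 <- 100 * (med_b - z * med_se) / total_b
  b2 <- 100 * (med_b + z * med_se) / total_b
  data.frame(exposure = exposure, mediator = mediator, outcome = outcome,
             total_b = total_b, total_se = total_se,
             a_b = a_b, a_se = a_se, b_b = b_b, b_se = b_se,
             med_b = med_b, med_se = med_se, med_p = med_p,
             prop_pct = prop, prop_lo = pmin(b1, b2), prop_hi = pmax(b1, b2),
             label = ifelse(sign(med_b) != sign(total_b),
                            "suppression", "mediation"),
             stringsAsFactors = FALSE)
}

#' Published CXCL6 / male-infertility mediation table
#'
#' The six-row mediation table for CXCL6 on male infertility through
#' plasma metabolites, shipped as a plain-text fixture: IVW total and
#' direct effects with the published indirect effects, delta SEs and
#' mediation proportions for comparison.
#'
#' @return `data.frame` with the printed effect columns
#'   (`total_b`, `total_se`, `a_b`, `a_se`, `b_b`, `b_se`) and the printed
#'   result columns (`med_b`, `med_se`, `med_p`, `prop_pct`, `prop_lo`,
#'   `prop_hi`, `label`).
#' @export
cxcl6MediationTable <- function() {
  path <- system.file("extdata", "cxcl6_male_infertility_mediation.tsv",
                      package = "mrpipe", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Screen candidate mediators by two-step MR
#'
#' Step 1 estimates exposure-to-mediator effects (IVW on the exposure's
#' instruments); step 2 estimates mediator-to-outcome effects (IVW on each
#' mediator's own instruments). Candidates are mediators nominally
#' significant in both steps.
#'
#' @param exposure_stats Exposure GWAS summary statistics.
#' @param mediator_stats Named list of mediator GWAS summary statistics.
#' @param outcome_stats Outcome GWAS summary statistics.
#' @param ld Optional LD matrix for clumping.
#' @param p_instrument Instrument p-value threshold (default 1e-5).
#' @param f_min Instrument-strength floor (default 10).
#' @param p_screen Nominal screening threshold for both steps (default 0.05).
#' @param eaf_window Palindrome ambiguity window for harmonization.
#' @return `data.frame` with one row per mediator: step effects, p-values,
#'   `candidate` flag and exclusion `reason` (empty when candidate).
#' @export
screenMediators <- function(exposure_stats, mediator_stats, outcome_stats,
                            ld = NULL, p_instrument = 1e-5, f_min = 10,
                            p_screen = 0.05, eaf_window = 0.08) {
  if (length(mediator_stats) == 0L) {
    return(data.frame(mediator = character(), step1_beta = numeric(),
                      step1_se = numeric(), step1_p = numeric(),
                      step2_beta = numeric(), step2_se = numeric(),
                      step2_p = numeric(), candidate = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  if (is.null(names(mediator_stats))) {
    names(mediator_stats) <- paste0("mediator_", seq_along(mediator_stats))
  }
  exp_inst <- selectInstruments(exposure_stats, p_instrument, ld,
                                f_min = f_min)
  rows <- lapply(names(mediator_stats), function(nm) {
    med <- mediator_stats[[nm]]
    row <- data.frame(mediator = nm, step1_beta = NA_real_,
                      step1_se = NA_real_, step1_p = NA_real_,
                      step2_beta = NA_real_, step2_se = NA_real_,
                      step2_p = NA_real_, candidate = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    s1 <- tryCatch({
      h <- harmonizeSets(exp_inst, med, eaf_window = eaf_window)
      if (nSnp(h) < 2L) stop("fewer than 2 instruments")
      mrIVW(h)
    }, error = function(e) e)
    if (inherits(s1, "error")) {
      row$reason <- "step1_unestimable"
      return(row)
    }
    row$step1_beta <- mrBeta(s1); row$step1_se <- mrSE(s1)
    row$step1_p <- mrPval(s1)
    med_inst <- selectInstruments(med, p_instrument, ld, f_min = f_min)
    s2 <- tryCatch({
      if (nrow(med_inst) == 0L) stop("no mediator instruments")
      h <- harmonizeSets(med_inst, outcome_stats, eaf_window = eaf_window)
      if (nSnp(h) < 2L) stop("fewer than 2 instruments")
      mrIVW(h)
    }, error = function(e) e)
    if (inherits(s2, "error")) {
      row$reason <- "step2_unestimable"
      return(row)
    }
    row$step2_beta <- mrBeta(s2); row$step2_se <- mrSE(s2)
    row$step2_p <- mrPval(s2)
    if (row$step1_p >= p_screen) {
      row$reason <- "step1_not_significant"
    } else if (row$step2_p >= p_screen) {
      row$reason <- "step2_not_significant"
    } else {
      row$candidate <- TRUE
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
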