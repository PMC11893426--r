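#' @import methods
NULL

# ---------------------------------------------------------------------------
# HarmonizedSet
# ---------------------------------------------------------------------------

#' Harmonized exposure/outcome effect pairs
#'
#' Container for per-SNP exposure and outcome associations aligned to the
#' same effect allele, the unit on which all causal estimators operate.
#' Created by [harmonizeSets()] or directly by [HarmonizedSet()] when the
#' data are already aligned.
#'
#' @slot exposure Name of the exposure trait.
#' @slot outcome Name of the outcome trait.
#' @slot data A `data.frame` with one row per retained SNP and columns
#'   `snp_id`, `bx`, `sx`, `by`, `sy`, `eaf_x`, `eaf_y`, `action`.
#' @slot drops A `data.frame` drop log with columns `snp_id`, `reason`.
#'
#' @seealso [mrIVW()], [mrEgger()], [mrWeightedMedian()], [mrWeightedMode()]
#' @export
setClass("HarmonizedSet",
  representation(
    exposure = "character",
    outcome = "character",
    data = "data.frame",
    drops = "data.frame"
  )
)

setValidity("HarmonizedSet", function(object) {
  need <- c("snp_id", "bx", "sx", "by", "sy", "eaf_x", "eaf_y", "action")
  d <- object@data
  msgs <- character()
  if (!all(need %in% names(d))) {
    msgs <- c(msgs, paste("data must have columns:", paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(d$snp_id)) msgs <- c(msgs, "snp_id values must be unique")
    if (nrow(d) > 0L && (any(d$sx <= 0) || any(d$sy <= 0))) {
      msgs <- c(msgs, "all standard errors must be > 0")
    }
  }
  if (!all(c("snp_id", "reason") %in% names(object@drops))) {
    msgs <- c(msgs, "drops must have columns snp_id, reason")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HarmonizedSet from aligned effect vectors
#'
#' @param bx,sx Exposure effects and standard errors (same effect allele as
#'   the outcome effects).
#' @param by,sy Outcome effects and standard errors.
#' @param snp_id SNP identifiers; defaults to `snp_1 ... snp_n`.
#' @param eaf_x,eaf_y Effect-allele frequencies (optional, `NA` allowed).
#' @param exposure,outcome Trait names.
#' @param drops Optional drop-log `data.frame` (`snp_id`, `reason`).
#' @return A [HarmonizedSet-class] object.
#' @examples
#' h <- HarmonizedSet(bx = c(0.1, 0.2, 0.15), sx = rep(0.01, 3),
#'                    by = c(0.03, 0.06, 0.045), sy = rep(0.01, 3))
#' nSnp(h)
#' @export
HarmonizedSet <- function(bx, sx, by, sy,
                          snp_id = paste0("snp_", seq_along(bx)),
                          eaf_x = rep(NA_real_, length(bx)),
                          eaf_y = rep(NA_real_, length(bx)),
                          exposure = "exposure", outcome = "outcome",
                          drops = data.frame(snp_id = character(),
                                             reason = character())) {
  n <- length(bx)
  sx <- rep_len(sx, n); sy <- rep_len(sy, n)
  eaf_x <- rep_len(eaf_x, n); eaf_y <- rep_len(eaf_y, n)
  stopifnot(length(by) == n, length(snp_id) == n)
  new("HarmonizedSet",
      exposure = exposure, outcome = outcome,
      data = data.frame(snp_id = as.character(snp_id),
                        bx = as.numeric(bx), sx = as.numeric(sx),
                        by = as.numeric(by), sy = as.numeric(sy),
                        eaf_x = as.numeric(eaf_x), eaf_y = as.numeric(eaf_y),
                        action = rep("unchanged", n),
                        stringsAsFactors = FALSE),
      drops = drops)
}

#' @describeIn HarmonizedSet-class Number of retained SNPs.
#' @param x,object A `HarmonizedSet`.
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' @rdname HarmonizedSet-class
#' @export
setMethod("nSnp", "HarmonizedSet", function(x) nrow(x@data))

#' @describeIn HarmonizedSet-class Per-SNP harmonized data.
#' @export
setGeneric("harmonizedData", function(x) standardGeneric("harmonizedData"))

#' @rdname HarmonizedSet-class
#' @export
setMethod("harmonizedData", "HarmonizedSet", function(x) x@data)

#' @describeIn HarmonizedSet-class Drop log of removed SNPs with reasons.
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))

#' @rdname HarmonizedSet-class
#' @export
setMethod("dropLog", "HarmonizedSet", function(x) x@drops)

#' @describeIn HarmonizedSet-class Exposure trait name.
#' @export
setGeneric("exposureName", function(x) standardGeneric("exposureName"))

#' @rdname HarmonizedSet-class
#' @export
setMethod("exposureName", "HarmonizedSet", function(x) x@exposure)

#' @describeIn HarmonizedSet-class Outcome trait name.
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))

#' @rdname HarmonizedSet-class
#' @export
setMethod("outcomeName", "HarmonizedSet", function(x) x@outcome)

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", object@exposure, "->", object@outcome, "\n")
  cat("  SNPs retained:", nrow(object@data),
      " dropped:", nrow(object@drops), "\n")
  if (nrow(object@drops)) {
    tab <- table(object@drops$reason)
    cat("  drop reasons:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(object)
})

# ---------------------------------------------------------------------------
# MREstimate and method-specific subclasses
# ---------------------------------------------------------------------------

#' Causal-effect estimate from one MR method
#'
#' Holds the causal effect on the log-odds (binary outcome) or SD
#' (continuous outcome) scale, its standard error, two-sided normal p-value,
#' and the odds-ratio representation with its confidence interval.
#'
#' @slot method One of `wald`, `ivw_fixed`, `ivw_random`, `egger`,
#'   `weighted_median`, `weighted_mode`.
#' @slot beta,se,pval Estimate, standard error, two-sided p-value.
#' @slot or,ciLow,ciHigh `exp(beta)` and `exp(beta -/+ z se)`.
#' @slot level Confidence level used for the interval.
#' @slot nsnp Number of SNPs entering the estimate.
#' @export
setClass("MREstimate",
  representation(
    method = "character",
    beta = "numeric", se = "numeric", pval = "numeric",
    or = "numeric", ciLow = "numeric", ciHigh = "numeric",
    level = "numeric", nsnp = "integer"
  )
)

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (object@se < 0) msgs <- c(msgs, "se must be >= 0")
  if (object@se > 0 &&
      !(object@ciLow < object@or && object@or < object@ciHigh)) {
    msgs <- c(msgs, "CI must bracket the odds ratio when se > 0")
  }
  if (length(msgs)) msgs else TRUE
})

# Internal constructor shared by the estimators.
newMREstimate <- function(class = "MREstimate", method, beta, se, nsnp,
                          level = 0.95, ...) {
  ci <- orCI(beta, se, level)
  new(class, method = method, beta = beta, se = se,
      pval = normalP(beta, se),
      or = unname(ci["or"]), ciLow = unname(ci["ci_low"]),
      ciHigh = unname(ci["ci_high"]),
      level = level, nsnp = as.integer(nsnp), ...)
}

#' @describeIn MREstimate-class Causal effect (log scale).
#' @param x,object An `MREstimate`.
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname MREstimate-class
#' @export
setMethod("mrBeta", "MREstimate", function(x) x@beta)

#' @describeIn MREstimate-class Standard error of the causal effect.
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname MREstimate-class
#' @export
setMethod("mrSE", "MREstimate", function(x) x@se)

#' @describeIn MREstimate-class Two-sided p-value.
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))

#' @rdname MREstimate-class
#' @export
setMethod("mrPval", "MREstimate", function(x) x@pval)

#' @describeIn MREstimate-class Odds ratio with CI as a named vector.
#' @export
setGeneric("mrOR", function(x) standardGeneric("mrOR"))

#' @rdname MREstimate-class
#' @export
setMethod("mrOR", "MREstimate", function(x) {
  c(or = x@or, ci_low = x@ciLow, ci_high = x@ciHigh)
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", object@method, object@nsnp))
  cat(sprintf("  beta = %.4f (SE %.4f), p = %.4g\n",
              object@beta, object@se, object@pval))
  cat(sprintf("  OR = %.4f (%g%% CI: %.4f to %.4f)\n",
              object@or, 100 * object@level, object@ciLow, object@ciHigh))
  invisible(object)
})

#' Inverse-variance-weighted estimate with heterogeneity
#'
#' Extends [MREstimate-class] with Cochran's Q heterogeneity statistic for
#' the fitted set.
#'
#' @slot Q,Qdf,Qpval Cochran's Q, its degrees of freedom (`nsnp - 1`), and
#'   chi-square p-value.
#' @slot model `"fixed"` or `"random"` (multiplicative random effects).
#' @export
setClass("IVWResult",
  contains = "MREstimate",
  representation(Q = "numeric", Qdf = "integer", Qpval = "numeric",
                 model = "character")
)

#' MR-Egger estimate with intercept and heterogeneity
#'
#' Extends [MREstimate-class]; the slope is the causal estimate and the
#' intercept measures directional pleiotropy.
#'
#' @slot intercept,interceptSE,interceptPval Egger intercept test.
#' @slot Q,Qdf,Qpval Weighted residual sum of squares, `nsnp - 2`, p-value.
#' @export
setClass("EggerResult",
  contains = "MREstimate",
  representation(intercept = "numeric", interceptSE = "numeric",
                 interceptPval = "numeric",
                 Q = "numeric", Qdf = "integer", Qpval = "numeric")
)

#' @describeIn EggerResult-class Egger intercept test as a named vector.
#' @param x,object An `EggerResult`.
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

#' @rdname EggerResult-class
#' @export
setMethod("eggerIntercept", "EggerResult", function(x) {
  c(intercept = x@intercept, se = x@interceptSE, pval = x@interceptPval)
})

#' @describeIn IVWResult-class Cochran's Q as a named vector.
#' @param x,object An `IVWResult` or `EggerResult`.
#' @export
setGeneric("heterogeneity", function(x) standardGeneric("heterogeneity"))

#' @rdname IVWResult-class
#' @export
setMethod("heterogeneity", "IVWResult", function(x) {
  c(Q = x@Q, df = x@Qdf, pval = x@Qpval)
})

#' @rdname EggerResult-class
#' @export
setMethod("heterogeneity", "EggerResult", function(x) {
  c(Q = x@Q, df = x@Qdf, pval = x@Qpval)
})

setMethod("show", "IVWResult", function(object) {
  callNextMethod()
  cat(sprintf("  Cochran Q = %.3f (df %d), p = %.4g [%s effects]\n",
              object@Q, object@Qdf, object@Qpval, object@model))
  invisible(object)
})

setMethod("show", "EggerResult", function(object) {
  callNextMethod()
  cat(sprintf("  intercept = %.4f (SE %.4f), p = %.4g\n",
              object@intercept, object@interceptSE, object@interceptPval))
  cat(sprintf("  residual Q = %.3f (df %d), p = %.4g\n",
              object@Q, object@Qdf, object@Qpval))
  invisible(object)
})

# ---------------------------------------------------------------------------
# PressoResult
# ---------------------------------------------------------------------------

#' MR-PRESSO global, outlier and distortion results
#'
#' @slot rssObs Observed leave-one-out weighted residual sum of squares.
#' @slot globalP Simulation p-value of the global test (add-one corrected,
#'   never exactly 0).
#' @slot perSnpP Per-SNP simulation p-values (outlier test).
#' @slot outlierIds SNP ids flagged at the Bonferroni threshold.
#' @slot betaRaw,betaCorrected IVW slope with all SNPs / without outliers.
#' @slot distortionP Distortion-test p-value (`NA` when no outliers).
#' @slot K Number of simulated datasets.
#' @slot snpIds SNP ids of the analyzed set.
#' @export
setClass("PressoResult",
  representation(
    rssObs = "numeric", globalP = "numeric",
    perSnpP = "numeric", outlierIds = "character",
    betaRaw = "numeric", betaCorrected = "numeric",
    distortionP = "numeric", K = "integer", snpIds = "character"
  )
)

setValidity("PressoResult", function(object) {
  msgs <- character()
  if (object@globalP <= 0 || object@globalP > 1) {
    msgs <- c(msgs, "globalP must lie in (0, 1]")
  }
  if (!all(object@outlierIds %in% object@snpIds)) {
    msgs <- c(msgs, "outlierIds must be a subset of snpIds")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PressoResult-class Global-test p-value.
#' @param x,object A `PressoResult`.
#' @export
setGeneric("globalP", function(x) standardGeneric("globalP"))

#' @rdname PressoResult-class
#' @export
setMethod("globalP", "PressoResult", function(x) x@globalP)

#' @describeIn PressoResult-class Flagged outlier SNP ids.
#' @export
setGeneric("outlierIds", function(x) standardGeneric("outlierIds"))

#' @rdname PressoResult-class
#' @export
setMethod("outlierIds", "PressoResult", function(x) x@outlierIds)

setMethod("show", "PressoResult", function(object) {
  cat("MR-PRESSO (K =", object@K, "simulations)\n")
  cat(sprintf("  RSS_obs = %.4f, global p = %.4g\n",
              object@rssObs, object@globalP))
  cat("  outliers:", if (length(object@outlierIds))
      paste(object@outlierIds, collapse = ", ") else "none", "\n")
  if (length(object@outlierIds)) {
    cat(sprintf("  beta raw = %.4f, outlier-corrected = %.4f, distortion p = %.4g\n",
                object@betaRaw, object@betaCorrected, object@distortionP))
  }
  invisible(object)
})
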