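# Causal-effect estimators on a HarmonizedSet.

# Per-SNP Wald ratios and their first-order inverse-variance weights
# (w = bx^2 / sy^2, the reciprocal of var(by/bx) to first order).
.ratios <- function(set) {
  d <- harmonizedData(set)
  list(ratio = d$by / d$bx, w = d$bx^2 / d$sy^2, d = d)
}

#' Single-SNP Wald ratio
#'
#' @param bx,sx Exposure effect and SE.
#' @param by,sy Outcome effect and SE.
#' @return Named vector `c(beta, se)` with `beta = by/bx` and the
#'   first-order SE `sy/|bx|`.
#' @examples
#' waldRatio(0.1, 0.01, 0.05, 0.02) # beta 0.5, se 0.2
#' @export
waldRatio <- function(bx, sx, by, sy) {
  if (bx == 0) stop("Wald ratio undefined for bx = 0")
  c(beta = by / bx, se = sy / abs(bx))
}

#' Odds ratio with confidence interval
#'
#' @param beta Log-odds effect.
#' @param se Standard error (>= 0).
#' @param level Confidence level (default 0.95; the exact normal quantile
#'   1.959964 is used, not 1.96).
#' @return Named vector `c(or, ci_low, ci_high)`.
#' @examples
#' orCI(1.1979, 0.3238)
#' @export
orCI <- function(beta, se, level = 0.95) {
  stopifnot(se >= 0)
  z <- zQuantile(level)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (ratio_j - theta)^2)` over per-SNP Wald ratios with
#' first-order inverse-variance weights, compared to chi-square on
#' `nsnp - 1` degrees of freedom.
#'
#' @param set A [HarmonizedSet-class] with at least 2 SNPs.
#' @param theta Causal estimate to test against (defaults to the IVW
#'   slope of `set`).
#' @return Named vector `c(Q, df, pval)`.
#' @export
cochranQ <- function(set, theta = NULL) {
  r <- .ratios(set)
  n <- length(r$ratio)
  stopifnot(n >= 2)
  if (is.null(theta)) theta <- .ivwSlope(harmonizedData(set))
  Q <- sum(r$w * (r$ratio - theta)^2)
  df <- n - 1L
  c(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

# Closed-form IVW slope (origin-constrained WLS, weights 1/sy^2); the beta
# is identical under fixed and multiplicative-random effects.
.ivwSlope <- function(d) {
  sum(d$bx * d$by / d$sy^2) / sum(d$bx^2 / d$sy^2)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/sy^2`. The fixed-effects SE is
#' `1/sqrt(sum(bx^2/sy^2))`; the default multiplicative random-effects
#' model inflates it by `max(1, sqrt(Q/(nsnp-1)))`, retaining the IVW
#' point estimate under heterogeneity. A single-SNP set degenerates to the
#' Wald ratio with a warning.
#'
#' @param set A [HarmonizedSet-class].
#' @param model `"random"` (default) or `"fixed"`.
#' @param level Confidence level for the odds-ratio interval.
#' @return An [IVWResult-class].
#' @export
mrIVW <- function(set, model = c("random", "fixed"), level = 0.95) {
  model <- match.arg(model)
  d <- harmonizedData(set)
  n <- nrow(d)
  if (n == 0L) stop("no SNPs to estimate from")
  if (n == 1L) {
    warning("single SNP: IVW degenerates to the Wald ratio")
    wr <- waldRatio(d$bx, d$sx, d$by, d$sy)
    return(newMREstimate("IVWResult", method = "wald",
                         beta = unname(wr["beta"]), se = unname(wr["se"]),
                         nsnp = 1L, level = level,
                         Q = 0, Qdf = 0L, Qpval = 1, model = model))
  }
  beta <- .ivwSlope(d)
  se_fixed <- 1 / sqrt(sum(d$bx^2 / d$sy^2))
  q <- cochranQ(set, beta)
  scale <- if (model == "random") max(1, sqrt(q[["Q"]] / (n - 1))) else 1
  newMREstimate("IVWResult",
                method = if (model == "random") "ivw_random" else "ivw_fixed",
                beta = beta, se = se_fixed * scale, nsnp = n, level = level,
                Q = q[["Q"]], Qdf = as.integer(q[["df"]]), Qpval = q[["pval"]],
                model = model)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept
#' (weights `1/sy^2`), after orienting all exposure effects to be
#' non-negative. The slope is the causal estimate (consistent under the
#' InSIDE assumption); a nonzero intercept indicates directional
#' pleiotropy. Standard errors are inflated by
#' `max(1, sqrt(RSS_w/(nsnp-2)))`.
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param level Confidence level.
#' @return An [EggerResult-class].
#' @export
mrEgger <- function(set, level = 0.95) {
  d <- harmonizedData(set)
  n <- nrow(d)
  if (n < 3L) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- abs(d$bx)
  by <- d$by * flip
  w <- 1 / d$sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma  # sqrt(RSS_w / (n - 2))
  # coef SEs from lm already carry sigma; enforce the max(1, sigma) rule
  adj <- 1 / min(1, sigma)
  est <- stats::coef(sm)
  slope <- est["bx", "Estimate"]; slope_se <- est["bx", "Std. Error"] * adj
  inter <- est["(Intercept)", "Estimate"]
  inter_se <- est["(Intercept)", "Std. Error"] * adj
  rss <- sum(w * stats::residuals(fit)^2)
  newMREstimate("EggerResult", method = "egger",
                beta = unname(slope), se = unname(slope_se),
                nsnp = n, level = level,
                intercept = unname(inter), interceptSE = unname(inter_se),
                interceptPval = normalP(inter, inter_se),
                Q = rss, Qdf = n - 2L,
                Qpval = stats::pchisq(rss, n - 2, lower.tail = FALSE))
}

# Weighted median of `x` with weights `w` by linear interpolation of the
# weighted empirical CDF evaluated at probability 0.5.
.weightedMedian <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  n <- length(x)
  if (0.5 >= p[n]) return(x[n])
  stats::approx(p, x, xout = 0.5)$y
}

# Parametric bootstrap SE for ratio-based estimators: resample observed
# effects from their sampling normals and re-apply `fun(ratios, weights)`.
.bootstrapSE <- function(d, fun, n_boot, seed) {
  withSeed(seed, {
    n <- nrow(d)
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, d$bx, d$sx)
      by <- stats::rnorm(n, d$by, d$sy)
      fun(by / bx, bx^2 / d$sy^2)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median causal estimate
#'
#' Consistent when SNPs contributing at least half the weight are valid
#' instruments. The estimate interpolates the inverse-variance-weighted
#' empirical CDF of per-SNP Wald ratios at 0.5; the SE comes from a
#' parametric bootstrap (resampling `bx`, `by` from their sampling
#' normals).
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (reproducible when set).
#' @param level Confidence level.
#' @return An [MREstimate-class].
#' @export
mrWeightedMedian <- function(set, n_boot = 1000, seed = NULL, level = 0.95) {
  d <- harmonizedData(set)
  if (nrow(d) < 3L) stop("weighted median requires at least 3 SNPs")
  est <- .weightedMedian(d$by / d$bx, d$bx^2 / d$sy^2)
  se <- .bootstrapSE(d, .weightedMedian, n_boot, seed)
  newMREstimate(method = "weighted_median", beta = est, se = se,
                nsnp = nrow(d), level = level)
}

# Weighted kernel-density mode of ratios; bandwidth from the scaled
# median-absolute-deviation rule h = bw_factor * 0.9 * mad * n^(-1/5).
.weightedMode <- function(x, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  s <- stats::mad(x)
  if (s == 0 || length(unique(x)) == 1L) {
    # degenerate spread: mode = value carrying the most weight
    agg <- tapply(w, x, sum)
    return(as.numeric(names(agg))[which.max(agg)])
  }
  h <- bandwidth_factor * 0.9 * s * length(x)^(-1 / 5)
  dens <- stats::density(x, weights = w, bw = h, n = 512)
  dens$x[which.max(dens$y)]
}

#' Weighted-mode causal estimate
#'
#' Mode of the Gaussian-kernel-smoothed, inverse-variance-weighted density
#' of per-SNP Wald ratios; consistent when the largest group of SNPs
#' sharing the same ratio are valid instruments. Bandwidth follows a
#' scaled median-absolute-deviation rule times `bandwidth_factor`; the SE
#' comes from a parametric bootstrap.
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param bandwidth_factor Multiplier on the MAD bandwidth (default 1).
#' @param n_boot,seed Bootstrap settings.
#' @param level Confidence level.
#' @return An [MREstimate-class].
#' @export
mrWeightedMode <- function(set, bandwidth_factor = 1, n_boot = 1000,
                           seed = NULL, level = 0.95) {
  d <- harmonizedData(set)
  if (nrow(d) < 3L) stop("weighted mode requires at least 3 SNPs")
  est <- .weightedMode(d$by / d$bx, d$bx^2 / d$sy^2, bandwidth_factor)
  se <- .bootstrapSE(d, function(x, w) .weightedMode(x, w, bandwidth_factor),
                     n_boot, seed)
  newMREstimate(method = "weighted_mode", beta = est, se = se,
                nsnp = nrow(d), level = level)
}

#' Benjamini-Hochberg adjustment with two-threshold tiers
#'
#' Adjusts raw p-values by the BH step-up procedure and assigns the
#' reporting tiers used for screening many exposures: `significant` when
#' the FDR-adjusted p is below `fdr_threshold`, `potential` when only the
#' raw p is below `p_threshold`, otherwise `null`.
#'
#' @param pvals Raw p-values in (0, 1].
#' @param fdr_threshold FDR significance cutoff (default 0.05).
#' @param p_threshold Nominal cutoff for the `potential` tier (default 0.05).
#' @return `data.frame` with `raw_p`, `fdr_p`, `tier`.
#' @export
bhFDR <- function(pvals, fdr_threshold = 0.05, p_threshold = 0.05) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  fdr <- stats::p.adjust(pvals, method = "BH")
  tier <- ifelse(fdr < fdr_threshold, "significant",
                 ifelse(pvals < p_threshold, "potential", "null"))
  data.frame(raw_p = pvals, fdr_p = fdr, tier = tier,
             stringsAsFactors = FALSE)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the (random-effects) IVW estimate excluding each SNP in
#' turn, flagging exclusions that change the sign of the estimate or
#' nullify its nominal significance — i.e. SNPs that single-handedly drive
#' the result.
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param level Confidence level.
#' @return `data.frame` with `excluded_snp`, `beta`, `se`, `pval`,
#'   `flagged`; the full-set estimate is attached as attribute `"full"`.
#' @export
leaveOneOut <- function(set, level = 0.95) {
  d <- harmonizedData(set)
  n <- nrow(d)
  if (n < 3L) stop("leave-one-out requires at least 3 SNPs")
  full <- mrIVW(set, level = level)
  rows <- lapply(seq_len(n), function(j) {
    sub <- new("HarmonizedSet", exposure = set@exposure,
               outcome = set@outcome, data = d[-j, , drop = FALSE],
               drops = set@drops)
    est <- mrIVW(sub, level = level)
    data.frame(excluded_snp = d$snp_id[j], beta = mrBeta(est),
               se = mrSE(est), pval = mrPval(est),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- sign(out$beta) != sign(mrBeta(full)) |
    (mrPval(full) < 0.05 & out$pval >= 0.05)
  attr(out, "full") <- full
  out
}
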