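# MR-PRESSO: residual-sum-of-squares simulation tests for horizontal
# pleiotropy (global), per-SNP outliers, and estimate distortion.

# Leave-one-out IVW slopes and observed residuals; shared by all parts.
.pressoObserved <- function(d) {
  w <- 1 / d$sy^2
  S1 <- sum(d$bx * d$by * w)
  S2 <- sum(d$bx^2 * w)
  theta_loo <- (S1 - d$bx * d$by * w) / (S2 - d$bx^2 * w)
  r <- d$by - theta_loo * d$bx
  list(w = w, theta_loo = theta_loo, r = r, rss = sum(w * r^2))
}

# Simulation engine: K null datasets drawn around the leave-one-out
# expectations; returns the simulated RSS vector and per-SNP squared
# residual exceedance counts. Deterministic under `seed`.
.pressoEngine <- function(d, K, seed) {
  obs <- .pressoObserved(d)
  n <- nrow(d)
  withSeed(seed, {
    bx_s <- matrix(stats::rnorm(K * n, mean = rep(d$bx, each = K),
                                sd = rep(d$sx, each = K)), nrow = K)
    by_s <- matrix(stats::rnorm(K * n, mean = rep(obs$theta_loo * d$bx, each = K),
                                sd = rep(d$sy, each = K)), nrow = K)
    wM <- matrix(obs$w, nrow = K, ncol = n, byrow = TRUE)
    S1 <- rowSums(bx_s * by_s * wM)
    S2 <- rowSums(bx_s^2 * wM)
    theta_s <- (S1 - bx_s * by_s * wM) / (S2 - bx_s^2 * wM)
    r_s <- by_s - theta_s * bx_s
    rss_sim <- rowSums(wM * r_s^2)
    exceed <- colSums(r_s^2 >= matrix(obs$r^2, nrow = K, ncol = n,
                                      byrow = TRUE))
    list(obs = obs, rss_sim = rss_sim, exceed = exceed)
  })
}

#' MR-PRESSO global pleiotropy test
#'
#' For each SNP the leave-one-out IVW slope predicts its outcome effect;
#' the observed weighted residual sum of squares is compared against `K`
#' datasets simulated under the no-pleiotropy null (`by* ~ N(theta_-j bx_j,
#' sy_j)`, `bx* ~ N(bx_j, sx_j)`). The add-one corrected p-value
#' `(1 + #\{RSS_sim >= RSS_obs\}) / (K + 1)` is never exactly zero.
#'
#' @param set A [HarmonizedSet-class] with at least 4 SNPs.
#' @param K Number of simulated datasets (default 1000).
#' @param seed RNG seed; the same seed reproduces the result exactly.
#' @return A [PressoResult-class] with the global and per-SNP outlier
#'   parts filled in (distortion p is `NA` until [pressoDistortion()]).
#' @export
pressoGlobal <- function(set, K = 1000, seed = NULL) {
  d <- harmonizedData(set)
  n <- nrow(d)
  if (n < 4L) stop("MR-PRESSO requires at least 4 SNPs")
  if (1 / (K + 1) >= 0.05 / n) {
    warning("K = ", K, " cannot resolve the Bonferroni outlier threshold ",
            "0.05/", n, "; increase K above ", 20 * n)
  }
  eng <- .pressoEngine(d, K, seed)
  global_p <- (1 + sum(eng$rss_sim >= eng$obs$rss)) / (K + 1)
  per_snp <- (1 + eng$exceed) / (K + 1)
  outliers <- d$snp_id[per_snp < 0.05 / n]
  beta_raw <- .ivwSlope(d)
  beta_corr <- if (length(outliers) && length(outliers) < n) {
    .ivwSlope(d[!(d$snp_id %in% outliers), , drop = FALSE])
  } else {
    NA_real_
  }
  new("PressoResult", rssObs = eng$obs$rss, globalP = global_p,
      perSnpP = stats::setNames(per_snp, d$snp_id), outlierIds = outliers,
      betaRaw = beta_raw, betaCorrected = beta_corr,
      distortionP = NA_real_, K = as.integer(K), snpIds = d$snp_id)
}

#' MR-PRESSO per-SNP outlier test
#'
#' Per-SNP add-one simulation p-values comparing each observed squared
#' residual with its simulated null distribution; SNPs with
#' `p < 0.05/nsnp` (Bonferroni) are flagged as outliers. Uses the same
#' simulation stream as [pressoGlobal()] under the same seed.
#'
#' @inheritParams pressoGlobal
#' @return `data.frame` with `snp_id`, `pval`, `outlier`.
#' @export
pressoOutlier <- function(set, K = 1000, seed = NULL) {
  res <- pressoGlobal(set, K = K, seed = seed)
  data.frame(snp_id = res@snpIds, pval = unname(res@perSnpP),
             outlier = res@snpIds %in% res@outlierIds,
             stringsAsFactors = FALSE)
}

#' MR-PRESSO distortion test
#'
#' Quantifies how much the flagged outliers distort the IVW estimate:
#' `D = (beta_raw - beta_corrected) / |beta_corrected|`, compared against
#' the distribution of the same statistic when random same-size SNP
#' subsets are removed instead.
#'
#' @param set A [HarmonizedSet-class].
#' @param outlier_ids SNP ids flagged by the outlier test (at least one;
#'   flagging every SNP is an error).
#' @param n_boot Random subsets drawn (default 1000).
#' @param seed RNG seed.
#' @return Named list `beta_raw`, `beta_corrected`, `distortion`,
#'   `distortion_p`.
#' @export
pressoDistortion <- function(set, outlier_ids, n_boot = 1000, seed = NULL) {
  d <- harmonizedData(set)
  n <- nrow(d)
  m <- length(outlier_ids)
  if (m == 0L) stop("no outliers flagged")
  if (!all(outlier_ids %in% d$snp_id)) stop("unknown outlier id(s)")
  if (m >= n) stop("all SNPs flagged as outliers; nothing to correct with")
  beta_raw <- .ivwSlope(d)
  beta_corr <- .ivwSlope(d[!(d$snp_id %in% outlier_ids), , drop = FALSE])
  D_obs <- (beta_raw - beta_corr) / abs(beta_corr)
  D_null <- withSeed(seed, {
    vapply(seq_len(n_boot), function(b) {
      drop_idx <- sample.int(n, m)
      beta_b <- .ivwSlope(d[-drop_idx, , drop = FALSE])
      (beta_raw - beta_b) / abs(beta_b)
    }, numeric(1))
  })
  p <- mean(abs(D_null) >= abs(D_obs))
  list(beta_raw = beta_raw, beta_corrected = beta_corr,
       distortion = D_obs, distortion_p = p)
}

#' Run the full MR-PRESSO battery
#'
#' Global test, outlier flags, and (when outliers are found and some SNPs
#' remain) the distortion test, in one seeded call.
#'
#' @inheritParams pressoGlobal
#' @param n_boot Subsets for the distortion test.
#' @return A [PressoResult-class] with all parts filled.
#' @export
runPresso <- function(set, K = 1000, n_boot = 1000, seed = NULL) {
  res <- pressoGlobal(set, K = K, seed = seed)
  n_out <- length(res@outlierIds)
  if (n_out > 0L && n_out < length(res@snpIds)) {
    dist_seed <- if (is.null(seed)) NULL else substreamSeed(seed, "distortion")
    dt <- pressoDistortion(set, res@outlierIds, n_boot = n_boot,
                           seed = dist_seed)
    res@distortionP <- dt$distortion_p
  }
  res
}
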