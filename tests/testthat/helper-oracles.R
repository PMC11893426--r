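# Shared fixtures and independent reference implementations (oracles).
# Oracles deliberately use different code paths (matrix solves,
# enumeration, brute force) than the package functions they check.

# HarmonizedSet straight from a simulated exposure/outcome pair (the pair
# is aligned by construction).
toSet <- function(sim) {
  HarmonizedSet(bx = sim$exposure$beta, sx = sim$exposure$se,
                by = sim$outcome$beta, sy = sim$outcome$se,
                snp_id = sim$exposure$snp_id,
                eaf_x = sim$exposure$eaf, eaf_y = sim$outcome$eaf)
}

# Canonical summary-statistics data frame from vectors.
makeStats <- function(snp_id, beta, se, eaf = 0.3,
                      effect_allele = "A", other_allele = "G",
                      chrom = "1", pos = seq_along(snp_id) * 1e6,
                      n = 10000, pval = NULL) {
  k <- length(snp_id)
  rep_k <- function(x) rep_len(x, k)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(snp_id = snp_id, chrom = rep_k(chrom), pos = rep_k(pos),
             effect_allele = rep_k(effect_allele),
             other_allele = rep_k(other_allele),
             eaf = rep_k(eaf), beta = beta, se = se, pval = pval,
             n = rep_k(n),
             palindromic = isPalindromic(rep_k(effect_allele),
                                         rep_k(other_allele)),
             stringsAsFactors = FALSE)
}

# Origin-constrained WLS via the normal equations.
wlsOriginOracle <- function(bx, by, sy) {
  W <- diag(1 / sy^2)
  X <- matrix(bx, ncol = 1)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
  se_fixed <- sqrt(solve(t(X) %*% W %*% X)[1, 1])
  c(beta = beta[1, 1], se_fixed = se_fixed)
}

# WLS with intercept via the normal equations, on bx-oriented data, with
# the same max(1, sigma) SE scaling rule as MR-Egger.
wlsInterceptOracle <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  bx <- abs(bx); by <- by * flip
  W <- diag(1 / sy^2)
  X <- cbind(1, bx)
  XtWX <- t(X) %*% W %*% X
  coef <- solve(XtWX, t(X) %*% W %*% by)
  resid <- by - X %*% coef
  rss <- sum((1 / sy^2) * resid^2)
  sigma2 <- rss / (length(by) - 2)
  cov_unscaled <- solve(XtWX)
  ses <- sqrt(diag(cov_unscaled) * max(1, sigma2))
  list(intercept = as.numeric(coef[1, 1]), slope = as.numeric(coef[2, 1]),
       intercept_se = unname(ses[1]), slope_se = unname(ses[2]), rss = rss)
}

# Benjamini-Hochberg by explicit step-up with monotonicity enforcement.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Two-sided Fisher exact p by exhaustive enumeration of the conditional
# hypergeometric distribution (point-probability rule).
fisherEnumOracle <- function(k_i, n_i, k_c, n_c) {
  k <- k_i + k_c
  xs <- max(0, k - n_c):min(n_i, k)
  probs <- dhyper(xs, n_i, n_c, k)
  p_obs <- dhyper(k_i, n_i, n_c, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent greedy clumping: rank by p (ties by id), sweep and mark.
greedyClumpOracle <- function(df, ld, r2_max, window_kb) {
  df <- df[order(df$pval, df$snp_id), , drop = FALSE]
  kept <- character()
  removed <- character()
  for (i in seq_len(nrow(df))) {
    id <- df$snp_id[i]
    if (id %in% removed) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(df))) {
      other <- df$snp_id[j]
      if (other == id || other %in% removed || other %in% kept) next
      if (df$chrom[j] == df$chrom[i] &&
          abs(df$pos[j] - df$pos[i]) <= window_kb * 1000 &&
          ld[id, other] > r2_max) {
        removed <- c(removed, other)
      }
    }
  }
  kept
}
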