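# Causal estimators, heterogeneity, FDR tiers, leave-one-out.

test_that("Wald ratio is by/bx with first-order SE", {
  expect_equal(waldRatio(0.1, 0.01, 0, 0.02), c(beta = 0, se = 0.2))
  expect_equal(waldRatio(0.1, 0.01, 0.05, 0.02), c(beta = 0.5, se = 0.2))
  expect_error(waldRatio(0, 0.01, 0.05, 0.02), "bx = 0")
})

test_that("IVW degenerates to Wald on one SNP and is exact on homogeneity", {
  one <- HarmonizedSet(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.02)
  expect_warning(est <- mrIVW(one), "single SNP")
  expect_equal(mrBeta(est), 0.5)
  expect_equal(mrSE(est), 0.2)

  hom <- HarmonizedSet(bx = c(0.1, 0.2, 0.05), sx = 0.01,
                       by = 0.3 * c(0.1, 0.2, 0.05), sy = 0.01)
  fixed <- mrIVW(hom, model = "fixed")
  rand <- mrIVW(hom, model = "random")
  expect_equal(mrBeta(fixed), 0.3)
  expect_equal(unname(heterogeneity(fixed)["Q"]), 0)
  expect_equal(mrSE(fixed), mrSE(rand))
})

test_that("IVW equals the closed-form WLS solve and the ratio identity", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    bx <- runif(n, 0.05, 0.2); by <- 0.4 * bx + rnorm(n, 0, 0.01)
    sy <- runif(n, 0.005, 0.02)
    h <- HarmonizedSet(bx = bx, sx = 0.01, by = by, sy = sy)
    est <- mrIVW(h, model = "fixed")
    oracle <- wlsOriginOracle(bx, by, sy)
    expect_equal(mrBeta(est), unname(oracle["beta"]), tolerance = 1e-10)
    expect_equal(mrSE(est), unname(oracle["se_fixed"]), tolerance = 1e-10)
    # identity: IVW(fixed) is the weighted mean of Wald ratios, w = bx^2/sy^2
    w <- bx^2 / sy^2
    expect_equal(mrBeta(est), sum(w * by / bx) / sum(w), tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates the SE only under excess heterogeneity", {
  set.seed(6)
  bx <- runif(6, 0.05, 0.2)
  by <- 0.4 * bx + rnorm(6, 0, 0.05)  # overdispersed
  h <- HarmonizedSet(bx = bx, sx = 0.01, by = by, sy = 0.005)
  fixed <- mrIVW(h, model = "fixed"); rand <- mrIVW(h, model = "random")
  q <- heterogeneity(rand)
  expect_gt(unname(q["Q"]), unname(q["df"]))
  expect_equal(mrSE(rand),
               mrSE(fixed) * sqrt(unname(q["Q"]) / unname(q["df"])))
  expect_equal(mrBeta(rand), mrBeta(fixed))
})

test_that("Egger recovers an exact linear law and matches the WLS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  exact <- HarmonizedSet(bx = bx, sx = 0.01, by = 0.02 + 0.4 * bx, sy = 0.01)
  est <- mrEgger(exact)
  expect_equal(mrBeta(est), 0.4, tolerance = 1e-12)
  expect_equal(unname(eggerIntercept(est)["intercept"]), 0.02,
               tolerance = 1e-12)
  expect_equal(unname(heterogeneity(est)["Q"]), 0, tolerance = 1e-20)

  set.seed(7)
  by <- 0.02 + 0.4 * bx + rnorm(4, 0, 0.01)
  sy <- runif(4, 0.005, 0.02)
  h <- HarmonizedSet(bx = bx, sx = 0.01, by = by, sy = sy)
  est2 <- mrEgger(h)
  oracle <- wlsInterceptOracle(bx, by, sy)
  expect_equal(mrBeta(est2), oracle$slope, tolerance = 1e-10)
  expect_equal(unname(eggerIntercept(est2)["intercept"]), oracle$intercept,
               tolerance = 1e-10)
  expect_equal(mrSE(est2), oracle$slope_se, tolerance = 1e-10)
  expect_equal(unname(heterogeneity(est2)["Q"]), oracle$rss,
               tolerance = 1e-10)
  expect_error(mrEgger(HarmonizedSet(bx = c(1, 2), sx = 1, by = c(1, 2),
                                     sy = 1)), "at least 3")
})

test_that("estimators are invariant to per-SNP sign representation", {
  set.seed(8)
  bx <- runif(5, 0.05, 0.2); by <- 0.4 * bx + rnorm(5, 0, 0.01)
  h <- HarmonizedSet(bx = bx, sx = 0.01, by = by, sy = 0.01)
  flip <- c(-1, 1, 1, -1, 1)
  hf <- HarmonizedSet(bx = bx * flip, sx = 0.01, by = by * flip, sy = 0.01)
  expect_equal(mrBeta(mrIVW(h)), mrBeta(mrIVW(hf)), tolerance = 1e-12)
  expect_equal(mrBeta(mrEgger(h)), mrBeta(mrEgger(hf)), tolerance = 1e-12)
  expect_equal(mrBeta(mrWeightedMedian(h, n_boot = 10, seed = 1)),
               mrBeta(mrWeightedMedian(hf, n_boot = 10, seed = 1)),
               tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted CDF at one half", {
  # equal weights: the plain median
  h <- HarmonizedSet(bx = c(1, 1, 1), sx = 0.01,
                     by = c(0.1, 0.3, 0.8), sy = 1)
  expect_equal(mrBeta(mrWeightedMedian(h, n_boot = 10, seed = 1)), 0.3)
  # weights (0.5, 0.25, 0.25): hand-computed CDF crossing
  # p = (0.25, 0.625, 0.875); interpolate (0.25,0.1)-(0.625,0.3) at 0.5
  hw <- HarmonizedSet(bx = c(sqrt(2), 1, 1), sx = 0.01,
                      by = c(0.1, 0.3, 0.8) * c(sqrt(2), 1, 1), sy = 1)
  expect_equal(mrBeta(mrWeightedMedian(hw, n_boot = 10, seed = 1)),
               0.1 + 0.2 * (0.25 / 0.375), tolerance = 1e-12)
  # same seed, same bootstrap SE
  expect_identical(mrSE(mrWeightedMedian(h, n_boot = 50, seed = 9)),
                   mrSE(mrWeightedMedian(h, n_boot = 50, seed = 9)))
})

test_that("equal-weight weighted median equals the sample median (odd n)", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(c(3, 5, 7, 9), 1)
    ratios <- rnorm(n)
    h <- HarmonizedSet(bx = rep(1, n), sx = 0.01, by = ratios, sy = 1)
    expect_equal(mrBeta(mrWeightedMedian(h, n_boot = 5, seed = 1)),
                 median(ratios), tolerance = 1e-12)
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  h0 <- HarmonizedSet(bx = rep(1, 4), sx = 0.01, by = rep(0.25, 4), sy = 1)
  expect_equal(mrBeta(mrWeightedMode(h0, n_boot = 10, seed = 1)), 0.25)
  ratios <- c(0.28, 0.29, 0.295, 0.3, 0.305, 0.31, 0.32, 2, 2)
  h <- HarmonizedSet(bx = rep(1, 9), sx = 0.01, by = ratios, sy = 1)
  est <- mrBeta(mrWeightedMode(h, n_boot = 10, seed = 1))
  expect_gt(est, 0.25); expect_lt(est, 0.35)  # the mean (0.63) would fail
  expect_identical(mrBeta(mrWeightedMode(h, n_boot = 20, seed = 2)),
                   mrBeta(mrWeightedMode(h, n_boot = 20, seed = 2)))
})

test_that("Cochran's Q measures ratio dispersion and ignores order", {
  hom <- HarmonizedSet(bx = c(0.1, 0.2), sx = 0.01,
                       by = 0.3 * c(0.1, 0.2), sy = 0.01)
  q <- cochranQ(hom, 0.3)
  expect_equal(unname(q["Q"]), 0)
  expect_equal(unname(q["pval"]), 1)
  # two unit-weight ratios {0, 1} against theta = 0.5
  h2 <- HarmonizedSet(bx = c(1, 1), sx = 0.01, by = c(0, 1), sy = 1)
  expect_equal(unname(cochranQ(h2, 0.5)["Q"]), 0.5)
  set.seed(12)
  bx <- runif(6, 0.05, 0.2); by <- 0.3 * bx + rnorm(6, 0, 0.01)
  h <- HarmonizedSet(bx = bx, sx = 0.01, by = by, sy = 0.01)
  perm <- sample.int(6)
  hp <- HarmonizedSet(bx = bx[perm], sx = 0.01, by = by[perm], sy = 0.01)
  expect_equal(unname(cochranQ(h, 0.3)["Q"]), unname(cochranQ(hp, 0.3)["Q"]))
})

test_that("odds-ratio intervals use the exact normal quantile", {
  ci <- orCI(1.1979, 0.3238)
  expect_equal(unname(ci["ci_low"]), 1.7564, tolerance = 1e-3)
  expect_equal(unname(ci["ci_high"]), 6.2502, tolerance = 1e-3)
  ci0 <- orCI(0, 0.5)
  expect_equal(unname(ci0["or"]), 1)
  expect_equal(unname(ci0["ci_low"] * ci0["ci_high"]), 1, tolerance = 1e-12)
  expect_equal(unname(orCI(0.7, 0)), rep(exp(0.7), 3))
})

test_that("BH tiers match a brute-force step-up", {
  single <- bhFDR(0.03)
  expect_equal(single$fdr_p, 0.03)
  expect_equal(single$tier, "significant")
  four <- bhFDR(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(four$fdr_p, rep(0.04, 4))
  set.seed(13)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))^2
    res <- bhFDR(p)
    expect_equal(res$fdr_p, bruteBH(p), tolerance = 1e-12)
    expect_true(all(res$fdr_p >= res$raw_p))
    expect_identical(res$tier == "significant", res$fdr_p < 0.05)
    expect_identical(res$tier == "potential",
                     res$raw_p < 0.05 & res$fdr_p >= 0.05)
  }
})

test_that("leave-one-out matches pairwise IVW and flags a driving outlier", {
  h <- HarmonizedSet(bx = c(0.1, 0.15, 0.2), sx = 0.01,
                     by = c(0.031, 0.047, 0.059), sy = 0.01)
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo), 3)
  for (j in 1:3) {
    d <- harmonizedData(h)[-j, ]
    pair <- mrIVW(HarmonizedSet(bx = d$bx, sx = d$sx, by = d$by, sy = d$sy))
    expect_equal(loo$beta[j], mrBeta(pair))
  }
  # homogeneous ratios: every exclusion reproduces the full estimate
  hom <- HarmonizedSet(bx = c(0.1, 0.15, 0.2, 0.3), sx = 0.01,
                       by = 0.3 * c(0.1, 0.15, 0.2, 0.3), sy = 0.01)
  lh <- leaveOneOut(hom)
  expect_true(all(abs(lh$beta - 0.3) < 1e-12))
  expect_false(any(lh$flagged))
  # one gross outlier flips the sign when present: its exclusion is flagged
  ho <- HarmonizedSet(bx = rep(1, 3), sx = 0.01,
                      by = c(0.12, -0.10, -3), sy = 0.1,
                      snp_id = c("a", "b", "out"))
  lo <- leaveOneOut(ho)
  expect_identical(lo$excluded_snp[lo$flagged], "out")
})
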