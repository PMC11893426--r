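# Instrument selection: p-value screening, strength, clumping, proxies.

test_that("p-value selection keeps exactly the sub-threshold records", {
  st <- makeStats(c("a", "b", "c"), beta = c(0.1, 0.1, 0.1),
                  se = 0.02, pval = c(1e-6, 2e-5, 1e-4))
  expect_equal(selectByPvalue(st, 1e-5)$snp_id, "a")
  expect_equal(nrow(selectByPvalue(st, 1e-7)), 0)
  expect_equal(selectByPvalue(st, 1)$snp_id, c("a", "b", "c"))
})

test_that("F statistic is the squared Z and gates the strength filter", {
  expect_equal(fStatistic(0, 0.1), 0)
  expect_equal(fStatistic(0.1, 0.01), 100)
  f <- fStatistic(0.0316, 0.01)
  expect_lt(f, 10)
  expect_gt(f, 9.9)
  expect_error(fStatistic(0.1, 0), "se must be > 0")

  st <- makeStats(c("weak", "strong"), beta = c(0.0316, 0.1), se = 0.01)
  kept <- filterByStrength(st, f_min = 10)
  expect_equal(kept$snp_id, "strong")
  expect_equal(attr(kept, "weak"), "weak")
  # idempotent
  again <- filterByStrength(kept, f_min = 10)
  expect_equal(again$snp_id, kept$snp_id)
})

test_that("clumping keeps the best SNP among correlated neighbours", {
  st <- makeStats(c("s1", "s2"), beta = c(0.1, 0.1), se = 0.02,
                  pval = c(1e-8, 1e-6), pos = c(1e6, 1e6 + 1000))
  ld <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("s1", "s2"), c("s1", "s2")))
  out <- ldClump(st, ld, r2_max = 0.001, window_kb = 10000)
  expect_equal(out$snp_id, "s1")
  # single candidate is its own clump
  one <- ldClump(st[1, ], ld)
  expect_equal(one$snp_id, "s1")
})

test_that("clumping matches an independent greedy reference on fixtures", {
  set.seed(11)
  ids <- paste0("v", 1:5)
  st <- makeStats(ids, beta = runif(5), se = 0.02,
                  pval = c(1e-8, 5e-7, 3e-9, 2e-6, 1e-7),
                  chrom = c("1", "1", "1", "2", "1"),
                  pos = c(1e6, 1.4e6, 2e6, 1e6, 50e6))
  r2 <- matrix(runif(25, 0, 0.6), 5, dimnames = list(ids, ids))
  r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
  out <- ldClump(st, r2, r2_max = 0.1, window_kb = 10000)
  expect_setequal(out$snp_id, greedyClumpOracle(st, r2, 0.1, 10000))
})

test_that("clumped output is invariant to candidate order", {
  set.seed(21)
  ids <- paste0("v", 1:8)
  st <- makeStats(ids, beta = runif(8), se = 0.02,
                  pval = runif(8, 1e-9, 1e-5), pos = sort(runif(8, 1e6, 9e6)))
  r2 <- matrix(runif(64, 0, 0.9), 8, dimnames = list(ids, ids))
  r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
  ref <- ldClump(st, r2, r2_max = 0.2)
  for (i in 1:10) {
    perm <- st[sample.int(8), , drop = FALSE]
    expect_equal(ldClump(perm, r2, r2_max = 0.2)$snp_id, ref$snp_id)
  }
})

test_that("clumping edge thresholds behave as documented", {
  ids <- paste0("v", 1:4)
  st <- makeStats(ids, beta = runif(4), se = 0.02,
                  pval = c(1e-8, 1e-7, 1e-6, 1e-5), pos = c(1, 2, 3, 4) * 1e5)
  r2 <- matrix(0.99, 4, 4, dimnames = list(ids, ids)); diag(r2) <- 1
  # r2_max = 1 admits everything (strict inequality)
  expect_equal(nrow(ldClump(st, r2, r2_max = 1)), 4)
  # r2_max = 0 with a chromosome-wide window keeps one per correlated set
  expect_equal(nrow(ldClump(st, r2, r2_max = 0, window_kb = 1e6)), 1)
  expect_error(ldClump(makeStats("zz", 0.1, 0.02), r2), "zz")
})

test_that("proxy lookup takes the best r2 with deterministic ties", {
  ids <- c("miss", "p1", "p2", "p3")
  ld <- matrix(0, 4, 4, dimnames = list(ids, ids)); diag(ld) <- 1
  ld["miss", c("p1", "p2", "p3")] <- c(0.95, 0.9, 0.5)
  ld[, "miss"] <- ld["miss", ]
  pool <- makeStats(c("p1", "p2", "p3"), beta = 0.1, se = 0.02,
                    pval = c(0.5, 1e-6, 1e-8))
  expect_equal(findProxy("miss", ld, pool)$snp_id, "p1")
  # nothing strictly above the floor
  ld["miss", c("p1", "p2", "p3")] <- c(0.8, 0.7, 0.6)
  ld[, "miss"] <- ld["miss", ]
  expect_null(findProxy("miss", ld, pool))
  # exact tie resolved by smaller p
  ld["miss", c("p1", "p2")] <- 0.9
  ld[, "miss"] <- ld["miss", ]
  expect_equal(findProxy("miss", ld, pool)$snp_id, "p2")
  expect_error(findProxy("nope", ld, pool), "nope")
})

test_that("selectInstruments chains screen, clump and strength filter", {
  ids <- paste0("v", 1:6)
  st <- makeStats(ids, beta = c(0.1, 0.1, 0.005, 0.1, 0.1, 0.1), se = 0.02,
                  pval = c(1e-8, 1e-7, 1e-9, 1e-3, 1e-6, 1e-6),
                  pos = c(1e6, 1.01e6, 2e6, 3e6, 5e6, 5.01e6))
  st$pval[3] <- 1e-9  # strong p but weak F
  ld <- simulateLDMatrix(ids, block_size = 2, r2_within = 0.9)
  out <- selectInstruments(st, p_threshold = 1e-5, ld = ld, f_min = 10)
  expect_false("v4" %in% out$snp_id)  # p too large
  expect_false("v3" %in% out$snp_id)  # weak instrument
  expect_false(all(c("v1", "v2") %in% out$snp_id))  # same LD block
  expect_true("f_stat" %in% names(out))
})
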