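# Allele-specific harmonization.

rec <- function(id = "rs1", ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                se = 0.02) {
  list(snp_id = id, effect_allele = ea, other_allele = oa, eaf = eaf,
       beta = beta, se = se)
}

test_that("palindrome detection covers both complementary pairs", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("C", "G"))
  expect_true(isPalindromic("G", "C"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("T", "C"))
})

test_that("matching orientations pass through unchanged", {
  h <- harmonizePair(rec(), rec(beta = 0.05))
  expect_equal(h$action, "unchanged")
  expect_equal(h$by, 0.05)
  expect_equal(h$bx, 0.1)
})

test_that("swapped alleles flip the outcome sign and frequency", {
  h <- harmonizePair(rec(), rec(ea = "G", oa = "A", beta = 0.05, eaf = 0.7))
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$by, -0.05)
  expect_equal(h$eaf_y, 0.3)
})

test_that("strand flips are resolved via complements", {
  # T/C is the complement of A/G, same orientation
  h <- harmonizePair(rec(), rec(ea = "T", oa = "C", beta = 0.05))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$by, 0.05)
  # complement plus swap
  h2 <- harmonizePair(rec(), rec(ea = "C", oa = "T", beta = 0.05, eaf = 0.7))
  expect_equal(h2$action, "strand_flipped")
  expect_equal(h2$by, -0.05)
  expect_equal(h2$eaf_y, 0.3)
})

test_that("ambiguous palindromes are dropped, informative ones oriented", {
  pal <- rec(ea = "A", oa = "T", eaf = 0.5)
  h <- harmonizePair(pal, rec(ea = "A", oa = "T", eaf = 0.5, beta = 0.05))
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "ambiguous_palindrome")
  # frequencies on the same side of 0.5: aligned
  h2 <- harmonizePair(rec(ea = "A", oa = "T", eaf = 0.2),
                      rec(ea = "A", oa = "T", eaf = 0.25, beta = 0.05))
  expect_equal(h2$action, "unchanged")
  expect_equal(h2$by, 0.05)
  # opposite sides: the outcome is reported on the other strand label
  h3 <- harmonizePair(rec(ea = "A", oa = "T", eaf = 0.2),
                      rec(ea = "A", oa = "T", eaf = 0.75, beta = 0.05))
  expect_equal(h3$action, "sign_flipped")
  expect_equal(h3$by, -0.05)
  # missing frequency cannot be oriented
  h4 <- harmonizePair(rec(ea = "A", oa = "T", eaf = NA),
                      rec(ea = "A", oa = "T", eaf = 0.2, beta = 0.05))
  expect_equal(h4$drop_reason, "palindrome_missing_eaf")
  # keep_palindromes retains the ambiguous SNP, frequency-oriented
  h5 <- harmonizePair(rec(ea = "A", oa = "T", eaf = 0.45),
                      rec(ea = "A", oa = "T", eaf = 0.56, beta = 0.05),
                      keep_palindromes = TRUE)
  expect_equal(h5$action, "sign_flipped")
})

test_that("incompatible allele sets and id mismatches fail safely", {
  h <- harmonizePair(rec(), rec(ea = "A", oa = "C"))
  expect_equal(h$drop_reason, "allele_mismatch")
  expect_error(harmonizePair(rec(id = "rs1"), rec(id = "rs2")),
               "snp_id mismatch")
})

test_that("set harmonization joins, drops and logs correctly", {
  # 10 matched SNPs, 2 ambiguous palindromes
  exp <- do.call(rbind, lapply(1:10, function(i) {
    as.data.frame(rec(id = paste0("rs", i),
                      ea = if (i <= 2) "A" else "A",
                      oa = if (i <= 2) "T" else "G",
                      eaf = if (i <= 2) 0.5 else 0.3),
                  stringsAsFactors = FALSE)
  }))
  out <- exp
  out$beta <- 0.05
  h <- harmonizeSets(exp, out)
  expect_s4_class(h, "HarmonizedSet")
  expect_equal(nSnp(h), 8)
  expect_equal(sum(dropLog(h)$reason == "ambiguous_palindrome"), 2)
  # disjoint SNP sets are fatal with a diagnostic
  out2 <- out
  out2$snp_id <- paste0("zz", 1:10)
  expect_error(harmonizeSets(exp, out2), "no instrument SNPs")
  # idempotence: re-harmonizing the harmonized representation is a no-op
  d <- harmonizedData(h)
  out3 <- exp[match(d$snp_id, exp$snp_id), ]
  out3$beta <- d$by
  out3$se <- d$sy
  h2 <- harmonizeSets(exp, out3)
  expect_equal(harmonizedData(h2)$by, d$by)
  expect_true(all(harmonizedData(h2)$action == "unchanged"))
})

test_that("scramble then harmonize is an exact involution off palindromes", {
  sim <- simulateGwasPair(simScenario(n_snps = 200, theta = 0.3, seed = 77))
  ref <- harmonizeSets(sim$exposure, sim$outcome)
  scr <- scrambleAlleles(sim$outcome, seed = 78)
  rec2 <- harmonizeSets(sim$exposure, scr)
  d1 <- harmonizedData(ref); d2 <- harmonizedData(rec2)
  keep <- intersect(d1$snp_id, d2$snp_id)
  m1 <- d1[match(keep, d1$snp_id), ]; m2 <- d2[match(keep, d2$snp_id), ]
  expect_identical(m1$by, m2$by)
  expect_equal(m1$eaf_y, m2$eaf_y, tolerance = 1e-15)
  # harmonization never touches the exposure side
  expect_identical(m1$bx, m2$bx)
  expect_identical(m1$sx, m2$sx)
  # |by| preserved under any sign flip
  expect_identical(abs(m2$by)[order(keep)],
                   abs(sim$outcome$beta[match(keep, sim$outcome$snp_id)])[order(keep)])
})

test_that("downstream estimates ignore the outcome file's allele choice", {
  sim <- simulateGwasPair(simScenario(n_snps = 50, theta = 0.3, seed = 79,
                                      prop_palindromic = 0))
  b1 <- mrBeta(mrIVW(harmonizeSets(sim$exposure, sim$outcome)))
  scr <- scrambleAlleles(sim$outcome, seed = 80)
  b2 <- mrBeta(mrIVW(harmonizeSets(sim$exposure, scr)))
  expect_identical(b1, b2)
})

test_that("proxy substitution fills instruments missing from the outcome", {
  ids <- c("i1", "i2", "i3", "prox")
  exp <- makeStats(ids, beta = c(0.1, 0.12, 0.11, 0.1), se = 0.02,
                   pval = c(1e-8, 1e-8, 1e-8, 1e-7))
  out <- makeStats(c("i1", "i2", "prox"), beta = 0.03, se = 0.02)
  ld <- simulateLDMatrix(ids)
  ld["i3", "prox"] <- ld["prox", "i3"] <- 0.95
  inst <- exp[1:3, ]
  h <- harmonizeSets(inst, out, allow_proxies = TRUE, ld = ld,
                     proxy_pool = exp)
  expect_setequal(harmonizedData(h)$snp_id, c("i1", "i2", "prox"))
  expect_true(any(grepl("proxied_by:prox", dropLog(h)$reason)))
  # proxies off: the missing instrument is simply dropped
  h2 <- harmonizeSets(inst, out)
  expect_setequal(harmonizedData(h2)$snp_id, c("i1", "i2"))
  expect_true("absent_from_outcome" %in% dropLog(h2)$reason)
})
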