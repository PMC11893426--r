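# Synthetic GWAS summary statistics with known ground truth: the test
# substrate for every analysis stage. All generators are pure functions of
# (scenario, seed).

#' Define a simulation scenario
#'
#' Defaults reflect the data structure the pipeline targets: an Olink-scale
#' protein GWAS as exposure (n = 14824), a FinnGen-scale binary outcome
#' (n = 73479), a metabolite-panel-scale mediator (n = 8299), per-SNP
#' standard errors `1/sqrt(2 n maf (1 - maf))`, and instrument effects
#' `bx ~ N(0, 0.05^2)` resampled until the per-SNP F reaches 10.
#'
#' @param n_snps Number of instrument SNPs (per instrument set).
#' @param theta True causal effect of exposure on outcome.
#' @param pleiotropy_model One of `none`, `balanced`, `directional`,
#'   `inside_violating` (direct effects correlated with instrument
#'   strength at rho = 0.5, breaking the InSIDE assumption).
#' @param pleiotropy_sd Scale of pleiotropic direct effects.
#' @param prop_pleiotropic Fraction of SNPs given a pleiotropic effect.
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.
#' @param maf_range Range minor-allele frequencies are drawn from.
#' @param prop_palindromic Fraction of SNPs given A/T or C/G allele pairs.
#' @param mediator_chain Optional `list(a, b, direct)` defining a mediation
#'   chain exposure -> mediator -> outcome with an additional direct path.
#' @param seed RNG seed.
#' @return A `SimScenario` list.
#' @export
simScenario <- function(n_snps = 50, theta = 0.3,
                        pleiotropy_model = c("none", "balanced",
                                             "directional",
                                             "inside_violating"),
                        pleiotropy_sd = 0.1, prop_pleiotropic = 0.3,
                        n_exposure = 14824, n_outcome = 73479,
                        n_mediator = 8299,
                        maf_range = c(0.05, 0.5), prop_palindromic = 0.2,
                        mediator_chain = NULL, seed = NULL) {
  pleiotropy_model <- match.arg(pleiotropy_model)
  stopifnot(n_snps >= 1, prop_pleiotropic >= 0, prop_pleiotropic <= 1,
            prop_palindromic >= 0, prop_palindromic <= 1,
            n_exposure > 0, n_outcome > 0, n_mediator > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_snps = n_snps, theta = theta,
                 pleiotropy_model = pleiotropy_model,
                 pleiotropy_sd = pleiotropy_sd,
                 prop_pleiotropic = prop_pleiotropic,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 n_mediator = n_mediator, maf_range = maf_range,
                 prop_palindromic = prop_palindromic,
                 mediator_chain = mediator_chain, seed = seed),
            class = "SimScenario")
}

# Random biallelic SNP identities: ids, positions, allele pairs (a stated
# fraction palindromic), and effect-allele frequencies from the MAF.
.simSnpFrame <- function(n, maf_range, prop_palindromic, prefix = "rs") {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  npal_pairs <- list(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                     c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))
  is_pal <- stats::runif(n) < prop_palindromic
  pick <- function(pairs) pairs[[sample.int(length(pairs), 1)]]
  al <- t(vapply(is_pal, function(p) {
    if (p) pick(pal_pairs) else pick(npal_pairs)
  }, character(2)))
  maf <- stats::runif(n, maf_range[1], maf_range[2])
  eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
  data.frame(snp_id = sprintf("%s%06d", prefix, sample.int(999999, n)),
             chrom = as.character(sample.int(22, n, replace = TRUE)),
             pos = sample.int(2.4e8, n),
             effect_allele = al[, 1], other_allele = al[, 2],
             maf = maf, eaf = eaf, stringsAsFactors = FALSE)
}

# Draw true instrument effects bx ~ N(0, 0.05^2), resampling each SNP
# until its true F = (bx/se)^2 reaches f_min.
.drawStrongEffects <- function(se, f_min = 10, sd = 0.05, max_draws = 1e5) {
  n <- length(se)
  bx <- stats::rnorm(n, 0, sd)
  need <- (bx / se)^2 < f_min
  draws <- n
  while (any(need)) {
    if (draws > max_draws) {
      stop("could not satisfy F >= ", f_min, " after ", max_draws,
           " draws; increase the exposure sample size")
    }
    bx[need] <- stats::rnorm(sum(need), 0, sd)
    draws <- draws + sum(need)
    need <- (bx / se)^2 < f_min
  }
  bx
}

# Pleiotropic direct effects on the outcome for a subset of SNPs.
.drawPleiotropy <- function(scen, bx) {
  n <- length(bx)
  alpha <- numeric(n)
  if (scen$pleiotropy_model == "none" || scen$prop_pleiotropic == 0) {
    return(alpha)
  }
  k <- max(1L, round(scen$prop_pleiotropic * n))
  idx <- sample.int(n, k)
  sd <- scen$pleiotropy_sd
  alpha[idx] <- switch(scen$pleiotropy_model,
    balanced = stats::rnorm(k, 0, sd),
    # directional pleiotropy acts relative to the exposure-increasing
    # allele, hence the sign(bx) orientation
    directional = sign(bx[idx]) * stats::rnorm(k, sd, sd),
    inside_violating = {
      rho <- 0.5
      z <- stats::rnorm(k)
      bstd <- (bx[idx] - mean(bx)) / stats::sd(bx)
      sd * (rho * bstd + sqrt(1 - rho^2) * z)
    })
  alpha
}

.assembleStats <- function(frame, beta_true, se, n_sample) {
  beta <- beta_true + stats::rnorm(nrow(frame), 0, se)
  data.frame(snp_id = frame$snp_id, chrom = frame$chrom, pos = frame$pos,
             effect_allele = frame$effect_allele,
             other_allele = frame$other_allele,
             eaf = frame$eaf, beta = beta, se = se,
             pval = normalP(beta, se), n = n_sample,
             palindromic = isPalindromic(frame$effect_allele,
                                         frame$other_allele),
             stringsAsFactors = FALSE)
}

#' Simulate an exposure/outcome GWAS pair
#'
#' Generates paired summary statistics under a known causal effect
#' `theta`, with optional pleiotropy: per-SNP MAF from `maf_range`,
#' standard errors `1/sqrt(2 n maf (1-maf))`, true instrument effects
#' resampled to F >= 10, outcome effects `theta * bx + alpha`, and
#' observed effects with normal sampling noise. The returned truth record
#' stores every latent quantity.
#'
#' @param scenario A [simScenario()].
#' @return List `exposure`, `outcome` (summary-statistics data frames in
#'   the package's canonical columns) and `truth`.
#' @export
simulateGwasPair <- function(scenario) {
  stopifnot(inherits(scenario, "SimScenario"))
  withSeed(scenario$seed, {
    fr <- .simSnpFrame(scenario$n_snps, scenario$maf_range,
                       scenario$prop_palindromic)
    se_x <- 1 / sqrt(2 * scenario$n_exposure * fr$maf * (1 - fr$maf))
    se_y <- 1 / sqrt(2 * scenario$n_outcome * fr$maf * (1 - fr$maf))
    bx <- .drawStrongEffects(se_x)
    alpha <- .drawPleiotropy(scenario, bx)
    by <- scenario$theta * bx + alpha
    exposure <- .assembleStats(fr, bx, se_x, scenario$n_exposure)
    outcome <- .assembleStats(fr, by, se_y, scenario$n_outcome)
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = scenario$theta, bx_true = bx, by_true = by,
                      alpha = alpha, maf = fr$maf, se_x = se_x, se_y = se_y,
                      snp_id = fr$snp_id,
                      palindromic = isPalindromic(fr$effect_allele,
                                                  fr$other_allele)))
  })
}

#' Simulate a mediation triplet
#'
#' Generates exposure, mediator and outcome GWAS tables under the chain
#' X -> M -> Y with path coefficients `a` (X on M), `b` (M on Y) and a
#' `direct` X -> Y path, so the total effect is `direct + a b` by
#' construction. Exposure and mediator carry independent instrument sets;
#' all three tables report every SNP.
#'
#' @param scenario A [simScenario()] with `mediator_chain = list(a, b,
#'   direct)`.
#' @param mediator_mode `"causal"` (the chain above), `"null"` (a = 0), or
#'   `"downstream_of_outcome"` (the mediator is a consequence of the
#'   outcome, `M = 0.2 Y`, so it has no instruments of its own and must
#'   fail the two-step screen).
#' @return List `exposure`, `mediator`, `outcome`, `truth` (with the
#'   implied mediation proportion in percent).
#' @export
simulateMediationTriplet <- function(scenario,
                                     mediator_mode = c("causal", "null",
                                                       "downstream_of_outcome")) {
  stopifnot(inherits(scenario, "SimScenario"),
            !is.null(scenario$mediator_chain))
  mediator_mode <- match.arg(mediator_mode)
  ch <- scenario$mediator_chain
  a <- if (mediator_mode == "null") 0 else ch$a
  b <- ch$b; direct <- ch$direct
  total <- direct + a * b
  withSeed(scenario$seed, {
    n <- scenario$n_snps
    frA <- .simSnpFrame(n, scenario$maf_range, scenario$prop_palindromic,
                        prefix = "rsA")
    frB <- .simSnpFrame(n, scenario$maf_range, scenario$prop_palindromic,
                        prefix = "rsB")
    fr <- rbind(frA, frB)
    se_x <- 1 / sqrt(2 * scenario$n_exposure * fr$maf * (1 - fr$maf))
    se_m <- 1 / sqrt(2 * scenario$n_mediator * fr$maf * (1 - fr$maf))
    se_y <- 1 / sqrt(2 * scenario$n_outcome * fr$maf * (1 - fr$maf))
    iA <- seq_len(n); iB <- n + seq_len(n)

    bx <- numeric(2 * n)
    bx[iA] <- .drawStrongEffects(se_x[iA])
    if (mediator_mode == "downstream_of_outcome") {
      c_rev <- 0.2
      by <- numeric(2 * n)
      by[iA] <- total * bx[iA]
      by[iB] <- .drawStrongEffects(se_y[iB])  # outcome's own variants
      bm <- c_rev * by
    } else {
      bm <- numeric(2 * n)
      bm[iA] <- a * bx[iA]
      bm[iB] <- .drawStrongEffects(se_m[iB])
      by <- numeric(2 * n)
      by[iA] <- (direct + a * b) * bx[iA]
      by[iB] <- b * bm[iB]
    }
    list(exposure = .assembleStats(fr, bx, se_x, scenario$n_exposure),
         mediator = .assembleStats(fr, bm, se_m, scenario$n_mediator),
         outcome = .assembleStats(fr, by, se_y, scenario$n_outcome),
         truth = list(a = a, b = b, direct = direct, total = total,
                      prop_pct = if (total != 0) 100 * a * b / total else NA,
                      mediator_mode = mediator_mode,
                      exposure_snps = frA$snp_id, mediator_snps = frB$snp_id))
  })
}

#' Randomly corrupt allele encoding
#'
#' Applies, independently per SNP, an allele swap (effect and other allele
#' exchanged, beta negated, frequency complemented) and/or a strand
#' complement, each with probability 0.5 — the encoding noise that
#' harmonization must undo. The corruption log records the ground truth.
#'
#' @param stats Summary-statistics `data.frame`.
#' @param seed RNG seed.
#' @return `stats` corrupted, with attribute `"corruption_log"`
#'   (`snp_id`, `swapped`, `strand_flipped`).
#' @export
scrambleAlleles <- function(stats, seed = NULL) {
  withSeed(seed, {
    n <- nrow(stats)
    swap <- stats::runif(n) < 0.5
    strand <- stats::runif(n) < 0.5
    out <- stats
    if (any(swap)) {
      tmp <- out$effect_allele[swap]
      out$effect_allele[swap] <- out$other_allele[swap]
      out$other_allele[swap] <- tmp
      out$beta[swap] <- -out$beta[swap]
      out$eaf[swap] <- 1 - out$eaf[swap]
    }
    if (any(strand)) {
      out$effect_allele[strand] <- complementAllele(out$effect_allele[strand])
      out$other_allele[strand] <- complementAllele(out$other_allele[strand])
    }
    attr(out, "corruption_log") <- data.frame(snp_id = stats$snp_id,
                                              swapped = swap,
                                              strand_flipped = strand,
                                              stringsAsFactors = FALSE)
    out
  })
}

#' Block-diagonal LD matrix
#'
#' A simple LD structure for clumping and proxy tests: consecutive SNPs
#' form blocks with constant within-block r-squared, zero between blocks,
#' unit diagonal.
#'
#' @param snp_ids SNP identifiers (order defines the blocks).
#' @param block_size SNPs per block (default 1 = independent SNPs).
#' @param r2_within Within-block r-squared (default 0.3).
#' @return Square symmetric matrix with `snp_ids` dimnames.
#' @export
simulateLDMatrix <- function(snp_ids, block_size = 1, r2_within = 0.3) {
  n <- length(snp_ids)
  block <- (seq_len(n) - 1L) %/% block_size
  m <- outer(block, block, "==") * r2_within
  diag(m) <- 1
  dimnames(m) <- list(snp_ids, snp_ids)
  m
}

#' Simulate a PheWAS world
#'
#' Annotations for index SNPs and a matchable control pool, plus a long
#' SNP-by-trait association table: p-values Uniform(0, 1) everywhere
#' except traits named in `enrichment_spec`, where each index SNP is
#' nominally associated (p < 0.01) with the stated probability.
#'
#' @param n_index Number of index SNPs.
#' @param n_pool Control-pool size (should be much larger than
#'   `4 * n_index`).
#' @param n_traits Number of traits (default 778).
#' @param enrichment_spec Optional `data.frame(trait, prob_index)` naming
#'   enriched traits; `trait` indexes `trait_1 ... trait_n`.
#' @param seed RNG seed.
#' @return List `annotations` (index + pool, with `role` column), `assoc`
#'   (long table `snp_id`, `trait`, `pval`), `truth`.
#' @export
simulatePhewasWorld <- function(n_index, n_pool, n_traits = 778,
                                enrichment_spec = NULL, seed = NULL) {
  stopifnot(n_pool >= 4 * n_index)
  withSeed(seed, {
    ann1 <- data.frame(
      snp_id = sprintf("idx%04d", seq_len(n_index)),
      maf = stats::runif(n_index, 0.05, 0.5),
      gene_density = stats::rpois(n_index, 6) + 1L,
      dist_nearest_gene = round(stats::rexp(n_index, 1 / 20000)) + 100L,
      n_ld_partners = stats::rpois(n_index, 10) + 1L,
      role = "index", stringsAsFactors = FALSE)
    # pool mostly jittered copies of index annotations so matches exist
    base <- ann1[sample.int(n_index, n_pool, replace = TRUE), ]
    pool <- data.frame(
      snp_id = sprintf("ctl%05d", seq_len(n_pool)),
      maf = pmin(0.5, pmax(0.01, base$maf + stats::runif(n_pool, -0.04, 0.04))),
      gene_density = pmax(1L, as.integer(round(
        base$gene_density * stats::runif(n_pool, 0.6, 1.4)))),
      dist_nearest_gene = pmax(100L, as.integer(round(
        base$dist_nearest_gene * stats::runif(n_pool, 0.6, 1.4)))),
      n_ld_partners = pmax(1L, as.integer(round(
        base$n_ld_partners * stats::runif(n_pool, 0.6, 1.4)))),
      role = "pool", stringsAsFactors = FALSE)
    ann <- rbind(ann1, pool)
    traits <- sprintf("trait_%03d", seq_len(n_traits))
    assoc <- expand.grid(snp_id = ann$snp_id, trait = traits,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    assoc$pval <- stats::runif(nrow(assoc))
    if (!is.null(enrichment_spec) && nrow(enrichment_spec)) {
      for (i in seq_len(nrow(enrichment_spec))) {
        tr <- enrichment_spec$trait[i]
        pr <- enrichment_spec$prob_index[i]
        sel <- assoc$trait == tr & assoc$snp_id %in% ann1$snp_id
        k <- sum(sel)
        enriched <- stats::runif(k) < pr
        p_new <- assoc$pval[sel]
        p_new[enriched] <- stats::runif(sum(enriched), 0, 0.01)
        assoc$pval[sel] <- p_new
      }
    }
    list(annotations = ann, assoc = assoc,
         truth = list(index_ids = ann1$snp_id,
                      enriched_traits = if (is.null(enrichment_spec))
                        character() else enrichment_spec$trait))
  })
}
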