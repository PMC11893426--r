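# Config-driven orchestration: forward screen, bidirectional reruns,
# mediation pass, PheWAS pass.

#' Default pipeline thresholds
#'
#' The thresholds the screening design uses: instrument p < 1e-5, clumping
#' at r-squared 0.001 within 10000 kb, per-SNP F >= 10, proxies (off by
#' default) at r-squared > 0.8, FDR significance at 0.05 with a nominal
#' 0.05 "potential" tier, palindrome ambiguity window 0.08.
#'
#' @param ... Named overrides.
#' @return Named list of settings.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(p_instrument = 1e-5, clump_r2 = 0.001, clump_kb = 10000,
              f_min = 10, proxy_r2 = 0.8, allow_proxies = FALSE,
              eaf_window = 0.08, fdr_threshold = 0.05, p_threshold = 0.05,
              presso_k = 1000, n_boot = 1000, p_nominal = 0.01,
              n_controls = 4, seed = 20240101)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; unknown keys are rejected, missing keys take the
#' [pipelineConfig()] defaults.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

# One exposure's estimates + sensitivity battery; NULL fields where the
# SNP count is insufficient.
.analyzeExposure <- function(name, exp_stats, out_stats, ld, cfg, outcome) {
  inst <- selectInstruments(exp_stats, cfg$p_instrument, ld,
                            r2_max = cfg$clump_r2, window_kb = cfg$clump_kb,
                            f_min = cfg$f_min)
  if (nrow(inst) == 0L) {
    return(list(status = "skipped", reason = "no_instruments"))
  }
  h <- tryCatch(
    harmonizeSets(inst, out_stats, exposure = name, outcome = outcome,
                  eaf_window = cfg$eaf_window,
                  allow_proxies = cfg$allow_proxies, ld = ld,
                  proxy_pool = exp_stats, proxy_r2 = cfg$proxy_r2),
    error = function(e) e)
  if (inherits(h, "error") || nSnp(h) < 2L) {
    return(list(status = "skipped", reason = "fewer_than_2_instruments"))
  }
  seed_of <- function(stage) substreamSeed(cfg$seed, paste0(name, ":", stage))
  n <- nSnp(h)
  res <- list(status = "ok", set = h,
              ivw = mrIVW(h),
              egger = if (n >= 3) mrEgger(h) else NULL,
              wmedian = if (n >= 3)
                mrWeightedMedian(h, n_boot = cfg$n_boot,
                                 seed = seed_of("median")) else NULL,
              wmode = if (n >= 3)
                mrWeightedMode(h, n_boot = cfg$n_boot,
                               seed = seed_of("mode")) else NULL,
              loo = if (n >= 3) leaveOneOut(h) else NULL,
              presso = if (n >= 4)
                runPresso(h, K = cfg$presso_k, n_boot = cfg$n_boot,
                          seed = seed_of("presso")) else NULL)
  res
}

.estimateRow <- function(exposure, outcome, est, extra = list()) {
  base <- data.frame(exposure = exposure, outcome = outcome,
                     method = est@method, nsnp = est@nsnp,
                     beta = mrBeta(est), se = mrSE(est),
                     or = est@or, ci_low = est@ciLow, ci_high = est@ciHigh,
                     pval = mrPval(est), stringsAsFactors = FALSE)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

#' Forward MR screen of many exposures against one outcome
#'
#' Per exposure: instrument selection, harmonization, IVW (random
#' effects), MR-Egger and weighted median, Cochran's Q, leave-one-out and
#' MR-PRESSO; then Benjamini-Hochberg FDR across exposures on the IVW
#' p-values with significant/potential/null tier labels. Exposures with
#' fewer than two surviving instruments are reported as skipped, not
#' fatal.
#'
#' @param exposures Named list of exposure summary-statistics data frames.
#' @param outcome Outcome summary-statistics `data.frame`.
#' @param ld Optional LD matrix for clumping.
#' @param config A [pipelineConfig()].
#' @param outcome_name Label for reports.
#' @return List: `report` (one row per exposure-method with OR/CI, p,
#'   FDR p and tier on the IVW rows, sensitivity columns), `skipped`,
#'   and `details` (per-exposure result objects).
#' @export
runForward <- function(exposures, outcome, ld = NULL,
                       config = pipelineConfig(),
                       outcome_name = "outcome") {
  stopifnot(length(exposures) >= 1)
  if (is.null(names(exposures))) {
    names(exposures) <- paste0("exposure_", seq_along(exposures))
  }
  details <- lapply(names(exposures), function(nm) {
    .analyzeExposure(nm, exposures[[nm]], outcome, ld, config, outcome_name)
  })
  names(details) <- names(exposures)
  ok <- vapply(details, function(x) x$status == "ok", logical(1))
  skipped <- data.frame(
    exposure = names(details)[!ok],
    reason = vapply(details[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)

  rows <- list()
  for (nm in names(details)[ok]) {
    d <- details[[nm]]
    sens <- list(
      Q_pval = unname(heterogeneity(d$ivw)["pval"]),
      egger_intercept_pval = if (!is.null(d$egger))
        unname(eggerIntercept(d$egger)["pval"]) else NA_real_,
      global_p = if (!is.null(d$presso)) globalP(d$presso) else NA_real_,
      n_outliers = if (!is.null(d$presso))
        length(outlierIds(d$presso)) else NA_integer_,
      beta_outlier_corrected = if (!is.null(d$presso))
        d$presso@betaCorrected else NA_real_,
      loo_flagged = if (!is.null(d$loo)) sum(d$loo$flagged) else NA_integer_)
    rows[[paste0(nm, ":ivw")]] <-
      .estimateRow(nm, outcome_name, d$ivw, sens)
    for (m in c("egger", "wmedian")) {
      if (!is.null(d[[m]])) {
        rows[[paste0(nm, ":", m)]] <- .estimateRow(nm, outcome_name, d[[m]], sens)
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(report)) {
    ivw_rows <- report$method %in% c("ivw_random", "ivw_fixed", "wald")
    adj <- bhFDR(report$pval[ivw_rows], config$fdr_threshold,
                 config$p_threshold)
    report$fdr_p <- NA_real_
    report$tier <- NA_character_
    report$fdr_p[ivw_rows] <- adj$fdr_p
    report$tier[ivw_rows] <- adj$tier
    # carry the exposure's tier onto its sensitivity-method rows
    for (nm in unique(report$exposure)) {
      sel <- report$exposure == nm
      tier <- report$tier[sel & ivw_rows]
      if (length(tier)) report$tier[sel] <- tier
    }
    rownames(report) <- NULL
  }
  list(report = report, skipped = skipped, details = details)
}

#' Bidirectional (reverse-direction) MR reruns
#'
#' Swaps exposure and outcome roles for each forward hit: instruments are
#' selected from the outcome GWAS and tested against the protein, using
#' IVW, MR-Egger and the weighted mode. A reverse p < 0.05 flags possible
#' reverse causation.
#'
#' @param exposures Named list of the original exposure GWAS tables.
#' @param outcome The original outcome GWAS table.
#' @param hits Character vector of exposure names to rerun (typically the
#'   significant/potential tier). Empty gives an empty report.
#' @param ld,config,outcome_name As in [runForward()].
#' @return List `report` (rows per hit and method with
#'   `reverse_significant`), `skipped`.
#' @export
runBidirectional <- function(exposures, outcome, hits, ld = NULL,
                             config = pipelineConfig(),
                             outcome_name = "outcome") {
  empty <- data.frame(exposure = character(), outcome = character(),
                      method = character(), nsnp = integer(),
                      beta = numeric(), se = numeric(), or = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      pval = numeric(), reverse_significant = logical(),
                      stringsAsFactors = FALSE)
  if (length(hits) == 0L) {
    return(list(report = empty, skipped = data.frame(exposure = character(),
                                                     reason = character())))
  }
  rows <- list()
  skipped <- list()
  for (nm in hits) {
    d <- .analyzeExposure(outcome_name, outcome, exposures[[nm]], ld,
                          config, nm)
    if (d$status != "ok") {
      skipped[[nm]] <- data.frame(exposure = nm, reason = d$reason,
                                  stringsAsFactors = FALSE)
      next
    }
    for (m in c("ivw", "egger", "wmode")) {
      if (!is.null(d[[m]])) {
        rows[[paste0(nm, ":", m)]] <- .estimateRow(outcome_name, nm, d[[m]])
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(report)) {
    report$reverse_significant <- report$pval < config$p_threshold
    rownames(report) <- NULL
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(exposure = character(), reason = character())
  list(report = report, skipped = skipped)
}

#' Two-step mediation pass
#'
#' Screens the mediator panel with [screenMediators()], then produces the
#' mediation table for candidates: total effect (exposure on outcome, IVW
#' on the exposure's instruments), direct effects A and B from the screen,
#' indirect effect by product of coefficients with delta-method SE, and
#' mediation-proportion CI with suppression labels.
#'
#' @param exposure_stats Exposure (hit) GWAS summary statistics.
#' @param mediator_stats Named list of mediator GWAS summary statistics.
#' @param outcome_stats Outcome GWAS summary statistics.
#' @param ld,config As in [runForward()].
#' @param exposure_name,outcome_name Labels for the table.
#' @return List `screen` (all mediators with step results) and `table`
#'   (mediation summary rows for candidates; zero-row with full header
#'   when there are none).
#' @export
runMediation <- function(exposure_stats, mediator_stats, outcome_stats,
                         ld = NULL, config = pipelineConfig(),
                         exposure_name = "exposure",
                         outcome_name = "outcome") {
  inst <- selectInstruments(exposure_stats, config$p_instrument, ld,
                            r2_max = config$clump_r2,
                            window_kb = config$clump_kb,
                            f_min = config$f_min)
  h <- harmonizeSets(inst, outcome_stats, exposure = exposure_name,
                     outcome = outcome_name, eaf_window = config$eaf_window)
  total <- mrIVW(h)
  screen <- screenMediators(exposure_stats, mediator_stats, outcome_stats,
                            ld = ld, p_instrument = config$p_instrument,
                            f_min = config$f_min,
                            p_screen = config$p_threshold,
                            eaf_window = config$eaf_window)
  cand <- screen[screen$candidate, , drop = FALSE]
  tab <- if (nrow(cand)) {
    mediationSummary(mrBeta(total), mrSE(total),
                     cand$step1_beta, cand$step1_se,
                     cand$step2_beta, cand$step2_se,
                     exposure = exposure_name, mediator = cand$mediator,
                     outcome = outcome_name)
  } else {
    mediationSummary(1, 1, 0, 1, 0, 1)[0, , drop = FALSE]
  }
  list(screen = screen, table = tab, total = total)
}

#' Matched-control PheWAS pass
#'
#' Matches `n_controls` control SNPs to each index SNP (controls are
#' removed from the pool as they are used), then runs the Fisher
#' trait-enrichment comparison of index versus pooled control SNPs.
#'
#' @param annotations Annotation `data.frame` covering index SNPs and the
#'   control pool.
#' @param assoc Long SNP-by-trait association table.
#' @param index_ids Index (hit) SNP ids.
#' @param config A [pipelineConfig()].
#' @return List `matches` (index -> control ids), `enrichment`
#'   (trait-level results), `shortfall` (controls missing per index SNP).
#' @export
runPhewas <- function(annotations, assoc, index_ids,
                      config = pipelineConfig()) {
  pool <- annotations[!(annotations$snp_id %in% index_ids), , drop = FALSE]
  matches <- list()
  shortfall <- integer()
  for (i in seq_along(index_ids)) {
    idx <- annotations[annotations$snp_id == index_ids[i], , drop = FALSE]
    if (nrow(idx) == 0L) stop("index SNP not annotated: ", index_ids[i])
    ctl <- matchControls(idx, pool, n_controls = config$n_controls,
                         seed = substreamSeed(config$seed,
                                              paste0("match:", index_ids[i])))
    matches[[index_ids[i]]] <- ctl$snp_id
    shortfall[index_ids[i]] <- attr(ctl, "shortfall")
    pool <- pool[!(pool$snp_id %in% ctl$snp_id), , drop = FALSE]
  }
  control_ids <- unlist(matches, use.names = FALSE)
  enr <- traitEnrichment(assoc, index_ids, control_ids,
                         p_nominal = config$p_nominal)
  list(matches = matches, enrichment = enr, shortfall = shortfall)
}
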