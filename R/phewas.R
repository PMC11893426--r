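# Matched-control PheWAS trait enrichment.

#' Match control SNPs to an index SNP
#'
#' Controls are drawn from a pool of annotated SNPs whose minor allele
#' frequency lies within `maf_tol` (absolute) of the index SNP and whose
#' surrounding gene density, distance to the nearest gene and number of LD
#' partners (r-squared >= 0.5) each lie within `rel_tol` (relative) of the
#' index values. `n_controls` eligible SNPs are sampled uniformly without
#' replacement; when fewer are eligible, all are returned and the
#' shortfall is recorded in attribute `"shortfall"`.
#'
#' @param index One-row annotation `data.frame` with columns `snp_id`,
#'   `maf`, `gene_density`, `dist_nearest_gene`, `n_ld_partners`.
#' @param pool Annotation `data.frame` of candidate controls (must exclude
#'   the index SNP and any previously chosen controls).
#' @param n_controls Controls per index SNP (default 4).
#' @param maf_tol Absolute MAF tolerance (default 0.05).
#' @param rel_tol Relative tolerance for the other criteria (default 0.5).
#' @param seed RNG seed for the sampling step.
#' @return Annotation rows of the chosen controls.
#' @export
matchControls <- function(index, pool, n_controls = 4, maf_tol = 0.05,
                          rel_tol = 0.5, seed = NULL) {
  if (nrow(pool) == 0L) stop("empty control pool")
  pool <- pool[pool$snp_id != index$snp_id, , drop = FALSE]
  relOK <- function(x, ref) abs(x - ref) <= rel_tol * ref
  elig <- abs(pool$maf - index$maf) <= maf_tol &
    relOK(pool$gene_density, index$gene_density) &
    relOK(pool$dist_nearest_gene, index$dist_nearest_gene) &
    relOK(pool$n_ld_partners, index$n_ld_partners)
  cand <- pool[elig, , drop = FALSE]
  take <- min(n_controls, nrow(cand))
  picked <- withSeed(seed, cand[sample.int(nrow(cand), take), , drop = FALSE])
  rownames(picked) <- NULL
  attr(picked, "shortfall") <- n_controls - take
  if (take < n_controls) {
    message("only ", take, " eligible control(s) for ", index$snp_id,
            " (wanted ", n_controls, ")")
  }
  picked
}

#' PheWAS trait enrichment by Fisher's exact test
#'
#' For each trait, counts index and control SNPs nominally associated
#' (`p < p_nominal`), tests the 2x2 table with a two-sided Fisher's exact
#' test, and adjusts across traits by Benjamini-Hochberg FDR. A trait with
#' no associated SNP on either arm is reported with `fisher_or = NA` and
#' `fisher_p = 1`.
#'
#' @param assoc Long association table with columns `snp_id`, `trait`,
#'   `pval`, covering every listed SNP.
#' @param index_ids,control_ids SNP ids of the two arms.
#' @param p_nominal Nominal association threshold (default 0.01).
#' @return `data.frame` with one row per trait: `trait`, `k_index`,
#'   `n_index`, `k_control`, `n_control`, `fisher_or`, `fisher_p`, `fdr_p`,
#'   ordered by raw p.
#' @export
traitEnrichment <- function(assoc, index_ids, control_ids, p_nominal = 0.01) {
  missing_ids <- setdiff(c(index_ids, control_ids), unique(assoc$snp_id))
  if (length(missing_ids)) {
    stop("association table is missing SNP(s): ",
         paste(missing_ids, collapse = ", "))
  }
  traits <- unique(assoc$trait)
  n_i <- length(index_ids); n_c <- length(control_ids)
  hit <- assoc$pval < p_nominal
  rows <- lapply(traits, function(tr) {
    sub <- assoc$trait == tr
    k_i <- sum(sub & hit & assoc$snp_id %in% index_ids)
    k_c <- sum(sub & hit & assoc$snp_id %in% control_ids)
    if (k_i + k_c == 0L) {
      or <- NA_real_; p <- 1
    } else {
      ft <- stats::fisher.test(matrix(c(k_i, n_i - k_i, k_c, n_c - k_c),
                                      nrow = 2, byrow = TRUE))
      or <- unname(ft$estimate); p <- ft$p.value
    }
    data.frame(trait = tr, k_index = k_i, n_index = n_i,
               k_control = k_c, n_control = n_c,
               fisher_or = or, fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- stats::p.adjust(out$fisher_p, method = "BH")
  out <- out[order(out$fisher_p, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}
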