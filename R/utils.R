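# Internal helpers shared across modules.

VALID_BASES <- c("A", "C", "G", "T")

#' Two-sided normal quantile for a confidence level
#' @noRd
zQuantile <- function(level) {
  stopifnot(level > 0, level < 1)
  stats::qnorm(1 - (1 - level) / 2)
}

#' Complement single-base alleles
#'
#' @param a Character vector of single bases (A/C/G/T).
#' @return Character vector of the complementary bases.
#' @examples
#' complementAllele(c("A", "C"))
#' @export
complementAllele <- function(a) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bad <- !(a %in% names(comp))
  if (any(bad)) {
    stop("invalid allele(s): ", paste(unique(a[bad]), collapse = ", "))
  }
  unname(comp[a])
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. A NULL seed evaluates in the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a named pipeline stage, kept inside 32-bit
# integer range.
substreamSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 1009 + h) %% 2147483629)
}

# Two-sided normal p-value for an estimate/SE pair; se == 0 collapses to
# 0 or 1 depending on the estimate.
normalP <- function(beta, se) {
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(beta / se)),
              ifelse(beta == 0, 1, 0))
  pmin(pmax(p, 0), 1)
}
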