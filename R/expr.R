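#' @include utils.R
NULL

#' Relative expression level from qRT-PCR Ct values
#'
#' Normalizes a target gene's Ct against the mean Ct of one or more
#' housekeeping genes on the exponential PCR scale:
#' 2^(mean Ct housekeeping - Ct target).  Adding a constant to every Ct
#' leaves the result unchanged; raising the target Ct strictly lowers it.
#'
#' @param ctTarget target-gene Ct value (cycles); vectorized.
#' @param ctHousekeeping numeric vector (one sample) or matrix (samples x
#'   genes) of housekeeping Ct values.
#' @return Positive relative expression level(s).
#' @export
relativeExpression <- function(ctTarget, ctHousekeeping) {
  if (is.matrix(ctHousekeeping)) hk <- rowMeans(ctHousekeeping)
  else {
    if (!length(ctHousekeeping)) stop("need at least one housekeeping Ct")
    hk <- mean(ctHousekeeping)
  }
  2^(hk - ctTarget)
}

#' Genotype-expression regression under three inheritance models
#'
#' Regresses log10 relative expression on the risk-allele count under the
#' multiplicative model (dosage 0/1/2 as a linear term), the recessive
#' model (homozygote indicator) and the full genotype model (heterozygote
#' and homozygote indicators), by ordinary least squares.  Each submodel
#' is compared to the full model by a 1-df likelihood-ratio test under a
#' Gaussian likelihood; the F-test equivalent is reported alongside.
#' Per-genotype geometric means are 10^(mean log10 expression).
#'
#' @param expression positive relative expression levels.
#' @param genotype risk-allele counts 0/1/2, aligned with
#'   \code{expression}.  Samples with a missing value in either vector
#'   are dropped listwise with a message.
#' @return list with \code{fits} (a data.frame: model, df, logLik,
#'   chi2_vs_full, P_LR_vs_full, F_vs_full, P_F_vs_full, skipped) and
#'   \code{geometric_means} (named by genotype class).
#' @export
expressionGenotypeModels <- function(expression, genotype) {
  keep <- !is.na(expression) & !is.na(genotype)
  if (any(!keep)) message(sum(!keep), " sample(s) with missing data dropped")
  y <- log10(expression[keep])
  g <- as.integer(genotype[keep])
  if (!all(g %in% 0:2)) stop("genotype must be a 0/1/2 risk-allele count")
  classes <- sort(unique(g))
  if (length(classes) < 2L) stop("need at least two genotype classes")
  gm <- tapply(y, g, mean)
  geo <- 10^gm
  names(geo) <- paste0("g", names(gm))

  full_ok <- length(classes) == 3L
  fit_full <- if (full_ok) stats::lm(y ~ factor(g)) else NULL
  fit_mult <- stats::lm(y ~ g)
  fit_rec <- if (2L %in% classes) stats::lm(y ~ I(g == 2L)) else NULL

  cmp <- function(sub, name) {
    if (is.null(sub) || !full_ok) {
      if (is.null(sub)) warning("genotype class absent; ", name, " model skipped")
      else warning("full model needs all 3 genotype classes; comparison skipped")
      return(data.frame(model = name, df = NA_integer_,
                        logLik = if (is.null(sub)) NA_real_
                                 else as.numeric(stats::logLik(sub)),
                        chi2_vs_full = NA_real_, P_LR_vs_full = NA_real_,
                        F_vs_full = NA_real_, P_F_vs_full = NA_real_,
                        skipped = TRUE))
    }
    chi2 <- max(0, 2 * (stats::logLik(fit_full) - stats::logLik(sub)))
    an <- stats::anova(sub, fit_full)
    data.frame(model = name, df = length(stats::coef(sub)),
               logLik = as.numeric(stats::logLik(sub)),
               chi2_vs_full = chi2,
               P_LR_vs_full = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
               F_vs_full = an$F[2], P_F_vs_full = an$`Pr(>F)`[2],
               skipped = FALSE)
  }
  fits <- rbind(
    data.frame(model = "full",
               df = if (full_ok) 3L else NA_integer_,
               logLik = if (full_ok) as.numeric(stats::logLik(fit_full)) else NA_real_,
               chi2_vs_full = 0, P_LR_vs_full = 1,
               F_vs_full = NA_real_, P_F_vs_full = NA_real_,
               skipped = !full_ok),
    cmp(fit_mult, "multiplicative"),
    cmp(fit_rec, "recessive")
  )
  rownames(fits) <- NULL
  list(fits = fits, geometric_means = geo)
}
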