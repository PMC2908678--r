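#' @include AllClasses.R utils.R
NULL

#' Mantel-Haenszel combination of stratified 2x2 allele tables
#'
#' Strata (cohorts or ancestries) are allowed different population allele
#' frequencies but share a common odds ratio.  The point estimate is
#' OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i); the 95\% CI uses the
#' Robins-Breslow-Greenland variance of ln OR_MH; the combined P comes
#' from the 1-df likelihood-ratio statistic of the common-OR binomial
#' likelihood (per-stratum case/control allele counts, free allele
#' frequencies) against the null of OR = 1, deflated per stratum by its
#' genomic-control lambda when supplied.  Heterogeneity is quantified by
#' the likelihood-ratio statistic of stratum-specific ORs against the
#' common OR (see \code{\link{heterogeneityLR}}) with its I-squared.
#'
#' @param strata list of 2x2 numeric matrices (rows case/control, columns
#'   counted/other allele).
#' @param lambdaPerStratum optional numeric vector of inflation factors.
#' @return A \linkS4class{MetaResult} with method "mantel_haenszel".
#' @export
mantelHaenszel <- function(strata, lambdaPerStratum = NULL) {
  if (!length(strata)) stop("need at least one stratum")
  empty <- vapply(strata, function(t) any(rowSums(t) == 0), TRUE)
  if (any(empty)) {
    warning(sum(empty), " stratum/strata with an empty row dropped")
    strata <- strata[!empty]
    if (!is.null(lambdaPerStratum)) lambdaPerStratum <- lambdaPerStratum[!empty]
  }
  if (!length(strata)) stop("no usable strata")
  k <- length(strata)
  if (is.null(lambdaPerStratum)) lambdaPerStratum <- rep(1, k)

  a <- vapply(strata, function(t) t[1, 1], 0)
  b <- vapply(strata, function(t) t[1, 2], 0)
  c_ <- vapply(strata, function(t) t[2, 1], 0)
  d <- vapply(strata, function(t) t[2, 2], 0)
  n <- a + b + c_ + d
  R <- sum(a * d / n); S <- sum(b * c_ / n)
  or_mh <- R / S

  ## Robins-Breslow-Greenland variance of ln(OR_MH)
  P <- (a + d) / n; Q <- (b + c_) / n
  var_ln <- sum(P * a * d / n) / (2 * R^2) +
    sum(P * b * c_ / n + Q * a * d / n) / (2 * R * S) +
    sum(Q * b * c_ / n) / (2 * S^2)
  ci <- exp(log(or_mh) + c(-1, 1) * 1.96 * sqrt(var_ln))

  ## common-OR LR statistic vs OR = 1, lambda-deflated per stratum
  psi_hat <- .commonORMLE(strata)
  lr_terms <- vapply(seq_len(k), function(i) {
    2 * (.profileLL2x2(strata[[i]], psi_hat) -
         .profileLL2x2(strata[[i]], 1)) / lambdaPerStratum[i]
  }, 0)
  lr <- max(0, sum(lr_terms))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)

  if (k >= 2L) {
    het <- heterogeneityLR(strata)
    qstat <- het$LR
    phet <- het$P_het
    i2 <- if (qstat > 0) max(0, (qstat - (k - 1)) / qstat) * 100 else 0
  } else {
    qstat <- 0; phet <- 1; i2 <- 0
  }
  new("MetaResult", or = or_mh, ciLow = ci[1], ciHigh = ci[2], p = p,
      q = qstat, pHet = phet, i2 = i2, method = "mantel_haenszel",
      k = as.integer(k))
}

## MLE of the common odds ratio across strata (profile likelihood).
.commonORMLE <- function(strata) {
  obj <- function(lpsi)
    -sum(vapply(strata, .profileLL2x2, 0, psi = exp(lpsi)))
  exp(stats::optimize(obj, c(-8, 8), tol = 1e-9)$minimum)
}

#' Fixed-effect (inverse-variance) combination from printed summaries
#'
#' Combines per-stratum odds ratios and 95\% CIs when raw counts are not
#' available: weights w_i = 1/SE_i^2 with SE_i recovered from the CI as
#' ln(high/low)/(2 z_{0.975}), pooled ln OR as the weighted mean, and the
#' combined P from the Wald z of the pooled estimate.  Cochran's
#' Q = sum w_i (ln OR_i - pooled)^2 gives the heterogeneity P on
#' chi-squared(k - 1) and I2 = max(0, (Q - (k-1))/Q) x 100.
#'
#' @param strata data.frame with columns OR, CI_low, CI_high (one row per
#'   stratum), or a list of such rows.
#' @return A \linkS4class{MetaResult} with method "inverse_variance".
#' @export
fixedEffectFromSummaries <- function(strata) {
  strata <- as.data.frame(strata)
  if (!all(c("OR", "CI_low", "CI_high") %in% names(strata)))
    stop("strata need columns OR, CI_low, CI_high")
  if (any(strata$CI_high <= strata$CI_low))
    stop("CI_high must exceed CI_low in every stratum")
  k <- nrow(strata)
  z <- stats::qnorm(0.975)
  se <- log(strata$CI_high / strata$CI_low) / (2 * z)
  w <- 1 / se^2
  pooled <- sum(w * log(strata$OR)) / sum(w)
  pse <- sqrt(1 / sum(w))
  ci <- exp(pooled + c(-1, 1) * z * pse)
  p <- 2 * stats::pnorm(-abs(pooled / pse))
  qstat <- sum(w * (log(strata$OR) - pooled)^2)
  phet <- if (k >= 2) stats::pchisq(qstat, df = k - 1, lower.tail = FALSE) else 1
  i2 <- if (k >= 2 && qstat > 0) max(0, (qstat - (k - 1)) / qstat) * 100 else 0
  new("MetaResult", or = exp(pooled), ciLow = ci[1], ciHigh = ci[2], p = p,
      q = qstat, pHet = phet, i2 = i2, method = "inverse_variance",
      k = as.integer(k))
}

#' Likelihood-ratio test of effect heterogeneity across strata
#'
#' Compares the hypothesis of a single common odds ratio in all strata
#' against stratum-specific odds ratios:
#' LR = 2 [ sum_i maxlik(free OR_i) - maxlik(common OR) ], referred to
#' chi-squared with k - 1 df.
#'
#' @param strata list of at least two 2x2 allele-count tables.
#' @return list with elements LR and P_het.
#' @export
heterogeneityLR <- function(strata) {
  k <- length(strata)
  if (k < 2L) stop("heterogeneity needs at least two strata")
  psi_hat <- .commonORMLE(strata)
  ll_common <- sum(vapply(strata, .profileLL2x2, 0, psi = psi_hat))
  ll_free <- sum(vapply(strata, .freeLL2x2, 0))
  lr <- max(0, 2 * (ll_free - ll_common))
  list(LR = lr, P_het = stats::pchisq(lr, df = k - 1, lower.tail = FALSE))
}
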