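#' @include AllClasses.R utils.R
NULL

.snp_index <- function(study, snp) {
  i <- match(snp, study@genotypes@variants$id)
  if (is.na(i)) stop("SNP not typed in study: ", snp)
  i
}

#' Allele-count 2x2 table for one SNP
#'
#' Rows are case/control, columns counted-allele/other-allele chromosome
#' counts.  Samples with a missing genotype contribute their expected
#' fractional dosage when an imputation vector is supplied, otherwise
#' they are dropped, so counts may be non-integer.
#'
#' @param study a \linkS4class{CaseControlStudy}.
#' @param snp SNP id.
#' @param imputed optional named numeric vector of expected dosages for
#'   samples whose genotype is missing (names are sample ids).
#' @return 2x2 numeric matrix with dimnames.
#' @export
alleleCountTable <- function(study, snp, imputed = NULL) {
  i <- .snp_index(study, snp)
  d <- as.numeric(study@genotypes@genotypes[, i])
  ids <- study@genotypes@sampleIds
  if (!is.null(imputed)) {
    hit <- is.na(d) & ids %in% names(imputed)
    d[hit] <- imputed[ids[hit]]
  }
  keep <- !is.na(d)
  status <- study@phenotypes$status[keep]
  d <- d[keep]
  tab <- rbind(
    case = c(sum(d[status == "case"]), sum(2 - d[status == "case"])),
    control = c(sum(d[status == "control"]), sum(2 - d[status == "control"]))
  )
  colnames(tab) <- c("counted", "other")
  if (any(rowSums(tab) == 0))
    stop("no informative chromosomes in one status group for ", snp)
  tab
}

#' Genomic-control correction of a chi-squared statistic
#'
#' Deflates a 1-df association statistic by the study's inflation factor.
#'
#' @param chi2 uncorrected chi-squared statistic(s).
#' @param lambda genomic-control inflation factor.
#' @return chi2 / lambda.
#' @export
gcCorrect <- function(chi2, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  chi2 / lambda
}

#' Single-SNP allelic association under the multiplicative model
#'
#' The multiplicative (allelic) test operates on chromosome counts: the
#' odds ratio is (a d)/(b c) from the 2x2 allele-count table, the test
#' statistic is the likelihood-ratio G statistic of that table on 1 df,
#' and the 95\% CI assumes ln OR is normal with
#' SE = sqrt(1/a + 1/b + 1/c + 1/d).  With \code{useLambda} the study's
#' genomic-control factor divides the chi-squared before the P value and
#' inflates the SE by sqrt(lambda), keeping CI and P mutually consistent.
#' A 0.5 continuity correction applies to OR/CI only when a cell is zero,
#' never to the LR statistic.
#'
#' @param study a \linkS4class{CaseControlStudy}.
#' @param snp SNP id.
#' @param useLambda apply the study's inflation factor (default TRUE).
#' @param imputed optional expected dosages for missing genotypes, as in
#'   \code{\link{alleleCountTable}}.
#' @return One-row data.frame with columns snp, allele, cohort,
#'   freq_controls, OR, CI_low, CI_high, P, chi2, model; the allele-count
#'   table is attached as attribute \code{"table"}.
#' @export
allelicAssociation <- function(study, snp, useLambda = TRUE, imputed = NULL) {
  i <- .snp_index(study, snp)
  tab <- alleleCountTable(study, snp, imputed = imputed)
  if (any(colSums(tab) == 0)) stop("monomorphic SNP: ", snp)
  g <- .gStat2x2(tab)
  lam <- if (useLambda) study@lambda else 1.0
  chi2 <- gcCorrect(g, lam)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  est <- .or2x2(tab)
  se <- est["se"] * sqrt(lam)
  ci <- exp(log(est["or"]) + c(-1, 1) * stats::qnorm(0.975) * se)
  out <- data.frame(
    snp = snp,
    allele = study@genotypes@variants$counted[i],
    cohort = study@cohort,
    freq_controls = unname(tab["control", "counted"] / sum(tab["control", ])),
    OR = unname(est["or"]),
    CI_low = ci[1], CI_high = ci[2],
    P = p, chi2 = chi2, model = "multiplicative",
    stringsAsFactors = FALSE
  )
  attr(out, "table") <- tab
  out
}

#' Compare genotype risk models against the full genotype model
#'
#' Fits the full (two-parameter genotype) model, the multiplicative
#' model (log-odds linear in dosage, so the homozygote relative risk is
#' the square of the heterozygote's) and the recessive model by maximum
#' likelihood on genotype counts via logistic regression, and returns
#' 1-df likelihood-ratio P values of each submodel against the full
#' model.  When fewer than three genotype classes are observed the
#' comparison is skipped with a warning.
#'
#' @param study a \linkS4class{CaseControlStudy}.
#' @param snp SNP id.
#' @return data.frame with columns snp, comparison, chi2, P, skipped.
#' @export
genotypeModelTest <- function(study, snp) {
  i <- .snp_index(study, snp)
  d <- study@genotypes@genotypes[, i]
  keep <- !is.na(d)
  d <- d[keep]
  y <- as.integer(study@phenotypes$status[keep] == "case")
  if (length(unique(d)) < 3L) {
    warning("fewer than 3 genotype classes for ", snp, "; model test skipped")
    return(data.frame(snp = snp,
                      comparison = c("multiplicative_vs_full", "recessive_vs_full"),
                      chi2 = NA_real_, P = NA_real_, skipped = TRUE))
  }
  full <- stats::glm(y ~ factor(d), family = stats::binomial())
  mult <- stats::glm(y ~ d, family = stats::binomial())
  rec <- stats::glm(y ~ I(d == 2L), family = stats::binomial())
  lr <- function(sub) {
    stat <- max(0, 2 * (stats::logLik(full) - stats::logLik(sub)))
    c(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  m <- lr(mult); r <- lr(rec)
  data.frame(snp = snp,
             comparison = c("multiplicative_vs_full", "recessive_vs_full"),
             chi2 = c(m[1], r[1]), P = c(m[2], r[2]), skipped = FALSE)
}

#' Likelihood recovery of missing genotypes from correlated SNPs
#'
#' For every sample whose target genotype is missing, the expected dosage
#' of the counted allele is the posterior mean over unordered haplotype
#' pairs compatible with the sample's observed genotypes at the helper
#' SNPs, weighted by EM haplotype frequencies estimated on the whole
#' cohort (cases and controls jointly).  Samples missing every helper
#' genotype receive the cohort-wide mean dosage.
#'
#' @param study a \linkS4class{CaseControlStudy}.
#' @param targetSnp SNP whose missing genotypes are recovered.
#' @param helperSnps correlated typed SNPs used for recovery; if empty,
#'   every sample falls back to the cohort mean with a warning.
#' @return Named numeric vector of expected dosages in [0,2] for samples
#'   with a missing target genotype (possibly length zero).
#' @export
imputeMissing <- function(study, targetSnp, helperSnps = character()) {
  gm <- study@genotypes
  ti <- .snp_index(study, targetSnp)
  target_missing <- which(is.na(gm@genotypes[, ti]))
  if (!length(target_missing)) return(stats::setNames(numeric(0), character(0)))
  obs_d <- gm@genotypes[, ti]
  mean_dosage <- mean(obs_d, na.rm = TRUE)
  if (!length(helperSnps)) {
    warning("no helper SNPs supplied; using cohort-mean dosage")
    return(stats::setNames(rep(mean_dosage, length(target_missing)),
                           gm@sampleIds[target_missing]))
  }
  hi <- match(helperSnps, gm@variants$id)
  if (anyNA(hi)) stop("helper SNP(s) not typed in study")
  cols <- c(ti, hi)
  sub <- .subsetGenotypes(gm, cols)
  ft <- emHaplotypeFrequencies(sub)
  haps_bin <- .hapStringsToBinary(ft@haplotypes, ft@snps, ft@counted,
                                  sub@variants)
  out <- numeric(length(target_missing))
  for (k in seq_along(target_missing)) {
    s <- target_missing[k]
    g <- sub@genotypes[s, ]
    if (all(is.na(g[-1]))) { out[k] <- mean_dosage; next }
    post <- .diplotypePosterior(g, haps_bin, ft@freq[, 1])
    if (is.null(post)) { out[k] <- mean_dosage; next }
    dose <- haps_bin[post$pairs[, 1], 1] + haps_bin[post$pairs[, 2], 1]
    out[k] <- sum(post$w * dose)
  }
  stats::setNames(pmin(pmax(out, 0), 2), gm@sampleIds[target_missing])
}

.subsetGenotypes <- function(gm, cols) {
  GenotypeMatrix(gm@variants[cols, , drop = FALSE],
                 gm@genotypes[, cols, drop = FALSE],
                 gm@sampleIds)
}

#' Conditional (adjusted) association of one SNP for another
#'
#' Fits a logistic model with additive allele-dosage terms for the
#' primary and adjusting SNP.  The adjusted OR is exp of the primary
#' SNP's coefficient and the residual P is the 1-df likelihood-ratio test
#' of the two-SNP model against the adjust-SNP-only model.  Missing
#' dosages may be supplied via \code{imputed} so that the same individual
#' set supports every SNP pair in a batch; samples still missing either
#' dosage are dropped listwise.
#'
#' @param study a \linkS4class{CaseControlStudy}.
#' @param primarySnp SNP whose residual effect is estimated.
#' @param adjustSnp SNP adjusted for.
#' @param imputed optional list with elements \code{primary} and
#'   \code{adjust}: named expected-dosage vectors for missing genotypes.
#' @return One-row data.frame: primary_snp, adjust_snp, cohort, OR_adj,
#'   CI_low, CI_high, P_residual, n.
#' @export
conditionalAssociation <- function(study, primarySnp, adjustSnp,
                                   imputed = NULL) {
  if (primarySnp == adjustSnp)
    stop("cannot adjust a SNP for itself")
  pi <- .snp_index(study, primarySnp)
  ai <- .snp_index(study, adjustSnp)
  ids <- study@genotypes@sampleIds
  fill <- function(col, imp) {
    d <- as.numeric(study@genotypes@genotypes[, col])
    if (!is.null(imp)) {
      hit <- is.na(d) & ids %in% names(imp)
      d[hit] <- imp[ids[hit]]
    }
    d
  }
  dp <- fill(pi, imputed$primary)
  da <- fill(ai, imputed$adjust)
  keep <- !is.na(dp) & !is.na(da)
  dp <- dp[keep]; da <- da[keep]
  y <- as.integer(study@phenotypes$status[keep] == "case")
  if (stats::sd(dp) == 0 || stats::sd(da) == 0)
    stop("monomorphic dosage in the analysis sample")
  if (abs(stats::cor(dp, da)) > 1 - 1e-10)
    stop("inseparable: dosages perfectly collinear (r2 = 1 in sample)")
  both <- stats::glm(y ~ dp + da, family = stats::binomial())
  adj_only <- stats::glm(y ~ da, family = stats::binomial())
  lr <- max(0, 2 * (stats::logLik(both) - stats::logLik(adj_only)))
  co <- summary(both)$coefficients
  beta <- co["dp", "Estimate"]; se <- co["dp", "Std. Error"]
  data.frame(
    primary_snp = primarySnp, adjust_snp = adjustSnp, cohort = study@cohort,
    OR_adj = exp(beta),
    CI_low = exp(beta - 1.96 * se), CI_high = exp(beta + 1.96 * se),
    P_residual = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    n = length(y), stringsAsFactors = FALSE
  )
}
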