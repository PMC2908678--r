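#' @import methods
NULL

## Central containers. Allele matrices are stored as character matrices of
## single-letter alleles with NA for missing; genotype matrices as integer
## dosages (0/1/2) of a per-variant counted allele, NA for missing.

#' HaplotypePanel: phased reference haplotypes for one ancestry
#'
#' A phased allele matrix over a set of biallelic SNPs, with two chromosome
#' rows per diploid sample.  Panels are the substrate for linkage
#' disequilibrium: all r2/D' screening is done on phased reference data,
#' never on study genotypes.
#'
#' @slot variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based), \code{a1}, \code{a2} (single-character alleles)
#'   and \code{risk} (the at-risk allele, or NA when unoriented).
#' @slot haplotypes character matrix, one row per chromosome (2 per
#'   sample), one column per variant; entries are \code{a1}/\code{a2} of
#'   the column's variant or NA.
#' @slot sampleIds character vector, length \code{nrow(haplotypes)/2}.
#' @slot ancestry single ancestry label.
#'
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  slots = c(
    variants = "data.frame",
    haplotypes = "matrix",
    sampleIds = "character",
    ancestry = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  v <- object@variants
  h <- object@haplotypes
  msg <- character()
  need <- c("id", "chrom", "pos", "a1", "a2", "risk")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variants must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(v$a1 == v$a2)) msg <- c(msg, "variant alleles must be distinct")
    if (any(v$pos < 1)) msg <- c(msg, "positions must be >= 1")
    bad <- !is.na(v$risk) & v$risk != v$a1 & v$risk != v$a2
    if (any(bad)) msg <- c(msg, "risk allele must be one of the variant's alleles")
    if (ncol(h) != nrow(v)) msg <- c(msg, "haplotype columns must match variant count")
    if (nrow(h) %% 2L != 0L) msg <- c(msg, "haplotype row count must be even")
    if (nrow(h) != 2L * length(object@sampleIds))
      msg <- c(msg, "need exactly 2 haplotype rows per sample id")
    for (j in seq_len(ncol(h))) {
      ok <- is.na(h[, j]) | h[, j] == v$a1[j] | h[, j] == v$a2[j]
      if (!all(ok)) {
        msg <- c(msg, sprintf("column %s carries alleles outside {%s,%s}",
                              v$id[j], v$a1[j], v$a2[j]))
        break
      }
    }
  }
  if (length(object@ancestry) != 1L) msg <- c(msg, "ancestry must be a single label")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: unphased diploid dosage calls
#'
#' @slot variants data.frame as in \linkS4class{HaplotypePanel}, plus a
#'   \code{counted} column naming the allele whose copies are counted.
#' @slot genotypes integer matrix, samples x variants, values 0/1/2/NA.
#' @slot sampleIds character vector of row identities.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(
    variants = "data.frame",
    genotypes = "matrix",
    sampleIds = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  v <- object@variants
  g <- object@genotypes
  msg <- character()
  if (!"counted" %in% names(v))
    msg <- c(msg, "variants must carry a 'counted' allele column")
  else if (any(v$counted != v$a1 & v$counted != v$a2))
    msg <- c(msg, "counted allele must be one of the variant's alleles")
  if (ncol(g) != nrow(v)) msg <- c(msg, "genotype columns must match variant count")
  if (nrow(g) != length(object@sampleIds))
    msg <- c(msg, "one genotype row per sample id")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2))
    msg <- c(msg, "genotype values must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' CaseControlStudy: genotypes, phenotypes and a genomic-control factor
#'
#' The unit of association testing: an unphased \linkS4class{GenotypeMatrix}
#' aligned with a phenotype table (case/control status plus cohort label)
#' and an inflation factor lambda used to deflate chi-squared statistics
#' for cryptic relatedness.
#'
#' @slot genotypes a \linkS4class{GenotypeMatrix}.
#' @slot phenotypes data.frame with columns \code{sampleId},
#'   \code{status} ("case"/"control"), \code{cohort}; row order matches
#'   the genotype rows.
#' @slot cohort single cohort/ancestry label.
#' @slot lambda genomic-control inflation factor (>= 1 expected).
#'
#' @exportClass CaseControlStudy
setClass("CaseControlStudy",
  slots = c(
    genotypes = "GenotypeMatrix",
    phenotypes = "data.frame",
    cohort = "character",
    lambda = "numeric"
  )
)

setValidity("CaseControlStudy", function(object) {
  ph <- object@phenotypes
  msg <- character()
  need <- c("sampleId", "status", "cohort")
  if (!all(need %in% names(ph)))
    msg <- c(msg, paste("phenotypes must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(ph$status %in% c("case", "control")))
      msg <- c(msg, "status must be 'case' or 'control'")
    if (!identical(ph$sampleId, object@genotypes@sampleIds))
      msg <- c(msg, "phenotype rows must align with genotype sample ids")
  }
  if (length(object@lambda) != 1L || is.na(object@lambda) || object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' LDMatrix: pairwise r-squared and D-prime over a SNP set
#'
#' @slot snpIds SNP identifiers (row/column order of the matrices).
#' @slot r2 symmetric matrix of squared allelic correlations in [0,1];
#'   NA flags pairs undefined because a SNP is monomorphic.
#' @slot dprime symmetric matrix of |D|/Dmax in [0,1].
#' @slot nUsed integer matrix of haplotype counts used per pair after
#'   pairwise deletion of missing alleles.
#'
#' @exportClass LDMatrix
setClass("LDMatrix",
  slots = c(
    snpIds = "character",
    r2 = "matrix",
    dprime = "matrix",
    nUsed = "matrix"
  )
)

setValidity("LDMatrix", function(object) {
  msg <- character()
  k <- length(object@snpIds)
  for (nm in c("r2", "dprime", "nUsed")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(k, k))) msg <- c(msg, sprintf("%s must be %d x %d", nm, k, k))
  }
  if (!length(msg)) {
    for (nm in c("r2", "dprime")) {
      m <- slot(object, nm)
      if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
        msg <- c(msg, paste(nm, "must be symmetric"))
      vals <- m[!is.na(m)]
      if (length(vals) && (min(vals) < -1e-12 || max(vals) > 1 + 1e-12))
        msg <- c(msg, paste(nm, "values must lie in [0,1]"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' EquivalenceClassSet: r-squared-defined partition of SNPs with tags
#'
#' Equivalence classes are branches of the average-linkage dendrogram on
#' distance 1 - r2, cut at height 1 - r2_threshold: within a class the
#' SNPs are statistically interchangeable in the given ancestry.
#'
#' @slot classes named list of character vectors partitioning the SNP set.
#' @slot tags one designated tag SNP per class (same order as classes).
#' @slot ancestry ancestry label of the panel the classes came from.
#' @slot r2Threshold the r2 cut defining class membership.
#' @slot mergeHeights dendrogram merge heights on the 1 - r2 scale.
#' @slot tree the underlying \code{hclust} object (or NULL for a single SNP).
#'
#' @exportClass EquivalenceClassSet
setClass("EquivalenceClassSet",
  slots = c(
    classes = "list",
    tags = "character",
    ancestry = "character",
    r2Threshold = "numeric",
    mergeHeights = "numeric",
    tree = "ANY"
  )
)

setValidity("EquivalenceClassSet", function(object) {
  msg <- character()
  all_snps <- unlist(object@classes, use.names = FALSE)
  if (anyDuplicated(all_snps)) msg <- c(msg, "classes must be disjoint")
  if (length(object@tags) != length(object@classes))
    msg <- c(msg, "one tag per class required")
  else if (length(object@tags) &&
           !all(mapply(function(t, cl) t %in% cl, object@tags, object@classes)))
    msg <- c(msg, "each tag must belong to its class")
  if (length(object@r2Threshold) != 1L ||
      object@r2Threshold <= 0 || object@r2Threshold > 1)
    msg <- c(msg, "r2Threshold must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' HaplotypeFrequencyTable: EM-estimated multilocus haplotype frequencies
#'
#' @slot snps ordered SNP ids spanning the haplotypes.
#' @slot counted per-SNP counted (at-risk) allele defining orientation.
#' @slot haplotypes allele strings (one character per SNP).
#' @slot freq matrix haplotypes x groups; each column sums to 1.
#' @slot logLik observed-data log-likelihood at convergence, per group.
#' @slot iterations EM iterations used, per group.
#' @slot nChrom chromosomes contributing per group (expected counts base).
#'
#' @exportClass HaplotypeFrequencyTable
setClass("HaplotypeFrequencyTable",
  slots = c(
    snps = "character",
    counted = "character",
    haplotypes = "character",
    freq = "matrix",
    logLik = "numeric",
    iterations = "integer",
    nChrom = "numeric"
  )
)

setValidity("HaplotypeFrequencyTable", function(object) {
  msg <- character()
  if (any(nchar(object@haplotypes) != length(object@snps)))
    msg <- c(msg, "haplotype strings must have one character per SNP")
  if (nrow(object@freq) != length(object@haplotypes))
    msg <- c(msg, "one frequency row per haplotype")
  if (any(object@freq < -1e-12))
    msg <- c(msg, "frequencies must be nonnegative")
  cs <- colSums(object@freq)
  if (length(cs) && any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "each group's frequencies must sum to 1")
  if (length(msg)) msg else TRUE
})

#' MetaResult: combined effect across strata with heterogeneity diagnostics
#'
#' @slot or combined odds ratio.
#' @slot ciLow,ciHigh 95\% confidence limits for the combined OR.
#' @slot p two-sided P for the combined effect.
#' @slot q Cochran's Q (inverse-variance route) or the heterogeneity LR
#'   statistic (count route).
#' @slot pHet heterogeneity P on chi-squared with k - 1 df.
#' @slot i2 percent of variation attributable to heterogeneity.
#' @slot method "mantel_haenszel" or "inverse_variance".
#' @slot k number of strata combined.
#'
#' @exportClass MetaResult
setClass("MetaResult",
  slots = c(
    or = "numeric", ciLow = "numeric", ciHigh = "numeric", p = "numeric",
    q = "numeric", pHet = "numeric", i2 = "numeric",
    method = "character", k = "integer"
  )
)

setValidity("MetaResult", function(object) {
  msg <- character()
  if (!object@method %in% c("mantel_haenszel", "inverse_variance"))
    msg <- c(msg, "method must be 'mantel_haenszel' or 'inverse_variance'")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@or && object@or <= object@ciHigh))
    msg <- c(msg, "CI must bracket the combined OR")
  if (!is.na(object@i2) && (object@i2 < 0 || object@i2 > 100))
    msg <- c(msg, "I2 must lie in [0,100]")
  if (length(msg)) msg else TRUE
})

#' AncestrySpec: a closed haplotype pool with a causal allele
#'
#' Defines one ancestry for the retrospective simulator: an ordered SNP
#' panel, a pool of haplotype strings with population frequencies (any
#' remaining mass goes to a catch-all haplotype carrying no risk allele at
#' the causal SNP), the causal SNP and its multiplicative allelic OR.
#'
#' @slot ancestry label.
#' @slot variants data.frame with \code{id}, \code{chrom}, \code{pos},
#'   \code{a1}, \code{a2}, \code{risk}.
#' @slot haplotypes allele strings over the SNP order.
#' @slot freq population frequencies, summing to 1 (catch-all included).
#' @slot causalSnp id of the causal SNP.
#' @slot causalOR multiplicative per-allele odds ratio at the causal SNP.
#'
#' @exportClass AncestrySpec
setClass("AncestrySpec",
  slots = c(
    ancestry = "character",
    variants = "data.frame",
    haplotypes = "character",
    freq = "numeric",
    causalSnp = "character",
    causalOR = "numeric"
  )
)

setValidity("AncestrySpec", function(object) {
  msg <- character()
  m <- nrow(object@variants)
  if (any(nchar(object@haplotypes) != m))
    msg <- c(msg, "haplotype strings must span the SNP order")
  if (length(object@freq) != length(object@haplotypes))
    msg <- c(msg, "one frequency per haplotype")
  if (any(object@freq < 0) || abs(sum(object@freq) - 1) > 1e-9)
    msg <- c(msg, "frequencies must be nonnegative and sum to 1")
  if (!object@causalSnp %in% object@variants$id)
    msg <- c(msg, "causal SNP must be in the variant list")
  if (object@causalOR <= 0) msg <- c(msg, "causal OR must be positive")
  if (anyDuplicated(object@haplotypes)) msg <- c(msg, "haplotypes must be distinct")
  if (length(msg)) msg else TRUE
})
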