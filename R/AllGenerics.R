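#' @include AllClasses.R
NULL

#' Accessors for the core containers
#'
#' \code{variants()} returns the variant annotation data.frame;
#' \code{sampleIds()} the sample identifiers; \code{haplotypes()} the
#' phased allele matrix of a panel (or the haplotype strings of a
#' frequency table); \code{genotypes()} the dosage matrix;
#' \code{phenotypes()} the phenotype table; \code{ancestry()} the
#' ancestry/cohort label; \code{inflationFactor()} the genomic-control
#' lambda; \code{ldR2()} / \code{ldDprime()} the LD matrices;
#' \code{classMembers()} / \code{classTags()} the equivalence classes and
#' their tag SNPs; \code{hapFrequencies()} the per-group haplotype
#' frequency matrix.
#'
#' @param x an ancestryShift object.
#' @return The slot contents described above.
#' @name accessors
#' @aliases variants sampleIds haplotypes genotypes phenotypes ancestry
#'   inflationFactor ldR2 ldDprime classMembers classTags hapFrequencies
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("ancestry", function(x) standardGeneric("ancestry"))
#' @rdname accessors
#' @export
setGeneric("inflationFactor", function(x) standardGeneric("inflationFactor"))
#' @rdname accessors
#' @export
setGeneric("ldR2", function(x) standardGeneric("ldR2"))
#' @rdname accessors
#' @export
setGeneric("ldDprime", function(x) standardGeneric("ldDprime"))
#' @rdname accessors
#' @export
setGeneric("classMembers", function(x) standardGeneric("classMembers"))
#' @rdname accessors
#' @export
setGeneric("classTags", function(x) standardGeneric("classTags"))
#' @rdname accessors
#' @export
setGeneric("hapFrequencies", function(x) standardGeneric("hapFrequencies"))

setMethod("variants", "HaplotypePanel", function(x) x@variants)
setMethod("variants", "GenotypeMatrix", function(x) x@variants)
setMethod("variants", "CaseControlStudy", function(x) x@genotypes@variants)
setMethod("variants", "AncestrySpec", function(x) x@variants)

setMethod("sampleIds", "HaplotypePanel", function(x) x@sampleIds)
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)
setMethod("sampleIds", "CaseControlStudy", function(x) x@genotypes@sampleIds)

setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)
setMethod("haplotypes", "HaplotypeFrequencyTable", function(x) x@haplotypes)
setMethod("haplotypes", "AncestrySpec", function(x) x@haplotypes)

setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)
setMethod("genotypes", "CaseControlStudy", function(x) x@genotypes@genotypes)

setMethod("phenotypes", "CaseControlStudy", function(x) x@phenotypes)

setMethod("ancestry", "HaplotypePanel", function(x) x@ancestry)
setMethod("ancestry", "EquivalenceClassSet", function(x) x@ancestry)
setMethod("ancestry", "CaseControlStudy", function(x) x@cohort)
setMethod("ancestry", "AncestrySpec", function(x) x@ancestry)

setMethod("inflationFactor", "CaseControlStudy", function(x) x@lambda)

setMethod("ldR2", "LDMatrix", function(x) x@r2)
setMethod("ldDprime", "LDMatrix", function(x) x@dprime)

setMethod("classMembers", "EquivalenceClassSet", function(x) x@classes)
setMethod("classTags", "EquivalenceClassSet", function(x) x@tags)

setMethod("hapFrequencies", "HaplotypeFrequencyTable", function(x) {
  out <- x@freq
  rownames(out) <- x@haplotypes
  out
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel [%s]: %d haplotypes (%d samples) x %d SNPs\n",
              object@ancestry, nrow(object@haplotypes),
              length(object@sampleIds), nrow(object@variants)))
  cat("  SNPs:", paste(utils::head(object@variants$id, 8), collapse = ", "),
      if (nrow(object@variants) > 8) "..." else "", "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs (%.1f%% missing)\n",
              nrow(object@genotypes), ncol(object@genotypes),
              100 * mean(is.na(object@genotypes))))
})

setMethod("show", "CaseControlStudy", function(object) {
  st <- table(object@phenotypes$status)
  cat(sprintf("CaseControlStudy [%s]: %d cases / %d controls, %d SNPs, lambda = %.3g\n",
              object@cohort, sum(object@phenotypes$status == "case"),
              sum(object@phenotypes$status == "control"),
              nrow(object@genotypes@variants), object@lambda))
  invisible(st)
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix over %d SNPs (r2 and D')\n", length(object@snpIds)))
})

setMethod("show", "EquivalenceClassSet", function(object) {
  cat(sprintf("EquivalenceClassSet [%s]: %d classes at r2 >= %.3g\n",
              object@ancestry, length(object@classes), object@r2Threshold))
  for (i in seq_along(object@classes))
    cat(sprintf("  %s: {%s} tag=%s\n", names(object@classes)[i] %||% i,
                paste(object@classes[[i]], collapse = ", "), object@tags[i]))
})

setMethod("show", "HaplotypeFrequencyTable", function(object) {
  cat(sprintf("HaplotypeFrequencyTable: %d haplotypes over %d SNPs, groups: %s\n",
              length(object@haplotypes), length(object@snps),
              paste(colnames(object@freq), collapse = ", ")))
  print(round(hapFrequencies(object), 4))
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult (%s, k = %d): OR = %.3f (%.3f, %.3f), P = %.3g\n",
              object@method, object@k, object@or, object@ciLow, object@ciHigh,
              object@p))
  cat(sprintf("  heterogeneity: Q/LR = %.3f, P_het = %.3g, I2 = %.1f%%\n",
              object@q, object@pHet, object@i2))
})

setMethod("show", "AncestrySpec", function(object) {
  cat(sprintf("AncestrySpec [%s]: %d haplotypes over %d SNPs; causal %s, OR = %.3g\n",
              object@ancestry, length(object@haplotypes), nrow(object@variants),
              object@causalSnp, object@causalOR))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
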