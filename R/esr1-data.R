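#' @include AllClasses.R
NULL

## Published reference values for the C6orf97/ESR1 (6q25.1) breast cancer
## risk locus, used to seed the simulator and the summary-level
## meta-analysis.  SNP order and at-risk orientation follow the published
## haplotype convention: rs12662670_G, rs6929137_A, rs3734805_C,
## rs9383589_G, rs12665607_A, rs2046210_T, rs9397435_G.  Positions are
## nominal (ordering only).

#' SNP panel of the C6orf97/ESR1 risk locus
#'
#' The seven genotyped SNPs spanning the locus's common haplotypes, with
#' allele pairs and at-risk orientation.
#'
#' @return data.frame with columns id, chrom, pos, a1, a2, risk.
#' @export
esr1Snps <- function() {
  data.frame(
    id = c("rs12662670", "rs6929137", "rs3734805", "rs9383589",
           "rs12665607", "rs2046210", "rs9397435"),
    chrom = "6",
    pos = as.integer(c(151917000, 151928000, 151949000, 151955000,
                       151974000, 151990000, 151997000)),
    a1 = c("G", "A", "A", "A", "A", "C", "A"),
    a2 = c("T", "G", "C", "G", "T", "T", "G"),
    risk = c("G", "A", "C", "G", "A", "T", "G"),
    stringsAsFactors = FALSE
  )
}

#' Published per-ancestry haplotype frequencies at the locus
#'
#' Control (and case) frequencies of the ten common 7-SNP haplotypes
#' (IDs A-J) in the Nigerian, Icelandic, U.S. European-ancestry and
#' Taiwanese population samples.
#'
#' @return data.frame with columns haplotype, id and one case/control
#'   frequency column pair per population.
#' @export
esr1HaplotypeFrequencies <- function() {
  data.frame(
    haplotype = c("TAAATTA", "TGAATTA", "TGAATCA", "TAAATCA", "TGAATTG",
                  "TAAATTG", "TACATTG", "GACGATG", "TACGATG", "GGAATCA"),
    id = LETTERS[1:10],
    nigeria_case    = c(0.346, 0.263, 0.164, 0.120, 0.028, 0.023, 0.011, 0.015, 0.000, 0.000),
    nigeria_control = c(0.368, 0.276, 0.158, 0.127, 0.015, 0.014, 0.013, 0.009, 0.000, 0.000),
    iceland_case    = c(0.225, 0.018, 0.673, 0.004, 0.000, 0.000, 0.000, 0.065, 0.007, 0.006),
    iceland_control = c(0.232, 0.022, 0.679, 0.000, 0.000, 0.000, 0.000, 0.053, 0.004, 0.004),
    usa_case        = c(0.239, 0.026, 0.635, 0.006, 0.002, 0.000, 0.000, 0.067, 0.009, 0.004),
    usa_control     = c(0.233, 0.025, 0.646, 0.007, 0.000, 0.000, 0.000, 0.059, 0.008, 0.007),
    taiwan_case     = c(0.012, 0.024, 0.550, 0.001, 0.001, 0.000, 0.000, 0.304, 0.049, 0.023),
    taiwan_control  = c(0.018, 0.024, 0.590, 0.005, 0.000, 0.001, 0.000, 0.260, 0.036, 0.023),
    stringsAsFactors = FALSE
  )
}

#' Published per-ancestry association summaries at the locus
#'
#' Odds ratios, 95\% CIs, P values and control allele frequencies for
#' the seven SNPs typed in all three ancestral groups (Asian, European,
#' African & African American), supporting summary-level meta-analysis.
#'
#' @return data.frame with columns snp, allele, ancestry, freq_controls,
#'   OR, CI_low, CI_high, P.
#' @export
esr1AncestrySummaries <- function() {
  rows <- rbind(
    c("rs9397435", "G", "Asian", 0.326, 1.23, 1.09, 1.40, 8.0e-4),
    c("rs9397435", "G", "European", 0.063, 1.15, 1.06, 1.25, 1.2e-3),
    c("rs9397435", "G", "African", 0.063, 1.35, 1.06, 1.71, 0.014),
    c("rs12662670", "G", "Asian", 0.343, 1.22, 1.07, 1.39, 2.5e-3),
    c("rs12662670", "G", "European", 0.071, 1.12, 1.03, 1.21, 6.4e-3),
    c("rs12662670", "G", "African", 0.027, 1.54, 1.06, 2.23, 0.022),
    c("rs12665607", "A", "Asian", 0.323, 1.24, 1.10, 1.40, 6.2e-4),
    c("rs12665607", "A", "European", 0.072, 1.14, 1.05, 1.23, 1.1e-3),
    c("rs12665607", "A", "African", 0.010, 1.94, 1.14, 3.30, 0.015),
    c("rs9383589", "G", "Asian", 0.323, 1.20, 1.06, 1.36, 4.2e-3),
    c("rs9383589", "G", "European", 0.070, 1.15, 1.06, 1.25, 6.2e-4),
    c("rs9383589", "G", "African", 0.016, 1.61, 1.05, 2.48, 0.029),
    c("rs3734805", "C", "Asian", 0.324, 1.22, 1.07, 1.37, 2.0e-3),
    c("rs3734805", "C", "European", 0.072, 1.13, 1.05, 1.23, 1.8e-3),
    c("rs3734805", "C", "African", 0.028, 1.27, 0.91, 1.78, 0.16),
    c("rs6929137", "A", "Asian", 0.348, 1.15, 1.02, 1.30, 0.025),
    c("rs6929137", "A", "European", 0.316, 1.04, 0.99, 1.09, 0.082),
    c("rs6929137", "A", "African", 0.538, 1.02, 0.89, 1.16, 0.81),
    c("rs2046210", "T", "Asian", 0.363, 1.24, 1.10, 1.40, 4.3e-4),
    c("rs2046210", "T", "European", 0.337, 1.04, 0.99, 1.08, 0.099),
    c("rs2046210", "T", "African", 0.716, 0.98, 0.86, 1.11, 0.77)
  )
  out <- data.frame(snp = rows[, 1], allele = rows[, 2], ancestry = rows[, 3],
                    stringsAsFactors = FALSE)
  out$freq_controls <- as.numeric(rows[, 4])
  out$OR <- as.numeric(rows[, 5])
  out$CI_low <- as.numeric(rows[, 6])
  out$CI_high <- as.numeric(rows[, 7])
  out$P <- as.numeric(rows[, 8])
  out
}

#' Published sample sizes per ancestral group
#'
#' @return data.frame with columns ancestry, cases, controls.
#' @export
esr1SampleSizes <- function() {
  data.frame(
    ancestry = c("Asian", "European", "African"),
    cases = c(1126L, 7899L, 1151L),
    controls = c(1118L, 11234L, 934L),
    stringsAsFactors = FALSE
  )
}

#' Construct an AncestrySpec
#'
#' @param ancestry label.
#' @param variants SNP panel data.frame (id, chrom, pos, a1, a2, risk).
#' @param haplotypes allele strings over the SNP order.
#' @param freq population frequencies; any shortfall from 1 is assigned
#'   to \code{catchAll} (which must be absent from \code{haplotypes}).
#' @param causalSnp id of the causal SNP.
#' @param causalOR multiplicative allelic odds ratio at the causal SNP.
#' @param catchAll haplotype string absorbing the remaining mass.
#' @return An \linkS4class{AncestrySpec}.
#' @export
ancestrySpec <- function(ancestry, variants, haplotypes, freq,
                         causalSnp, causalOR,
                         catchAll = NULL) {
  keep <- freq > 0
  haplotypes <- haplotypes[keep]; freq <- freq[keep]
  rem <- 1 - sum(freq)
  if (rem > 1e-9) {
    if (is.null(catchAll)) stop("frequencies sum below 1; supply catchAll")
    if (catchAll %in% haplotypes) stop("catch-all collides with a listed haplotype")
    haplotypes <- c(haplotypes, catchAll)
    freq <- c(freq, rem)
  }
  new("AncestrySpec", ancestry = ancestry, variants = variants,
      haplotypes = haplotypes, freq = freq / sum(freq),
      causalSnp = causalSnp, causalOR = causalOR)
}

#' Built-in four-ancestry haplotype pools for the locus
#'
#' One \linkS4class{AncestrySpec} per population sample (nigeria,
#' iceland, usa, taiwan), seeded from the published control haplotype
#' frequencies with the causal allele at rs9397435[G].  Residual mass
#' (0.6--4.3\% per pool) goes to a catch-all haplotype that carries no
#' risk allele at the causal SNP.
#'
#' @param causalOR common multiplicative OR at rs9397435 (default 1.23).
#' @return Named list of \linkS4class{AncestrySpec} objects.
#' @export
esr1Pools <- function(causalOR = 1.23) {
  snps <- esr1Snps()
  hf <- esr1HaplotypeFrequencies()
  pools <- c(nigeria = "nigeria_control", iceland = "iceland_control",
             usa = "usa_control", taiwan = "taiwan_control")
  out <- lapply(names(pools), function(p)
    ancestrySpec(p, snps, hf$haplotype, hf[[pools[[p]]]],
                 causalSnp = "rs9397435", causalOR = causalOR,
                 catchAll = "TGCATCA"))
  names(out) <- names(pools)
  out
}
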