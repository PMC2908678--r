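#' @include AllClasses.R utils.R esr1-data.R
NULL

.specBinary <- function(spec) {
  v <- spec@variants
  v$counted <- ifelse(!is.na(v$risk), v$risk, pmin(v$a1, v$a2))
  m <- nrow(v)
  bins <- matrix(0L, length(spec@haplotypes), m)
  for (j in seq_len(m))
    bins[, j] <- as.integer(substr(spec@haplotypes, j, j) == v$counted[j])
  list(variants = v, bins = bins)
}

#' Simulate a retrospective case-control study from a haplotype pool
#'
#' Controls draw two haplotypes independently from the population
#' frequencies (random pairing, HWE).  Cases are sampled retrospectively
#' under the multiplicative model: a diplotype (h1, h2) is drawn with
#' probability proportional to f_h1 f_h2 theta^(risk-allele count at the
#' causal SNP), normalized over all diplotypes.  Genotypes are returned
#' unphased; the true phased haplotypes ride along in a \code{truth}
#' side channel for test oracles only.  One master seed drives named
#' sub-streams (controls, cases, missingness), so adding a stage never
#' perturbs another stage's draws.
#'
#' @param spec an \linkS4class{AncestrySpec}.
#' @param nCases,nControls sample counts.
#' @param seed master integer seed.
#' @param missingness per-genotype missing probability in [0,1).
#' @param lambda inflation factor attached to the study (default 1).
#' @return list with \code{study} (a \linkS4class{CaseControlStudy}) and
#'   \code{truth} (data.frame of the sampled haplotype-string pairs).
#' @export
simulateStudy <- function(spec, nCases, nControls, seed,
                          missingness = 0, lambda = 1.0) {
  if (spec@causalOR <= 0) stop("causal OR must be positive")
  sb <- .specBinary(spec)
  causal <- match(spec@causalSnp, sb$variants$id)
  H <- length(spec@freq)
  f <- spec@freq
  ctrl_idx <- .withSeed(.subSeed(seed, paste0("controls:", spec@ancestry)), {
    matrix(sample.int(H, 2 * nControls, replace = TRUE, prob = f),
           ncol = 2)
  })
  ## retrospective case sampling over ordered diplotypes
  risk_count <- outer(sb$bins[, causal], sb$bins[, causal], `+`)
  pmat <- outer(f, f) * spec@causalOR^risk_count
  pvec <- as.vector(pmat / sum(pmat))
  case_cell <- .withSeed(.subSeed(seed, paste0("cases:", spec@ancestry)), {
    sample.int(H * H, nCases, replace = TRUE, prob = pvec)
  })
  case_idx <- cbind((case_cell - 1L) %% H + 1L, (case_cell - 1L) %/% H + 1L)

  all_idx <- rbind(case_idx, ctrl_idx)
  dosage <- sb$bins[all_idx[, 1], , drop = FALSE] +
    sb$bins[all_idx[, 2], , drop = FALSE]
  ids <- c(sprintf("case%04d", seq_len(nCases)),
           sprintf("ctrl%04d", seq_len(nControls)))
  status <- c(rep("case", nCases), rep("control", nControls))
  gm <- GenotypeMatrix(sb$variants, dosage, ids)
  if (missingness > 0)
    gm <- injectMissingness(gm, missingness,
                            .subSeed(seed, paste0("missing:", spec@ancestry)))
  ph <- data.frame(sampleId = ids, status = status,
                   cohort = spec@ancestry, stringsAsFactors = FALSE)
  study <- CaseControlStudy(gm, ph, cohort = spec@ancestry, lambda = lambda)
  truth <- data.frame(sampleId = ids, status = status,
                      hap1 = spec@haplotypes[all_idx[, 1]],
                      hap2 = spec@haplotypes[all_idx[, 2]],
                      stringsAsFactors = FALSE)
  list(study = study, truth = truth)
}

#' Simulate parent-offspring trios from a haplotype pool
#'
#' Parents are random diplotypes from the pool; each child receives one
#' uniformly chosen haplotype from each parent.  All genotypes are
#' returned unphased, with the true phases in the side channel.
#'
#' @param spec an \linkS4class{AncestrySpec}.
#' @param nTrios number of trios.
#' @param seed master integer seed.
#' @return list with \code{genotypes} (\linkS4class{GenotypeMatrix} over
#'   fathers, mothers and children), \code{pedigree} (child, father,
#'   mother) and \code{truth}.
#' @export
simulateTrios <- function(spec, nTrios, seed) {
  sb <- .specBinary(spec)
  H <- length(spec@freq)
  draws <- .withSeed(.subSeed(seed, paste0("trios:", spec@ancestry)), {
    par_idx <- matrix(sample.int(H, 4 * nTrios, replace = TRUE,
                                 prob = spec@freq), ncol = 4)
    trans <- matrix(sample.int(2, 2 * nTrios, replace = TRUE), ncol = 2)
    list(par = par_idx, trans = trans)
  })
  par_idx <- draws$par  # columns: father h1, father h2, mother h1, mother h2
  childF <- par_idx[cbind(seq_len(nTrios), draws$trans[, 1])]
  childM <- par_idx[cbind(seq_len(nTrios), 2L + draws$trans[, 2])]
  fid <- sprintf("fa%03d", seq_len(nTrios))
  mid <- sprintf("mo%03d", seq_len(nTrios))
  cid <- sprintf("ch%03d", seq_len(nTrios))
  dose <- function(i1, i2) sb$bins[i1, , drop = FALSE] + sb$bins[i2, , drop = FALSE]
  gm <- GenotypeMatrix(sb$variants,
                       rbind(dose(par_idx[, 1], par_idx[, 2]),
                             dose(par_idx[, 3], par_idx[, 4]),
                             dose(childF, childM)),
                       c(fid, mid, cid))
  ped <- data.frame(child = cid, father = fid, mother = mid,
                    stringsAsFactors = FALSE)
  truth <- data.frame(
    sampleId = c(fid, mid, cid),
    hap1 = spec@haplotypes[c(par_idx[, 1], par_idx[, 3], childF)],
    hap2 = spec@haplotypes[c(par_idx[, 2], par_idx[, 4], childM)],
    stringsAsFactors = FALSE)
  list(genotypes = gm, pedigree = ped, truth = truth)
}

#' Set genotypes missing at random
#'
#' Each genotype is independently set to missing with probability
#' \code{rate}; deterministic under the seed.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param rate missing probability in [0,1).
#' @param seed integer seed.
#' @return The genotype matrix with NAs injected.
#' @export
injectMissingness <- function(gm, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0,1)")
  if (rate == 0) return(gm)
  g <- gm@genotypes
  drop <- .withSeed(seed, {
    matrix(stats::runif(length(g)) < rate, nrow(g), ncol(g))
  })
  g[drop] <- NA_integer_
  GenotypeMatrix(gm@variants, g, gm@sampleIds)
}

#' Phased haplotype panel drawn from a pool specification
#'
#' Convenience generator for LD screening tests: draws 2n chromosomes
#' from the pool frequencies and wraps them as a
#' \linkS4class{HaplotypePanel}.
#'
#' @param spec an \linkS4class{AncestrySpec}.
#' @param nSamples diploid sample count.
#' @param seed integer seed.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
simulatePanel <- function(spec, nSamples, seed) {
  sb <- .specBinary(spec)
  idx <- .withSeed(.subSeed(seed, paste0("panel:", spec@ancestry)), {
    sample.int(length(spec@freq), 2 * nSamples, replace = TRUE,
               prob = spec@freq)
  })
  v <- sb$variants
  other <- ifelse(v$counted == v$a1, v$a2, v$a1)
  hap <- matrix(NA_character_, 2 * nSamples, nrow(v))
  for (j in seq_len(nrow(v)))
    hap[, j] <- ifelse(sb$bins[idx, j] == 1L, v$counted[j], other[j])
  HaplotypePanel(v[setdiff(names(v), "counted")], hap,
                 ancestry = spec@ancestry)
}
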