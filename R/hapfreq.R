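#' @include AllClasses.R utils.R
NULL

## --- internal haplotype bookkeeping --------------------------------------
## Haplotypes are handled internally as binary vectors (1 = counted allele)
## and keyed by their "0101..." string.  Allele-letter strings are produced
## only at the container boundary.

.binKey <- function(b) paste(b, collapse = "")

.binToString <- function(bin, variants) {
  counted <- variants$counted
  other <- ifelse(counted == variants$a1, variants$a2, variants$a1)
  paste(ifelse(bin == 1L, counted, other), collapse = "")
}

.hapStringsToBinary <- function(strings, snps, counted, variants) {
  m <- length(snps)
  out <- matrix(0L, length(strings), m)
  for (j in seq_len(m)) out[, j] <- as.integer(substr(strings, j, j) == counted[j])
  out
}

## Per-site ordered allele-pair options for a dosage g (NA = missing).
.siteOptions <- function(g) {
  if (is.na(g)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  else if (g == 0L) list(c(0L, 0L))
  else if (g == 2L) list(c(1L, 1L))
  else list(c(0L, 1L), c(1L, 0L))
}

## All ordered haplotype pairs compatible with a dosage vector.
## Returns a list of (h1, h2) integer matrices (rows = configurations).
.orderedPairs <- function(g) {
  opts <- lapply(g, .siteOptions)
  grid <- do.call(expand.grid, c(lapply(opts, function(o) seq_along(o)),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  n <- nrow(grid); m <- length(g)
  h1 <- h2 <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    ch <- opts[[j]]
    pick <- grid[[j]]
    h1[, j] <- vapply(ch, `[`, 0L, 1L)[pick]
    h2[, j] <- vapply(ch, `[`, 0L, 2L)[pick]
  }
  list(h1 = h1, h2 = h2)
}

## Registry of haplotypes: environment mapping key -> index, plus a grow
## function; returns indices for a binary matrix of haplotypes.
.registryIndex <- function(reg, mat) {
  keys <- apply(mat, 1, .binKey)
  idx <- integer(length(keys))
  for (k in seq_along(keys)) {
    key <- keys[k]
    if (is.null(reg$map[[key]])) {
      reg$n <- reg$n + 1L
      reg$map[[key]] <- reg$n
      reg$haps[[reg$n]] <- mat[k, ]
    }
    idx[k] <- reg$map[[key]]
  }
  idx
}

## Unordered pair structure for one genotype pattern: unique (i, j) index
## pairs with i <= j and a het/hom multiplicity (2 or 1).
.pairStructure <- function(g, reg) {
  op <- .orderedPairs(g)
  i1 <- .registryIndex(reg, op$h1)
  i2 <- .registryIndex(reg, op$h2)
  a <- pmin(i1, i2); b <- pmax(i1, i2)
  key <- paste(a, b)
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  list(i = a, j = b, mult = ifelse(a == b, 1, 2))
}

## Trio configuration structure: ordered (transmitted, untransmitted)
## pairs for each parent, filtered on child compatibility.  Each ordered
## configuration carries prior weight 1/4 (transmission choice).
.trioStructure <- function(gF, gM, gC, reg) {
  opF <- .orderedPairs(gF)
  opM <- .orderedPairs(gM)
  nF <- nrow(opF$h1); nM <- nrow(opM$h1)
  keepF <- rep(seq_len(nF), times = nM)
  keepM <- rep(seq_len(nM), each = nF)
  ## child receives the first (transmitted) haplotype of each parent
  childDose <- opF$h1[keepF, , drop = FALSE] + opM$h1[keepM, , drop = FALSE]
  ok <- rep(TRUE, length(keepF))
  for (j in seq_along(gC)) {
    if (!is.na(gC[j])) ok <- ok & childDose[, j] == gC[j]
  }
  if (!any(ok)) return(NULL)
  keepF <- keepF[ok]; keepM <- keepM[ok]
  list(
    fi = .registryIndex(reg, opF$h1[keepF, , drop = FALSE]),
    fj = .registryIndex(reg, opF$h2[keepF, , drop = FALSE]),
    mi = .registryIndex(reg, opM$h1[keepM, , drop = FALSE]),
    mj = .registryIndex(reg, opM$h2[keepM, , drop = FALSE])
  )
}

## Core EM over one group of samples.  Returns freq vector (named by
## binary key), logLik, iterations.
.emCore <- function(dosages, trio_idx = NULL, tol = 1e-8, maxIter = 2000L,
                    debug = FALSE, perturb = 0) {
  n <- nrow(dosages)
  in_trio <- if (is.null(trio_idx)) rep(FALSE, n)
             else seq_len(n) %in% unlist(trio_idx)
  reg <- new.env(parent = emptyenv())
  reg$map <- new.env(parent = emptyenv(), hash = TRUE)
  reg$n <- 0L; reg$haps <- list()

  unrelated <- which(!in_trio)
  pat_key <- apply(dosages[unrelated, , drop = FALSE], 1, .binKey)
  upat <- !duplicated(pat_key)
  structures <- lapply(which(upat), function(r)
    .pairStructure(dosages[unrelated[r], ], reg))
  pat_count <- as.numeric(table(factor(pat_key,
                                       levels = pat_key[upat])))
  trios <- lapply(trio_idx, function(tr)
    .trioStructure(dosages[tr["father"], ], dosages[tr["mother"], ],
                   dosages[tr["child"], ], reg))
  bad <- vapply(trios, is.null, TRUE)
  if (any(bad)) {
    warning(sum(bad), " Mendelian-inconsistent trio(s) dropped")
    trios <- trios[!bad]
  }
  H <- reg$n
  if (H == 0L) stop("no compatible haplotypes; all genotypes missing?")
  f <- rep(1 / H, H)
  if (perturb > 0) {
    ## nudge off the symmetric double-heterozygote saddle
    f <- f + perturb * (seq_len(H) == 1L)
    f <- f / sum(f)
  }
  nChrom <- 2 * length(unrelated) + 4 * length(trios)
  ll_prev <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(H)
    ll <- 0
    for (s in seq_along(structures)) {
      st <- structures[[s]]
      w <- f[st$i] * f[st$j] * st$mult
      tot <- sum(w)
      if (tot <= 0) { w <- st$mult / sum(st$mult); tot <- NA_real_ }
      else w <- w / tot
      cnt <- pat_count[s]
      ll <- ll + cnt * log(if (is.na(tot)) .Machine$double.xmin else tot)
      wc <- w * cnt
      for (k in seq_along(st$i)) {
        counts[st$i[k]] <- counts[st$i[k]] + wc[k]
        counts[st$j[k]] <- counts[st$j[k]] + wc[k]
      }
    }
    for (tr in trios) {
      w <- 0.25 * f[tr$fi] * f[tr$fj] * f[tr$mi] * f[tr$mj]
      tot <- sum(w)
      if (tot <= 0) { w <- rep(1 / length(w), length(w)); tot <- NA_real_ }
      else w <- w / tot
      ll <- ll + log(if (is.na(tot)) .Machine$double.xmin else tot)
      for (k in seq_along(tr$fi)) {
        counts[tr$fi[k]] <- counts[tr$fi[k]] + w[k]
        counts[tr$fj[k]] <- counts[tr$fj[k]] + w[k]
        counts[tr$mi[k]] <- counts[tr$mi[k]] + w[k]
        counts[tr$mj[k]] <- counts[tr$mj[k]] + w[k]
      }
    }
    if (debug && ll < ll_prev - 1e-8)
      stop("EM log-likelihood decreased: ", ll_prev, " -> ", ll)
    f_new <- counts / sum(counts)
    delta <- max(abs(f_new - f))
    f <- f_new
    ll_prev <- ll
    if (delta < tol || iter >= maxIter) break
  }
  keys <- vapply(reg$haps, .binKey, "")
  list(freq = stats::setNames(f, keys),
       bins = do.call(rbind, reg$haps),
       logLik = ll_prev, iterations = iter, nChrom = nChrom)
}

#' EM estimation of multilocus haplotype frequencies
#'
#' Standard EM on unphased genotypes, optionally sharpened by trio
#' constraints: the E-step assigns each unrelated individual posterior
#' weights over unordered compatible haplotype pairs, and each trio
#' posterior weights over family-consistent parental diplotype
#' configurations given the child (children contribute phase information
#' only, not extra chromosomes); the M-step re-estimates frequencies from
#' expected counts.  Initialization is deterministic uniform over
#' observed-compatible haplotypes; missing genotypes are handled by
#' summing over compatible alleles.  Convergence is declared when the
#' largest absolute frequency change drops below \code{tol}.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} (at most 12 SNPs).
#' @param trios optional pedigree data.frame (child, father, mother ids).
#' @param groups optional character/factor (aligned with samples)
#'   partitioning individuals, e.g. case/control; frequencies are then
#'   estimated per group.  Trios are used within a group only when all
#'   three members fall in it.
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param maxIter iteration cap (default 2000).
#' @param prune drop haplotypes below this frequency in every group
#'   (default 1e-6); remaining frequencies are renormalized.
#' @param debug assert the log-likelihood is non-decreasing each iteration.
#' @param perturb optional nudge of the uniform initialization (e.g. 1e-3)
#'   to escape the symmetric double-heterozygote saddle point.
#' @return A \linkS4class{HaplotypeFrequencyTable}.
#' @export
emHaplotypeFrequencies <- function(genotypes, trios = NULL, groups = NULL,
                                   tol = 1e-8, maxIter = 2000L,
                                   prune = 1e-6, debug = FALSE,
                                   perturb = 0) {
  m <- nrow(genotypes@variants)
  if (m > 12L) stop("haplotype space too large: more than 12 SNPs")
  if (nrow(genotypes@genotypes) == 0L) stop("no individuals")
  ids <- genotypes@sampleIds
  trio_rows <- function(sample_subset) {
    if (is.null(trios)) return(NULL)
    keep <- trios$child %in% sample_subset &
      trios$father %in% sample_subset & trios$mother %in% sample_subset
    lapply(which(keep), function(r) c(
      child = match(trios$child[r], ids),
      father = match(trios$father[r], ids),
      mother = match(trios$mother[r], ids)))
  }
  if (is.null(groups)) {
    group_list <- list(pooled = seq_along(ids))
  } else {
    groups <- as.character(groups)
    group_list <- split(seq_along(ids), groups)
  }
  fits <- lapply(names(group_list), function(gname) {
    rows <- group_list[[gname]]
    sub <- genotypes@genotypes[rows, , drop = FALSE]
    t_idx <- trio_rows(ids[rows])
    if (!is.null(t_idx) && length(t_idx)) {
      ## re-map trio row indices into the subset
      t_idx <- lapply(t_idx, function(tr) {
        out <- match(tr, rows); names(out) <- names(tr); out
      })
    } else t_idx <- NULL
    .emCore(sub, t_idx, tol = tol, maxIter = as.integer(maxIter),
            debug = debug, perturb = perturb)
  })
  names(fits) <- names(group_list)
  all_keys <- unique(unlist(lapply(fits, function(f) names(f$freq))))
  freq <- matrix(0, length(all_keys), length(fits),
                 dimnames = list(all_keys, names(fits)))
  for (g in names(fits)) freq[names(fits[[g]]$freq), g] <- fits[[g]]$freq
  keep <- apply(freq, 1, function(r) any(r >= prune))
  freq <- freq[keep, , drop = FALSE]
  freq <- sweep(freq, 2, colSums(freq), "/")
  ## canonical row order so output is invariant to sample order
  freq <- freq[order(rownames(freq)), , drop = FALSE]
  bins <- t(vapply(rownames(freq),
                   function(k) as.integer(strsplit(k, "")[[1]]),
                   integer(m)))
  strings <- apply(bins, 1, .binToString, variants = genotypes@variants)
  dimnames(freq) <- list(NULL, names(fits))
  new("HaplotypeFrequencyTable",
      snps = genotypes@variants$id,
      counted = genotypes@variants$counted,
      haplotypes = strings,
      freq = freq,
      logLik = vapply(fits, `[[`, 0, "logLik"),
      iterations = vapply(fits, function(f) as.integer(f$iterations), 0L),
      nChrom = vapply(fits, `[[`, 0, "nChrom"))
}

## Posterior over unordered compatible diplotypes for one dosage vector,
## given a haplotype set (binary matrix) and its frequencies.  Returns
## NULL when nothing in the set is compatible.
.diplotypePosterior <- function(g, haps_bin, freq) {
  op <- .orderedPairs(g)
  keys <- apply(haps_bin, 1, .binKey)
  k1 <- match(apply(op$h1, 1, .binKey), keys)
  k2 <- match(apply(op$h2, 1, .binKey), keys)
  ok <- !is.na(k1) & !is.na(k2)
  if (!any(ok)) return(NULL)
  a <- pmin(k1[ok], k2[ok]); b <- pmax(k1[ok], k2[ok])
  key <- paste(a, b)
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  w <- freq[a] * freq[b] * ifelse(a == b, 1, 2)
  if (sum(w) <= 0) {
    warning("no compatible pair with positive frequency; uniform posterior")
    w <- rep(1, length(a))
  }
  list(pairs = cbind(a, b), w = w / sum(w))
}

#' Phase posteriors for one sample
#'
#' Posterior over the unordered haplotype pairs compatible with a
#' sample's unphased genotype, proportional to f_h1 f_h2 (2 - [h1 == h2]).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} covering the SNPs of
#'   \code{frequencies}.
#' @param frequencies a \linkS4class{HaplotypeFrequencyTable} (the first
#'   frequency column is used).
#' @param sampleId the sample to phase.
#' @return data.frame with columns hap1, hap2 (allele strings) and
#'   weight; weights sum to 1.
#' @export
phasePosteriors <- function(genotypes, frequencies, sampleId) {
  s <- match(sampleId, genotypes@sampleIds)
  if (is.na(s)) stop("sample not present: ", sampleId)
  idx <- match(frequencies@snps, genotypes@variants$id)
  if (anyNA(idx)) stop("frequency table covers SNPs absent from genotypes")
  g <- genotypes@genotypes[s, idx]
  haps_bin <- .hapStringsToBinary(frequencies@haplotypes, frequencies@snps,
                                  frequencies@counted,
                                  genotypes@variants[idx, , drop = FALSE])
  post <- .diplotypePosterior(g, haps_bin, frequencies@freq[, 1])
  if (is.null(post)) stop("no compatible diplotype for sample ", sampleId)
  data.frame(
    hap1 = frequencies@haplotypes[post$pairs[, 1]],
    hap2 = frequencies@haplotypes[post$pairs[, 2]],
    weight = post$w, stringsAsFactors = FALSE
  )
}

#' Haplotype association: one haplotype against all others
#'
#' Estimates the target haplotype's frequency separately in cases and
#' controls by EM, then treats the haplotype-vs-rest contrast as an
#' allelic 2x2 problem on expected chromosome counts: OR from the odds of
#' carrying the target, SE on ln OR from expected counts (0.5 correction
#' when any expected count falls below 0.5), and P from the 1-df
#' likelihood-ratio G statistic comparing a common target frequency to
#' group-specific ones.
#'
#' @param study a \linkS4class{CaseControlStudy}.
#' @param snps ordered SNP ids spanning the haplotype.
#' @param targetHaplotype allele string over \code{snps}.
#' @param trios optional pedigree passed to the EM.
#' @return One-row data.frame: haplotype, freq_cases, freq_controls, OR,
#'   CI_low, CI_high, P.
#' @export
haplotypeAssociation <- function(study, snps, targetHaplotype, trios = NULL) {
  gm <- study@genotypes
  idx <- match(snps, gm@variants$id)
  if (anyNA(idx)) stop("SNP(s) not typed in study")
  sub <- .subsetGenotypes(gm, idx)
  ft <- emHaplotypeFrequencies(sub, trios = trios,
                               groups = study@phenotypes$status)
  hit <- match(targetHaplotype, ft@haplotypes)
  fc <- if (!is.na(hit) && "case" %in% colnames(ft@freq)) ft@freq[hit, "case"] else 0
  f0 <- if (!is.na(hit) && "control" %in% colnames(ft@freq)) ft@freq[hit, "control"] else 0
  if (fc == 0 && f0 == 0)
    stop("target haplotype absent from both groups: ", targetHaplotype)
  n_case <- ft@nChrom[["case"]]
  n_ctrl <- ft@nChrom[["control"]]
  tab <- rbind(case = c(n_case * fc, n_case * (1 - fc)),
               control = c(n_ctrl * f0, n_ctrl * (1 - f0)))
  g <- .gStat2x2(tab)
  p <- stats::pchisq(g, df = 1, lower.tail = FALSE)
  t2 <- if (any(tab < 0.5)) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  data.frame(haplotype = targetHaplotype,
             freq_cases = fc, freq_controls = f0,
             OR = or, CI_low = ci[1], CI_high = ci[2], P = p,
             stringsAsFactors = FALSE)
}
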