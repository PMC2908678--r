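#' @include AllClasses.R
NULL

#' Pairwise linkage disequilibrium on a phased panel
#'
#' Computes r-squared and D-prime for every SNP pair from phased
#' haplotypes, with pairwise deletion of chromosomes missing an allele at
#' either SNP.  For alleles A and B with haplotype frequency p_AB,
#' D = p_AB - p_A p_B, r2 = D^2 / (p_A(1-p_A) p_B(1-p_B)) and
#' D' = |D| / D_max where D_max is min(p_A(1-p_B), (1-p_A)p_B) for D > 0
#' and min(p_A p_B, (1-p_A)(1-p_B)) for D < 0.  Pairs involving a
#' monomorphic SNP are undefined and flagged NA.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param snps SNP ids to include (default: all panel SNPs).
#' @return An \linkS4class{LDMatrix}.
#' @export
pairwiseLD <- function(panel, snps = NULL) {
  v <- panel@variants
  if (is.null(snps)) snps <- v$id
  miss <- setdiff(snps, v$id)
  if (length(miss)) stop("SNP(s) absent from panel: ", paste(miss, collapse = ", "))
  idx <- match(snps, v$id)
  h <- panel@haplotypes[, idx, drop = FALSE]
  ## indicator of the a2 allele; which allele is coded 1 does not matter
  x <- matrix(NA_real_, nrow(h), length(idx))
  for (j in seq_along(idx)) x[, j] <- as.numeric(h[, j] == v$a2[idx[j]])
  k <- length(snps)
  r2 <- dp <- matrix(NA_real_, k, k)
  nU <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      n <- sum(ok)
      nU[i, j] <- nU[j, i] <- n
      if (n == 0L) next
      pa <- mean(x[ok, i]); pb <- mean(x[ok, j])
      if (i == j) {
        if (pa > 0 && pa < 1) { r2[i, i] <- 1; dp[i, i] <- 1 }
        next
      }
      if (pa %in% c(0, 1) || pb %in% c(0, 1)) next  # monomorphic: undefined
      pab <- mean(x[ok, i] * x[ok, j])
      D <- pab - pa * pb
      r2[i, j] <- r2[j, i] <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
      dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
              else        min(pa * pb, (1 - pa) * (1 - pb))
      dp[i, j] <- dp[j, i] <- if (dmax == 0) NA_real_ else abs(D) / dmax
    }
  }
  r2 <- pmin(pmax(r2, 0), 1); dp <- pmin(pmax(dp, 0), 1)
  new("LDMatrix", snpIds = snps, r2 = r2, dprime = dp, nUsed = nU)
}

#' Select SNPs correlated with an index SNP
#'
#' Returns all SNPs (the index included) whose r2 with the index meets
#' the threshold, ordered by genomic position when positions are known.
#'
#' @param ld an \linkS4class{LDMatrix}.
#' @param indexSnp id of the index SNP.
#' @param threshold inclusive r2 cutoff (default 0.65).
#' @param positions optional named numeric vector of SNP positions used
#'   for ordering; default keeps matrix order.
#' @return Character vector of selected SNP ids.
#' @export
selectCorrelated <- function(ld, indexSnp, threshold = 0.65, positions = NULL) {
  i <- match(indexSnp, ld@snpIds)
  if (is.na(i)) stop("index SNP not in LD matrix: ", indexSnp)
  if (is.na(ld@r2[i, i])) stop("index SNP is monomorphic; screening undefined")
  r <- ld@r2[, i]
  undef <- is.na(r) & seq_along(r) != i
  if (any(undef))
    warning("SNP(s) with undefined LD excluded from screening: ",
            paste(ld@snpIds[undef], collapse = ", "))
  sel <- ld@snpIds[!is.na(r) & r >= threshold]
  if (!is.null(positions)) sel <- sel[order(positions[sel])]
  sel
}

#' Partition SNPs into r-squared equivalence classes
#'
#' Average-linkage agglomerative clustering on distance 1 - r2; classes
#' are the branches obtained by cutting the tree at height
#' 1 - \code{classR2}.  Undefined r2 entries are treated as distance 1.
#'
#' @param ld an \linkS4class{LDMatrix}.
#' @param snps ids to cluster (default all in \code{ld}).
#' @param classR2 within-class r2 threshold (default 0.8).
#' @param ancestry label stored on the result.
#' @return An \linkS4class{EquivalenceClassSet} with per-class membership,
#'   provisional tags (first member by position order) and merge heights.
#' @export
clusterClasses <- function(ld, snps = NULL, classR2 = 0.8,
                           ancestry = "unknown") {
  if (is.null(snps)) snps <- ld@snpIds
  idx <- match(snps, ld@snpIds)
  if (anyNA(idx)) stop("SNP(s) absent from LD matrix")
  if (classR2 <= 0 || classR2 > 1) stop("classR2 must lie in (0,1]")
  r2 <- ld@r2[idx, idx, drop = FALSE]
  if (anyNA(r2)) {
    message("undefined r2 entries treated as distance 1")
    r2[is.na(r2)] <- 0
  }
  dimnames(r2) <- list(snps, snps)
  if (length(snps) == 1L) {
    cls <- stats::setNames(list(snps), "class1")
    return(new("EquivalenceClassSet", classes = cls, tags = snps,
               ancestry = ancestry, r2Threshold = classR2,
               mergeHeights = numeric(0), tree = NULL))
  }
  d <- stats::as.dist(1 - r2)
  tree <- stats::hclust(d, method = "average")
  memb <- stats::cutree(tree, h = 1 - classR2)
  cls <- split(names(memb), memb)
  names(cls) <- paste0("class", seq_along(cls))
  tags <- vapply(cls, `[`, "", 1L)
  new("EquivalenceClassSet", classes = cls, tags = unname(tags),
      ancestry = ancestry, r2Threshold = classR2,
      mergeHeights = tree$height, tree = tree)
}

#' Choose a tag SNP for each equivalence class
#'
#' Per class the tag is a preferred SNP when one is a member; otherwise
#' the member maximizing mean r2 to its classmates, ties broken by
#' smaller genomic position.
#'
#' @param classes an \linkS4class{EquivalenceClassSet}.
#' @param ld the \linkS4class{LDMatrix} the classes were built from.
#' @param preferred SNP ids preferred as tags (e.g. already-genotyped ones).
#' @param positions optional named position vector for tie-breaking;
#'   default uses matrix order.
#' @return The class set with tags replaced.
#' @export
chooseTags <- function(classes, ld, preferred = character(),
                       positions = NULL) {
  if (!length(classes@classes)) stop("empty class set")
  pos_of <- function(id) {
    if (!is.null(positions) && id %in% names(positions)) positions[[id]]
    else match(id, ld@snpIds)
  }
  tags <- vapply(classes@classes, function(members) {
    hit <- intersect(preferred, members)
    if (length(hit)) return(hit[1])
    if (length(members) == 1L) return(members)
    i <- match(members, ld@snpIds)
    sub <- ld@r2[i, i, drop = FALSE]
    meanr2 <- (rowSums(sub, na.rm = TRUE) - 1) / (length(members) - 1)
    best <- which(abs(meanr2 - max(meanr2)) < 1e-12)
    if (length(best) > 1L)
      best <- best[which.min(vapply(members[best], pos_of, 0))]
    members[best]
  }, "")
  methods::initialize(classes, tags = unname(tags))
}

#' Bonferroni threshold over equivalence classes
#'
#' The multiple-testing unit is the equivalence class, not the SNP:
#' within a class the signals are statistically interchangeable, so the
#' significance threshold is alpha divided by the number of classes.
#'
#' @param alpha family-wise error rate, in (0,1).
#' @param classes an \linkS4class{EquivalenceClassSet} or a class count.
#' @return alpha / number of classes.
#' @export
bonferroniThreshold <- function(alpha, classes) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  k <- if (is(classes, "EquivalenceClassSet")) length(classes@classes)
       else as.integer(classes)
  if (k < 1) stop("need at least one class")
  alpha / k
}

#' Export a class dendrogram as Newick text
#'
#' Merge heights (on the 1 - r2 scale) become branch lengths.
#'
#' @param classes an \linkS4class{EquivalenceClassSet} built by
#'   \code{\link{clusterClasses}}.
#' @return A single Newick string.
#' @export
classDendrogramNewick <- function(classes) {
  tree <- classes@tree
  if (is.null(tree)) {
    return(paste0("(", unlist(classes@classes)[1], ");"))
  }
  recurse <- function(node, parent_h) {
    if (node < 0) {
      lab <- tree$labels[-node]
      sprintf("%s:%.6g", lab, parent_h)
    } else {
      h <- tree$height[node]
      left <- recurse(tree$merge[node, 1], h)
      right <- recurse(tree$merge[node, 2], h)
      sprintf("(%s,%s):%.6g", left, right, parent_h - h)
    }
  }
  n <- length(tree$height)
  h <- tree$height[n]
  paste0("(", recurse(tree$merge[n, 1], h), ",",
         recurse(tree$merge[n, 2], h), ");")
}
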