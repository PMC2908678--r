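ld_variants <- function() {
  data.frame(id = c("s1", "s2"), chrom = "1", pos = c(10L, 20L),
             a1 = c("C", "A"), a2 = c("T", "G"), risk = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("r2 and D' recover hand-computed values", {
  # identical allele patterns: full LD
  rows <- list(c("T", "G"), c("T", "G"), c("C", "A"), c("C", "A"))
  ld <- pairwiseLD(panel_from_rows(rows, ld_variants()))
  expect_equal(ldR2(ld)[1, 2], 1)
  expect_equal(ldDprime(ld)[1, 2], 1)

  # 4x(T,G), 2x(C,G), 2x(C,A): D = 0.125, r2 = 1/3, D' = 1
  rows <- c(rep(list(c("T", "G")), 4), rep(list(c("C", "G")), 2),
            rep(list(c("C", "A")), 2))
  ld <- pairwiseLD(panel_from_rows(rows, ld_variants()))
  expect_equal(ldR2(ld)[1, 2], 1 / 3, tolerance = 1e-12)
  expect_equal(ldDprime(ld)[1, 2], 1, tolerance = 1e-12)

  # all four gametes equally frequent: independence
  rows <- list(c("T", "G"), c("T", "A"), c("C", "G"), c("C", "A"))
  ld <- pairwiseLD(panel_from_rows(rows, ld_variants()))
  expect_equal(ldR2(ld)[1, 2], 0, tolerance = 1e-12)
})

test_that("LD is symmetric and invariant to row permutation and allele relabeling", {
  set.seed(42)
  pools <- esr1Pools()
  panel <- simulatePanel(pools$usa, 60, seed = 9)
  ld <- pairwiseLD(panel)
  expect_equal(ldR2(ld), t(ldR2(ld)))
  perm <- sample(nrow(haplotypes(panel)))
  panel2 <- HaplotypePanel(variants(panel), haplotypes(panel)[perm, ],
                           ancestry = "usa")
  expect_equal(ldR2(pairwiseLD(panel2)), ldR2(ld))
  # relabel one SNP's alleles (swap a1/a2 and recode the column)
  v <- variants(panel)
  h <- haplotypes(panel)
  h[, 3] <- ifelse(h[, 3] == v$a1[3], v$a2[3], v$a1[3])
  panel3 <- HaplotypePanel(v, h, ancestry = "usa")
  expect_equal(ldR2(pairwiseLD(panel3)), ldR2(ld), tolerance = 1e-12)
})

test_that("index screening is inclusive at the threshold and matches a direct scan", {
  pools <- esr1Pools()
  panel <- simulatePanel(pools$taiwan, 90, seed = 3)
  ld <- pairwiseLD(panel)
  pos <- stats::setNames(variants(panel)$pos, variants(panel)$id)
  sel <- selectCorrelated(ld, "rs2046210", 0.65, pos)
  # brute-force oracle: direct pairwise r2 via the indicator-correlation route
  h <- haplotypes(panel)
  i0 <- match("rs2046210", variants(panel)$id)
  manual <- variants(panel)$id[vapply(seq_len(ncol(h)), function(j)
    r2_direct(h[, j], h[, i0]) >= 0.65 - 1e-12, TRUE)]
  expect_setequal(sel, manual)
  expect_true("rs2046210" %in% sel)
  expect_equal(sel, sel[order(pos[sel])])

  # exact-boundary inclusion on a constructed matrix
  r2 <- matrix(c(1, 0.65, 0.65, 1), 2, 2)
  ldx <- new("LDMatrix", snpIds = c("a", "b"), r2 = r2, dprime = r2,
             nUsed = matrix(10L, 2, 2))
  expect_setequal(selectCorrelated(ldx, "a", 0.65), c("a", "b"))
})

test_that("equivalence classes follow the average-linkage cut", {
  mk_ld <- function(r2, ids) {
    diag(r2) <- 1
    new("LDMatrix", snpIds = ids, r2 = r2, dprime = r2,
        nUsed = matrix(100L, nrow(r2), nrow(r2)))
  }
  ids5 <- paste0("v", 1:5)
  # all r2 = 1: one class; all r2 = 0: singletons
  cl <- clusterClasses(mk_ld(matrix(1, 5, 5), ids5))
  expect_length(classMembers(cl), 1L)
  cl <- clusterClasses(mk_ld(matrix(0, 5, 5), ids5))
  expect_length(classMembers(cl), 5L)
  # two blocks at 0.9 within / 0.1 between: two classes
  blk <- matrix(0.1, 5, 5)
  blk[1:3, 1:3] <- 0.9; blk[4:5, 4:5] <- 0.9
  cl <- clusterClasses(mk_ld(blk, ids5), classR2 = 0.8)
  expect_length(classMembers(cl), 2L)
  got <- lapply(classMembers(cl), sort)
  expect_setequal(got, list(c("v1", "v2", "v3"), c("v4", "v5")))
})

test_that("class cuts agree with a naive agglomeration oracle on small panels", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    r2 <- matrix(stats::runif(k * k), k, k)
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    ids <- paste0("m", seq_len(k))
    ld <- new("LDMatrix", snpIds = ids, r2 = r2, dprime = r2,
              nUsed = matrix(50L, k, k))
    cut <- stats::runif(1, 0.2, 0.95)
    got <- lapply(classMembers(clusterClasses(ld, classR2 = cut)),
                  function(s) sort(match(s, ids)))
    got <- got[order(vapply(got, `[`, 0, 1))]
    want <- naive_average_linkage_cut(1 - r2, 1 - cut)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("tag choice honors preference, mean-r2 and the position tie-break", {
  ids <- c("p1", "p2", "p3", "p4")
  r2 <- matrix(c(1, .9, .9, .2,
                 .9, 1, .95, .2,
                 .9, .95, 1, .2,
                 .2, .2, .2, 1), 4, 4)
  ld <- new("LDMatrix", snpIds = ids, r2 = r2, dprime = r2,
            nUsed = matrix(10L, 4, 4))
  cl <- clusterClasses(ld, classR2 = 0.8)
  # singleton class tags itself
  singles <- classMembers(cl)[lengths(classMembers(cl)) == 1]
  tagged <- chooseTags(cl, ld)
  expect_true(all(unlist(singles) %in% classTags(tagged)))
  # best mean r2 in {p1,p2,p3} is p2 or p3 (0.925) vs p1 (0.9); tie -> p2
  big <- which(lengths(classMembers(tagged)) == 3)
  expect_equal(classTags(tagged)[big], "p2")
  # preference overrides
  pref <- chooseTags(cl, ld, preferred = "p1")
  expect_equal(classTags(pref)[big], "p1")
})

test_that("class-count Bonferroni threshold matches the hand values", {
  expect_equal(round(bonferroniThreshold(0.05, 7), 3), 0.007)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 5), 0.01)
  expect_error(bonferroniThreshold(1.2, 5), "alpha")
})

test_that("dendrogram exports as parseable Newick with 1 - r2 heights", {
  blk <- matrix(0.1, 4, 4)
  blk[1:2, 1:2] <- 0.9; blk[3:4, 3:4] <- 0.9
  diag(blk) <- 1
  ld <- new("LDMatrix", snpIds = paste0("w", 1:4), r2 = blk, dprime = blk,
            nUsed = matrix(10L, 4, 4))
  cl <- clusterClasses(ld, classR2 = 0.8)
  nwk <- classDendrogramNewick(cl)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(paste0("w", 1:4), grepl, TRUE, x = nwk)))
})
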