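test_that("allele-count tables book-keep dosages, fractions and conservation", {
  st <- study_from_counts(30, 70, 20, 80)
  tab <- alleleCountTable(st, "snp1")
  expect_equal(unname(tab), rbind(c(30, 70), c(20, 80)))
  expect_equal(sum(tab), 2 * length(sampleIds(st)))

  # a missing sample with expected dosage 1.3 contributes (1.3, 0.7)
  g <- genotypes(st)
  g[1, 1] <- NA
  st2 <- CaseControlStudy(GenotypeMatrix(variants(st), g, sampleIds(st)),
                          phenotypes(st), cohort = "toy")
  tab2 <- alleleCountTable(st2, "snp1", imputed = c(ca001 = 1.3))
  expect_equal(unname(tab2["case", ]), c(30 - 2 + 1.3, 70 + 0.7))
  expect_equal(sum(tab2), 2 * length(sampleIds(st2)))
})

test_that("allelic association matches the closed-form 2x2 quantities", {
  st <- study_from_counts(30, 70, 20, 80)
  res <- allelicAssociation(st, "snp1")
  expect_equal(res$OR, 12 / 7, tolerance = 1e-12)
  expect_equal(res$freq_controls, 0.2)
  # independent G-statistic via loglin-free arithmetic
  tab <- attr(res, "table")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi2, 2 * sum(tab * log(tab / e)), tolerance = 1e-12)
  se <- sqrt(sum(1 / tab))
  expect_equal(res$CI_low, exp(log(12 / 7) - qnorm(.975) * se), tolerance = 1e-10)

  # identical case/control frequencies: null in every respect
  st0 <- study_from_counts(20, 80, 20, 80)
  res0 <- allelicAssociation(st0, "snp1")
  expect_equal(res0$OR, 1)
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$P, 1)
})

test_that("genomic control deflates the statistic and widens the interval", {
  expect_equal(gcCorrect(10, 1.08), 9.259259, tolerance = 1e-6)
  st1 <- study_from_counts(30, 70, 20, 80, lambda = 1.0)
  st8 <- study_from_counts(30, 70, 20, 80, lambda = 1.08)
  r1 <- allelicAssociation(st1, "snp1")
  r8 <- allelicAssociation(st8, "snp1")
  expect_equal(r8$chi2, r1$chi2 / 1.08, tolerance = 1e-12)
  expect_equal(log(r8$CI_high / r8$CI_low),
               sqrt(1.08) * log(r1$CI_high / r1$CI_low), tolerance = 1e-10)
  expect_gt(r8$P, r1$P)
  # lambda = 1 leaves corrected and uncorrected identical
  expect_equal(allelicAssociation(st1, "snp1", useLambda = FALSE), r1)
})

test_that("label and allele swaps behave as exact symmetries", {
  st <- study_from_counts(30, 70, 20, 80)
  res <- allelicAssociation(st, "snp1")
  # swap case/control labels
  ph <- phenotypes(st)
  ph$status <- ifelse(ph$status == "case", "control", "case")
  st_sw <- CaseControlStudy(st@genotypes, ph, cohort = "toy")
  res_sw <- allelicAssociation(st_sw, "snp1")
  expect_equal(res_sw$OR, 1 / res$OR, tolerance = 1e-12)
  expect_equal(res_sw$chi2, res$chi2, tolerance = 1e-12)
  expect_equal(res_sw$P, res$P, tolerance = 1e-12)
  # swap the counted allele
  v <- variants(st)
  v$counted <- "T"
  st_al <- CaseControlStudy(GenotypeMatrix(v, 2L - genotypes(st),
                                           sampleIds(st)),
                            phenotypes(st), cohort = "toy")
  res_al <- allelicAssociation(st_al, "snp1")
  expect_equal(res_al$OR, 1 / res$OR, tolerance = 1e-12)
  expect_equal(res_al$CI_low, 1 / res$CI_high, tolerance = 1e-10)
  expect_equal(res_al$P, res$P, tolerance = 1e-12)
})

test_that("genotype-model tests respect nesting and detect a recessive effect", {
  set.seed(101)
  n <- 4000
  g <- sample(0:2, n, replace = TRUE, prob = c(.49, .42, .09))
  # multiplicative truth: odds multiply per allele
  p <- plogis(-1 + 0.3 * g)
  y <- rbinom(n, 1, p)
  ids <- sprintf("x%04d", 1:n)
  v <- two_snp_variants()[1, ]
  st <- CaseControlStudy(
    GenotypeMatrix(v, matrix(as.integer(g), ncol = 1), ids),
    data.frame(sampleId = ids, status = ifelse(y == 1, "case", "control"),
               cohort = "sim"), cohort = "sim")
  res <- genotypeModelTest(st, "snp1")
  expect_false(any(res$skipped))
  expect_true(all(res$chi2 >= 0))     # full model always fits at least as well
  expect_gt(res$P[res$comparison == "multiplicative_vs_full"], 0.001)

  # homozygote-only effect: multiplicative rejected, recessive not
  p2 <- plogis(-1 + 1.2 * (g == 2))
  y2 <- rbinom(n, 1, p2)
  st2 <- CaseControlStudy(
    GenotypeMatrix(v, matrix(as.integer(g), ncol = 1), ids),
    data.frame(sampleId = ids, status = ifelse(y2 == 1, "case", "control"),
               cohort = "sim"), cohort = "sim")
  res2 <- genotypeModelTest(st2, "snp1")
  expect_lt(res2$P[res2$comparison == "multiplicative_vs_full"], 0.01)
  expect_gt(res2$P[res2$comparison == "recessive_vs_full"], 0.01)

  # two observed classes: skipped with warning
  g3 <- pmin(g, 1L)
  st3 <- CaseControlStudy(
    GenotypeMatrix(v, matrix(as.integer(g3), ncol = 1), ids),
    phenotypes(st), cohort = "sim")
  expect_warning(res3 <- genotypeModelTest(st3, "snp1"), "skipped")
  expect_true(all(res3$skipped))
})

test_that("null multiplicative-vs-full P values are close to uniform", {
  set.seed(77)
  reps <- 200
  pvals <- replicate(reps, {
    n <- 600
    g <- sample(0:2, n, replace = TRUE, prob = c(.36, .48, .16))
    y <- rbinom(n, 1, plogis(-0.5 + 0.25 * g))
    ids <- sprintf("x%03d", 1:n)
    v <- two_snp_variants()[1, ]
    st <- CaseControlStudy(
      GenotypeMatrix(v, matrix(as.integer(g), ncol = 1), ids),
      data.frame(sampleId = ids, status = ifelse(y == 1, "case", "control"),
                 cohort = "sim"), cohort = "sim")
    res <- genotypeModelTest(st, "snp1")
    res$P[res$comparison == "multiplicative_vs_full"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("likelihood recovery of missing genotypes uses LD and stays in bounds", {
  pools <- esr1Pools()
  sim <- simulateStudy(pools$iceland, 400, 400, seed = 21)
  st <- sim$study
  v <- variants(st)
  # blank the causal SNP for some samples
  g <- genotypes(st)
  miss <- seq(1, 800, by = 13)
  ti <- match("rs9397435", v$id)
  g[miss, ti] <- NA
  st2 <- CaseControlStudy(GenotypeMatrix(v, g, sampleIds(st)),
                          phenotypes(st), cohort = "iceland")
  dos <- imputeMissing(st2, "rs9397435",
                       setdiff(v$id, "rs9397435"))
  expect_length(dos, length(miss))
  expect_true(all(dos >= 0 & dos <= 2))
  # strong LD in this pool: imputed dosage close to the hidden truth on average
  truth <- genotypes(st)[miss, ti]
  expect_lt(mean(abs(dos - truth)), 0.35)

  # perfect-LD helper determines the dosage exactly
  v2 <- two_snp_variants()
  gm <- GenotypeMatrix(v2, cbind(c(NA, NA, NA, rep(0:2, 10)),
                                 c(0L, 1L, 2L, rep(0:2, 10))),
                       sprintf("p%02d", 1:33))
  ph <- data.frame(sampleId = sprintf("p%02d", 1:33),
                   status = rep(c("case", "control"), length.out = 33),
                   cohort = "toy")
  stp <- CaseControlStudy(gm, ph, cohort = "toy")
  dosp <- imputeMissing(stp, "snp1", "snp2")
  expect_equal(unname(dosp), c(0, 1, 2), tolerance = 1e-6)

  # helpers independent of the target: posterior reduces to the prior 2*freq
  set.seed(5)
  gind <- cbind(c(NA, rbinom(400, 2, 0.3)), rbinom(401, 2, 0.5))
  gmi <- GenotypeMatrix(v2, gind, sprintf("q%03d", 1:401))
  phi <- data.frame(sampleId = sprintf("q%03d", 1:401),
                    status = rep(c("case", "control"), length.out = 401),
                    cohort = "toy")
  sti <- CaseControlStudy(gmi, phi, cohort = "toy")
  dosi <- imputeMissing(sti, "snp1", "snp2")
  expect_equal(unname(dosi), 2 * mean(gind[-1, 1]) / 2, tolerance = 0.1)

  # empty helper list: cohort-mean fallback with warning
  expect_warning(dose <- imputeMissing(sti, "snp1", character()),
                 "cohort-mean")
  expect_equal(unname(dose), mean(gind[-1, 1]), tolerance = 1e-12)
})

test_that("conditioning on an irrelevant SNP leaves the primary effect intact", {
  # construct cell counts where case fraction depends only on the primary
  # dosage, and the adjust dosage varies freely within cells: the MLE then
  # sets the adjust coefficient to zero and the adjusted OR equals the
  # single-SNP logistic OR exactly
  grid <- expand.grid(dp = 0:2, da = 0:2)
  ncell <- 40
  case_frac <- c(`0` = 0.3, `1` = 0.45, `2` = 0.6)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    nc <- round(ncell * case_frac[as.character(grid$dp[i])])
    data.frame(dp = grid$dp[i], da = grid$da[i],
               y = c(rep(1, nc), rep(0, ncell - nc)))
  }))
  ids <- sprintf("z%03d", seq_len(nrow(rows)))
  v <- two_snp_variants()
  gm <- GenotypeMatrix(v, cbind(rows$dp, rows$da), ids)
  ph <- data.frame(sampleId = ids,
                   status = ifelse(rows$y == 1, "case", "control"),
                   cohort = "toy")
  st <- CaseControlStudy(gm, ph, cohort = "toy")
  res <- conditionalAssociation(st, "snp1", "snp2")
  solo <- stats::glm(rows$y ~ rows$dp, family = binomial())
  expect_equal(res$OR_adj, unname(exp(coef(solo)[2])), tolerance = 1e-6)

  expect_error(conditionalAssociation(st, "snp1", "snp1"), "itself")
  # perfectly collinear dosages are inseparable
  gm2 <- GenotypeMatrix(v, cbind(rows$dp, rows$dp), ids)
  st2 <- CaseControlStudy(gm2, ph, cohort = "toy")
  expect_error(conditionalAssociation(st2, "snp1", "snp2"), "inseparable")
})

test_that("adjusting a tagger for the causal SNP kills the residual signal", {
  pools <- esr1Pools()
  hits <- 0L
  for (s in 1:10) {
    sim <- simulateStudy(pools$taiwan, 1126, 1118, seed = 3000 + s)
    res <- conditionalAssociation(sim$study, "rs2046210", "rs9397435")
    if (res$P_residual > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
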