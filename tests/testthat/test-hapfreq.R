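test_that("fully phased inputs resolve in one pass", {
  # 2x(TT,GG) and 2x(CC,AA): haplotypes TG and CA at 0.5 each
  gm <- tiny_2snp_gm(rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L)))
  ft <- emHaplotypeFrequencies(gm)
  fr <- hapFrequencies(ft)
  expect_setequal(rownames(fr), c("TG", "CA"))
  expect_equal(unname(fr[, 1]), c(0.5, 0.5), tolerance = 1e-12)
  expect_lte(ft@iterations[[1]], 2L)
})

test_that("a lone double heterozygote sits at the symmetric fixed point", {
  gm <- tiny_2snp_gm(rbind(c(1L, 1L)))
  ft <- emHaplotypeFrequencies(gm)
  expect_equal(unname(hapFrequencies(ft)[, 1]), rep(0.25, 4),
               tolerance = 1e-9)
  # the perturbation flag escapes the saddle
  ft2 <- emHaplotypeFrequencies(gm, perturb = 1e-3)
  expect_gt(max(hapFrequencies(ft2)[, 1]), 0.45)
})

test_that("EM log-likelihood matches a direct numerical maximizer on tiny instances", {
  set.seed(404)
  for (rep in 1:6) {
    m <- sample(2:3, 1)
    n <- sample(4:6, 1)
    dos <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), n, m)
    if (all(is.na(dos))) next
    gm <- tiny_genotype_matrix(dos, m)
    ft <- emHaplotypeFrequencies(gm, tol = 1e-12, maxIter = 5000)
    oracle <- hap_loglik_oracle(dos, m)
    expect_equal(ft@logLik[[1]], oracle, tolerance = 1e-6)
  }
})

test_that("trio constraints resolve double-heterozygous parents", {
  # both parents double-het, child homozygous for the counted alleles:
  # each parent must carry haplotypes 11 and 00
  dos <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L))
  gm <- tiny_2snp_gm(dos, ids = c("fa", "mo", "ch"))
  ped <- data.frame(child = "ch", father = "fa", mother = "mo")
  ft <- emHaplotypeFrequencies(gm, trios = ped)
  fr <- hapFrequencies(ft)
  expect_setequal(rownames(fr), c("CA", "TG"))
  expect_equal(unname(fr[, 1]), c(0.5, 0.5), tolerance = 1e-9)
  # without the trio the same parents sit at the four-way saddle
  ft0 <- emHaplotypeFrequencies(tiny_2snp_gm(dos[1:2, , drop = FALSE]))
  expect_equal(unname(hapFrequencies(ft0)[, 1]), rep(0.25, 4),
               tolerance = 1e-9)
})

test_that("debug mode asserts a non-decreasing likelihood on noisy data", {
  set.seed(9)
  sim <- simulateStudy(esr1Pools()$usa, 80, 80, seed = 31, missingness = 0.05)
  expect_no_error(emHaplotypeFrequencies(sim$study@genotypes, debug = TRUE))
})

test_that("frequencies are invariant to sample order and SNP column order", {
  sim <- simulateStudy(esr1Pools()$taiwan, 150, 150, seed = 77)
  gm <- sim$study@genotypes
  ft <- emHaplotypeFrequencies(gm)
  perm <- rev(seq_along(sampleIds(gm)))
  gm_s <- GenotypeMatrix(variants(gm), genotypes(gm)[perm, ],
                         sampleIds(gm)[perm])
  expect_equal(hapFrequencies(emHaplotypeFrequencies(gm_s)),
               hapFrequencies(ft), tolerance = 1e-8)
  cperm <- c(3, 1, 7, 2, 6, 5, 4)
  gm_c <- GenotypeMatrix(variants(gm)[cperm, ], genotypes(gm)[, cperm],
                         sampleIds(gm))
  fr_c <- hapFrequencies(emHaplotypeFrequencies(gm_c))
  # reindex haplotype strings back to the original SNP order
  relabel <- vapply(rownames(fr_c), function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(chars[match(seq_along(cperm), cperm)], collapse = "")
  }, "")
  fr_orig <- hapFrequencies(ft)
  expect_equal(fr_c[order(relabel), 1],
               fr_orig[order(rownames(fr_orig)), 1],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("EM recovers the Icelandic pool frequencies from 3000 individuals", {
  pool <- esr1Pools()$iceland
  # theta = 1 so the whole sample is one draw from the pool
  null_pool <- ancestrySpec("iceland", esr1Snps(), pool@haplotypes,
                            pool@freq, "rs9397435", 1.0)
  sim <- simulateStudy(null_pool, 1500, 1500, seed = 123)
  ft <- emHaplotypeFrequencies(sim$study@genotypes)
  est <- stats::setNames(hapFrequencies(ft)[, 1], haplotypes(ft))
  truth <- stats::setNames(pool@freq, haplotypes(pool))
  keys <- union(names(est), names(truth))
  tv <- sum(abs(ifelse(is.na(est[keys]), 0, est[keys]) -
                ifelse(is.na(truth[keys]), 0, truth[keys]))) / 2
  expect_lt(tv, 0.02)
})

test_that("phase posteriors follow Bayes arithmetic", {
  gm <- tiny_2snp_gm(rbind(c(0L, 0L), c(1L, 1L)), ids = c("hom", "het"))
  ft <- new("HaplotypeFrequencyTable",
            snps = c("snp1", "snp2"), counted = c("C", "A"),
            haplotypes = c("TG", "CA", "TA", "CG"),
            freq = matrix(c(0.45, 0.45, 0.05, 0.05), ncol = 1,
                          dimnames = list(NULL, "pooled")),
            logLik = 0, iterations = 1L, nChrom = 4)
  post_hom <- phasePosteriors(gm, ft, "hom")
  expect_equal(nrow(post_hom), 1L)
  expect_equal(post_hom$weight, 1)
  expect_setequal(c(post_hom$hap1, post_hom$hap2), "TG")
  post_het <- phasePosteriors(gm, ft, "het")
  expect_equal(sum(post_het$weight), 1, tolerance = 1e-12)
  w_cis <- post_het$weight[post_het$hap1 %in% c("TG", "CA") &
                           post_het$hap2 %in% c("TG", "CA")]
  expect_equal(w_cis, (0.45 * 0.45) / (0.45 * 0.45 + 0.05 * 0.05),
               tolerance = 1e-9)
})

test_that("haplotype association behaves as a one-vs-rest allelic contrast", {
  pool_null <- ancestrySpec("taiwan", esr1Snps(),
                            esr1Pools()$taiwan@haplotypes,
                            esr1Pools()$taiwan@freq, "rs9397435", 1.0)
  sim <- simulateStudy(pool_null, 500, 500, seed = 55)
  res <- haplotypeAssociation(sim$study, esr1Snps()$id, "GACGATG")
  expect_gt(res$OR, 0.75); expect_lt(res$OR, 1.35)   # null: OR near 1
  # relabeling case/control inverts the OR
  ph <- phenotypes(sim$study)
  ph$status <- ifelse(ph$status == "case", "control", "case")
  st_sw <- CaseControlStudy(sim$study@genotypes, ph, cohort = "taiwan")
  res_sw <- haplotypeAssociation(st_sw, esr1Snps()$id, "GACGATG")
  expect_equal(res_sw$OR, 1 / res$OR, tolerance = 1e-6)
  # risk haplotype under theta = 1.23 shows an elevated point estimate
  sim_r <- simulateStudy(esr1Pools()$taiwan, 1126, 1118, seed = 66)
  res_r <- haplotypeAssociation(sim_r$study, esr1Snps()$id, "GACGATG")
  expect_gt(res_r$OR, 1.0)
  expect_lt(res_r$OR, 1.7)
})
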