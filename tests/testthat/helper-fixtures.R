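# Fixtures are built in code at test time; no binary files.

# Two-SNP variant table: snp1 T/C (counted C), snp2 G/A (counted A).
two_snp_variants <- function() {
  data.frame(id = c("snp1", "snp2"), chrom = "1", pos = c(100L, 200L),
             a1 = c("C", "A"), a2 = c("T", "G"),
             risk = c(NA_character_, NA_character_),
             counted = c("C", "A"), stringsAsFactors = FALSE)
}

# Study realizing a given 2x2 allele-count table (a, b = case counted/other;
# c, d = control counted/other).  Counts must be even.
study_from_counts <- function(a, b, c_, d, lambda = 1.0, cohort = "toy") {
  stopifnot((a + b) %% 2 == 0, (c_ + d) %% 2 == 0)
  make <- function(counted, other) c(rep(2L, counted / 2), rep(0L, other / 2))
  g_case <- make(a, b)
  g_ctrl <- make(c_, d)
  v <- two_snp_variants()[1, ]
  ids <- c(sprintf("ca%03d", seq_along(g_case)),
           sprintf("co%03d", seq_along(g_ctrl)))
  gm <- GenotypeMatrix(v, matrix(c(g_case, g_ctrl), ncol = 1), ids)
  ph <- data.frame(sampleId = ids,
                   status = c(rep("case", length(g_case)),
                              rep("control", length(g_ctrl))),
                   cohort = cohort, stringsAsFactors = FALSE)
  CaseControlStudy(gm, ph, cohort = cohort, lambda = lambda)
}

# Panel from explicit haplotype rows (character matrix) over a variant table.
panel_from_rows <- function(rows, variants, ancestry = "toy") {
  HaplotypePanel(variants, do.call(rbind, rows), ancestry = ancestry)
}

# Textbook r-squared between two allele columns, written independently of
# pairwiseLD (indicator covariance route).
r2_direct <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  a <- as.numeric(x[ok] == sort(unique(x[ok]))[1])
  b <- as.numeric(y[ok] == sort(unique(y[ok]))[1])
  stats::cor(a, b)^2
}

# Naive average-linkage agglomeration over a distance matrix, cut at h:
# independent oracle for clusterClasses.
naive_average_linkage_cut <- function(d, h) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- c()
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    heights <- c(heights, bestd)
  }
  # canonical form: sorted members, sorted by first member
  parts <- lapply(clusters, sort)
  parts[order(vapply(parts, `[`, 0, 1))]
}

# Observed-data log-likelihood of haplotype frequencies for unphased
# genotypes (HWE random pairing), independent of the EM implementation.
hap_loglik_direct <- function(dosages, haps_bin, freq) {
  ll <- 0
  for (r in seq_len(nrow(dosages))) {
    g <- dosages[r, ]
    tot <- 0
    H <- nrow(haps_bin)
    for (i in seq_len(H)) for (j in i:H) {
      d <- haps_bin[i, ] + haps_bin[j, ]
      ok <- all(is.na(g) | d == g)
      if (ok) tot <- tot + freq[i] * freq[j] * ifelse(i == j, 1, 2)
    }
    ll <- ll + log(max(tot, .Machine$double.xmin))
  }
  ll
}

# Maximize hap_loglik_direct by multi-start softmax optimization: the
# brute-force oracle for the EM on tiny instances.
hap_loglik_oracle <- function(dosages, m) {
  haps_bin <- as.matrix(expand.grid(rep(list(0:1), m)))
  colnames(haps_bin) <- NULL
  H <- nrow(haps_bin)
  obj <- function(theta) {
    f <- exp(theta - max(theta)); f <- f / sum(f)
    -hap_loglik_direct(dosages, haps_bin, f)
  }
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    fit <- stats::optim(stats::rnorm(H, sd = s - 1), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  -best
}

# Two-SNP genotype matrix over two_snp_variants(); dosages count C and A.
tiny_2snp_gm <- function(dosages, ids = sprintf("i%02d", seq_len(nrow(dosages)))) {
  GenotypeMatrix(two_snp_variants(), dosages, ids)
}

tiny_genotype_matrix <- function(dosages, m) {
  v <- data.frame(id = paste0("s", seq_len(m)), chrom = "1",
                  pos = seq_len(m) * 10L,
                  a1 = "A", a2 = "G", risk = NA_character_, counted = "A",
                  stringsAsFactors = FALSE)
  GenotypeMatrix(v, dosages, paste0("i", seq_len(nrow(dosages))))
}
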