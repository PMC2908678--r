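## Internal helpers shared across modules.

## Named sub-streams derived from one master seed, so adding a stage never
## perturbs another stage's draws.  Kept below 2^31 - 1.
.subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Likelihood-ratio G statistic for a 2x2 table (rows: case/control,
## cols: counted/other allele).  Accepts fractional counts.
.gStat2x2 <- function(tab) {
  tot <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / tot
  terms <- tab * log(tab / e)
  terms[tab == 0] <- 0
  2 * sum(terms)
}

## Odds ratio and log-OR standard error with Haldane-Anscombe 0.5
## correction applied only when a cell is zero (never to the LR statistic).
.or2x2 <- function(tab) {
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  c(or = or, se = se)
}

## Binomial log-likelihood of allele counts (x counted out of n) at freq p.
.binll <- function(x, n, p) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  x * log(p) + (n - x) * log(1 - p)
}

## Per-stratum profile log-likelihood of a 2x2 allele table under a fixed
## odds ratio psi: cases ~ Bin(n1, p1), controls ~ Bin(n0, p0) with
## odds(p1) = psi * odds(p0); maximized over p0 numerically.
.profileLL2x2 <- function(tab, psi) {
  x1 <- tab[1, 1]; n1 <- sum(tab[1, ])
  x0 <- tab[2, 1]; n0 <- sum(tab[2, ])
  f <- function(q) {
    p0 <- stats::plogis(q)
    p1 <- stats::plogis(q + log(psi))
    -(.binll(x1, n1, p1) + .binll(x0, n0, p0))
  }
  -stats::optimize(f, c(-30, 30), tol = 1e-10)$objective
}

## Saturated (free-frequency) log-likelihood of a 2x2 allele table.
.freeLL2x2 <- function(tab) {
  x1 <- tab[1, 1]; n1 <- sum(tab[1, ])
  x0 <- tab[2, 1]; n0 <- sum(tab[2, ])
  .binll(x1, n1, x1 / n1) + .binll(x0, n0, x0 / n0)
}
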