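---
title: "Ancestry-shift refinement mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-shift refinement mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryShift)
```

## Scope and rationale

`ancestryShift` refines a case-control association signal by exploiting
differences in linkage disequilibrium (LD) between ancestral
populations. Within one population, SNPs with r² ≥ 0.8 form an
*equivalence class*: their association evidence is statistically
interchangeable, so no amount of within-population genotyping
distinguishes them. Shifting the analysis to a population whose
haplotype structure fractionates the class differently — and combining
evidence across ancestries under a common-odds-ratio model — can resolve
members of the class against each other. The package covers the whole
chain: LD screening, class construction, per-cohort association,
conditional adjustment, cross-ancestry combination with heterogeneity
diagnostics, haplotype-level analysis, genotype-stratified expression
models, and a simulator that reproduces the statistical structure of the
multi-ancestry design at the 6q25.1 (*C6orf97*/*ESR1*) locus.

## Linkage disequilibrium and equivalence classes

LD is always computed on **phased reference panels**, never on study
genotypes: screening decisions should not be contaminated by the data
that will later be tested. For alleles A and B with haplotype frequency
$p_{AB}$,

$$D = p_{AB} - p_A p_B, \qquad
r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad
D' = |D|/D_{\max},$$

with $D_{\max}$ the usual bound given the sign of $D$. Chromosomes
missing an allele at either SNP are deleted pairwise; a monomorphic SNP
makes the pair undefined (`NA`), and undefined entries are excluded from
screening with a warning rather than imputed — treating an unobserved
correlation as zero would silently keep an uninformative SNP.

Classes are realized exactly as the `hclust`/`cutree` idiom: average
linkage agglomeration on the distance $1 - r^2$, tree cut at height
$1 - r^2_{\text{class}}$. The defaults $r^2 \ge 0.65$ for index-SNP
screening and $r^2 \ge 0.8$ for class membership are the study design's
own operating points: 0.65 casts a wide net around the index signal
while 0.8 is the conventional "statistically redundant" level. Tag
choice prefers an externally supplied list (e.g. already-genotyped
SNPs), otherwise the member maximizing mean r² to its classmates, ties
broken by smaller genomic position — a deterministic rule so reruns are
identical. The multiple-testing unit is the class, not the SNP:
the Bonferroni threshold is $\alpha$ divided by the number of classes.

## Allelic association under the multiplicative model

The multiplicative model states that a genotype's relative risk is the
product of its two alleles' relative risks, so the natural sufficient
statistic is the 2×2 **allele-count** table (case/control ×
counted/other allele). The test statistic is the likelihood-ratio G
statistic on 1 df; the odds ratio is the cross-product ratio; the 95% CI
assumes $\ln \widehat{OR}$ is normal with
$SE = \sqrt{1/a + 1/b + 1/c + 1/d}$. Numerical choices:

* the Haldane–Anscombe 0.5 correction applies to OR/CI only when a cell
  is zero, never to the G statistic, which keeps P values exact under
  permutation symmetries (case/control swap, allele relabeling);
* a genomic-control factor λ divides the statistic before the P value
  and inflates the SE by √λ, so CI and P remain mutually consistent. The
  package treats λ as an input per cohort (default 1); it is not
  re-derived. Values below 1 are accepted with a warning.

Genotype-model checking fits full (two-parameter), multiplicative
(dosage-linear) and recessive logistic models on genotype counts and
reports 1-df LR tests of each submodel against the full model; with
fewer than three observed genotype classes the comparison is skipped
rather than silently degenerate.

### Missing-genotype recovery

SNPs in a class are strongly correlated, so a missing genotype carries
recoverable information. For each sample missing the target SNP, the
expected dosage is the posterior mean over unordered haplotype pairs
compatible with its observed helper genotypes, weighted by EM haplotype
frequencies estimated on the whole cohort — cases and controls jointly,
to avoid imputing the association into existence. Samples missing every
helper receive the cohort-mean dosage. This keeps the individual set
identical across SNPs within a cohort, making P values directly
comparable.

### Conditional analysis

The adjusted effect of SNP $i$ given SNP $j$ is estimated by logistic
regression with additive allele-dosage terms for both SNPs; $OR_{adj} =
e^{\beta_i}$ and the residual P is the 1-df LR test of the two-SNP model
against the $j$-only model. A joint haplotype-risk likelihood is a
defensible alternative and can differ in strong-LD corners; the logistic
route was chosen because it is standard, transparent, and exact for the
orthogonal case. Perfectly collinear dosages (sample r² = 1) are
reported as inseparable rather than fitted.

## Cross-ancestry combination and heterogeneity

With raw counts, the default is the Mantel-Haenszel estimator
$OR_{MH} = \sum_i (a_i d_i / n_i) \big/ \sum_i (b_i c_i / n_i)$, whose
model allows each stratum its own allele frequencies but a common odds
ratio; the CI uses the Robins-Breslow-Greenland variance and the
combined P comes from the 1-df LR statistic of the common-OR binomial
likelihood against OR = 1 (λ-deflated per stratum). Heterogeneity is the
LR statistic of stratum-specific ORs against the common OR on $k-1$ df,
summarized as $I^2 = \max(0, (Q - (k-1))/Q) \times 100$.

When only printed OR/CI summaries exist, the inverse-variance route
recovers $SE_i = \ln(\text{hi}_i/\text{lo}_i)/(2 z_{0.975})$, combines
on the log scale, and uses Cochran's Q. The two routes agree closely on
well-populated balanced tables (the suite checks ln-OR agreement within
0.005 at cell counts ≥ 50) but are labelled in output and never silently
mixed; the count route is preferred whenever counts exist.

## Haplotype frequencies by trio-aware EM

For $m \le 12$ SNPs the EM algorithm estimates multilocus haplotype
frequencies from unphased genotypes. Unrelated individuals contribute
posterior weights over unordered compatible haplotype pairs
($\propto f_{h_1} f_{h_2} (2 - [h_1 = h_2])$); trios contribute weights
over family-consistent parental diplotype configurations (ordered
transmitted/untransmitted pairs with prior 1/4 per transmission choice),
with children supplying phase constraints only — no extra chromosomes.
Missing genotypes are summed over compatible alleles. Numerical
choices:

* deterministic uniform initialization over observed-compatible
  haplotypes — reproducibility is preferred to random restarts at this
  problem size. The lone double heterozygote is a known symmetric saddle
  (all four haplotypes at 0.25); a `perturb` flag (e.g. `1e-3`) breaks
  the symmetry when escape is wanted;
* convergence when the largest absolute frequency change falls below
  `tol` (default 1e-8), capped at `maxIter` (2000); `debug = TRUE`
  asserts the observed-data log-likelihood never decreases;
* haplotypes below 1e-6 in every group are pruned and the remainder
  renormalized; rows are ordered canonically so output is invariant to
  sample order;
* Mendelian-inconsistent trios are dropped with a warning.

Case/control frequencies for haplotype ORs are estimated **stratified**;
imputation uses **pooled** frequencies (see above). Both are exposed via
the `groups` argument. Haplotype association is one-vs-rest: the target
haplotype against all others as an allelic 2×2 contrast on expected
chromosome counts, with a 0.5 correction when an expected count falls
below 0.5. No global multi-haplotype risk model is fitted.

## Expression models

Relative expression is $2^{\overline{Ct}_{\text{hk}} - Ct_{\text{target}}}$;
the statistic is shift-equivariant in Ct. Genotype effects are fitted by
OLS on $\log_{10}$ relative expression under multiplicative (dosage),
recessive (homozygote indicator) and full (heterozygote + homozygote
indicators) parameterizations. The LR tests use a Gaussian likelihood;
because the choice between LR and F statistics is genuinely open at
these sample sizes, both are reported. Per-genotype summaries are
geometric means, $10^{\text{mean}(\log_{10})}$.

## The simulator: what it emulates, and what it does not

`esr1Pools()` ships four ancestry-specific haplotype pools (Nigerian,
Icelandic, U.S. European, Taiwanese) over the seven genotyped SNPs of
the 6q25.1 locus, seeded from the published control haplotype
frequencies, with the causal allele rs9397435[G] and a default
multiplicative OR of 1.23 (the published Asian point estimate for that
SNP). Control frequencies serve as the population pool — an
approximation to the study's ascertainment, since cases then follow from
θ. Each pool's residual mass (0.6–4.3%) goes to a catch-all haplotype
(`TGCATCA`): every listed haplotype combination of non-risk alleles is
already taken, so the catch-all necessarily carries one risk allele; it
was placed at rs3734805, keeping the causal SNP clean, and the choice
also brings the pool's implied rs3734805 allele frequency closer to the
published control frequency in the Taiwanese sample.

Sampling is **retrospective**: controls are random haplotype pairs
(HWE); cases draw diplotypes with probability
$\propto f_{h_1} f_{h_2}\,\theta^{x}$ where $x$ is the risk-allele count
at the causal SNP. This is exact for OR-parameterized case-control data
and makes the allelic odds ratio at the causal SNP equal θ by
construction. One master seed feeds named sub-streams (controls, cases,
trios, missingness), so adding a stage never perturbs another's draws;
positions in the SNP table are nominal (ordering only).

Deliberately **not** modelled: recombination and mutation (pools are
closed), admixture, genotyping error beyond missingness-at-random,
relatedness beyond the explicit trios, and covariates. Passing tests
therefore demonstrate correctness of the statistical machinery under the
multiplicative-model design, not robustness to those real-data
complications.

## Problem sizes used by the test suite

The suite balances evidence against runtime: the EM-versus-exhaustive
oracle runs on ≤ 3-SNP/≤ 6-individual instances (where direct numerical
maximization of the observed-data likelihood is reliable); test size of
the allelic test uses 10,000 null replicates at 250 cases/controls;
causal-OR coverage uses 500 replicates at the Taiwanese sample sizes
(1,126/1,118); the four-pool ancestry-shift pattern uses 15 replicates
at the published per-ancestry sample sizes. Because near-perfect proxies
of the causal SNP exist outside Africa (they tag the same risk
haplotypes), single replicates can rank a proxy first within noise; the
ranking claim is therefore evaluated on the replicate median of the
combined P, under which the causal SNP comes first, with a plurality of
single-replicate wins.

## Known limitations

* The exact multivariate likelihood behind published adjusted ORs is not
  specified by the design this package follows; the logistic realization
  here can differ from a haplotype-risk likelihood in strong-LD corners.
* Whether a published λ correction also widened CIs is unknowable from
  the statistic alone; this package widens them for internal
  consistency.
* No relatedness inference is attempted outside declared trios; no
  partition-ligation EM for large SNP sets (hard guard at 12 SNPs); no
  random-effects meta-analysis.
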