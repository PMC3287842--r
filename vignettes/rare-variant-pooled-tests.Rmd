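---
title: "Pooled rare-variant association tests: models, simulation design, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled rare-variant association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarepool)
```

## The problem

Individually, rare variants (minor allele frequency, MAF, below a few
percent) carry too little information for single-marker association
tests: a variant seen in a handful of carriers cannot reach exome-wide
significance on its own. Pooled (burden) tests address this by
collapsing all qualifying variants of a gene into one per-sample score
and testing that score against the phenotype. The choice of *which*
variants qualify — the MAF threshold — largely determines what each test
can see, and this package exists to make that dependence measurable: it
implements the four classic pooled tests under one statistical engine
and provides the simulation and evaluation machinery to compare them
under controlled genetic architectures.

## The tests

All four tests share one linear model. For a gene with variants
$i = 1, \dots, m$, minor-allele counts $x_{ji} \in \{0,1,2\}$ for sample
$j$, and weights $w_i \ge 0$, the per-sample burden is
$C_j = \sum_i w_i x_{ji}$, and the association statistic is the
standardized score of the slope in the regression of the phenotype $y$
on $C$:

$$
z \;=\; \frac{\sum_j C_j (y_j - \bar y)}
             {\widehat{\mathrm{sd}}(y)\,\sqrt{\sum_j (C_j - \bar C)^2}},
$$

with $\widehat{\mathrm{sd}}$ the divide-by-$n$ standard deviation. The
tests differ only in the weights:

* **T1 / T5 (fixed threshold).** $w_i = 1$ if $\text{maf}_i < T$
  (strictly), else $0$, with $T = 0.01$ or $0.05$. A gene with no
  variant below $T$ is *not testable* by that test and is excluded from
  its gene universe.
* **WS (weighted sum).** $w_i = 1/\sqrt{n\,p_i(1-p_i)}$ with $p_i$ the
  full-sample MAF: every variant enters, rarer variants get larger
  weights. The factor $n$ cancels in $z$ (the statistic is scale
  invariant in the burden), so only $p_i(1-p_i)$ matters.
* **VT (variable threshold).** The candidate thresholds are the gene's
  distinct observed MAFs, each used inclusively
  ($w_i = 1\{\text{maf}_i \le t\}$); the statistic is
  $z_{\max} = \max_t z(t)$ and the reported optimal threshold is the
  argmax (smallest on ties).

Significance always comes from permutation of the phenotype: with $P$
permutations and statistics $s_1, \dots, s_P$, the add-one estimator is
$p = (1 + \#\{k: s_k \ge s_{\mathrm{obs}}\})/(1 + P)$, which is never
zero and is super-uniform under the null. For VT the *entire threshold
maximization is re-run inside every permutation*, so a permuted
$z_{\max}$ may peak at a different threshold — this is what keeps VT
valid despite its data-driven threshold choice. Binary phenotypes go
through the identical linear path (no logistic model): permutation
inference does not require a correctly specified variance model, and a
single code path keeps all traits comparable.

### Covariate adjustment

Adjustment is two-stage: each trait is regressed on the covariates
(ordinary least squares, intercept included) once per replicate, and the
residuals are carried forward as the adjusted phenotype. Binary traits
are residualized the same linear way. The operation is a projection —
idempotent, and harmless (pure centering) with an empty covariate list —
so adjusted and unadjusted analyses share one pipeline. Adjustment
*inside* the permutation scheme (Freedman–Lane-style) is deliberately
out of scope: the two-stage procedure is the one under study.

## Numerical choices

* **Exact z form.** The score form above is algebraically equivalent to
  the slope test of the burden regression but cheap under permutation:
  $\bar y$ and $\widehat{\mathrm{sd}}(y)$ are permutation invariant and
  the burden sums of squares depend only on genotypes, so all permuted
  statistics for all tests (and all VT thresholds) of a gene reduce to
  one matrix crossproduct. Whether the divide-by-$n$ or
  divide-by-$(n-1)$ deviation is used changes no p-value, again by
  permutation invariance.
* **Sidedness.** One-sided-greater by default (higher burden, higher
  phenotype — the direction the max-$z$ construction looks in); a
  two-sided $|z|$ option covers protective effects.
* **Ties.** Per-sample burdens are small integers, so permutations that
  only shuffle samples within equal-burden groups produce exact
  mathematical ties whose floating-point sums may differ in the last
  bit. Tied permuted statistics must count against the observed one, so
  the comparison is $s_k \ge s_{\mathrm{obs}} - 10^{-9}$; the tolerance
  is many orders of magnitude below any gap between genuinely distinct
  statistics at the sample sizes involved.
* **Degenerate inputs.** A constant burden gives $z = 0$ (neutral); a
  constant phenotype is an error; monomorphic variants (sample MAF 0)
  are dropped before weighting everywhere — they carry no information
  and would break the WS weight.
* **Threshold asymmetry.** Fixed tests use strict `maf < T`, following
  the "below 1% (or 5%)" convention; the VT grid uses inclusive
  `maf <= t` because its candidates *are* the observed MAFs — inclusive
  grouping is the only way each variant can enter at its own frequency.
* **Seeding.** Per-gene permutation streams derive deterministically
  from (master seed, gene name, replicate), so results are independent
  of gene processing order, and all tests of a gene share one stream,
  which pairs cross-test comparisons and removes permutation noise from
  their differences.
* **MAF source.** Frequencies are estimated from all loaded samples
  pooled. A single-cohort quantitative-trait design offers no natural
  external reference panel; this is an assumption, not a theorem, and
  is the one place a case/control user might want to intervene.

## The synthetic-data generator

Real exome benchmark panels with known answers are access-restricted,
so the package ships a generator that emulates their *structure*: a
fixed panel (default 697 unrelated individuals) typed at genes laid out
as disjoint coordinate blocks, mostly-rare MAF spectra (log-uniform on
[0.001, 0.05] with a 15% common admixture on [0.05, 0.5]), genotypes
binomial under Hardy–Weinberg, many phenotype replicates (default 200)
redrawn over the same genotypes, and a truth table of causal genes and
per-copy effects. Quantitative traits are linear in the causal counts,
Age and Smoking, plus Gaussian noise; the binary trait thresholds a
liability mixing a genetic latent trait with a noise-only one at 30%
prevalence (the liability construction is an interpretation — the
benchmark being emulated states only that its binary trait is built on
a noisy model — and prevalence is a knob, not a measured value).

Two named architectures drive the power analyses, at a deliberately
reduced desk scale (50 causal + 200 null genes, 20 replicates, 999
permutations — sizes chosen so each analysis completes in minutes on one
CPU while leaving binomial error well below the effects measured):

* **`q1like` (rare-only signals).** Three causal variants per causal
  gene, MAFs in (0.005, 0.05), effect 0.5 per copy (per-gene burden
  heritability around 1.5% — comfortably detectable at $n = 697$
  without being trivial); the trait also loads on Age and Smoking.
* **`q2like` (mixed signals).** One rare (MAF 0.008) and one common
  (MAF 0.17) causal variant per causal gene, effect 0.35 per copy, no
  covariate influence. Most of the association information sits in the
  common variant, which T1 and T5 discard by construction.

The **confounded null** splits the panel into two subpopulations with a
10-year Age gap and distinct allele frequencies: common variants drift
independently (classic stratification), while rare variants are
systematically twice as frequent (capped at the 5% rare bound) in the
older subpopulation — the imprint left when carriers of risk genotypes
die out of the younger stratum, one of the two latent-confounder
mechanisms (stratification, preferential death of carriers) usually
invoked for burden-test inflation. The trait is `0.05 * Age + noise`,
with no genotype effect. Burden then correlates with subpopulation,
subpopulation with Age, and Age with the trait, so unadjusted tests
inflate; residualizing on Age leaves pure noise, independent of
genotype, and calibration returns. With the Age gap, the enrichment and
the frequency drift all switched off the construction collapses to an
ordinary null panel.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: linkage disequilibrium between
variants (variants are independent), relatedness, genotyping error or
missingness, site-frequency spectra from a demographic model, gene
length/variant density correlation, and any real gene's effect-size
profile. Conclusions supported here are about the *relative* behavior
of the tests under controlled architectures, not about absolute power
on any particular cohort.

## Evaluation statistics

With $p_{i,r}$ the p-value of gene $i$ in replicate $r$, a test's gene
universe $T_g$ (the genes it can evaluate), and the causal set $S_g$:

* type I error at level $\alpha$ (null traits):
  $\sum_r \sum_{i \in T_g} 1\{p_{i,r} \le \alpha\} / (R\,|T_g|)$;
* true-positive proportion: the same mean over $S_g \cap T_g$ — when a
  causal gene falls outside a universe (e.g. no sub-1% variant for T1)
  it is excluded and the exclusion is reported, keeping the proportion
  well defined while preserving comparability information;
* false-positive proportion: the mean over $T_g \setminus S_g$;
* ROC: (FPP, TPP) swept over a 200-point logarithmic $\alpha$ grid from
  $10^{-5}$ to 1 (thresholding the permutation p-value, which is how
  the proportions are defined), sorted by FPP, extended to exact (0,0)
  and (1,1) endpoints; AUC by the trapezoid rule on that polyline. AUC
  is invariant under monotone p-value transforms once the grid resolves
  every distinct p-value; on a coarse grid the invariance is only
  approximate.
* Bonferroni threshold: $\alpha_{\mathrm{FW}} / \#\text{genes}$, e.g.
  $0.05/3205 = 1.56 \times 10^{-5}$ for a full exome scan.

Not-testable cells are excluded from numerators and denominators
everywhere, mirroring per-test universe sizes.

## What the analyses show

The `analysis/` drivers (and the equivalent acceptance checks under
`tests/testthat/`) compute, at the desk scales above:

1. calibration of all four tests on a pure null (rates inside the 3-SE
   binomial band at $\alpha \in \{0.01, 0.05, 0.1\}$ over 2,000
   gene-replicates);
2. inflation of unadjusted T5/WS/VT on the confounded null and its
   disappearance after Age adjustment;
3. the architecture dependence of power: T5 beats VT when every causal
   variant is rare, VT beats T1 and T5 when a common causal variant
   hides above the fixed thresholds — i.e., no uniformly most powerful
   test among the three methods.

Every number quoted in the README is printed by this code; none is
transcribed from elsewhere.

## Known limitations

* Permutation p-values are lower-bounded at $1/(P+1)$; exome-wide
  thresholds near $10^{-5}$ need the full $10^5$ permutations (the
  package default outside the desk-scale analyses).
* The exhaustive mode is a verification tool for $n \le 7$, not an
  analysis mode.
* Two-stage residual adjustment is exactly valid here because the
  simulated confounder acts through the trait only; with confounders
  that also interact with genotype effects the two-stage scheme is an
  approximation.
* Only biallelic SNPs are supported; multi-allelic records are rejected
  at parse time.
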