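---
title: "Methods: gene-based eQTL mapping by partial least squares"
author: "geqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-based eQTL mapping by partial least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`geqtl`, the choices that were genuinely open when the package was
designed, and what the accompanying simulations do and do not establish.

# The two-block model

A *gene-based* eQTL analysis treats a whole S-gene (the SNPs it contains,
coded 0/1/2 copies of the B allele) and a whole T-gene (its transcript
probes) as the units of association. For an `n × s` genotype block `S`
and an `n × t` expression block `T`, partial least squares extracts pairs
of latent scores `F_S = S W_S`, `F_T = T W_T` that maximize the
between-block covariance, one factor at a time (NIPALS). After each
factor both blocks are deflated by their regression on the X-score, so
successive X-scores are exactly orthogonal; the per-factor explained
variation of each block is the squared norm of the deflation term over
the block's total (centered, scaled) sum of squares. The accumulated
loadings assemble the prediction model `T = S B_PLS + E_PLS`, and the
strength of an S-gene/T-gene association is reported as the Pearson
correlation between the paired first-factor scores ("canonical
correlation").

Assumptions worth stating: effects are additive and linear on the coded
genotypes; samples are independent within a population (analyses run per
population, never pooled across them, except for the explicitly
cross-population ancestry tests); and expression values are already
normalized upstream — the package performs no normalization of its own.

## Why PLS here

Within a gene, `s` can exceed `n` and SNPs are collinear through linkage
disequilibrium; ordinary multi-response regression is then ill-posed.
PLS handles both regimes and, in the univariate limit (`s = t = 1`, one
factor), reproduces ordinary least squares exactly — a property the test
suite asserts to 1e-10.

# Choosing the number of genetic factors

`cv_press()` runs k-fold cross-validation (default `k = 7`) over factor
counts `0..max_factors` and records the root mean PRESS,
`sqrt(PRESS / (n t))`. The count 0 — predicting every held-out response
by the training mean — is always included, because it is the null model
whose rejection justifies calling an eQTL. For every count below the
PRESS-minimizing one, `van_der_voet_test()` compares the two models'
held-out squared residuals: the statistic is the summed difference of
paired squared residuals, and its null distribution is generated by
swapping each pair with probability 1/2 (2000 randomizations by
default). The selected model is the smallest count whose p-value is at
least `alpha = 0.10`; the minimizer's own p is 1 by construction.

Numerical and design choices:

* **Fold assignment is keyed to sample ids sorted lexicographically**,
  not to row order ("interleaved": every k-th sorted sample shares a
  fold; a seeded-random scheme is available). This makes every scan
  result invariant to permutations of the input rows, which the tests
  assert.
* **Centering and scaling are recomputed inside each training fold**;
  reusing full-data statistics would leak the held-out samples into the
  fit and bias PRESS downward.
* Both blocks are centered and unit-variance scaled with training
  statistics. Scaling puts SNPs with different allele frequencies and
  probes with different dynamic ranges on one footing.
* The van der Voet test is one-sided (candidate worse than minimizer),
  since only smaller models are ever tested against the minimizer. With
  identical residual matrices all randomized statistics are 0, so p = 1.
* `alpha = 0.10` follows the convention of the PRESS-comparison test in
  standard PLS software.

# Calling eQTL

`call_pair()` emits a record when the selected factor count is ≥ 1 *and*
the explained variation of both blocks at that count exceeds an epsilon
of 1e-8 (the operational reading of "non-zero"). The pair is *cis* when
the S-gene and T-gene ids coincide, *trans* otherwise; `call_seqtl()` is
the single-SNP special case (cis when the T-gene is among the genes
containing the SNP). After selection the model is refit on all samples —
cross-validation is used only to pick the factor count.

The scan applies no multiple-testing control across pairs: each pair's
call stands on its own cross-validated selection. Users scanning many
pairs should treat the record list as a screening result; the guardrail
`max_pairs` (default 10^4) forces an explicit pair filter before
genome-scale all-pairs scans, which are cluster-scale jobs.

Missing genotypes are mean-imputed per SNP before fitting; call-rate QC
upstream bounds the missing fraction at 10%, where mean imputation
perturbs the fit negligibly. Degenerate inputs are defined away rather
than propagated: all-constant blocks return no record with a warning,
and constant columns are dropped (a monomorphic SNP carries no
association information).

**Sign convention.** NIPALS weights are sign-indeterminate; the package
canonicalizes each factor so the largest-magnitude X-weight entry is
positive, making weights, scores, and loadings reproducible across
platforms.

# Quality control and probe selection

`qc_snps()` removes SNPs in a fixed order — non-autosomal, call rate
< 0.9, minor allele frequency < 0.01 (computed on non-missing calls),
Hardy–Weinberg violations, inter-gene — and reports the per-step tallies.
The HWE test is a permutation test: the statistic is the absolute excess
of heterozygotes over the expectation given the allele counts, and the
null re-pairs the 2N observed alleles into N genotypes. Its p-values are
Benjamini–Hochberg adjusted across the SNPs that survive the MAF filter,
and a SNP is removed when the adjusted p falls below 0.001. Note the
permutation floor: with B permutations the smallest attainable p is
1/(B+1), so B must comfortably exceed 1/threshold for the step to be able
to act — the default is B = 2000. The permutation construction is
validated in the tests against full enumeration of the exact conditional
(re-pairing) distribution.

`select_probes()` mirrors the two-list probe selection: list A is the
intersection across populations of the `top_k` probes by
within-population variability, list B the union over population pairs of
the top fraction (default 1%) by absolute rank difference; the union
A ∪ B is then restricted to annotation sources deemed validated (default
RefSeq) and to autosomes. "Variability" is the sample variance by
default (an IQR option exists); ranks use mid-ranks, and boundary ties
are included wholesale so the selection is independent of input order.

# Ancestry tests

`fisher_exact_2xk()` implements the Freeman–Halton exact test on a 2×K
allele-count table: conditioning on all margins, the two-sided p is the
sum of multivariate hypergeometric probabilities of every table no more
probable than the observed one (relative tolerance 1e-12 treats
numerically tied probabilities as ties). All arithmetic is in log space
— the worked examples reach p ≈ 1e-23, far below what term-by-term
summation of raw probabilities would represent reliably. Enumeration
walks the K−1 free cells (the largest column margin is made the
dependent cell); tables beyond a configurable budget fall back to Monte
Carlo sampling from the conditional null with a warning. Allele counts
exclude missing genotypes and no continuity correction is applied.

`mnm_test()` tests multivariate expression differences across K groups
on component-wise mid-ranks: `W = Σ_g n_g (R̄_g − R̄)' V̂⁻¹ (R̄_g − R̄)`
with `V̂` the rank covariance across all samples (divisor n − 1). With
one response this is algebraically the Kruskal–Wallis H statistic, which
anchors the implementation. The asymptotic reference is chi-square with
t(K−1) degrees of freedom; a label-permutation mode is the
assumption-free fallback, and a singular `V̂` is handled by pseudo-
inverse with a warning. The statistic depends on the data only through
ranks, so it is invariant under strictly monotone transforms of any
single probe — useful when probes sit on arbitrary intensity scales.

# Ancestry-predictive panels

`nested_cv_classify()` selects a small SNP panel that predicts population
membership: an outer stratified 10-fold cross-validation; inside each
training portion, greedy forward selection adds the candidate SNP with
the largest training-accuracy increment under a discriminant fit,
breaking accuracy ties by the smaller within/between sum-of-squares
ratio (the more separable marker) and residual ties lexicographically;
selection stops at accuracy 1.0 or when the best increment drops below
0.001. Of the ten fold-models, the one with the highest held-out
accuracy is returned (ties: smaller panel, then lower fold index).

The discriminant is flexible discriminant analysis with a **linear**
basis — equivalent to linear discriminant analysis with pooled
within-class covariance and sample priors. Predictors are three-valued
genotype codes, so nonlinear bases add little and cost much; the linear
fit is also directly checkable against a reference LDA implementation,
which the tests do. A numerically singular within-class scatter (e.g. a
SNP constant inside every class) receives a ridge jitter of 1e-8 of the
mean diagonal, with a warning.

The empty-panel baseline is the majority-class rate, so the first
selected SNP must beat majority guessing by the stopping increment.
Candidate sets for a two-population comparison follow three set-algebra
rules on the per-population eQTL lists (union, intersection, and the
symmetric difference of population-specific markers),
`eqtl_candidate_set()`.

# The synthetic-data generator

`simulate_genotypes()` draws, per SNP, an ancestral frequency
p ~ Uniform(0.1, 0.9) and per-population frequencies from the
Balding–Nichols model, Beta(p(1−F)/F, (1−p)(1−F)/F), with the divergence
F settable separately for "neutral" and "aim" SNP classes; genotypes are
Binomial(2, p_pop) — Hardy–Weinberg within population — with uniform
missingness on top. Gene coordinates are laid out deterministically
along the 22 autosomes so the generated annotation and gene map are
consistent by construction. `simulate_expression()` adds planted linear
effects (β per SNP, applied to the first SNPs of the source gene) plus
i.i.d. Gaussian noise (a heavier-tailed t₅ option exists for rank-test
robustness checks).

What the generator emulates: multi-population allele-frequency
divergence, HWE within population, missing calls, cis/trans linear
regulation with known truth. What it does not: linkage disequilibrium
(SNPs are independent by default; an autoregressive option exists but is
off), expression normalization artifacts, batch structure, relatedness,
and any nonlinearity. Passing simulations therefore establish the
implementation's statistical behavior under the stated model, not
performance on real cell-line data.

The `tiny` fixture profile uses a compact worked-example shape (45
people; 7 T-genes × 4 transcripts; 43 S-genes × 28 SNPs = 1,204 SNP
columns). The 45 samples are split into two
subpopulations of 23 and 22 so that every pipeline stage — including the
cross-population ancestry tests and the classifier — can run on the
fixture; its planted cis effects are spread over the first six SNPs of
the source gene (β = 1.2 each), a block-like regulatory signal that is
detectable at n = 23 where a lone-SNP effect inside a 28-SNP block would
mostly be washed out by the 27 noise directions.

# Problem sizes in the test suite

The simulation suites run at sizes chosen to make their bounds sharp but
cheap: 500 pure-noise pairs for the overfitting guard (selected count 0
in ≥ 85%), 200 planted one-factor pairs at R² = 0.5 and n = 90
(recovered in ≥ 95%), a 20-planted/180-null scan benchmark (sensitivity
≥ 0.9, false-positive rate ≤ 0.15), 500-replicate type-I-error checks
for the permutation tests, a 200-SNP frequency-homogeneous panel for the
FDR flags, and 50 replicates of the two-population classifier at a 0.4
allele-frequency gap (median held-out accuracy ≥ 0.85). One
null-classifier bound is asserted on the *median* over replicates: the
best-of-ten-folds accuracy on 9-sample test folds is a maximum of ten
noisy binomial proportions, and a single draw of it is too variable to
bound honestly.

# Known limitations

* Genome-scale all-pairs scans (10^4+ pairs) are deliberately refused
  without an explicit filter; the per-pair cost is a full cross-validated
  PLS plus randomization tests.
* The van der Voet randomization uses the squared-residual form only;
  the Hotelling-type approximation is not implemented.
* The exact 2×K enumeration is practical for K ≤ 4–5 at HapMap-size
  allele counts; beyond that the Monte Carlo fallback governs.
* The rank-score test uses marginal mid-ranks; spatial-rank variants are
  out of scope.
* cis/trans classification is by gene-id equality, so a SNP inside two
  overlapping genes is cis to both; there is no distance-based window.
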