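---
title: "Homozygosity disequilibrium scans: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity disequilibrium scans: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Runs of homozygosity (ROH) are stretches of the genome where an individual
carries two identical alleles at every SNP. Their genomic arrangement is not
random — autozygosity, selection and chromosomal aberrations all concentrate
homozygosity locally — and this nonrandom pattern, *homozygosity
disequilibrium* (HD), varies between individuals and aggregates in families.
`hdscan` asks whether that variation predicts a treatment response: it
estimates a per-individual, per-locus *homozygosity intensity* profile from
SNP-array genotypes, tests each locus for association with a
triglyceride-lowering drug response in family data, corrects for the heavy
dependence between overlapping tests, and then asks whether the implicated
loci also shift DNA-methylation response (cis/trans meQTL scans).

All stages run on a bundled synthetic cohort generator, because the
motivating cohort (family-based, with pre/post-treatment triglycerides and
450K methylation) is controlled-access.

## Homozygosity intensity: the double-weight local polynomial model

For sample $s$, SNP $i$ has homozygosity indicator $x_{si} \in \{0,1\}$
(missing genotypes are excluded, never imputed — imputing either value would
fabricate homozygosity information). On each chromosome with $n_j$ SNPs, a
sliding window is anchored at **every** SNP and contains the anchor's
$k_j = \max(2, \mathrm{round}(0.05\,n_j))$ nearest neighbours by physical
distance (ties toward the lower index, for determinism). Within the window
anchored at position $p_0$, define $u_i = (p_i - p_0)/h$ with bandwidth
$h = \max_i |p_i - p_0|$ — the nearest-neighbour bandwidth, so all members
satisfy $|u_i| \le 1$.

The intensity is the fitted value at $u = 0$ of a weighted polynomial
regression of $x_{si}$ on $u_i$ with the **double weight**

$$w_i = K(u_i)\, v_i, \qquad K(u) = (1 - |u|^3)^3, \qquad
  v_i = \min(\mathrm{MAF}_i / 0.05,\ 1).$$

* $K$ is the tricube kernel — the canonical "cubic" kernel of local
  polynomial regression; the furthest member gets weight 0, as in loess.
* $v_i$ is the locus weight: common homozygotes at rare SNPs are nearly
  guaranteed and carry little information about HD, so SNPs below the MAF
  threshold (default 0.05) are linearly down-weighted and monomorphic SNPs
  contribute nothing. The capped ramp is the simplest form encoding exactly
  that monotone statement; it is isolated in `locus_weights()` so
  alternatives (e.g. rescaled expected heterozygosity $2p(1-p)$) can be
  swapped in. MAF is computed from the analysis sample itself, with missing
  genotypes excluded.
* Default degree is 1 ("local polynomial" implies at least linear); the fit
  is clipped to $[0,1]$, and a rank-deficient weighted design (e.g.
  coincident usable positions) falls back to degree 0, i.e. the
  double-weighted mean. At degree 0 the estimate *is* the weighted mean, an
  identity the tests exploit.
* The fit is evaluated at the anchor position (not the window midpoint);
  with per-SNP anchoring this reports one intensity per SNP, which is also
  what makes "number of tests = number of windows" true downstream.

Because the fitted value at $u=0$ is a fixed linear functional of the
indicators whenever no genotype is missing, profiles are computed as one
sparse matrix product; samples with missing members take a per-window refit
path.

HD regions are maximal runs of consecutive windows with intensity at or
above 0.9 spanning at least 5 Mb (both thresholds exposed); region
coordinates are the first/last anchor positions, 1-based inclusive. Region
summaries use type-7 (R default) quantiles; the choice is arbitrary but
fixed and documented.

## Association: GEE with family clustering

The response is the post-minus-pre triglyceride change
$\bar{TG}_{34} - \bar{TG}_{12}$ (mg/dL). Under the default `"available"`
policy each side averages whatever visits are present (the motivating cohort
analysed everyone with post-treatment data); `"complete"` requires all four
visits.

Each window's intensity is tested in a Gaussian GEE with identity link,
exchangeable working correlation within pedigree, and the Liang–Zeger
sandwich covariance; covariates are sex, age, field centre (general
categorical coding), smoking, one metabolic-syndrome index (ATP *or* IDF —
two parallel runs, as in the motivating design) and the top 10 principal
components from an LD-pruned ($r^2 < 0.2$, 50-SNP window, 5-SNP step)
genotype set, standardized by $\sqrt{2p(1-p)}$ with missing entries zeroed
after centring. Exchangeable is the standard family-data choice; the
sandwich protects against its misspecification. With singleton clusters the
fit reduces *exactly* to OLS with HC0 robust errors, which is the
independent oracle used in the tests.

**Small-sample inference.** The reported standard error is the classical
sandwich (that is the module contract, and the singleton-cluster HC0
identity pins it). P-values, however, are computed from the Mancl–DeRouen
bias-corrected sandwich referred to a $t$ distribution with
(clusters − parameters) degrees of freedom. With 50–150 pedigrees the plain
sandwich-normal Wald test is well calibrated at $\alpha = 0.05$ but inflates
the far tail severalfold — and genome-wide (Bonferroni-scale) thresholds
live four standard deviations out. This is a deliberate design choice,
validated by the null simulations in the test suite.

## Multiplicity: effective number of independent tests

Overlapping windows make neighbouring tests almost perfectly dependent, so
raw Bonferroni over all windows would be absurdly conservative. Per
chromosome $j$, with $\lambda_{i,j}$ the eigenvalues of the correlation
matrix of window intensities across individuals,

$$n_{e,j} = n_j - \sum_i I[\lambda_{i,j} > 1]\,(\lambda_{i,j} - 1),$$

which equals $n_j$ for independent windows and 1 for perfectly correlated
ones; the genome-wide threshold is $\alpha / \sum_j n_{e,j}$ with
$\alpha = 0.05$. Zero-variance windows are excluded from the matrix (and
from $n_j$) with a logged count; rows are complete-case per chromosome so
the matrix stays positive semi-definite; tiny negative round-off eigenvalues
are clipped at zero. Closed-form cases (identity, rank-1, equicorrelation)
anchor the tests.

## Methylation arm

Beta values are clamped to $[10^{-6}, 1 - 10^{-6}]$ (the M-value transform
$M = \log_2 \beta/(1-\beta)$ is unbounded at the ends). Infinium type-II
probes have a compressed dynamic range relative to type-I probes, so before
any analysis each sample is normalized by beta-mixture quantile
normalization: a 3-state beta mixture (unmethylated / hemimethylated /
methylated) is fitted to each probe type by EM, each type-II probe is
assigned its maximum-posterior state, outer-state values are mapped onto the
corresponding type-I component by the probability integral transform
($\beta' = F^{-1}_{I}(F_{II}(\beta))$), and the intermediate stretch is
carried by a monotone affine bridge between the two transformed boundaries —
a documented simplification of the original method's conformal intermediate
map. Type-I values pass through bitwise unchanged; within-type rank order is
preserved by construction of the piecewise-monotone map.

EM details: deterministic tertile initialization (reproducibility without
seeds inside a normalization step); exact M-steps via the beta sufficient
statistics $\sum w \log x$, $\sum w \log(1-x)$ (BFGS with analytic
gradients, so each M-step is O(1) in the data); convergence at a
log-likelihood gain below $10^{-6}$ or 500 iterations; a component whose
weight collapses below $10^{-4}$ *or* whose mean lands within 0.1 of a
neighbour triggers a flagged refit with one fewer state (states closer than
that are not distinguishable states of a methylation profile). A sample
whose fit fails is passed through unnormalized with a warning.

The methylation response is the element-wise M-value change, visit 4 minus
visit 2; normalization is applied per visit and per sample. For a selected
window, cis CpGs default to the window span ± 1 Mb (gene models are external
data; the window-span rule is self-contained and configurable); everything
else is trans, tested with the same GEE contract and Bonferroni-corrected
over the number of CpGs actually tested — the conservative default where the
motivating analysis names no specific correction.

## The synthetic cohort

The generator emulates the *structure* of a family-based pharmacogenomics
cohort, not its LD or its biology:

* **Pedigrees** — by default 60 independent families of ~5 members (two
  founders, 2–4 children, and with probability 0.4 a married-in founder and
  grandchildren), giving three generations.
* **Genotypes** — founder haplotypes drawn per SNP as Bernoulli(frequency)
  with frequencies uniform on [0.01, 0.5]; offspring by Mendelian gene
  dropping with unlinked SNPs (no LD, no recombination map). Two chromosomes
  of 2,000 SNPs over 60 Mb by default, so the whole pipeline runs in
  minutes.
* **Planted ROH** — segments (default one 10 Mb segment in 10% of samples)
  imposed post hoc by setting carrier genotypes to the homozygote of the
  more frequent allele; this gives direct control of segment length and
  carrier set for recovery tests, which consanguineous-mating simulation
  would not.
* **Phenotype** — the treatment effect per sample is
  $\delta = \beta_0 + \beta_{HD} T + \text{covariates} + b_{family} +
  \varepsilon$, added to post-treatment visits on top of a lognormal
  baseline with visit-level noise. The true dose $T$ is the
  *tricube-weighted homozygosity over a 3 Mb effect window* at the segment
  centre: the planted effect is a window-level effect, and defining its dose
  at segment scale (10 Mb) while testing at window scale (~3 Mb under
  default settings) would build errors-in-variables attenuation of roughly
  15% into the world by construction. With the window-scale dose the GEE
  recovers $\beta_{HD}$ essentially unbiasedly (mean −39.3 for −40 across 50
  seeds in the acceptance suite). Defaults: $\beta_{HD} = -40$ mg/dL per
  unit intensity, family SD 20, residual SD 30, visit SD 5, 5% missing
  post-treatment visits.
* **Methylation** — per CpG a state from a 3-state mixture
  (Beta(2,20)/Beta(5,5)/Beta(20,2), weights 0.45/0.10/0.45) and a probe type
  (70% type II); the type-II bias is an affine compression of the M value
  toward 0 by factor 0.7 — mimicking the reduced dynamic range the
  normalization corrects, without claiming this is the physical mechanism.
  Cis-linked CpGs sit in the central third of the effect window and shift
  their visit-4 M value by (effect × true intensity), default 1 M-unit per
  unit intensity with 0.2 SD visit noise.

What a green test therefore establishes: the estimator, the GEE inference,
the multiplicity formula and the normalization behave correctly on data with
the declared family structure, planted signals and noise levels. What it
does not establish: behaviour under real LD, real MAF spectra, batch or
cell-composition effects (explicitly out of scope), or the original study's
specific findings, whose data are controlled-access.

## Numerical and policy choices, in one place

* Internal coordinates 1-based inclusive; BED export 0-based half-open.
* Genotype codes count a2/ALT alleles; multi-allelic and non-SNP VCF records
  dropped with a logged count; duplicate positions dropped.
* GEE: moment estimator for the exchangeable correlation (clamped to keep
  the closed-form inverse valid), GLS iterations to $10^{-10}$, cap 50.
* `effective_tests`: symmetric eigensolver, eigenvalues only.
* Quantiles: type 7 everywhere.
* Determinism: every simulation entry point derives its own seed from the
  config seed and a stage tag; equal config + seed means byte-identical
  result files (fixed-format TSV writers).
* One acceptance property sits on its own boundary: under perfectly
  calibrated p-values the probability of zero Bonferroni hits among 1000
  independent null tests is $e^{-0.05} = 0.9512$, so "clean in ≥ 95% of
  seeds" can fail by Monte-Carlo noise alone; the test suite documents this
  where it applies.

## Limitations

Unlinked-SNP simulation makes windows less correlated than on a real array,
so synthetic effective-test counts are closer to the raw window count than
they would be with LD. The locus-weight and kernel forms are declared
defaults for an estimator family whose original software does not publish
its exact internals. The meQTL arm tests only declared windows, not all
window-CpG pairs. Mixed-model (kinship) association, batch correction and
cell-type deconvolution are out of scope.
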