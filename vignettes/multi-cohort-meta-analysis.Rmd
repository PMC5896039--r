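---
title: "Multi-cohort metagenomic meta-analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort metagenomic meta-analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metameta)
```

## The problem

Case-control shotgun-metagenomic studies of the gut microbiome — here the
motivating setting is colorectal cancer (CRC) versus healthy controls —
often disagree across populations: taxa flagged in one cohort fail to
replicate in another because of cohort-specific ecology, technical
differences, and limited per-cohort sample sizes. metameta implements a
meta-analytic pipeline for species-level count tables from several such
cohorts: it removes species whose direction of change is inconsistent
across cohorts, aggregates the remaining evidence with a non-parametric
rank-sum statistic, controls significance with a permutation-based
estimated percentage of false positives (pfp), adjusts for measured
confounders such as age, and carries the resulting marker species into
co-occurrence network and classification analyses.

All statistics are exercised on synthetic data generated by the package
itself, so every pipeline property asserted by the test suite is computed,
not quoted.

## The core statistic: pairwise fold-change rank sums

Within each cohort, every case-control pair of samples yields a per-species
fold change of pseudocounted relative abundance. Species are ranked within
each pair — rank 1 is the most case-enriched species — and the statistic
for a species is the sum of its ranks over all pairs and all cohorts. A
species consistently enriched in cases accumulates small ranks in every
cohort, so small sums indicate consistent enrichment; the depletion
statistic uses the reversed ordering. Ranks are dimension-free, which is
what makes the statistic robust to the non-normality and overdispersion of
microbiome relative abundances and lets cohorts of different depths be
summed directly.

Significance is assigned per rank position rather than per test: case and
control labels are permuted within each cohort, the full statistic is
recomputed, and the species at observed rank $r$ with statistic $s$ gets

$$\mathrm{pfp}(r) = \frac{\mathbb{E}\,\#\{\text{null statistics} \le s\}}{r},$$

capped at 1 and monotonised to be non-decreasing along the ranked list.
This is an expected false-discovery count per selected set, so thresholding
at pfp < 0.01 bounds the expected fraction of false positives among the
selected species. Enrichment and depletion lists are computed and
thresholded separately.

Two rank layouts exist in the literature: summing ranks over all pairwise
fold changes, or ranking per-cohort summaries first. Both reduce to the
same within-cohort aggregation when only one cohort is supplied; the
pairwise layout is the default because it weighs each cohort by its pair
count and needs no per-cohort summary statistic. When a cohort's pair count
exceeds `pair_cap` (default 2000) a seeded random subset of pairs is used;
at the default cohort sizes this changes power by well under one Monte
Carlo standard error while bounding cost for arbitrarily large cohorts.

## Divergence filtering

Before meta-analysis, species whose evidence is structurally inconsistent
are removed, in this precedence order: (1) species below an abundance or
prevalence floor; (2) species entirely absent from at least one cohort;
(3) species with a *balanced* direction split — as many cohorts with a
positive median-based change as negative among the non-zero directions
(2-2 in the four-cohort design); (4) species where at least one cohort
changes *significantly* (Mann-Whitney p < 0.05) against the strict majority
direction. A 3-1 split whose minority cohort is not significant is kept:
the filter targets contradictory evidence, not unanimity. The outcome is
invariant to cohort order, and the per-species filter status is reported so
removals are auditable.

## Confounder handling

Covariates are screened per cohort (Welch t-test for continuous, chi-square
for categorical covariates against case/control status). For a flagged
covariate $X$, each associated species' abundance is regressed as
$\log y_i = \beta_0 + X_i \beta_1$ and adjusted to
$y_i' = y_i \exp(-X_i \beta_1)$, which removes the covariate's
multiplicative effect from every abundance ratio:
$y_i'/y_j' = (y_i/y_j)\exp(-(X_i - X_j)\beta_1)$. The identity is exact and
is asserted to $10^{-12}$ in the tests. Per-cohort significance of
individual species is additionally assessed with a stratified (van Elteren)
Mann-Whitney test, combining stratum-wise centred rank sums with weights
$1/(n_s + 1)$ over (by default) four quantile bins of the covariate — with
one stratum it reduces exactly to the standard normal-approximation
Mann-Whitney test.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume: a
four-cohort design with control x case sizes 52x48, 63x46, 92x73 and 64x88
(526 samples), per-cohort read depths equal to each cohort's rarefied
minimum (2,419,973; 1,596,424; 1,222,507; 856,204), roughly 994 species,
and counts drawn from a Dirichlet-multinomial: sample compositions are
Dirichlet with concentration $\alpha = \pi(1-\theta)/\theta$ around a base
composition $\pi$, then reads are multinomial at the cohort depth. Fifty
effect species are spiked multiplicatively in cases (fold changes 1.1, 1.2,
1.4 correspond to 10/20/40% shifts) and the case composition is
renormalised, so the closure constraint deflates non-spiked species
slightly — accepted as compositional reality.

Two generator parameters are not identified by any published value and had
to be fixed by design:

* **Base composition.** $\pi$ is drawn from a log-normal rank-abundance
  profile with $\sigma = 2$, giving the heavy-tailed curve typical of gut
  communities (a few dominant species, a long rare tail).
* **Overdispersion and spike placement.** Statistical power at a fixed fold
  change is governed almost entirely by $\theta$ and by where in the
  abundance distribution the effect species sit — rare species drown a 20%
  shift in Dirichlet noise regardless of sample size. The package defaults,
  $\theta = 10^{-4}$ with effect species drawn uniformly from the upper
  half of the base-abundance distribution, were calibrated once so that the
  simulated study reproduces the published operating point of this design —
  meta-analysis power near 0.88 and single-cohort power near 0.5 at a 20%
  fold change — and then frozen. The same frozen settings also reproduce,
  without further adjustment, the null baseline (recovery 50/994 at fold
  change 1.0), the ordering across 10/20/40% fold changes, and saturation
  at 40%. Drawing spikes from the abundant half also mirrors the analysed
  species set, which has already passed abundance and prevalence filters.
  Power is sensitive to both values; they are ordinary `dm_params()`
  arguments.

Each power replicate re-draws the base composition and the spike set, so
the reported Monte-Carlo standard errors include generator variability, not
just sampling noise. Power experiments use 20 replicates by default in the
acceptance script (SE of the meta power is about 0.01 at that size).

The generator can additionally attach an age-like confounder (cases shifted
by +8 years, matching the magnitude seen in the two confounded cohorts of
the motivating design) that multiplies affected species' compositions by
$\exp(X_i\beta_1)$; a latent multivariate log-normal layer for correlation
structure; functional-category tables with calibrated Spearman coupling to
chosen species (via the bivariate-normal relation
$\rho_s = (6/\pi)\arcsin(r/2)$); and binormal classifier scores whose
expected AUC is exact ($\Delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$).

What the generator does *not* emulate: taxonomic misclassification noise,
cohort-specific compositional signatures beyond depth differences, batch
effects, or zero-inflation beyond what the Dirichlet-multinomial itself
produces. Passing tests therefore demonstrate correctness of the statistics
under the stated model, not robustness to every artefact of real
metagenomes.

## Correlation networks

Per-cohort correlations come from SparCC, implemented from the published
algorithm: fractions are resampled from a Dirichlet posterior, the
log-ratio variance matrix $t_{ij} = \mathrm{var}\log(x_i/x_j)$ is computed,
basis variances $\omega_i^2$ are solved from the sparsity approximation,
and $\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij})/(2\omega_i\omega_j)$;
the most strongly correlated pair above 0.1 is iteratively excluded and the
system re-solved (20 outer iterations, 10 exclusion rounds, median
aggregation — the algorithm's published defaults). If exclusions would
leave a species with fewer than three retained partners the estimator falls
back to the no-exclusion solution with a warning. Setting
`resample = FALSE` uses observed fractions directly, which is deterministic
and exactly invariant to per-sample count scaling (the resampled version is
invariant only approximately, since the Dirichlet posterior sharpens with
depth). Pair significance uses the permutation scheme from the original
method: each species' counts are permuted independently and the two-sided
p is `(1 + hits) / (n_perm + 1)`.

Cohort correlation matrices are combined by the fixed-effect Fisher r-to-Z
rule with weights $n_k - 3$ — the convention of correlation meta-analysis —
and pairs with combined p < 0.05 become edges weighted by $|\bar r|$.
Connectivity metrics follow the definitions used in this literature:
weighted degree centrality $\sum_j w(i,j)$; global efficiency
$E_\mathrm{global} = \tfrac{2}{n(n-1)}\sum_{i \ne j} 1/d(i,j)$ with $d$ the
shortest-path hop count on the significant-edge graph and $1/d = 0$ for
disconnected pairs (a complete graph scores exactly 1; a 1/w-weighted
variant is available); and weighted connectance
$\sum_{i \ne j} w(i,j)/n^2$ summed over *ordered* pairs, the convention
that matches the $n^2$ denominator. Robustness curves remove nodes in
descending centrality order against a random-order baseline. Networks
export to GraphML and edge-list TSV for external visualisation.

## Classifier evaluation

The classification harness evaluates a radial-kernel SVM (cost 1, inverse
bandwidth from the median heuristic; both configurable — no published
values exist for them) under two schemes. Stratified k-fold
cross-validation standardises and median-imputes features with
training-fold statistics only; the pooled out-of-fold AUC is the headline
summary, with per-fold AUCs also reported, since "average AUC" is ambiguous
between the two. Leave-one-cohort-out repeats the *entire* marker-selection
path — divergence filter, rank-sum meta-analysis, pfp selection — on the
training cohorts alone before scoring the held-out cohort, which is what
makes it a leakage test: a signal present in only one cohort yields
held-out AUC near 0.5, and the test suite asserts exactly that. AUC is the
Mann-Whitney statistic with ties counted one half; the optimal F1 scans
every distinct score threshold. The accuracy-paradox simulation draws
binormal scores at fixed AUC 0.80 for a balanced (271/255) and an
imbalanced (271/30) design and compares optimal-F1 distributions over 500
simulations — the imbalanced median is lower although the AUC is identical.

## Functional association

Category tables are normalised to copies per million. Differential
categories per cohort use the stratified Mann-Whitney test with one-sided
p-values oriented by the consensus direction (majority sign of per-cohort
median differences); cohort p-values are combined by MaxP, with combined
$p = (\max_k p_k)^K$, exact for independent uniforms — a deliberately
conservative rule that calls a category only when every cohort agrees.
Species-category association uses Spearman correlation on average ranks
with the t approximation and BH adjustment across all tested pairs;
significant positive associations are grouped into pathways, keeping
pathways with at least two associated categories.

## Numerical choices and degenerate inputs

* Pseudocount 0.5 reads per cell before normalisation (configurable)
  defines fold changes in the presence of zeros.
* Ties always use average ranks; the AUC counts ties one half.
* All-zero species get direction 0 and p = 1 rather than an undefined test.
* Constant covariates, zero-variance regressors, one-class folds, zero CPM
  columns and non-PSD latent correlation matrices raise warnings or errors
  naming the offending sample, stratum or eigenvalue.
* SparCC estimates are clipped to [-1, 1]; exactly +/-1 correlations are
  rejected by the Fisher-z combiner (infinite transform) and should be
  clipped slightly inside the boundary first.
* Every stochastic function takes a `seed`; identical seeds give
  byte-identical outputs.

## Problem sizes used by the tests

The acceptance checks run the full four-cohort design (994 species, 526
samples, pair cap 2000) with 20 replicates at fold change 1.2 and 5-6
replicates at 1.0/1.1/1.4; pfp null calibration uses 100 runs of a reduced
design (100 species, two cohorts of 20v20, 20 permutations), chosen so the
whole suite completes in a few minutes while keeping Monte-Carlo error well
inside the asserted tolerances. The same trade-off is documented per test.

## Known limitations

* The rank-sum statistic assumes exchangeable pairs within cohorts; heavy
  pair subsampling below ~500 pairs per cohort adds visible Monte-Carlo
  noise to the statistic.
* pfp is an expected-false-positive rate per rank, not a per-species FDR;
  it is only as good as the within-cohort permutation null.
* The MaxP exponent assumes independent cohorts; shared technical artefacts
  across cohorts would make it anti-conservative.
* SparCC's sparsity assumption fails for densely correlated communities;
  with very few species (< ~10) the basis solve absorbs real correlation
  into the variances and estimates shrink toward zero.
* The generator calibration reproduces the published power operating point
  under one plausible parameterisation; other (theta, spike-placement)
  pairs could do the same, and real-data power may differ from both.
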