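---
title: "Associating the gut microbiome with a continuous host phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associating the gut microbiome with a continuous host phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtrait)
library(dplyr)
```

`microtrait` implements a complete analysis path from a rarefied 16S OTU
count table and a sample sheet to (i) per-taxon association statistics with
a continuous host phenotype such as weaning weight, (ii) a co-abundance
network over the associated taxa, and (iii) an estimate of how much
phenotypic variance the microbiome explains. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the bundled simulator does and does not emulate, and the numerical choices
made where the design was open.

## Preprocessing

Counts are first **rarefied**: each sample's tags are subsampled without
replacement (multivariate hypergeometric) to a common depth, 40,000 by
default, matching typical 16S library normalization. Samples below the
depth are dropped with a warning. Rarefaction equalizes the sampling effort
that downstream presence/absence calls implicitly depend on; its cost is
discarding reads, which we accept for comparability.

OTUs are then **filtered**: a taxon is kept when its *mean* relative
abundance across samples is at least 0.05% *and* it is detected in at least
5% of samples (both inclusive). The abundance summary is the mean because
that is the common microbiome-QC convention; a `max` variant is available
via `abundance_stat`. Retained abundances are deliberately *not*
renormalized, so "0.05%" keeps its meaning as a fraction of the whole
community. The prevalence denominator is the number of samples actually
analyzed (after rarefaction drops), not the nominal cohort size.

The **phenotype** is residualized on sex and cage by ordinary least squares
with both covariates as fixed categorical effects (a single-level term is
dropped, degenerating to centering). Residuals are mean-zero and orthogonal
to the design, and all association stages work on them. Two consequences
are worth knowing. A cage with one sampled animal gets residual zero: that
sample carries no association information afterwards. And with many small
cages the adjustment also absorbs part of any true microbial signal (for
two-animal cages roughly half); this is inherent to fixed-effect
residualization with near-saturated designs, and it is why power
simulations in the test-suite use fewer, larger cages.

## The two-part association model

Relative abundances are zero-inflated and far from normal, so each OTU is
tested in two parts:

* **Binary component** — OLS of the adjusted phenotype on the
  presence/absence indicator (equivalent to a pooled-variance two-sample
  t-test). The slope $\beta_1$ is the weight difference, in grams,
  attributable to carrying the taxon. Undefined when either carriage group
  has fewer than `min_group = 5` samples.
* **Quantitative component** — restricted to carriers, OLS of the adjusted
  phenotype on the natural log of relative abundance, standardized to mean
  0 / SD 1 within the carrier subset, so $\beta_2$ is grams per SD of log
  abundance. Undefined below `min_present = 10` carriers or at zero
  variance. A rank-based inverse-normal transform is available.
* **Meta-analysis** — the unweighted-Z combination
  $z_{meta} = (z_1 + z_2)/\sqrt{2}$ of the two signed z-scores, defined when
  both components are.

The final p-value is the minimum over the defined components. That min-P
combination is anticonservative under the null (the package's own null
simulations put the fraction of $p_{final} < 0.05$ near 0.10), which is why
significance is *never* declared on nominal p-values but through
**permutation FDR**: the adjusted phenotype is permuted across samples
(preserving the inter-OTU correlation structure), the full scan is re-run
per permutation (1000 by default), and for each observed threshold $t$ the
FDR estimate is the mean null count of $p_{final} \le t$ divided by the
observed count, monotonized step-up and capped at 1. OTUs whose model was
undefined are reported with $q = 1$: they were never tested and can never
be discoveries, which also gives the degenerate constant-phenotype case the
sensible "everything saturates at 1" behavior.

`min_group` and `min_present` are pragmatic defendedness thresholds, not
statistical optima; OLS on a handful of points is meaningless. The p-value
floor is $10^{-300}$, purely to avoid underflow in the z-conversion.

## Co-abundance network and CAGs

Correlation among the FDR-significant taxa is estimated with **SparCC**,
which corrects for the closed-sum distortion of compositional data: per
inner repetition (20 by default) counts are perturbed to fractions by a
Dirichlet draw (pseudocount 1), log-ratio variances
$t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$ are formed, and basis variances are
solved from the sparsity-assuming linear system; correlations follow as
$r_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to $[-1, 1]$. The single most strongly correlated pair above 0.1 is
iteratively excluded from basis estimation (20 iterations by default) and
the reported matrix is the median over repetitions. Two caveats matter in
practice: the method assumes most pairs are uncorrelated, so dense
correlation structure (more correlated pairs than the exclusion budget)
biases the estimates — raise `n_exclude_iter` when analyzing panels where
many taxa co-vary; and fewer than 4 taxa leave the basis system
underdetermined, so the network stage requires at least 4 significant OTUs.
Non-positive basis variances (possible on heavily zero-inflated panels) are
clipped with a warning.

Significance of each correlation comes from a **bootstrap** that shuffles
each OTU's counts independently across samples, destroying association
while preserving marginals; the two-sided add-one pseudo-p has minimum
$1/(n_{boot}+1)$, so the default 100 bootstraps support the edge threshold
p < 0.05 comfortably. Edges are kept at p < 0.05 and |r| > 0.4 (both
strict), matching common practice for SparCC networks.

Taxa are clustered into **co-abundance groups** on the distance
$d_{ij} = (1 - r_{ij})/2$ (mapping correlations into $[0,1]$) with Ward
linkage (`hclust` method `ward.D2`, the Ward criterion on distances), cut
at $k = 2$ by default; labels are renumbered so CAG 1 holds the
lexicographically smallest OTU id, making output deterministic. The chosen
$k$ is validated by a hand-rolled **PERMANOVA** (pseudo-F from squared
distances, 999 label permutations, add-one p); the implementation is
cross-checked against `vegan::adonis2` in the test-suite. Note that the
permutation p-value is granular: with $n$ objects in two groups of $n/2$
only $\binom{n}{n/2}$ distinct splits exist, so very small panels cannot
reach very small p-values regardless of separation.

Per-sample CAG abundance is the *sum* of member relative abundances; the
mean would be a monotone rescaling and leaves the Spearman correlation with
the phenotype (BH-corrected across CAGs) unchanged.

## Functional-feature screen

Predicted functional profiles (KO or pathway relative abundances) are
consumed as plain samples-by-features tables — the prediction itself
depends on reference databases and is out of scope. Each feature is tested
with Spearman's rho (average-rank ties, asymptotic two-sided p) against the
adjusted phenotype; q-values are Benjamini–Hochberg, and the significant
set requires q < 0.05 *and* |rho| > 0.3. BH was chosen over permutation FDR
here as the standard choice for a plain correlation screen.

## Microbiome-explained variance

The contribution of the microbiome to the phenotype is estimated by
repeated cross-validation: per repeat (100 by default) the samples are
split 80/20; the two-part scan runs on the discovery set alone; at each
p-value threshold (default grid $10^{-5}, 10^{-4}, 10^{-3}, 10^{-2}, 0.05,
0.1$, spanning the usual range log-uniformly) the OTUs with
$p_{final} \le t$ (nominal, pre-FDR) are selected and an **additive model**
predicts each validation sample:

$$r_m = \sum_j \left(\beta_{1j}\, b_j + \beta_{2j}\, q_j\right)$$

with $b_j$ the presence indicator, $q_j$ the log abundance standardized by
the *discovery* location and scale (0 when absent), and undefined
components contributing 0 — no information flows from validation samples
into selection, effect sizes or transforms. The explained variance is the
squared Pearson correlation between $r_m$ and the adjusted phenotype over
validation samples (0 when $r_m$ is constant), averaged over repeats.

An alternative reading of the additive formula, $\sum_j (\beta_1 + b_j +
\beta_2 q_j)$, is available behind `literal = TRUE` in
`additive_predict()` for auditability. It is *not* equivalent in general —
it discards the $\beta_1$ weighting of the binary term — and coincides (up
to an affine map, hence in $R^2$) only when all selected $\beta_1$ are
equal; the test-suite pins down both facts. The weighted product form is
the package's estimator.

Two properties of this estimator deserve emphasis. It is *optimistic* at
lax thresholds in small panels, because falsely selected OTUs inject noise
into $r_m$; and it is *attenuated* when true effects are weak, because
selection misses them and estimated effect sizes shrink toward noise. The
recovery simulations in the test-suite (30% planted heritability recovered
as roughly 0.15–0.35 across cohorts of n = 200 with 20 repeats) quantify
the combination.

## The synthetic-data generator

`simulate_microbiome()` generates the structure every stage assumes: per
sample, log basis abundances from a multivariate normal with configurable
correlation (see `block_correlation()`), exponentiated, masked by per-OTU
Bernoulli presence indicators (structural zeros, so binary ground truth is
well-defined), closed to fractions and counted multinomially at a fixed
depth — i.e. an already-rarefied table. The phenotype adds a grand mean
(500 g), a sex effect (30 g), cage intercepts (SD 40 g over 90 cages of
1–2 animals by default, mirroring a weaning cohort of 135), planted OTU
effects ($\beta_1$ per presence, $\beta_2$ per SD of log basis abundance
among carriers) and Gaussian noise (SD 50 g). `presence_groups` lets
planted taxa share their presence draws, emulating co-occurring guilds —
the structure real co-abundance groups show, and the only way ten planted
taxa can each carry a large marginal effect without their summed variance
exceeding the phenotype's.

What the simulator does *not* emulate: taxonomic structure, over-dispersion
beyond the lognormal-multinomial, sequencing error, cage-shared microbiota
(masks are independent of cage), or any relation between abundance and
detection efficiency. Passing recovery tests on these data therefore show
the estimators do what they claim under their own assumptions — not that
real cohorts satisfy those assumptions.

`simulate_features()` draws feature tables with approximately requested
Spearman correlations to the phenotype through a Gaussian copula
(Pearson $= 2\sin(\pi\rho_s/6)$ on the latent normals).

## Determinism and problem sizes

Every stochastic function takes a `seed` and isolates its RNG use
(`withr::with_seed`), so identical calls are bit-identical and the
pipeline's per-stage seeds (master seed plus a fixed per-stage offset) make
`run_pipeline()` reruns byte-identical, timings aside. The test-suite runs
its simulations at the cohort scale the package targets (135–200 samples,
panels of 30–500 OTUs, 100–200 permutations, 20 cross-validation repeats,
100 SparCC bootstraps), sizes chosen so the full suite completes in about a
minute on a single core while keeping every statistical check at realistic
dimensions.

## Worked example

```{r example, eval = FALSE}
eff <- data.frame(otu = 1:10, beta1 = c(rep(20, 5), rep(-20, 5)), beta2 = 0)
sim <- simulate_microbiome(n_samples = 135, n_otus = 300, depth = 40000,
                           n_cages = 15, effects = eff,
                           presence_groups = list(1:5, 6:10), seed = 1)

res <- run_pipeline(sim$counts, sim$metadata, out_dir = "run",
                    params = pipeline_params(n_perm = 300, cv_repeats = 20),
                    seed = 1)
res$manifest$n_otus_significant
autoplot(res$variance)
autoplot(res$network)
```

## Known limitations

* Fixed-effect cage adjustment wastes singleton cages and halves pair-cage
  signal; a mixed-model alternative is not implemented.
* SparCC assumes sparse correlation; dense panels need a larger exclusion
  budget and remain biased beyond it.
* The additive prediction ignores co-selection redundancy: correlated
  selected OTUs are double-counted, which rescales $r_m$ (harmless for
  $R^2$) but makes its absolute scale uninterpretable.
* Permutation FDR calibrates the min-P anticonservatism but inherits the
  granularity of the permutation count.
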