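---
title: "Models and methods behind grnvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grnvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

grnvar analyses naturally occurring gene-expression variation measured
across a developmental gene regulatory network in a North Carolina II
(NCII) breeding design, and relates that variation to downstream gene
expression and to larval skeletal morphology. This vignette explains the
models, the tunable parameters, the synthetic-data generator that the
package's tests run against, and the numerical and design choices that
were genuinely open.

## The NCII variance model

Each gene × time point response (relative transcript abundance per
culture, after background correction and division by a reference gene,
see `normalize_to_reference()`) is decomposed as

$$y_{ijk} = \mu + d_i + s_j + u_{ij} + e_{ijk},$$

with dam effects $d_i \sim N(0, \sigma^2_D)$, sire effects
$s_j \sim N(0, \sigma^2_S)$, family interactions
$u_{ij} \sim N(0, \sigma^2_{DS})$ and residuals
$e_{ijk} \sim N(0, \sigma^2_E)$; $k$ indexes replicate cultures. In a
half-sib design the sire component estimates a quarter of the additive
genetic variance ($V_A = 4\sigma^2_S$), because sperm transmit essentially
only genes; the dam component additionally absorbs non-genetic maternal
contributions such as egg provisioning, which is why the dam-sire
*contrast* is informative about maternal effects.

The model is fitted by a Gibbs sampler (full conditionals: normal updates
for $\mu$ and each effect batch, inverse-gamma updates for each
variance), implemented in C++ for speed. Rationale for a Bayesian fit
rather than ANOVA: samples can be missing per gene × time, leaving an
unbalanced design which the conditional updates tolerate naturally, and
posterior credible intervals for small-sample variances are positive and
asymmetric where asymptotic intervals are not. Gene × time combinations
with fewer than 20 above-background samples are refused
(`expressed_filter()`), since six dams and six sires cannot support
variance estimation with less.

Priors are inverse-gamma on every variance, shape 1.002 (diffuse), with
the scale set per response so the prior *mode* equals
$(0.1\,\bar y)^2$ — i.e. centred at a 10% coefficient of variation. The
centring CV and the shape are `chain_control()` parameters. Default
chain: 13,000 iterations, 3,000 burn-in, thinning 10 (1,000 kept draws);
effective sample sizes are computed from the initial positive sequence of
autocorrelations and chains with min ESS below 100 are flagged. Every
chain is seeded from a named substream of the run seed, so results do not
depend on fit order.

Consequence of the prior worth knowing: for a response with *no* variance
to explain, the variance posteriors collapse to the prior's lower tail,
i.e. scaled values near the prior CV² (0.01), not to exactly zero.

Term significance uses DIC (deviance information criterion,
$\mathrm{DIC} = \bar D + p_D$) comparisons between the full model and the
model dropping one term; the default ΔDIC threshold is 2, the
conventional "positive evidence" cut, and is configurable because DIC
thresholds are not canonical. An expected-mean-squares estimator
(`ncii_moments()`, built on `aov`) provides an independent
method-of-moments cross-check of the Gibbs posterior means; the two agree
to rank correlation > 0.95 in the recovery tests.

Breeding values are posterior means of the parental effects, centred
within role. The per-time G-matrix is estimated over genes from those
breeding values with parents as observations (a 6 × 6 cross cannot
support pairwise REML genetic covariances), its structure summarized by
the variance of eigenvalues normalized to proportions — 0 for an
isotropic matrix, large when one direction dominates — against a null
that permutes each gene's breeding values across parents independently
(within role), destroying cross-gene covariance while preserving each
gene's margin.

## Cross-gene tests

* `maternal_vs_paternal_test()`: paired Wilcoxon signed-rank of scaled
  dam vs sire components across genes at one time point. One-sided by
  default (dam exceeding sire is the maternal signature); after zygotic
  genome activation the two should be exchangeable.
* `parental_effect_trend_test()`: Kruskal–Wallis across time points of a
  per-gene parental measure (default the additive variance
  $2(\sigma^2_D + \sigma^2_S)$ on scaled components) plus an
  early (t1–2) vs late Wilcoxon; optionally restricted to genes at the
  time points where the network marks them active.
* `parental_effect_correlation()`: Spearman correlation of dam vs sire
  magnitudes across genes — low when an extra maternal channel decouples
  the two, higher under purely zygotic transcription.

## Edge analysis

Correlations are computed on family means (replicates averaged) at a
single time point, matching the per-culture resolution of the morphology
analyses; lagged cross-time correlations are out of scope, which is also
why self-loops are excluded at network curation.

`interactor_vs_random_test()` compares the mean r² over edges active at a
time point with a null that rewires the same number of edges onto active
gene pairs with *no known interaction at any time point* (a conservative
background, since unknown true edges can only dilute it). "Topology
intact" is interpreted as preserving the out-degree sequence and the
in-degree multiset by shuffling target stubs, with rejection of
self-pairs and known pairs and a per-edge uniform fallback; a plain
fixed-count uniform rewiring is available (`mode = "uniform"`). All
permutation p-values use the add-one rule $(b+1)/(n+1)$ and are never 0.
With few active genes the rewired means are all drawn from one small pair
pool and are therefore strongly inter-correlated, which makes the test
slightly anticonservative; its empirical size at nominal 0.05 is ~0.06
with 16 rewireable edges over a 32-gene pool (the calibration tests run
at that scale) and grows as the pool shrinks.

`classify_edge()` regresses target on source family means: a significant
slope (two-sided p below `alpha`, default 0.01) marks the interaction
`sensitive` (quantitative), otherwise `insensitive` (switch-like); fewer
than 5 usable family means leaves it unclassified, and unclassifiable
edge × times are excluded from (not imputed into) the trend test, which
is a plain contingency chi-square without continuity correction. A
property of the design worth knowing: when *both* genes carry parental
(dam/sire block) structure, the OLS t-test's nominal df overstates the
information content of 36 family means, so structured-but-independent
pairs are labelled sensitive more often than `alpha` (about 0.10–0.15
under the preset's late-time parental variances). The calibration target
of the classifier — type-I error equal to `alpha` — is defined for an
unstructured (pure-noise) target, where it holds exactly; the reference
preset's edge-kind mix was chosen with the structured false-positive rate
included so the *classified* fractions land near one third early and two
thirds late.

`paternal_by_class_test()` compares scaled sire components of source
genes upstream of insensitive vs sensitive interactions
(Kolmogorov–Smirnov), with a time-adjusted version from a linear model
including a time-point factor. `tissue_composition_test()` checks the
within-tissue mean pairwise correlation against equal-sized random gene
sets, the control for brood tissue-composition artifacts; tissues with
fewer than two annotated genes are skipped.

## Morphology

Eight 3-D landmarks define six inter-landmark rod lengths (µm), invariant
under rigid motion; the landmark-pair table is configurable because
landmark schemes are lab-specific. PCA of per-culture mean rod lengths
uses the covariance matrix (all measures share µm; correlation mode is a
flag). Parental effects on PC scores come from
`lmer(score ~ (1|dam) + (1|sire) + (1|dam:sire))` with LRTs of dropped
terms; because the null (variance 0) lies on the boundary, p-values use
the 50:50 chi-square mixture (naive chi-square(1) p halved).

The gene screen correlates each gene × time × leading-PC triple over
cultures (Pearson), with Benjamini–Hochberg adjustment across all tests
by default (Bonferroni/Holm available). The maternal-conditioned test
fits `score ~ dam + expression` and rejects the maternal-only hypothesis
when the expression coefficient is significant at 0.01. Two inferential
caveats are built into its design: observations are collapsed to family
(dam × sire) means first, because replicate cultures share their
family-level expression and morphology and culture-level fitting would
double the apparent df; and with only six sires, a gene whose variation
is strongly sire-structured can show chance within-dam alignment with
morphology (effective df near the number of sires), so the dam-only
conditioning is calibrated for maternal-vs-rest questions, not a
substitute for a full two-parent model.

## Two-block PLS

The expression block (one column per active gene × time, `gene@tN`) and
the skeletal block (per-culture mean rods) are centred; expression
columns are standardized to unit variance because the two blocks have
incommensurate units, skeletal columns stay in µm (both choices are
flags). The cross-covariance matrix is decomposed by SVD; each singular
pair maximizes cross-block covariance subject to orthogonality, and the
number of pairs is capped by the skeletal block (six). Factors are
oriented so the largest-magnitude skeletal loading is positive, since
singular-vector signs are arbitrary. "Eigenvalue" weights are normalized
squared singular values (sum 1). The RV coefficient
$\mathrm{tr}(X'YY'X)/\sqrt{\mathrm{tr}((X'X)^2)\,\mathrm{tr}((Y'Y)^2)}$
is the multivariate analogue of r², invariant to rotations and global
scalings of either block; its significance comes from permuting rows of
the skeletal block (1,000 by default). Contribution scores are
weight-averaged *absolute* loadings (signed versions available), top
fractions use `ceiling(f·N)` with stable tie-break, and time-point
enrichment of a selection is a 2 × 2 chi-square (1 df, no continuity
correction). Activity information does not exist for the final sampling
time, so columns at that time are retained unfiltered when a network is
supplied.

## The synthetic-data generator

`simulate_cross()` emulates the study design with known truth:

* Cross: 6 dams × 6 sires × 2 replicate cultures, 7 time points (504
  samples); parental effects drawn once per parent per gene × time.
* Maternal latent: one scalar per dam, standardized to zero mean and unit
  variance across the dams *by construction*, loading on genes only at
  time point 1 and on all rods. Standardization makes the strength of the
  maternal condition a fixed property of the loadings rather than the
  luck of six draws.
* Network propagation: genes downstream of active edges receive the
  summed edge responses of their regulators' family means — linear
  $a + bx$ or saturating Hill $a + v_{max}x^h/(K^h + x^h)$ — centred at
  the regulator's mean so propagation moves variance, not level.
  Generation is in topological order; cyclic wiring is rejected.
  Propagation of per-culture values instead of family means is a flag.
* Morphology: per-individual rods = baseline + driver loadings × terminal
  family means + maternal loading + noise, 24 individuals per culture.
* Seeding: every component draws from a named substream of the master
  seed (scrambled through one RNG draw so related names yield
  decorrelated streams); adding genes does not reshuffle the parental
  draws, and a seed fully determines the dataset.

`sim_config_urchin()` fixes the reference condition: 74 genes in three
layers; residual CV 13% (within the 10–15% range typical of
among-family expression variation); scaled parental variances 0.07 per
parent early (t1–2) and 0.015 late, making the scaled additive variance
≈ 0.28 early vs ≈ 0.06 late; maternal loadings ~N(0.35, 0.08); edge
propagation severed at t1–2 (early transcripts are predominantly
maternal); early-window edges one-fifth linear and late-window edges
two-thirds linear, which classifies (including the structured
false-positive rate above) to roughly one-third sensitive at the first
propagated time rising to two-thirds late; slope 2 for linear edges and a
deep-plateau Hill response ($K = 0.3\bar y$, $h = 4$) for saturating
ones; one terminal gene drives the body rod plus a maternal size factor
on all rods. `sim_config_recovery()` (no network, no maternal factor,
one time point) is the variance-recovery condition, and
`sim_config_morpho()` is a 12-gene cross for replicated morphology-driver
recovery, with driver loading 70 µm per expression unit — chosen so the
driver, not the maternal size factor, dominates the morphological signal
— and a *maternal-latent-only* early gene (no parental variance at all)
as the designated negative control for the conditioned test.

What the generator does not emulate: bead-level assay artifacts and
background structure, probe-level variation, tissue-resolved expression,
cross-time persistence of parental effects (each gene × time draws
fresh), and mechanistic promoter kinetics. Passing tests therefore show
that the estimators and tests behave correctly under the design's
variance structure — not that any particular biological dataset will meet
their assumptions.

## Problem sizes and runtime choices

The test-suite and acceptance-script simulations run at the study's own
scale (6 × 6 × 2 × 7; 74 genes for preset checks) with 500–1,000
permutations per test, 200 null replicates for size calibration, 1,000
null edges for classifier calibration and 50 replicates for driver
recovery; the full pipeline run uses the default chain and 1,000
permutations throughout. These sizes give Monte-Carlo error comfortably
below every margin asserted and complete in minutes on one CPU.

## Known limitations

* Classification p-values treat family means as independent; under
  strong shared parental structure the realized type-I rate exceeds the
  nominal `alpha` (quantified above). An exact family-structure-aware
  null would require permutations within the cross design.
* The rewiring null is mildly anticonservative for very small active-gene
  pools; report it alongside the bootstrap CI of the random-pair mean.
* Dam-only conditioning cannot separate sire-structured confounding from
  true signal when the sire panel is small (six here).
* DIC-based term flags approximate, but are not identical to, the
  permutation-REML significance flags used in classical NCII analyses.
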