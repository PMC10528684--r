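---
title: "Methods: feature analysis and psychophysical validation of aesthetic image sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature analysis and psychophysical validation of aesthetic image sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesthseq)
```

## The problem

Generative models can steer an image along a scalar parameter $\alpha$ so
that, by construction, its predicted aesthetic value increases with
$\alpha$. Validating such a model and asking *what changed* in the images
requires three ingredients: behavioral evidence that human observers
prefer higher-$\alpha$ images; image-feature measurements that track
$\alpha$; and screening tools to find sequences whose behavior deviates
from the bulk (stable low-level features, or an aesthetic dip at the top
of the sequence). `aesthseq` implements this full analysis chain, driven
by a synthetic generator that emulates $\alpha$-indexed image sequences
and simulated observers, so every stage is testable without trained
network weights or human participants.

## The synthetic generator

The generator defines the study conditions; it is deliberately simple and
auditable.

**Base images** are procedural: a seeded oriented luminance gradient, 3–6
elliptical "object" blobs with independent colours, and a faint sinusoidal
texture. This guarantees every operator a nonzero dynamic range (several
distinct region intensities, colour variation, local texture) without any
learned model. Images are deterministic in `(category_id, rng_seed)`.

**The $\alpha$-transform** steers the named features of
`effect_sizes` with elementary operators, each an exact identity at
$\alpha = 0$, with channel clipping to $[0, 255]$ applied last:

* brightness — additive luma shift, `img + s_b * alpha` intensity units;
* contrast — deviations about the mean luma scaled by `1 + s_c * alpha`;
* saturation and colorfulness — a luma-preserving chroma gain: each
  channel moves away from the per-pixel luma by the factor
  `(1 + s_s * alpha)(1 + s_col * alpha)`. The two gains compound in one
  operator. We chose the luma-preserving form (rather than a
  value-preserving HSV scaling) because it leaves measured brightness
  untouched, which keeps every positive-slope feature provably
  non-decreasing in $\alpha$ on unclipped images — the key qualitative
  property of the emulated sequences;
* sharpness — an unsharp-mask blend with a $3\times3$ box-blurred copy:
  negative $\alpha$ blurs, positive $\alpha$ enhances edges.

Default slopes (brightness 60 intensity units per unit $\alpha$; contrast
1.2, saturation 0.8, colorfulness 1.0, sharpness 2.0 as relative gains per
unit $\alpha$) give changes of roughly 5–30 % of each feature's base value
at $\alpha = \pm 0.25$ — visible but far from clipping on mid-range
images. Complexity and symmetry are not transformed directly; they vary
across categories through the procedural composition.

**The $\alpha$ grid** defaults to
$\pm\{0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.0025\} \cup \{0\}$ — 15
levels, symmetric about zero with increasing density near zero, spanning
clearly discriminable to near-indiscriminable differences. The grid is
fully configurable.

**Aesthetic scores** stand in for a learned assessor with a monotone
contract only: `score = base_cat + slope * alpha + N(0, noise_sd)`, with
per-category intercepts (`N(0.5, 0.05)`), slope 1 per unit $\alpha$ and
noise SD 0.02. A *downturn* category has its top-$\alpha$ score replaced
by the second-highest level's score minus `downturn_drop` (0.05),
emulating sequences that become less attractive at the extreme despite
still-increasing low-level features. `generate_dataset()` designates
exactly `ceiling(downturn_fraction * n_categories)` downturn categories,
sampled from the master seed: an exact count, rather than independent
per-category draws, so that the realized prevalence always equals the
configured rate and screening studies have a well-defined planted set.

**Observers** follow the standard 2AFC psychometric model
$$\psi(\alpha) = \gamma + (1 - \gamma - \lambda)\,
\Phi\!\left(\frac{\alpha - \mu}{s}\right),$$
with guess rate $\gamma$, lapse rate $\lambda$, point of subjective
equality $\mu$ and spread $s$. Defaults ($\mu = 0$, $s = 0.05$,
$\gamma = 0.07$, $\lambda = 0.17$) describe an observer who agrees with
the generator about 93 % of the time at $\alpha = -0.25$ and about 83 % at
$\alpha = +0.25$ — an asymmetry typical of aesthetic (as opposed to
purely sensory) judgments. Simulated trials pair a neutral
($\alpha = 0$) image with a comparison image at a nonzero level drawn
uniformly; the comparison's screen position is a fair coin; categories
never repeat within a participant. Response times are log-normal
(median 800 ms) — only the median matters for cleaning.

**What the generator does not emulate:** semantic content, photographic
composition, inter-observer heterogeneity beyond the four-parameter
psychometric model, trial-order effects, and any dependence of the
aesthetic score on image content beyond $\alpha$. Passing tests therefore
demonstrate the correctness of the measurement and inference machinery
under the stated statistical structure — not that real images or real
observers have that structure.

## The seven feature operators

All operators work on $H \times W \times 3$ arrays with values in
$[0, 255]$ and are exactly reproducible; standard deviations are
population SDs (divide by $N$) throughout, so the documented examples are
exact.

* **Grayscale** — ITU-R 601 luma $0.299R + 0.587G + 0.114B$, kept
  real-valued.
* **Brightness** — mean luma.
* **Contrast** — population SD of luma.
* **Sharpness** — mean absolute response to the 4-neighbour Laplacian
  $[[0,1,0],[1,-4,1],[0,1,0]]$ under zero padding. The absolute value is
  essential: signed responses integrate to the boundary flux and cancel
  over interior regions.
* **Saturation** — mean of per-pixel $S = (\max - \min)/\max$ (0 when
  $\max = 0$), on $[0, 1]$.
* **Colorfulness** — Hasler–Süsstrunk: with opponent components
  $rg = R - G$ and $yb = (R+G)/2 - B$,
  $\sqrt{\sigma_{rg}^2 + \sigma_{yb}^2} +
  0.3\sqrt{\mu_{rg}^2 + \mu_{yb}^2}$.
* **Complexity** — leaf count of a quadtree decomposition of the luma
  image: a block splits into four quadrants iff its SD exceeds
  `variance_threshold` (default 25), both halved dimensions stay at least
  `min_block_size` (default 8 px) and the depth is below `max_depth`
  (default 6). Odd dimensions split floor/ceil.
* **Symmetry** — the two halves about the chosen axis (vertical by
  default; the centre row/column of odd dimensions is dropped so the
  halves are congruent) are decomposed separately and their leaf counts
  $T_1, T_2$ compared: $100\,(1 - |T_1 - T_2| / \max(T_1, T_2))$.

The quadtree defaults were chosen so that 64–256 px images produce
informative leaf counts; at very small sizes (≤ 24 px with the default
`min_block_size`) the tree cannot split and complexity/symmetry become
constant — the pipeline then drops the degenerate feature from the
regressions with a warning. Complexity is verified against an
independent brute-force oracle in the test suite.

Standardization (`standardize_features()`) offers z-scores or min–max
scaling, globally or within category; a zero-spread feature is set to 0
with a warning rather than producing NaNs.

## Behavioral analysis

**Cleaning** removes a participant when any of four rules fires, with
attribution to the first rule in this order: side bias (left-choice
proportion outside $0.5 \pm 0.25$), near-chance performance (maximum
per-$\alpha$ agreement below 0.55), fast responding (median RT below
500 ms), or fewer than 50 trials. The bias rule is read as a deviation
from 50 % by more than 25 percentage points, and the chance rule as "no
$\alpha$ level reaches 0.55 agreement"; both readings are configurable.
Cleaning depends only on per-participant summaries and is therefore
invariant to row order.

**Aggregation** produces the psychometric view (per $\alpha$, proportion
of nonneutral choices) and the folded view (per $|\alpha|$ and sign, the
proportion agreeing with the generator: choosing the nonneutral image at
positive $\alpha$, the neutral image at negative $\alpha$).

**Psychometric fitting** maximizes the binomial log-likelihood of the
choice counts in $\psi$ with $\mu$, $\log s$, $\gamma$, $\lambda$ free
($0 \le \gamma, \lambda \le 0.5$), using L-BFGS-B from three starts;
probabilities are clamped at $10^{-9}$. The inner link is the cumulative
Gaussian. Confidence intervals are percentile intervals from a seeded
parametric bootstrap (resampling counts from the fitted curve; default
999 resamples at the 99 % level, both configurable). Parameter-recovery
simulations in the test suite show mean absolute bias below 0.02 for
$\gamma$ and $\lambda$ and below 0.01 for $\mu$ at 200 trials per level.

**Polynomial agreement models** regress folded agreement on
$\{|\alpha|, |\alpha|^2, \mathrm{positive}\}$ and additionally
$|\alpha|^3$, weighted by trial count (the unit of analysis is the
aggregated per-$(|\alpha|, \mathrm{sign})$ proportion; weighting is
configurable). Squared semi-partial correlations are computed as the
$R^2$ drop when a term is removed, with case-bootstrap intervals; the
cubic term is assessed by the nested-model $F$ test. A response that is
numerically constant reports $R^2 = 0$ rather than a 0/0 artifact.

**Confound ANOVA** aggregates agreement per (category, broad group,
position) cell and fits a two-way ANOVA without interaction.

## Feature modeling

Feature–$\alpha$ profiles average z-scored features per level.
`fit_feature_regression()` is OLS with intercept of the aesthetic score
(or of $\alpha$) on the seven features, reporting $b$, SE, $t$, $p$,
$R^2$, adjusted $R^2$ and per-feature squared semi-partials; a
rank-deficient design fails with the collinear features named.

`fit_ridge()` addresses multicollinearity: rows are split 80/20
(seeded, `floor(0.8 n)` training rows), predictors are z-scored with
training-set statistics, and the penalty is chosen from a logarithmic
grid ($10^{-4}$–$10^2$, 25 points) by seeded 5-fold cross-validation
inside the training split. The estimator is the closed-form centred
ridge solve, so $\lambda = 0$ reproduces OLS on the same split to
machine precision — an identity the test suite asserts at $10^{-8}$.
Coefficients are reported on the standardized-predictor scale.

`variance_contribution()` compares the one-feature $R^2$ with the full
model's, the nested-model identity guaranteeing a nonnegative delta.

## Sequence screening

RGB histograms use 256 exact unit bins per channel; counts always sum to
the pixel count. Two percentile screens operate on the extreme 5 % tail
(configurable `tail_fraction`; we read "the 95th percentile with the
smallest change" as that tail of smallness, and symmetrically for the
downturn screen): the *stability screen* ranks categories by the summed
absolute change of the standardized low-level features (brightness,
contrast, sharpness, saturation; the feature set is a flag) between the
extreme $\alpha$ levels and keeps the smallest; the *downturn screen*
ranks by `score(0.10) - score(0.25)` and keeps the largest. Selection
size is exactly `ceiling(tail_fraction * N)` over the categories entering
the screen (after skipping those missing a required level, with a
warning); ties break lexicographically by category id, preferring
reproducibility over any statistical rationale.

Realism profiles use the Fréchet (2-Wasserstein) distance between
Gaussian summaries of image embeddings:
$\|\mu_a - \mu_b\|^2 + \mathrm{Tr}(\Sigma_a + \Sigma_b -
2(\Sigma_a\Sigma_b)^{1/2})$, computed via the symmetric eigendecomposition
of $\Sigma_a^{1/2}\Sigma_b\Sigma_a^{1/2}$ with eigenvalues above
$-10^{-9}$ clipped to zero and anything more negative treated as an
error (reported with the eigenvalues). The embedding is pluggable; the
default is the seven-dimensional feature vector, which preserves the
"distance between $\alpha$-populations" semantics at desk scale. A
learned (Inception-style) embedding is deliberately not implemented, so
absolute distances are not comparable to published FID values — only the
shape of the profile across $\alpha$ is meaningful here.

## Numerical choices and degenerate inputs

* Population SDs in contrast, colorfulness, quadtree splitting and
  Gaussian summaries; sample SDs in z-scoring (the convention of
  `scale()`).
* Psychometric probabilities clamped at $10^{-9}$; optimizer restarts
  from three origins; the reported fit is the best of the converged
  starts.
* CSV numerics are written with 17 significant digits so write/read
  round-trips are bit-exact; readers validate the schema and reject
  malformed rows by number instead of coercing.
* Images smaller than twice `min_block_size` in either dimension cannot
  be decomposed (symmetry needs each half decomposable); the operators
  raise a configuration error rather than silently degrading.
* All randomness flows through explicit seeds (`withr::with_seed`), and
  per-category streams are derived from a rolling string hash of the
  category id, keeping every artifact reproducible bit-for-bit.

## Problem sizes

The shipped acceptance script runs the full design — 489 categories ×
15 levels at 64 px (7,335 images), 100 simulated observers at 150 trials
plus 21 planted violators — in well under a minute on one CPU. The test
suite uses 16–64 px images and 5–489 categories per test. These sizes
were chosen as the smallest at which every statistical property under
test is comfortably identifiable.

## Known limitations

* The aesthetic score is a monotone linear stand-in; no content-based
  nonlinearity is modelled, so feature-to-score $R^2$ values on synthetic
  data say nothing about the variance structure of real appraisals.
* Complexity and symmetry react to $\alpha$ only indirectly (through the
  contrast gain crossing quadtree thresholds), so their profiles are much
  flatter than the directly steered features.
* The Fréchet embedding is feature-based, not learned; see above.
* Observers are exchangeable; there is no participant-level random-effect
  structure, so mixed-effects analyses are out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_categories = 40, image_size = 48, rng_seed = 7)
seqs <- generate_dataset(cfg)
feats <- standardize_features(extract_feature_table(seqs),
                              "zscore", "global")
trials <- simulate_experiment(rep(list(observer_model()), 20), cfg,
                              trials_per_participant = 40,
                              rng_seed = 8)
cleaned <- clean_participants(trials,
                              cleaning_thresholds(min_trials = 20))
fit <- fit_psychometric(cleaned$trials, n_boot = 199)
fit
fit_feature_regression(feats, "aesthetic_score")$r2
aesthetic_downturn_sequences(seqs)$selected
```
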