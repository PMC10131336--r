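---
title: "Selecting top lines in genomic prediction: models, cutoff tuning, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting top lines in genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection ranks candidate breeding lines by marker-based
predictions of their genetic merit and advances the top fraction. In
practice the advancement decision is often a *threshold* decision: a line
is kept if its predicted value clears a bar $Y_\tau$ — a training-set
quantile (say the 80th percentile) or the mean or maximum performance of
repeatedly planted check cultivars. Used this way, the conventional
regression model is a binary classifier, and a poorly calibrated one:
because predictions shrink toward the mean, very few of them clear a bar
set in the upper tail of the *observed* distribution. The result is a
classifier with very high specificity and very low sensitivity — it almost
never advances a bad line, but it also misses most genuinely top lines.

`toplineGS` implements three classifiers around one genomic kernel, plus
the evaluation machinery to compare them honestly.

## Models

All three models share the VanRaden genomic relationship matrix computed
from centered allele dosages $W$:
$G = W W^\top / \left(2\sum_k p_k(1-p_k)\right)$.

**Model R (regression classifier).** The GBLUP mixed model
$Y_i = \mu + g_i + \epsilon_i$ with $g \sim N(0, \sigma_g^2 G)$ and
i.i.d. residuals. A held-out line is labelled *top* when its prediction
$\hat Y_i = \hat\mu + \hat g_i$ strictly exceeds $Y_\tau$.

**Model B (probit threshold classifier).** The trait is binarized at
$Y_\tau$ *before* fitting (observed labels use $\ge$), and a Bayesian
probit threshold model is fitted to the labels:
$P(Y_{b,i}=1\mid g_i) = \Phi(\beta_0 + g_i)$, arising from a latent
liability $l_i = \beta_0 + g_i + \epsilon_i$ with unit residual variance
and class 1 exactly when $l_i > 0$. $\beta_0$ carries a flat prior. The
decision cutoff on predicted probabilities is *tuned* (below) rather than
fixed at 0.5.

**Model RO (regression-optimum postprocessor).** Model R's continuous
predictions are kept, but the cutoff is tuned on validation data to a
value $Y_{\tau_0}$ (typically below $Y_\tau$, compensating the shrinkage
of predictions). Equivalently, predictions can be rescaled
$\hat Y^*_i = \hat Y_i\, (Y_\tau / Y_{\tau_0})$ and compared against the
familiar $Y_\tau$: for positive thresholds,
`classify(adjust_predictions(y, Y_tau, Y_tau0), Y_tau)` is *identical* to
`classify(y, Y_tau0)`, and the package asserts this identity rather than
assuming it.

### Cutoff tuning

Both B and RO choose their cutoff to minimize the squared difference
between sensitivity and specificity on validation folds. Because
sensitivity and specificity are step functions of the cutoff, the exact
optimum lies on the finite candidate set of midpoints between consecutive
distinct scores (plus one candidate below the minimum and one above the
maximum); `optimal_cutoff()` scans exactly that set, and ties are broken
toward the smallest candidate, which favors sensitivity — the known
weakness of the regression route. Per-fold optima are averaged across the
inner folds: model B averages the probability cutoffs directly
(probabilities share a common scale across fits), while model RO averages
the *quantile levels* and re-resolves the continuous cutoff on the refit
model's fitted training values, because fitted-value scales shift between
inner fits and the refit. Both aggregation modes are available for either
model. $Y_{\tau_0}$ is always resolved on training fitted values, never on
test predictions, keeping the decision rule test-independent.

### Nested cross-validation

Evaluation uses outer 5-fold CV; cutoff tuning uses inner 10-fold CV
within each outer-training set. The top-line threshold $Y_\tau$ is
re-resolved inside each outer fold from that fold's training responses
(check-based thresholds are resolved once — checks are fold-independent).
Inner validation labels are binarized at the *outer* fold's $Y_\tau$: the
paper-level procedure is silent on this point; the choice is leakage-free
(validation lines lie inside the outer-training set) and keeps one
threshold per fold. Inner folds are stratified on the binarized label —
at $\tau = 0.8$ an unstratified 10-fold split of a few hundred lines
frequently produces single-class validation folds. Single-class inner
folds are skipped and counted; an outer fold fails only when no inner fold
is usable. When R and RO are both requested they share the per-fold
GBLUP fit (identical mathematics; the shared predictions are asserted
identical in the tests, not assumed).

### Boundary conventions

Observed labels use $y \ge Y_\tau$ (a line *at* the bar is a top line);
predicted labels use strict $\hat y > $ cutoff. The source procedures
state both conventions in different places; the package pins these
defaults and exposes both operators.

## Fitting machinery

Both Bayesian samplers work in the eigenbasis of $G$ ($G = U D U^\top$,
computed once per fit), which makes each Gibbs sweep two dense
matrix–vector products plus $O(n)$ scalar conditional draws:

* **GBLUP Gibbs**: samples $(\mu, g, \sigma^2, \sigma_g^2)$;
  held-out phenotypes are masked and imputed each sweep from their
  conditional normal, so test lines receive genomic values inside one
  joint model rather than by post-hoc kriging.
* **Probit Gibbs**: truncated-normal data augmentation of the liabilities
  ($l_i > 0$ iff label 1), then the same eigenbasis update with residual
  variance fixed at 1. Tail draws use inverse-CDF sampling on the
  relevant tail, stable far into either tail.
* **Deterministic mode** (`blup_deterministic`): REML by 1-D profile
  likelihood over $\lambda = \sigma^2/\sigma_g^2$ on the eigenspectrum
  (tolerance $10^{-8}$), then the closed-form conditional mean
  $\hat g = G_{\cdot,\text{obs}} (G_{\text{obs}} + \lambda I)^{-1}
  (y_{\text{obs}} - \hat\mu)$. This is the exact posterior mean of the
  Gibbs model at the REML variances and is used where speed and exactness
  matter (oracle tests, large nested-CV benchmarks).

MCMC defaults are 6,000 iterations, 1,000 burn-in, thinning 5, with
scaled-inverse-chi-square priors (df 5) whose scales split the sample
variance evenly between the genomic and residual components (prior scale
$\sigma_g^2$ is 1 on the liability scale for the probit model). These
mirror common defaults for Gibbs-sampled whole-genome regression; the
source work does not report its iteration counts or priors, so these are
stated choices, not inferences. The predicted class-1 probability is the
posterior mean of $\Phi(\beta_0^{(s)} + g_i^{(s)})$ over retained draws
(the proper posterior predictive); the plug-in
$\Phi(\hat\beta_0 + \hat g_i)$ is also exposed. All samplers consume R's
RNG, so a seed makes fits bit-reproducible; the CV harness derives one
deterministic sub-seed per fold, model and inner fold from the single run
seed.

## Marker quality control

Markers are retained when minor allele frequency $\ge 0.05$ (boundary
inclusive), missing fraction $< 0.5$, and heterozygosity $< 0.05$ — the
filter set used for GBS wheat panels. MAF is the ALT-dosage mean over
non-missing calls, folded at 0.5. The heterozygosity filter presumes
diploid 0/1/2 calls and is skipped with a warning on already-imputed
real-valued matrices. Missing dosages are replaced by the marker mean —
deliberately simple; LD-aware imputation (e.g. LinkImpute or EM-based
methods used upstream of the original datasets) is preprocessing, not
part of the methods, and users can pre-impute externally. No pedigree
blending and no shrinkage of $G$ are applied; eigenvalues below zero by
numerical noise are clamped, and anything worse than $-10^{-6}\lambda_{\max}$
is an error rather than silently jittered.

## The synthetic world

The simulator emulates the *shape* of elite wheat yield-trial data: by
default 500 lines by 1,000 biallelic markers with MAF drawn uniformly on
[0.05, 0.5], an additive trait with $h^2 = 0.5$ from 100 causal markers,
and a top-line fraction of ~20% at $\tau = 0.8$. Two choices deserve
explanation:

* **Inbreeding.** Genotypes are homozygous with probability $F = 0.95$
  (dosage $2 \times \text{Bernoulli}(p)$) and Hardy–Weinberg otherwise.
  Wheat breeding lines are near-fully inbred; under outbred
  Hardy–Weinberg sampling nearly every marker would fail the 5%
  heterozygosity filter that the real pipelines apply, which is itself
  evidence that the filter presumes inbred material. Set
  `inbreeding = 0` for an outbred population (the mean diagonal of $G$
  is then ~1; for inbred material it approaches $1 + F$).
* **Positive trait scale.** Phenotypes are $10 + g + e$; the positive
  intercept keeps quantile thresholds positive, the regime in which the
  cutoff-rescaling identity of model RO holds exactly.

The simulator is additive-only — no dominance, epistasis,
genotype-by-environment interaction, LD structure or population
stratification. The models under test assume an additive kernel, so a
richer generator would test the wrong thing. Consequently, a green test
establishes that the pipeline recovers what the additive world contains;
it says nothing about robustness to confounding that real multi-
environment trials exhibit.

**What the stated world cannot deliver.** At $h^2 = 0.5$ with 400
training lines and 1,000 markers, GBLUP's prediction–truth correlation
sits near 0.5, and the Mann–Whitney AUC of *any* score against the
phenotype-defined top-20% set — including the continuous GBLUP score
itself — tops out near 0.68. The end-to-end recovery check asking for
probit AUC > 0.7 is therefore left failing by a margin of ~0.08, with the
analysis here rather than a loosened bound: the probit probabilities
cannot beat the continuous score they binarize, and the "true top" labels
themselves carry phenotype noise.

## Evaluation conventions

Metrics (sensitivity, specificity, precision, F1, Cohen's $\kappa$) are
computed per outer fold from that fold's confusion matrix and then
averaged — never pooled into one confusion matrix. Undefined metrics
propagate as `NA` and are excluded from fold means with their count
reported: a regression classifier that never predicts a positive has
undefined precision and F1, and `NA` (not 0) is the only reading
consistent with how such cells are reported in practice. F1 is the
harmonic mean of precision and sensitivity. Interval bounds in the
comparison table are t-based over folds (the source tables label LL/UL
without defining them; the choice is documented in the output). Relative
efficiency is the ratio of fold-averaged metrics; `percent_advantage()`
implements the better-model-first convention
$100\,(1 - \text{worse}/\text{better})$. The narrative convention
$100\,(RE - 1)$ appears in some published comparisons; both are
reproducible from the two exported operations.

## Known limitations

* Single trait, single environment, additive kernel only; no
  marker-effect (BayesA/B/Lasso) models, no ordinal extension of the
  threshold model.
* Mean imputation ignores LD; heavily missing panels should be imputed
  upstream.
* The probability-cutoff search is exact for the stated objective but
  implements no cost weighting, Youden's J, or AUC maximization — these
  are out of scope by design.
* Check-based thresholds assume checks are measured on the same scale as
  the candidates' BLUEs.
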