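---
title: "Estimating and stress-testing depression-anxiety symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and stress-testing depression-anxiety symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`symptomnet` treats a set of binary symptom indicators $x \in \{0,1\}^p$
(here: the nine PHQ-9 depression items and seven GAD-7 anxiety items,
binarized to absent/present) as an Ising model, the pairwise Markov random
field

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j\Big),$$

with node thresholds $\tau_i$ (the log-odds of symptom $i$ when all
neighbours are absent) and symmetric pairwise interactions $w_{ij}$. An edge
$w_{ij} \neq 0$ means symptoms $i$ and $j$ are conditionally associated
given all other symptoms; $w_{ij}$ is the change in the conditional log-odds
of one symptom when the other switches on.

Estimation follows the eLasso recipe (`estimate_network()`): each item is
regressed on all others by $\ell_1$-penalized logistic regression, the
penalty per node is chosen by the extended BIC

$$\mathrm{EBIC}_\gamma = -2\ell + k\ln n + 2\gamma k \ln(p-1),$$

and the directed fits are symmetrized. The conditional distribution of node
$i$ in the Ising model is exactly the logistic regression
$\operatorname{logit} P(x_i = 1 \mid x_{-i}) = \tau_i + \sum_j w_{ij} x_j$,
which is what makes the nodewise strategy consistent.

Defaults mirror the conventions of the psychometric-network literature:

* **gamma = 0.25.** A compromise between the plain BIC
  ($\gamma = 0$) and the very conservative $\gamma = 0.5$; it suppresses
  spurious edges while keeping moderate true ones. Larger gamma never adds
  edges, a monotonicity the tests assert.
* **AND rule.** An edge is kept only if both nodes select each other; the
  retained weight is the mean of the two directed coefficients. The OR rule
  (either selects; missing coefficient counts as 0) is available via
  `rule = "OR"` and always yields a superset of the AND edge set.
* **Lambda path.** 100 log-spaced values from $\lambda_{\max}$ (the
  null-model stationarity bound $\max_j |\sum_i x_{ij}(y_i - \bar y)|/n$,
  at which every slope is exactly zero) down to $0.01\,\lambda_{\max}$.
  The unpenalized endpoint is never included, so quasi-separated nodes keep
  finite estimates. EBIC ties are broken toward the sparser model (larger
  lambda).
* **No standardization.** All predictors share the $\{0,1\}$ scale, so
  coefficients are left on it; cross-implementation comparisons must use
  the same convention.
* **Solver.** The per-node problems are solved by coordinate descent via
  glmnet (convergence threshold `1e-7`, the solver's default, tightened to
  `1e-12` in oracle tests against unpenalized ML fits). The
  log-likelihood entering the EBIC is the unpenalized Bernoulli
  log-likelihood of the *penalized* solution, recovered from the model
  deviance — the convention of the estimator this package re-implements,
  and the reason nodewise selection can occasionally differ from exhaustive
  best-subset EBIC selection on weakly informative data (to relax strong
  coefficients toward their ML values the path must lower lambda, which can
  let a borderline extra predictor enter first).

One numerical consequence of delegating to coordinate descent: permuting
respondent rows changes floating-point summation order, so re-estimated
weights agree to about `1e-10` rather than bit-for-bit. The selected edge
set is unaffected.

## Preprocessing

`screen_items()` chains the screening steps applied before estimation:

* **Low-informativeness rule.** Item $i$ is dropped when
  $\mathrm{sd}_i \times 2.5 < \overline{\mathrm{sd}}$, the mean SD across
  items. The verbal rule "SD 2.5 times lower than the mean value of the
  items" is ambiguous; we read "mean value" as the mean of the item SDs
  (the screening-literature convention, and the reading consistent with no
  exclusions on the published SD column). The alternative reading — against
  the item's own mean score — is exposed as `mode = "item_mean"`.
* **Redundancy screen.** For each item pair correlating at least 0.5, the
  two items' correlations with every third item are compared with the
  Hittner-Steiger dependent overlapping-correlations z test; a pair whose
  profiles differ significantly in fewer than 25% of comparisons is flagged
  as potentially redundant. Flagged pairs are reported, never silently
  dropped. Correlations are product-moment on the raw ordinal scores.
* **Binarization.** 0 stays 0; 1, 2, 3 become 1. The positive skew of the
  raw scores means the presence proportion, not the mean, carries the
  marginal information into the network.
* **Reliability and prevalence.** Cronbach's alpha per scale on the raw
  ordinal items (sample-variance convention), and screening prevalence at a
  scale total of at least 5.

Missing responses are rejected, not imputed: the instrument this pipeline
models forces complete responses, and silent imputation would change the
estimand.

## Centrality, bridges, predictability

One-step expected influence $EI_1(i) = \sum_j w_{ij}$ ranks how strongly a
symptom activates the rest of the network (the two-step variant adds the
neighbours' own influence). Bridge expected influence restricts the sum to
edges crossing to the other diagnostic community; symptoms whose BEI
strictly exceeds the 80th percentile (linear-interpolation quantile; ties
excluded, so a constant BEI vector flags nothing) are reported as bridge
symptoms. With 16 items and distinct values this flags the top three.

Predictability quantifies how well each symptom is predicted by its
estimated neighbours. The published per-item values we calibrate against do
not name their metric; for binary nodes we default to normalized correct
classification,

$$nCC = \frac{CC - CC_0}{1 - CC_0},$$

where $CC$ is the in-sample accuracy of an unpenalized logistic refit on
the node's neighbours (probability threshold 0.5) and $CC_0$ the
majority-class rate. $nCC$ is 0 when neighbours add nothing and 1 for
perfect prediction; isolated nodes are 0 by definition. Raw accuracy is
available via `type = "CC"` since the ambiguity cannot be adjudicated
without the raw survey data.

## Stability diagnostics

`bootstrap_edges()` re-estimates the network on $B$ resamples drawn with
replacement and reports percentile 95% CIs per edge plus paired difference
tests (between edges, and between node centralities reconstructed from the
same resamples): a difference is significant when the percentile interval
of the paired differences excludes zero. No multiple-testing correction is
applied, matching the convention of the bootstrap framework this follows.

`case_dropping_bootstrap()` re-estimates on subsamples with 5%-75% of
respondents removed (steps of 5%) and correlates each subsample EI/BEI
vector with the full-sample one. The CS coefficient is the largest drop
proportion at which at least 95% of correlations stay at or above 0.7, with
every smaller proportion also qualifying; above 0.5 is conventionally good.
Degenerate replicates are handled explicitly: a resample with a constant
column is re-drawn under a deterministic spare seed (more than 10% redraws
aborts the run), and a replicate whose re-estimated network yields a
constant statistic vector has no defined correlation — it is recorded as
`NA` and counts against the stability criterion. On pure-noise data, where
re-estimated networks are empty, this drives the CS coefficient to 0 rather
than erroring out.

All bootstrap randomness flows from one master seed through deterministic
child seeds per replicate, so results are independent of execution order
and exactly reproducible.

## The synthetic-data generator

The survey the pipeline was built around is not publicly deposited, so the
package ships two generators that together make every stage testable.

**Ordinal questionnaire generator.** `paperlike_recipe()` draws a latent
multivariate normal and discretizes each coordinate at three cut-points.
Per item, the first cut-point reproduces the published presence proportion
(0.22-0.79 across the 16 items) and the upper two are solved so the
category tail probabilities decay geometrically while matching the
published item mean — giving positively skewed marginals throughout, as in
the reference sample. The latent correlation is block-exchangeable: 0.50
within each community, 0.35 across. Those values put observed item
correlations in the realistic 0.3-0.45 band — below the redundancy screen's
0.5 gate, so the full screening chain keeps all 16 items, mirroring the
reference analysis — while the positive manifold makes essentially every
estimated edge positive (the tests require 95% of 20 seeds at n = 1200).
What this generator does *not* emulate: heterogeneous pairwise structure
(every within-community pair is exchangeable, unlike real item content),
demographic covariates, and response styles. Passing tests therefore show
the pipeline's operations are correct under a realistic marginal/dependence
regime, not that the published network would be reproduced edge for edge.
One visible consequence: on this exchangeable data the node EI/BEI
differences are pure sampling noise, so case-dropping CS coefficients come
out near zero — correctly, since there is no true centrality ordering to
preserve. Stability benchmarking therefore uses heterogeneous ground-truth
networks instead.

**Ising ground truth.** `make_true_network()` draws a sparse two-community
network (defaults: 9 + 7 nodes, within-density 0.5, cross-density 0.3,
weights uniform on [0.2, 1.0], thresholds uniform on [-2, 0] — positive
edges and minority-presence symptoms, the typical regime of symptom
networks). `sample_ising()` draws exactly (full enumeration, p <= 20) or by
Gibbs sampling; `enumerate_ising()` is the exact oracle the samplers and
estimators are validated against, normalized with log-sum-exp.

The Gibbs sampler runs one chain per requested draw, vectorized across
chains: each chain is burned in for 1,000 full sweeps and recorded after 10
further sweeps, so draws are independent across rows rather than thinned
from one autocorrelated chain. Burn-in sufficiency is validated against
enumeration (total-variation distance below 0.02 at 100,000 draws on a
4-node network), not asserted.

For stability benchmarks the tests use a "strongly determined" 10-node
truth: weights uniform on [0.8, 1.2] at density 0.5/0.25 and thresholds
$\tau_i = -\tfrac{1}{2}\sum_j w_{ij}$, which centres every margin near 50%
presence. Early experiments with strong weights but unbalanced thresholds
showed why balance matters: saturated margins (presence above 0.9) starve
the nodewise regressions of minority-class cases, and subsample estimates
become unstable even though the generating couplings are strong.

## Problem sizes

Simulation-backed checks are sized for a single CPU: parameter recovery
uses ten 10-node truths at n = 5,000; case-dropping stability uses B = 200
subsamples per proportion at n = 1,500; bootstrap-CI coverage uses 200
trials of B = 50 at n = 800; the end-to-end synthetic pipeline in
`scripts/acceptance.R` runs at n = 1,000 with B = 150 edge resamples and 15
case-dropping subsamples per proportion. The `analysis/` scripts run the
same flow at the full reference sample size (n = 6,183) for the
deterministic stages and n = 1,500 for the case-dropping grid.

## Known limitations

* Binary-only estimation: no Gaussian or mixed graphical models, no
  polychoric EBICglasso variant; communities are given a priori, never
  detected.
* EBIC selection uses the penalized solution's log-likelihood (the
  estimator's convention), so it is not guaranteed to coincide with
  exhaustive best-subset EBIC on weak data.
* In-sample predictability slightly flatters nodes with many neighbours;
  no cross-validation is applied, matching the reporting convention the
  package targets.
* Bootstrap difference tests are uncorrected for multiplicity by design.
* The percentile-bootstrap CIs inherit lasso shrinkage and are valid for
  the *estimator's* sampling distribution, not for the generating weights:
  the EBIC-selected penalty biases every edge downward by roughly 0.8 of
  its standard error, a ratio that does not vanish with n (the selected
  lambda is bounded below by the path floor). Against true weights we
  observed ~83% coverage at a nominal 95% across n = 300-5000; against the
  estimator's own expected value coverage is near-nominal. Treat the CIs
  as accuracy/ordering diagnostics (their role in this literature), not as
  confidence statements about true edge parameters.
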