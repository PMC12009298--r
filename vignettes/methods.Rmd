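---
title: "Models, estimators, and design choices in introchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators, and design choices in introchoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`introchoice` measures how people make two-alternative, multi-attribute
choices — which attributes they weigh, and which simplifying heuristics they
use — and how accurately they can report on that process. This vignette
documents the model family, the estimators, the synthetic-data generator,
and the places where a genuine design choice had to be made.

## The choice-process model family

A decider faces `N` trials; on each, two options A and B are described by
`K` attribute values scaled to $[0, 1]$. The core process is the
weighted-additive ("classically rational") rule: signed attribute weights
$w \in [-1, 1]^K$, option values $v_A = w \cdot x_A$ and $v_B = w \cdot x_B$,
and a softmax choice rule with inverse temperature $\beta \ge 0$:

$$P(\text{choose } A) = \frac{1}{1 + e^{-\beta (v_A - v_B)}}.$$

For two options the softmax is exactly this logistic of the value
difference, which is how it is implemented (numerically stabler than
exponentiating the two values separately).

Three composable heuristics simplify this process:

* **single attribute** ("take the best", lexicographic): exactly one
  $w_k \in \{-1, 1\}$, the rest 0;
* **binary weights** ("equal weights", with opt-outs): every
  $w_k \in \{-1, 0, 1\}$;
* **binary attribute values** ("weighted pros"): per attribute, the greater
  option's value is replaced by 1 and the other by 0 — only the direction
  of each attribute difference is represented, not its size.

Single attribute cannot be combined with binary weights (it is the special
case with one nonzero weight), so six models remain, numbered 1 (no
heuristics) through 6 (single attribute + binary values). Models 1–2 have
continuous weights; models 3–6 restrict weights to finitely many
configurations (3^K for binary weights, 2K for single attribute).

Decisions taken where the definitions leave room:

* **Value ties under binary values** map to 0.5/0.5, so a tied attribute
  contributes nothing to the value difference. Ties cannot occur in
  generated tasks (see below), but imported data may contain them, and the
  symmetric convention keeps $P(A) + P(B) = 1$ exact.
* **The all-zero configuration is admitted in models 3–4**: an independent
  uniform prior over $\{-1, 0, 1\}$ per weight implies it. It predicts
  chance responding on every trial — a legitimate (if lazy) process.
* **K is configurable** (default 9). The estimator-validation tests run at
  `K` of 2–3, where brute-force enumeration and Monte-Carlo oracles are
  exact enough to pin every estimator down.

## Priors and Bayesian machinery

Weights get a uniform prior (a box on $[-1,1]^K$ for continuous models, a
discrete uniform over configurations otherwise); $\beta$ gets a
Gamma(shape 4, rate 1) prior — mean 4, mass concentrated over the range
where choices are stochastic but informative. The shape–rate reading
follows the convention of the major probabilistic-programming systems.

Per participant and model we compute MAP parameters and the log marginal
likelihood; normalizing marginal likelihoods across models under a uniform
model prior gives posterior model probabilities. This comparison carries a
built-in Occam's razor: the flexible continuous models integrate their
likelihood over a much larger parameter space and are penalized
automatically when a simple heuristic explains the data as well. Summing
model probabilities over the models that use a heuristic gives the three
heuristic-family probabilities (single attribute: models 5+6; binary
weights: 3+4; binary values: 2+4+6).

Because each model implies different best-fit weights, weight estimates are
**model-averaged**: the six MAP weight vectors averaged with the posterior
model probabilities. Self-reported weights, which participants give in
three formats (graded, binary checklist, single attribute), are averaged
with the same probabilities — graded weights standing in for models 1–2,
binary for 3–4, single for 5–6 — which makes reported and fitted weights
directly comparable.

### Discrete models: exact computation

For models 3–6 the marginal likelihood is computed exactly: the weight
configurations are enumerated and, for each, the likelihood is integrated
against the Gamma prior on $\beta$ by 64-node Gauss–Legendre quadrature on
the $\beta$ scale, over the prior's $[10^{-8}, 1-10^{-8}]$ quantile range
with the prior density folded into the quadrature weights. The integrand
(a bounded, smooth likelihood times a Gamma density) is machine-converged
well before 64 nodes; doubling the node count changes the log marginal by
less than $10^{-6}$, which the test suite checks. The inner
configuration-by-node likelihood grid (up to $3^9 \times 64$ evaluations
over 100 trials) is the package's one compiled (Rcpp) hot loop.

The discrete MAP is found by ranking all configurations on that same dense
$\beta$ grid and refining the best 20 (`refine_top`) with an exact 1-D
optimization of $\beta$; ties go to the lowest configuration index. At
small `K` this is verified against an exhaustive per-configuration
optimization oracle.

### Continuous models: Laplace importance sampling

For models 1–2 the MAP is found by multi-start (10 seeded restarts)
L-BFGS-B with analytic gradients on the box $[-1,1]^K \times (0, 50]$,
convergence factor near machine precision. The marginal likelihood is then
estimated by importance sampling with a multivariate-t proposal (df 5)
centered at the MAP, scale taken from the inverse finite-difference Hessian
of the negative log posterior — eigenvalue-floored, and inflated by 1.5 to
cover the ridge that the $\beta \cdot w$ scale degeneracy creates — with
draws outside the support given zero weight. The estimator reports its
Monte-Carlo standard error and effective sample size; if the Hessian is
unusable it falls back to sampling from the prior. This replaces
MCMC-plus-bridge-sampling with something deterministic given a seed and
dependency-free; both routes target the same integral, and the test suite
checks the estimates against large brute-force prior-sampling oracles at
small `K`.

Two consequences of the **scale degeneracy** (the likelihood depends on
$w$ and $\beta$ only through $\beta w$) are worth knowing. First, the MAP
weight vector's overall scale is set by the prior, not the data; we report
it under the stated priors without renormalization. Second, for that
reason the Pearson correlation — which ignores scale — is the primary
weight-accuracy measure, and the absolute weight error should be read with
this sensitivity in mind.

## Synthetic data: what it emulates, and what not

The generator emulates the measured task: `n_trials = 100` two-option
trials over `K = 9` attributes, values uniform on $[0,1]$, and the two
options forced to differ by at least `min_separation` on **every**
attribute, via per-attribute rejection sampling. Tasks of this kind
require the two options to differ clearly on every attribute; with no
canonical threshold to import, the default separation is 0.25 on the unit
scale, which guarantees every trial is informative about every attribute
and makes binary-values ties impossible. An optional discrete
value grid emulates Likert-style attribute levels.

Simulated deciders are drawn per model: continuous weights uniform on
$[-1,1]$ per attribute (matching the fitting prior), discrete weights
uniform over admissible configurations, $\beta$ from the Gamma(4, 1)
prior. Self-reports are truthful at `report_noise = 0`: graded weights
equal the generating weights, the binary and single formats are their
binarizations (binary: sign of any weight with $|w| \ge 0.5$; single: the
largest-magnitude attribute), and heuristic extents are the generating
model's 0/1 flags. With noise, magnitudes and extents get additive
Gaussian noise (sd = noise) clipped into range, signs flip with
probability noise/2, and the binary/single formats are re-derived from the
noisy graded vector so one coherent belief underlies all formats. A master
seed fans out into per-component sub-seeds (`derive_seeds`), so any stage
can be reproduced alone.

What the generator does **not** emulate: cover stories and attribute
semantics, the fixed pre-fabricated trial sets some study variants used
(it randomizes per participant), response times and the forced viewing
delay, and human report biases (its noise is symmetric and unstructured).
Passing recovery tests therefore show that the *inference machinery* is
sound under the task's statistical structure — not that human reports are
well calibrated, which is exactly the empirical question the metrics are
for.

## Accuracy metrics and chance levels

Per participant: the Pearson correlation and the mean absolute difference
between model-averaged fitted and reported weights; the heuristic error
(mean absolute difference between the three reported extents and the three
family probabilities); the reported model (each extent dichotomized at
50%); its Bayes factor relative to the best-fitting model; and whether the
reported model *is* the argmax model. Conventions: an extent of exactly
0.5 counts as "did not use" (the published rule defines only the two open
intervals; we resolve the boundary toward the simpler classification);
when both single-attribute and binary-weights are reported above 0.5 —
a combination no model allows — single-attribute wins (it is the subsumed
special case) and a warning is raised; correlations are undefined (`NA`)
when either weight vector is constant, and such participants are excluded
from cohort means with their count reported.

Chance levels come from re-pairing reports with other participants' fits
(`n_boot` random permutations, seeded), which preserves both marginal
distributions while destroying the within-person link. For
`correct_method` the analytic chance level under uniform guessing, 1/6,
is reported alongside.

## The recovery study

`run_recovery()` closes the loop: generate a cohort with known processes,
fit every decider, and score (a) *heuristic recovery* — a decider counts
as correct when each of the three 0.5-thresholded family probabilities
matches the generating model's flags (the published account does not state
its scoring rule; thresholded family probabilities are the natural
per-heuristic reading, and argmax-model agreement is reported alongside) —
and (b) *weight recovery* — the mean correlation between generating and
model-averaged fitted weights. The default study (10 deciders per model,
100 trials, K = 9, Gamma-drawn $\beta$; roughly 6–7 minutes on one core,
dominated by the 3^9-configuration models) validates the pipeline: at
seed 1 it identifies all three heuristic uses for 83% of deciders, with a
mean weight correlation of 0.985 between generating and fitted weights. The unit-test suite runs a scaled-down profile (K = 5,
fewer deciders, 32 quadrature nodes, fewer restarts and draws) that
exercises the identical code path in seconds.

Two negative results are worth recording as properties of the science, not
bugs. At $\beta = 0$ choices carry no information and recovery collapses
toward the no-heuristic classification (the family probabilities hover at
their prior-ish levels below 0.5). And at very high $\beta$ (e.g. 10),
choices are near-deterministic, which *erases the graded-vs-binary
value-format distinction for single-attribute deciders*: a take-the-best
decider is fit as well by the binary-values variant, which saturates at a
smaller $\beta$ and is favoured once the Gamma prior penalizes the larger
$\beta$ the graded model needs. The weight structure and the
single-attribute family are still recovered perfectly there. Misses in the
default study are of the same two kinds: low-$\beta$ deciders drifting to
"no heuristics", and continuous-weight deciders whose sampled weights lie
near a discrete configuration being absorbed by the binary-weights family.

## Numerical and scale choices, in one place

| Quantity | Default | Why |
|---|---|---|
| `K` / `n_trials` | 9 / 100 | the measured task's dimensions |
| `min_separation` | 0.25 | informative trials, no value ties; exact published rule unavailable |
| $\beta$ prior | Gamma(4, 1) | the fitting prior; shape–rate convention |
| quadrature nodes | 64 | machine-converged (<1e-6 under doubling) |
| IS draws | 4000 | log-marginal MC-SE ~0.02–0.05 nats, small vs. typical model gaps |
| restarts | 10 | ridge-shaped posterior; multi-start with one neutral start at w = 0 |
| `refine_top` | 20 | grid ranking is near-exact; refinement margin is generous |
| optimizer box | $[-1,1]^K \times [10^{-6}, 50]$ | prior support; Gamma prior makes $\beta > 50$ irrelevant |
| bootstrap `n_boot` | 1000 | chance-level SE well below metric differences of interest |

Known limitations: weights and method are assumed constant across trials
and attributes enter linearly (no interactions); sequential-sampling
accounts of the same choices are out of scope; the absolute-weight-error
metric inherits the continuous models' scale indeterminacy; and the
report-noise model is a convenience for studying metric sensitivity, not a
cognitive model of reporting.
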