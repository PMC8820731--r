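---
title: "Modelling judgments of agency: Second-order and First-order rating models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling judgments of agency: Second-order and First-order rating models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(joamodels)
library(dplyr)
```

## The question and the modelling framework

When people act and watch the sensory consequences of their action — here, a
virtual hand tracking their finger movement, sometimes with an added temporal
delay — they can report an explicit judgment of agency (JoA) on an ordinal
scale. The computational question this package addresses is whether such
judgments are *metacognitive* in the narrow sense: do they incorporate a
second-order estimate of the observer's own sensory noise, the way decision
confidence does, or are they a first-order readout of the perceived signal?

Both models are signal-detection models over a comparator signal: on a trial
with true delay $d$ (seconds), the observer receives an internal signal

$$x \sim \mathcal{N}(d, \sigma_z), \qquad z \in \{\mathrm{low}, \mathrm{high}\},$$

where $\sigma_z$ is the spread induced by the sensory-noise condition
(manipulated experimentally by scene illumination). A decision criterion $c$
splits the axis: $x < c$ is a "Yes, I had agency" decision, $x \ge c$ a "No"
decision. Ratings refine the decision: the 6-point scale is carved out of the
signal axis by additional criteria on each side of $c$, with `n_yes`
(NRYes) ratings allocated to the Yes side. The lowest perceived delay maps to
the highest rating.

The two models differ only in *where* those rating criteria sit:

* **Second-order model.** The rating tracks the posterior probability that
  the decision was correct given $x$ and the choice. We work with the
  *certainty* $v(x) = 2\,\Phi(|x - c| / \sigma_z) - 1 \in [0, 1]$
  (equivalently, probability correct $p = (v+1)/2$, running from 0.5 at the
  criterion to 1). Criteria are placed at equal certainty levels: with $m$
  ratings on a side, the interior boundaries solve $v(x) = k/m$,
  $k = 1, \dots, m - 1$, i.e.
  $x = c \pm \sigma_z\,\Phi^{-1}\!\big(\tfrac{1 + k/m}{2}\big)$.
  Because $\sigma_z$ enters the placement, the observer must know their own
  noise — the metacognitive ingredient. Equal-certainty spacing is the same
  thing as equal-width spacing in the probability coordinate
  $q = \Phi((x - c)/\sigma_z)$ (an affine reparameterisation; the package
  tests this equivalence). We note that closed-form definitions of
  confidence in the literature are written in several sign conventions that
  do not all agree as printed; this package is anchored to the
  equal-certainty construction above, which is unambiguous.

* **First-order model.** The rating is proportional to the signed evidence
  $f(x) = x - c$, with no noise estimate. The scale must be bounded to be
  divided into bins: the observer is assumed to calibrate the scale ends to
  the range of delays experienced *within a noise condition*, approximated
  as $[-s\,\sigma_z,\; d_{\max} + s\,\sigma_z]$ with $d_{\max}$ the largest
  programmed delay and $s$ a freely fit *scale range* multiplier. The spans
  on each side of $c$, $A_\mathrm{yes} = c + s\sigma_z$ and
  $A_\mathrm{no} = d_{\max} + s\sigma_z - c$, are divided into equal linear
  widths. Noise affects the criteria only through this per-condition
  rescaling — condition-relative use of the scale, not uncertainty
  monitoring.

Given the criteria $\gamma_1 = -\infty < \gamma_2 < \dots < \gamma_7 =
+\infty$ for a condition, the probability of each rating is a difference of
Normal CDFs, and the likelihood of a rating table is multinomial over
(delay, noise, rating) cells:

$$\log L = \sum_{z}\sum_{d}\sum_{\alpha = 1}^{6} n_{z,d,\alpha}
\log\!\Big(\Phi\big(\tfrac{\gamma_{\alpha+1} - d}{\sigma_z}\big) -
\Phi\big(\tfrac{\gamma_\alpha - d}{\sigma_z}\big)\Big).$$

```{r}
p2 <- representative_params("second_order")
place_criteria(p2, "low")
rating_probabilities(p2, delay_s = 0, noise = "low")
```

### Orientation, units, and numerical conventions

* The internal axis is in **seconds**; trial-table files store delays in
  **milliseconds** (converted on entry). Fitted spreads for this paradigm
  land around 0.15–0.25 s, which is why the internal axis must be seconds
  for the parameter magnitudes to be meaningful, and why the scale top of
  the agency task is $d_{\max} = 0.2$ s.
* Ascending signal maps to descending rating; negative perceived delays are
  allowed and count as strong agency evidence (an assumption appropriate
  when the observer knows the feedback cannot precede the movement).
* Bin probabilities are floored at `1e-300` before logging, so an observed
  rating in a numerically empty bin costs a large finite penalty instead of
  `-Inf`; the floor is a user-visible argument.
* First-order per-side spans are divided separately (`placement =
  "per_side"`, paralleling the per-side binning of the Second-order model).
  The phrase "maximum distance from the criterion to either bound" admits a
  second reading in which both sides share the larger span; that variant is
  available as `placement = "shared_max"` and is not the default.
* Degenerate mappings `n_yes` ∈ {1, 5} leave one side without interior
  criteria; there are always exactly six bins.

## The 2IFC confidence variant

For the two-interval forced-choice task the observer compares agency across
two movements, one delayed and one synchronous. The decision variable is the
signed difference $y \sim \mathcal{N}(\delta, \sigma_z)$ with $\delta = d_1 -
d_2$; how the two intervals combine is not identifiable from choice data, so
any combination factor (such as $\sqrt2$ for independent intervals) is
absorbed into the task-specific $\sigma_z$. The response is "interval 2 had
more agency" when $y > c$. Confidence uses 12 bins — six per side of $c$,
forced by the task, so there is no mapping parameter. Second-order criteria
sit at certainty levels $k/6$; First-order criteria divide a symmetric scale
$[-\delta_{\max} - s\sigma_z,\; \delta_{\max} + s\sigma_z]$ into equal
widths, with $\delta_{\max}$ taken as the largest $|\delta|$ realised in the
fitted data set (recomputed per fit).

## Synthetic sessions

The generators emulate the study design the models were built for:

* **Agency task**: delays {0, 70, 100, 200} ms × {low, high} noise ×
  `trials_per_cell` (default 60 — a 480-trial session with 25% synchronous
  trials), equal cell counts in each of 6 blocks, order shuffled by seed.
* **Confidence task**: `n_per_noise` (default 100) trials per condition
  across 5 blocks. Only the low-noise condition is staircased with a
  2-down-1-up rule — the delay drops one step after two consecutive correct
  responses and rises one step after every error — which converges to the
  delay yielding $\sqrt{1/2} \approx 70.7\%$ correct. Each high-noise trial
  reuses the delay of the low-noise trial with the same sequence index
  (trial-by-trial yoking). Staircase specifics are not dictated by the task
  description, so the defaults are chosen from the display hardware: start
  300 ms, step and floor 16.7 ms (one frame at 60 Hz), all configurable,
  with a 100-trial burn-in for accuracy summaries.

```{r}
s <- simulate_confidence_session(p2, n_per_noise = 1000, n_blocks = 5,
                                 seed = 7)
staircase_accuracy(s, burn_in = 100)
```

Simulated reaction times are uniform on 0.3–3 s and no trial is
error-flagged: plumbing so that [filter_trials()] is exercisable, with no
physiological content. The generators reproduce the *conditional rating
distributions* of a model observer exactly (trials are independent given
delay and condition); they do not emulate sequential dependencies, lapses,
motor or somatosensory noise, or idiosyncratic scale use, so passing
recovery tests certifies the estimation machinery, not the realism of any
particular behavioural data set.

## Fitting

`fit_model()` maximises the multinomial likelihood with multistart
Nelder-Mead simplex search (spreads and scale range on the log scale), start
points from a Latin hypercube over the box `fit_bounds()`: $\sigma \in
[0.005, 1]$ s, $c \in [-0.1, 0.4]$ s, $s \in [0.01, 10]$. These are design
choices, made because the problems are smooth and 3–4 dimensional; both the
optimiser settings and the bounds are exposed. The discrete mapping
parameter is enumerated exhaustively over 1..5 — a derivative-free search
over a discrete parameter is ill-posed, and five restarts of a 3-parameter
problem are cheap. Default 20 starts; the recovery harnesses use 5 because
their surfaces are refit thousands of times and, empirically, multistart
beyond a handful never changes the optimum at these sizes. `n_yes` counts
toward $k$ in AIC/BIC: $k$ = 4/5 (Second/First, agency) and 3/4
(confidence). A pooled group fit is simply a fit to the concatenated trials
of all participants.

## Model selection

* `compare_bic()` applies the conventional minimum BIC difference of 2
  before declaring a winner.
* `akaike_weights()` converts per-subject AICs into normalised model
  evidence.
* `rfx_bms()` implements random-effects Bayesian model selection: each
  subject's best model is a draw from population frequencies $r \sim
  \mathrm{Dirichlet}(\alpha_0)$, $\alpha_0 = 1$ per model (uninformative —
  the prior any practitioner would use absent other information). The
  Dirichlet posterior is found by the standard variational fixed point;
  exceedance probabilities $\mathrm{EP}_k = P(r_k = \max r)$ are then
  estimated by Monte-Carlo from $10^6$ Dirichlet draws (the sampling count
  used in the applied literature this mirrors; stable to two decimals across
  seeds). The Bayes omnibus risk compares the free energy of the
  random-effects model with the exact evidence of the equal-frequency null,
  $\mathrm{BOR} = 1/(1 + e^{F_1 - F_0})$, and protected exceedance
  probabilities are $\mathrm{PEP}_k = \mathrm{EP}_k(1 - \mathrm{BOR}) +
  \mathrm{BOR}/K$. Per-subject log evidence is conventionally $-\mathrm{AIC}/2$
  (Akaike-weight evidence); the input is a generic log-evidence matrix, so a
  BIC-based convention is a one-line change by the caller.

```{r}
fits <- cbind(second_order = rep(-100, 12), first_order = rep(-97, 12))
rfx_bms(fits, n_samples = 1e5, seed = 1)
```

## Recovery harnesses

`model_recovery()` closes the loop simulate → fit both → BIC winner and
reports a confusion matrix; `parameter_recovery()` refits the generating
model and reports per-parameter bias and RMSE. The default parameter sets
(`representative_params()`) are values in the middle of the range these
models recover from empirical sessions of this paradigm: Second-order
$\sigma_L = 0.19$, $\sigma_H = 0.24$, $c = 0.16$, NRYes $= 3$; First-order
$\sigma_L = \sigma_H = 0.16$, $c = 0.16$, NRYes $= 3$, $s = 1.11$. At the
standard 480-trial session size the two models are distinguishable
essentially every time; with a handful of trials the BIC winner is driven by
the penalty term rather than the data, which is the expected failure mode.

```{r}
mr <- model_recovery(n_sims = 4, trials_per_cell = 60, seed = 5,
                     n_starts = 3)
recovery_rate(mr)
```

## Problem sizes used by the test suite

The packaged tests run Monte-Carlo oracles at $10^6$ draws per case,
parameter recovery at sessions of 480–48,000 trials, and model recovery at
100 simulations per generating model of 480 trials each — sizes at which the
sampling error of each check is comfortably below the tolerance it asserts,
chosen so the whole suite completes in minutes on a single core.

## Known limitations

* Noise enters only as the spread of the perceived delay; motor,
  somatosensory and action-selection noise sources are out of scope.
* The ordinal likelihood treats trials as exchangeable within cells; real
  raters drift, lapse, and exhibit sequential effects.
* The First-order scale-range construction is an experimenter-side
  approximation to an unobservable perceived range; alternative bound
  constructions (e.g. shared-max) change the criteria but not the spirit of
  the model.
* The 2IFC decision variable is modelled as a single signed difference; a
  two-signal formulation with explicit interval noise is observationally
  equivalent for these data and therefore not separately implemented.
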