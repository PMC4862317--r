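---
title: "The TVA race model for temporal-order judgments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TVA race model for temporal-order judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvatoj)
```

## The generative model

A temporal-order judgment (TOJ) trial presents a probe and a reference
stimulus separated by a stimulus onset asynchrony (SOA, ms; negative values
mean the probe leads). Under the Theory of Visual Attention, each stimulus
races towards visual short-term memory with an exponentially distributed
encoding latency; the observer reports whichever representation completes
first. The latency rates are the processing rates `v_p` and `v_r` (Hz).
Before a race can start, a stimulus must be exposed for its maximal
ineffective exposure duration `t0`; the effective asynchrony is
`delta_t = soa + t0_p - t0_r`. For matched stimulus classes the `t0`s are
equal and cancel, which is why the package defaults them to zero while
keeping them as arguments.

Conditioning on `delta_t`, the probe is encoded first with probability

* `1 - exp(-v_p |dt|) + exp(-v_p |dt|) * v_p / (v_p + v_r)` for `dt < 0`:
  either the probe finishes inside its head start, or both stimuli are
  racing and the memoryless property reduces the outcome to Luce's choice
  rule between two competing exponentials;
* `exp(-v_r |dt|) * v_p / (v_p + v_r)` for `dt >= 0`, by symmetry.

The two branches meet continuously at `dt = 0`, where the probability equals
the attentional weight `w = v_p / (v_p + v_r)`. The curve is strictly
decreasing in `dt`, strictly increasing in `v_p`, and satisfies the
complementarity `P(v_p, v_r, dt) + P(v_r, v_p, -dt) = 1` — there are no ties
in continuous time. These invariants, together with a brute-force
Monte-Carlo race simulator (`simulate_race()`, `estimate_race_prob()`) that
knows nothing about the closed form, are what the test suite checks the
implementation against.

A note on the algebra: the completion probability within a head start of
length `|dt|` is necessarily `1 - exp(-v |dt|)`, with a *negative* exponent;
all exponents in the implementation are negative, which is the only reading
under which every branch is a probability. The race simulator confirms the
closed form to within Monte-Carlo error over a wide parameter grid.

## Parameters and their scales

| parameter | meaning | unit | typical magnitude |
|---|---|---|---|
| `v_p`, `v_r` | encoding rates of probe/reference | Hz | 10–35 |
| `C = v_p + v_r` | total processing capacity | Hz | 30–55 |
| `w = v_p / C` | attentional weight of the probe | — | 0.4–0.7 |
| `t0` | maximal ineffective exposure duration | s | ~0 (cancels) |
| SOA | onset asynchrony, negative = probe leads | ms | −100…+100 |

Public interfaces take SOA in milliseconds (the unit in which designs are
specified and data are recorded); all internal math converts once to seconds
at the module boundary so that rates stay in Hz.

## Hierarchical estimation

One condition's data are per-(participant, SOA) binomial counts of "probe
first" responses. `fit_toj()` estimates, per condition:

* participant weights `w_j ~ Normal(w_m, w_tau)` truncated to (0, 1);
* participant capacities `C_j ~ Normal(C_m, C_tau)` truncated to (0, Inf);
* derived rates `v_pj = C_j w_j`, `v_rj = C_j (1 - w_j)` (so the
  weight/capacity factorisation holds exactly in every draw);
* binomial likelihoods with the closed-form success probability at each SOA,
  clamped to `[1e-9, 1 - 1e-9]` so that an extreme SOA cell can never
  produce an infinite log-likelihood;
* group rates `nu_p`, `nu_r` as per-draw means of the participant rates.

The hierarchy is written as plain normals with truncation added because the
likelihood's domain requires it: an untruncated weight draw outside (0, 1)
or a negative capacity would be meaningless. The spread nodes are
parameterised as standard deviations throughout and reported as such.
Repeated sessions of one participant are pooled by summing counts within the
(participant, SOA) cell, which is exact under the model's exchangeability of
trials within a cell.

Sampling is delegated to JAGS through `rjags`; the model string (see
`tvatoj:::toj_jags_model`) spells out the psychometric likelihood rather
than using any built-in link. Chains receive deterministic initial values
and per-chain RNG seeds derived from the user seed, making fits exactly
reproducible. Convergence is flagged from split-R-hat (each chain halved
before computing the potential scale reduction factor) and effective sample
size on the six group-level parameters, with thresholds 1.01 and 400 —
stricter than the reporting precision requires. A flagged fit warns and is
marked `converged = FALSE`; the command-line `fit` subcommand additionally
exits nonzero unless told otherwise.

### Priors

Defaults (all overridable via `toj_priors()`):

* `w_m ~ Uniform(0, 1)` — no prior pull on the quantity of main interest;
* `w_tau ~ Half-Normal(0.2)` — between-participant weight SDs much above
  0.2 would put participants at the scale's ends;
* `C_m ~ Normal(40, 30)` truncated to (0, Inf) — centred on the tens-of-Hz
  magnitude established by TVA studies, but wide enough to be dominated by
  any real dataset;
* `C_tau ~ Half-Normal(15)`.

These are weakly informative choices made once for this implementation; a
published analysis with other defensible priors can differ slightly in its
estimates, so recovered and published values are compared under stochastic
rather than exact tolerances.

## Posterior summaries

* **Point estimate**: the mode, computed as the argmax of a Gaussian kernel
  density estimate (Silverman's rule-of-thumb bandwidth, 512-point grid
  spanning the draw range). A KDE mode is smooth and reproducible where a
  histogram mode depends on binning; constant draws return the constant.
* **Interval**: the 95% highest density interval, computed exactly as the
  shortest window of `ceiling(0.95 N)` consecutive sorted draws.
* **Condition contrasts** (`posterior_difference()`): conditions are fit
  independently, so their draws carry no joint structure; pairing is by
  index after a seeded random permutation of one side, which avoids
  spurious within-chain autocorrelation aligning across fits. Any pairing
  of independent draws is valid — the permutation makes the arbitrary
  choice explicit and reproducible. The `contains_zero` flag reports
  whether 0 lies in the difference's HDI.
* **Temporal-expectation correction** (`weight_correction()`): when the
  probe event occurs at a fixed, predictable time, even the neutral
  condition shows a weight slightly off 0.5. The correction subtracts the
  neutral deviation at the draw level, `w_clean = w_s - (w_n - 0.5)`,
  rather than subtracting modes: the mode of the corrected draws is not in
  general the arithmetic of the modes, and the draw-level version
  propagates both posteriors' uncertainty.
* **Posterior predictive** (`posterior_predictive()`): per retained draw,
  new counts are simulated for every cell from the closed-form probability
  at that draw's participant parameters and pooled into per-SOA
  proportions; 2.5/50/97.5% quantiles across draws form the predictive
  band, matching the 95% convention used everywhere else.

`fit_logistic()` provides the conventional psychometric analysis (binomial
GLM with logit link per participant and pooled; PSS = SOA at p = 0.5, slope
= derivative at the PSS). It is a comparison method, deliberately separate
from the TVA model: the two agree in sign (a weight above 0.5 shifts the
PSS positive) but the logistic fit yields no rates or capacity.

## The synthetic-experiment generator

`simulate_toj()` emulates the four reference designs: an 11-point SOA grid
from −100 to +100 ms in 20 ms steps with 24/32/48 trials per SOA (densest
where the function is steepest; 368 trials per participant) and 20/20/19/30
participants. One listing of that grid ends at "1 ms"; the trial-count
specification and the stated ±100 ms window both identify this as 100 ms,
and the generator uses +100 ms. Participant truths are drawn from exactly
the truncated hierarchies the inference model assumes, which makes
parameter recovery a well-posed self-consistency check. Counts can be drawn
binomially from the closed form or by simulating every race at the trial
level; the two modes are statistically indistinguishable (and a test checks
this), the race mode existing as an independent path through the generative
story.

Where published group estimates are used as generating truths, the
between-participant spreads are set to `w_sd = 0.05` and `C_sd = 5` Hz —
spreads of the magnitude the hierarchy's priors consider typical — since
the corresponding spread estimates are not printed.

What the generator does *not* emulate: lapses and finger errors, session
breaks and learning, response bias, SOA-dependent attention shifts, or any
stimulus-level variability — its observers are ideal TVA observers.
Passing recovery tests therefore demonstrates that the estimator inverts
its own generative model at realistic design sizes, not that the model is
true of human data.

## Numerical and design choices

* Probabilities entering a likelihood are clamped at `1e-9` from both ends.
* Monte-Carlo race ties (probability zero in exact arithmetic) are resolved
  for the reference, fixing determinism.
* Truncation bounds inside the sampler are nudged by `1e-6`/`1e-4` to keep
  JAGS's slice sampler off the exact boundary.
* The degenerate spread `sd = 0` in the generator produces exactly
  identical participants rather than an error, so exchangeability tests
  are exact.
* Dataset validation reports the offending row index for every schema
  violation (counts exceeding trials, duplicate cells, inconsistent
  grids).

Problem sizes used by the checks in this package: recovery fits run 2–3
chains with 1000–1500 retained draws each after equal warmup, on full-size
designs (19–30 participants); the HDI-calibration study runs 20 replicate
simulate–fit cycles at 8 participants with shorter chains. These sizes were
chosen as the smallest at which posterior modes stabilise well inside the
stochastic tolerances used for comparison; longer chains sharpen the
diagnostics but do not move the modes.

## Known limitations

* Single condition per fit; conditions are compared post hoc on draws.
  A joint model with shared capacity across conditions would be more
  efficient but is a different estimand.
* Two racers only; no VSTM capacity limit (K slots), no categorisation or
  pertinence biases — those are held constant by the designs targeted
  here.
* `t0` is passed through, not estimated; for mismatched stimulus classes
  (where the `t0`s do not cancel) estimates of `w` absorb the residual
  asynchrony.
* Aggregated binomial likelihoods assume stationarity within a cell;
  trial-level modeling (e.g. of sequential effects) is out of scope.
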