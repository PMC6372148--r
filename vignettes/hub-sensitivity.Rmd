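---
title: "Sensitivity trends across reproducible parameter ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity trends across reproducible parameter ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hubsens` studies how local sensitivities behave when a kinetic model is
constrained only up to *dynamic behavior*: many parameter sets fit, and the
question is which sensitivity features are shared by all of them. This
vignette documents the models, the statistical procedure, the numerical
choices, and the design decisions that were genuinely open — in enough
detail that a reader can audit or change any of them.

## The four hub motifs

Each motif is a small activation/deactivation network with conserved pools
(total amount 100 per pool, arbitrary concentration units; time in
minutes) and a single output, the active form X\*. Definitions live as
data in `inst/extdata/models/*.json`, one file per model, so the math is
auditable without reading code; `hub_model()` loads them and
`define_hub_model()` is the documented extension point for other networks.

* **M1, reversible reaction.** `A`: signal-driven Michaelis–Menten
  activation, rate `k1·s·X/(km1+X)`; `D`: first-order deactivation
  `k2a·X*`.
* **M2, cycle.** As M1, but deactivation sends X\* to a refractory state
  `Xr`, recycled by the saturable reaction `R` (`k3·Xr/(km3+Xr)`), so the
  available pool recovers with a delay.
* **M3, negative feedback.** The output activates its own deactivator
  (`FBA`: `k3·X*·Y/(km3+Y)`); active Y\* removes X\* through `DS`
  (`k2b·Y*·X*/(km2+X*)`); `FBR` (`k4·Y*`) resets the loop and `D`
  (`k2a·X*`) is weak basal deactivation.
* **M4, incoherent feedforward.** Identical skeleton to M3 except that the
  deactivator is activated by the *input* (`FFA`: `k3·s·Y/(km3+Y)`), not
  the output, with reset `FFR`.

The reference ("original") parameter values stored with each model were
chosen once to give the motifs their characteristic phenotypes on the
300-min observation window: activation responds within tens of minutes
(`k1 = 6`, `km1 = 30`), basal deactivation relaxes on a ~20–50 min scale,
and the feedback/feedforward arms accumulate slowly (`k3`, `k4` chosen so
that Y\* builds over ~100 min), which makes M3 adapt visibly (output
peaking near 55 and settling near 22 under sustained input) and M4 respond
transiently. The noise level of the study follows from the pool size: with
totals of 100 molecules the chemical Langevin ensembles have a
coefficient of variation of roughly 10%, a realistic single-cell scale
that leaves the classification band (below) neither trivial nor
unsatisfiable.

### Input signal patterns

The ten patterns S1–S10 (`inst/extdata/signals.json`) are pure functions
of time — the input is exogenous and has no dynamics of its own:

\[ s(t) = \begin{cases} 1 - e^{-\beta_{on} t} & t \le t_s \\
   s(t_s)\, e^{-\beta_{off}(t-t_s)} & t > t_s \end{cases} \]

with fast (`0.5/min`) or slow (`0.02/min`) initiation, fast (`0.2/min`) or
slow (`0.01/min`) decay, switch times of 90 or 210 min, plus two sustained
patterns. These realise every fast/slow initiation × decay combination, so
reactions sensitive to onset, duration, or recovery are each probed by
some pattern.

## Control data: the synthetic experiment

`generate_control_data()` runs `n_replicates` chemical Langevin
simulations per pattern at the reference parameters and summarises X\* at
t = 30, 60, …, 300 min by ensemble mean, SD and SE (SD/√n). The CLE is
integrated by Euler–Maruyama,
\[ X(t+\Delta t) = X(t) + \sum_j v_j a_j \Delta t
   + \sum_j v_j \sqrt{a_j \Delta t}\, \eta_j,\qquad \eta_j \sim N(0,1), \]
with the square root of each propensity in the diffusion term
(Gillespie's Langevin form) and one independent Wiener increment per
reaction per step.

What the generator emulates: replicate-to-replicate variability of a
stochastic reaction network, amplitude that is only meaningful relative to
a scale (the classifier removes scale by construction), and a sampling
grid coarse relative to the dynamics. What it does **not** emulate:
measurement error on top of intrinsic noise, cell-to-cell parameter
variability, unequal replicate counts across conditions, and model
misspecification — the fitted model family is by construction the family
that generated the data. Passing tests therefore demonstrate correctness
of the machinery and of structural claims *within* the model family, not
robustness to wrong models.

Numerical choices, all exposed as arguments:

* `dt = 0.01` min — well below the fastest deterministic time scale
  (minutes) at the reference parameters; the weak-convergence test checks
  that halving it moves ensemble means by less than Monte-Carlo error.
* `noise_scale = 1` — propensities are interpreted as molecule-count
  rates; a single global factor rescales the diffusion term (0 recovers
  the deterministic limit, used in tests).
* Negative excursions are clipped to 0 before the next propensity
  evaluation (`boundary = "clip"`; `"reflect"` and `"none"` are
  available — `"none"` is what the additive-noise Ornstein–Uhlenbeck
  validation uses, since clipping would break its linear drift).
  Replicates that still diverge are redrawn up to a retry budget.
* Randomness: one root seed; each (model, pattern) ensemble runs under a
  derived substream seed (`seed + 1000 × pattern index`), replicates
  drawn sequentially within the substream. Identical seeds give
  bit-identical control data.

## Scoring and classification

The cosine fitness compares 10-point output vectors per pattern:
\[ \mathrm{fitness} = \sum_{i=1}^{10}
   \left(1 - \frac{\langle x_{sim,i}, x_{ctrl,i}\rangle^2}
   {\|x_{sim,i}\|^2 \|x_{ctrl,i}\|^2}\right) \in [0, 10], \]
invariant to positive rescaling of either vector — it measures shape, not
amplitude. The scaling factor `α_i = ‖x̂_ctrl,i‖/‖x_sim,i‖` maps a
simulation onto the control amplitude per pattern; a set is **positive**
iff `α_i·x_sim,i` lies within the control band at all 10 time points of
all 10 patterns (strict AND; no partial credit).

Two open choices are worth recording:

* **Band width.** The default band is mean ± SD. A standard-error band is
  implemented (`band = "se"`), but with 1000 replicates it is ~32× finer
  than the intrinsic noise, and not even the generating parameter set
  stays inside it at all 100 checkpoints — the acceptance suite documents
  exactly this (positive under SD, negative under SE for all four
  models). A criterion that rejects the true parameters is not usable as
  a reproducibility definition, hence SD.
* **Per-pattern vs global α.** α is defined per pattern (each pattern is
  independently rescaled); a single pooled factor is available
  (`scaling = "global"`) for checking that conclusions do not hinge on
  this.

## Collecting candidate parameter sets

All parameters are searched in natural-log coordinates on `[-15, 5]`
(values `e^{-15}` to `e^{5}`); the box is deliberately much wider than the
reference values. `random_sample_params()` draws log-uniformly — these
sets map the negative class. `estimate_parameters()` is a hybrid genetic
local search: a generational GA (tournament selection of size 3, uniform
crossover, per-coordinate Gaussian mutation of 0.6 log units, elitism)
whose archive is filtered so no two candidates lie within
`diversity_radius = 0.5` log units of each other, after which **every**
selected endpoint is refined by Nelder–Mead on the cosine fitness. The
returned candidates are therefore diverse local minima, not clones of one
basin. Elitism makes the best fitness non-increasing across generations
(property-tested). Fitness evaluations whose ODE integration fails get
the worst-case score and the set is excluded downstream, mirroring the
exclusion rule for failed solver runs.

Defaults (population 64, 80 generations, Nelder–Mead budget 50) were
fixed during development as the smallest budget at which the search
reliably reaches the reproducible region of all four motifs; they are
configuration, not constants, and are recorded per run in the pipeline
manifests.

## Local sensitivity of the output integral

The target is the time integral `q = ∫₀³⁰⁰ X*(t) dt`, a scalar summary of
the whole transient. For each reaction's rate constant,
\[ s_{\log} = \frac{\partial \ln q}{\partial \ln p_i}
   \approx \frac{q(p_i(1+h)) - q(p)}{h\, q(p)},\qquad h = 10^{-3}, \]
a one-sided, increase-only forward difference. Only rate constants are
perturbed by default, one per reaction, reported under the reaction's
label (A, D, R, …); Michaelis constants are available via
`perturb = "all"`.

Numerics: `q` is computed by composite trapezoid on a 0.5-min grid (601
points), far below the 0.1% perturbation signal; base and perturbed runs
use identical grids and tolerances (rtol = atol = 1e-10) so quadrature
error cancels to first order. For a parameter entering `q` linearly the
forward difference is exact up to solver error — the test suite pins this
at 1e-8. Because `s_log` is a log-derivative it is invariant to any
positive rescaling of the output, so α-scaling cannot affect it; the
stored `q` values use the unscaled trajectory.

## Trend statistics

"Sensitivity strength" comparisons *between* reactions (z-scores,
dominance, ratios) use the magnitude `|s_log|` by default: activating and
deactivating reactions have opposite signs by structure, so signed
comparisons would only restate the sign pattern, while the scientific
question is which reaction the output responds to more strongly. A
`measure = "signed"` switch exists.

* `zscore_across_reactions()` standardises each set's strengths across
  reactions (sample SD by default; population-SD switch, since with two
  reactions the sample-SD z-scores are always ±0.707).
* `pairwise_dominance()` reports, per ordered reaction pair, the
  percentage of positive sets in which the first strength strictly
  exceeds the second, with ties counted separately at a relative
  tolerance of 1e-9 (structurally identical reactions can tie exactly;
  the three percentages always total 100).
* `sensitivity_ratio()` gives per-set `log2(|s_A|/|s_B|)`.
* `hub_pca()` is PCA with a fixed sign convention (largest-magnitude
  loading positive) so results are deterministic; sensitivity PCA
  standardises columns (correlation scale) because strengths differ
  across reactions by orders of magnitude, with a covariance-scale flag.
  Observations are parameter sets and variables are reaction × pattern
  strengths; restricting to one pattern gives the per-pattern layout.
* `integral_sensitivity_correlation()` fills the reaction × pattern grid
  of Pearson correlations between `q` and `s_log` across positive sets.

## Conserved pools and the state representation

Activation/deactivation pairs conserve their pools exactly because every
reaction moves material between pool members (+1/−1 stoichiometry
columns); the integrator works on the full state vector, and conservation
is verified along trajectories to 1e-6 relative rather than imposed by
substituting `inactive = total − active`. With a compiled right-hand side
the one-dimension saving of substitution is not worth a second code path;
the invariant test makes the two formulations equivalent in exact
arithmetic and verifies the one we run.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the study at a desk-scale
profile chosen so the full analysis of all four motifs completes in
minutes on one CPU: 100 CLE replicates per pattern for control data, 100
search candidates plus 1000 random sets per model, sensitivities for all
positive sets on the 0.5-min quadrature grid. The `paper` profile of
`run_config()` scales the same pipeline to 1000 replicates, 1000
candidates and 10000 random sets. Every stage is reproducible bit-for-bit
from its seed; stochastic assertions in the tests use moment tolerances
of 3–4 Monte-Carlo standard errors.

## Known limitations

* The genetic local search is a generic hybrid optimizer; it honours the
  contract "diverse candidate sets with low cosine fitness" but is not a
  faithful reimplementation of any particular asynchronous
  diversity-controlled algorithm, and positive-set *counts* depend on its
  budget and on the random-sampling volume. Counts are therefore
  reported relative to their own run conditions, not as universal
  constants.
* Local sensitivities are first-order and one-sided by design; no global
  sensitivity measures (Sobol, Morris) are provided.
* Sensitivities are attached to rate constants only (by default);
  saturation constants are known to widen the reproducible region and can
  be probed with `perturb = "all"`, but the trend statistics index by
  reaction label.
* The classifier assumes equal replicate counts and a Gaussian-width
  band; no likelihood-based goodness of fit is attempted.
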