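---
title: "Modelling and training a quorum-sensing consortium perceptron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and training a quorum-sensing consortium perceptron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsperceptron)
```

## The model

A consortium of engineered *E. coli* computes a single-layer perceptron.
Each input bit `x_i` is the presence (1) or absence (0) of the inducer OC6
in the well of one *sender* group; graded inputs in `[0, 1]` are also
supported. A sender converts its input into production of the signalling
molecule OHC14, with mCherry as the measured proxy, and the strength of its
P_lux promoter sets the perceptron weight `w_i`. Senders with mutated P_lux
activator promoters give positive weights of different magnitudes; a P_lux
*repressor* promoter (LuxR binding site downstream of a strong constitutive
promoter) gives a negative weight, because OC6 then shuts production off.
When the sender mixture is pooled with *receivers*, the OHC14 they receive
is the weighted sum `s = sum_i w_i x_i` on the mCherry-equivalent axis, and
the receiver converts it into EYFP through its activation function
`sigma`, measured directly as EYFP versus sender mCherry. The simulated
readout is therefore `R(x) = sigma(s)`.

Transfer functions are Hill forms. Activators:

$$f(x) = \beta_m \frac{(x/K_d)^n}{1 + (x/K_d)^n} + \beta_m \beta_0,$$

bounded in `[beta_m * beta0, beta_m * (1 + beta0))`, strictly increasing,
with the exact half-max identity `f(K_d) - beta_m*beta0 = beta_m / 2`. The
repressor:

$$f(x) = \frac{\alpha_m}{1 + (x/K_d)^n} + \alpha_0\,\alpha_m
       = \hat\alpha_m\!\left(h(x) - \alpha_0 - 1\right),
  \qquad \hat\alpha_m = -\alpha_m,$$

strictly decreasing from `alpha_m (1 + alpha0)` to the floor
`alpha0 * alpha_m`. Only the signed amplitude `alphaHatM = -alpha_m` enters
the network as a weight; the constant factor stays inside
`evalRepressor()`. The parameter registry (`defaultRegistry()`) carries the
eight characterized circuits with their input-axis units, and unit mixing
is refused: sender outputs and the receiver activation input are
mCherry-equivalent arbitrary units, inducer doses are in uM.

Key modelling assumptions, chosen once and exposed as options:

* **Bit-0 policy.** A "0" bit contributes nothing: experimentally, an
  aTc-driven double-inversion circuit suppresses uninduced senders. An
  optional `"leaky"` policy adds the basal activity `beta_m * beta0` of
  uninduced senders; it is off by default.
* **Summation scale.** The weighted sum is taken directly on the mCherry
  axis of the measured receiver activation function, with no extra dilution
  factor for the sender:receiver mixing ratio — the activation function was
  measured under the same mixing protocol and absorbs it.
* **Graded inputs** scale the calibrated weight linearly
  (`w_i * x_i`) rather than re-evaluating the sender Hill curve at a scaled
  dose; this mirrors how the graded pattern sets are constructed
  (elementwise multiplication by a random vector).
* **Negative sums** are clamped to zero before `sigma` — an OHC14
  concentration cannot be negative — with a warning so clamping is never
  silent.
* **Weight noise**, when enabled, is multiplicative lognormal with unit
  mean and the requested coefficient of variation, drawn once per network
  under its own seed.

## Pattern sets

Each grid size `N` in {3, 5, 7, 9} has three categories, `z`, `v`, `n`.
A category contributes one clean bitmap plus the `N^2` patterns obtained by
flipping each bit once (raster order, clean first, category-major), so a
three-category set has `(1 + N^2) * 3` patterns: 30, 78, 150, 246. Graded
sets multiply every pattern elementwise by **one** shared random vector
with entries uniform in `[0.5, 1]`, drawn once per set under a recorded
seed — so the graded set preserves the binary set's zero structure and its
ordering.

The published pixel layouts of the glyphs are figure content and not
recoverable from extracted text, so the bitmaps are **configurable**, with
defaults constrained by what the text does state: the zero-bit fractions
3/9, 16/25, 36/49, 64/81, and the visual relationship that the three
categories are transforms of one another. The default base glyph is
mirror-symmetric about the vertical axis and not 180-degree symmetric
(at `N >= 5` a T shape — full top row plus centre column, `2N - 1` ones,
hence `(N - 1)^2` zeros; at `N = 3` a six-ones glyph with rows
`010 / 111 / 101`), and the `v` and `n` bitmaps are its 90-degree
counter-clockwise and clockwise rotations. The mirror symmetry is
deliberate: it guarantees that the `v`- and `n`-category cross products of
a symmetric weight vector coincide as multisets, reproducing the strong
cross-category repetition visible in the published response grids.

One consequence is worth stating plainly. With the categories generated as
transforms of a single glyph, the three one-vs-rest training problems
cannot all be permutation images of each other — the symmetry group of the
square has no orbit of size three — so the trained weight triple on the
3x3 set yields 18 distinct weighted-sum values among the 90 products
(verified against exhaustive enumeration of the full `4^9` discrete weight
space), not the ten reported for the original hand-drawn glyphs, whose
exact overlap structure the defaults cannot reproduce. The qualitative
phenomenon — massive repetition, identical `v`/`n` value multisets, and
high-state values shared across categories — is reproduced; the precise
count is glyph-specific. Users with the true bitmaps can supply them via
the `base` argument of `makePatternSet()`.

## Weight learning

Training minimizes the span-normalized squared error

$$L(w) = \tfrac12 \sum_j \left(\frac{R_j(w) - t_j}{\beta_m^{rec}}\right)^2$$

over the pattern set, where targets are two levels: `H`, the receiver
response at `3 K_d` (near saturation), and `L`, the basal response at zero
input, assigned one-vs-rest per category. The H/L placement is a design
choice — the labels are given but not their numeric values — and both
levels are configurable in `makeTargets()`.

The gradient flows analytically through `sigma` (clamped sums contribute
zero); a central finite-difference mode exists purely as a cross-check and
the two agree to `1e-4` relative on random instances. Two numerical choices
make the descent robust:

* **Reparameterization.** Steps are taken as
  `w <- w - eta * Kd_rec^2 * grad`, i.e. on weights measured in units of
  the receiver `K_d`. Together with the span normalization this makes
  `eta` dimensionless; the default `eta = 0.1` works across grid sizes
  without retuning.
* **Halve-on-overshoot.** A step that would increase the loss is retried
  with half the rate (up to 60 halvings), and the rate relaxes back by a
  factor 1.2 (capped at its initial value) after accepted steps. Accepted
  steps never increase the loss, so the trajectory is non-increasing by
  construction.

Iteration stops at `loss <= lossTol` (default `1e-4`), at a stationary
point (vanishing gradient or no improving step), after 25 consecutive
steps that each improve by less than `1e-7` of the current loss, or at
`maxIter = 1e4`. Divergence (non-finite loss) is flagged in the result
with its trajectory, never raised silently.

Experimentally realizable promoter strengths are discrete, so the default
mode constrains the final weights to a palette — by default
`{-735, 450, 900, 3500}`: the three calibrated sender mCherry levels at
the 33 uM induction dose plus the fitted repressor amplitude with negative
sign. Discrete handling is two-stage by default: continuous descent to
convergence, then projection of each weight to the nearest palette level
(equidistant ties break toward the smaller magnitude), then a refinement
search. The refinement is exhaustive **direct search** over all palette
combinations within `directSearchRadius` index steps per coordinate when
that neighbourhood fits the budget (it never increases the loss, and with
a radius spanning the palette it is global enumeration — on the 3x3 set,
`4^9 = 262144` combinations are enumerated outright); for larger grids it
falls back to greedy coordinate sweeps, which are monotone and scale
linearly in the bit count. An alternative cadence projects after every
step, since the exact published per-step discrete update rules are not in
the main text; both modes are exposed and tested.

Initialization is seeded uniform over the positive palette range; each
category's training run forks its own seed from the run seed by stage
name, so results are bit-reproducible and adding a category does not
perturb the others.

## Fitting dose–response tables

Fits minimize least squares on **log** responses via Levenberg–Marquardt
(`minpack.lm::nlsLM`) with positivity bounds and `n` in `(0.1, 10]`;
dose–response data span decades and log residuals weight the dynamic range
evenly. Starting values use the response-midpoint heuristic (`K_d` at the
input nearest the midpoint, `n = 1`, amplitude from the extremes). Flat
tables are flagged `degenerate` (the Hill coefficient is unidentifiable),
a log-scale R-squared below 0.5 is flagged `poorFit` (e.g. the repressing
model on increasing data), and fewer than four distinct input levels is an
error.

The synthetic dose–response generator exists for self-consistency checks,
and its defaults are sized for identifiability rather than to mimic an
instrument's feasible dose window: a 14-point three-fold dilution from
`K_d/243` to `6561 K_d` plus a zero-dose anchor, 32 replicates, 5%
multiplicative Gaussian noise. The wide series brackets both plateaus even
at `n = 0.35`, without which `K_d` and the amplitude trade off freely; the
replicate count comes from a Cramér–Rao calculation at 5% noise, under
which the worst-identified parameter (the `K_d` of the shallowest sender
promoter, relative standard error 28% per single-replicate series) needs
32 replicates for three standard errors to fit inside a 15% relative
error band. Real assays with a handful of replicates and doses capped at
~100 uM cannot pin a shallow-promoter `K_d` that tightly — passing
round-trip checks here demonstrate estimator correctness, not attainable
experimental precision.

## What the simulations do and do not show

The generator emulates the *structure* of the experiments: binary or
graded induction patterns, calibrated discrete weights, collective
summation, and a measured activation function. It does not model sender
cross-talk (beyond the zero-contribution assumption for suppressed
senders), OHC14 transport or spatial effects, receiver growth variability,
or cell-to-cell stochasticity; the optional multiplicative weight noise is
a lump proxy for calibration error, not a mechanistic noise model. Margins
computed here are therefore upper bounds on what flow cytometry would
show, and the wet-lab fluorescence magnitudes of the published bar plots
are outside the simulation's reach.

Problem sizes used throughout the package's own checks: grids 3x3 to 9x9
(up to 246 patterns, 81 weights), full enumeration oracles up to `4^9`
discrete combinations, and fit round trips over all eight registry rows —
each small enough to run in seconds to a couple of minutes on one core.

```{r example}
ps  <- makePatternSet(3)
res <- trainMulticlass(ps, trainingConfig(seed = 1, directSearchRadius = 4))
res$margins
countUniqueProducts(res$responseMatrix)$count
```
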