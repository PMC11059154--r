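---
title: "Methods: fractional-order snow leopard optimization and the preprocessing toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional-order snow leopard optimization and the preprocessing toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sloptim)
```

This vignette is the package's account of its methods: the optimizer model
and the choices behind it, the preprocessing operators, the composite
tuning objective, what the synthetic generators do and do not emulate, and
the numerical conventions that make every run reproducible.

## The snow leopard lifecycle as an optimizer

A population of N candidate solutions (rows of an N×m matrix inside the
box `[lower, upper]^m`) is evolved by four phases per iteration, each
mimicking a behaviour of the animal:

1. **Motion.** Member i takes a zig-zag step toward or away from a guide
   member k: with a scalar `r ~ U(0,1)` and `I = round(1 + r)`, the
   candidate in dimension d is
   `z + r (z_k - I z) sign(P_i - P_k)`. The sign term points the step
   downhill relative to the guide; `I = 2` (probability one half)
   over-shoots, which is what produces the zig-zag exploration.
2. **Preying.** Member i attacks a prey drawn uniformly among members with
   strictly lower cost: it strides a fraction `F = 0.375` of the distance
   and lunges the complementary `1 - F` with a doubled self term. `F` is
   the stride share of a documented snow leopard attack (15 m of stalking
   out of a 40 m approach) and is exposed as `prey_fraction`.
3. **Breeding.** Cub l is the elementwise midpoint of members l and
   N−l+1. Cubs are convex combinations of parents, so they can never leave
   the box.
4. **Fatality.** Parents and cubs (3N/2 candidates) are pooled, sorted by
   cost, and the best N survive. We made the cull deterministic (elitist
   truncation with a stable tie-break: parents before cubs, then lower
   index) rather than probabilistic; determinism makes runs exactly
   reproducible and the elitism guarantees a non-increasing best cost.

Candidate moves in phases 1–2 are accepted greedily: only a strictly lower
cost replaces a member. Together with elitist fatality this makes the
best-cost trace non-increasing by construction — the property tests assert
it on every run.

### Fractional-order memory

The fractional variant replaces the bare position term in both update rules
by a truncated Grunwald–Letnikov sum over the current and recent accepted
positions:

$$z^{new}_{i,d} = \sum_{a=1}^{M} c_a\, z_{i,d}(t-a+1) + \text{(phase step)},
\qquad c_1 = \sigma,\quad c_{a+1} = c_a \frac{a-\sigma}{a+1}.$$

The coefficients are the magnitudes of the GL binomial weights; written as
the explicit products `σ, σ(1−σ)/2!, σ(1−σ)(2−σ)/3!, …` they are all
positive for `σ ∈ (0,1)`, strictly decreasing, and sum to at most 1. We
implement this expanded all-positive form; the sampling step of the
underlying discrete derivative is one algorithm iteration (unit time), so
no extra scale factor appears.

Numerical conventions worth stating:

- **Memory slots.** One snapshot is pushed after each accepted phase
  (motion, preying), so "one time step" is one phase. Before `M` phases
  have elapsed the missing slots hold the initial positions. After
  fatality, each survivor carries its own history; a surviving cub starts
  with its own position as history. The a = 1 term always uses the live
  row, which is what makes `σ = 1` (coefficients `1, 0, 0, 0`) collapse to
  the classic update bit-for-bit.
- **Draw order.** All randomness flows through one seeded stream in a fixed
  order: per member, first `r`, then (motion) one guide index per
  dimension, or (preying) one prey index when more than one better member
  exists. Classic and fractional mode execute the same draw sequence, so
  the σ = 1 reduction is exact, not just statistical.
- **Ties.** `sign(0) = 0`: members with equal costs induce no movement.
  `round(1 + r)` rounds half away from zero, so `I = 2` exactly when
  `r ≥ 0.5`.
- **Bounds.** Candidates are clamped (projected) onto the box before
  evaluation; every stored position is always feasible.
- **Population size** must be even and at least 4; odd sizes are rejected
  rather than silently adjusted, since breeding pairs members end-to-end.

Defaults — N = 60, 120 iterations, σ = 0.9, M = 4, F = 0.375 — are the
validation settings used throughout the package's own checks. The
effectiveness check runs sphere in dimension 5 over 10 seeds and requires
the median final best to be at most 1% of the median initial best; in
practice the contraction is many orders of magnitude deeper.

### Benchmarks and the trial harness

The registry holds the classic analytic suite (sphere, rosenbrock,
rastrigin, ackley, griewank, schwefel 2.26, step, noise-free quartic, and
the two penalized functions) with their standard bounds and known optima;
every stated optimum is verified by evaluation at the stated minimizer. The
schwefel minimizer coordinate (420.96874635998…) was computed once
numerically to full double precision and frozen in the registry.
`run_trials()` reports per-cell mean (AVG) and sample (n−1) standard
deviation (STD) of final best costs over R seeded repeats, the standard
comparison protocol for metaheuristics; adapters for external optimizers
plug into the same harness. Published benchmark tables for this family of
algorithms are single stochastic outcomes on incompletely specified
function sets, so they are not numerical targets for this suite.

## Preprocessing operators

### Fuzzy-entropy adaptive median denoising

The operator assigns each pixel a membership to the "noisy" class from its
robust deviation: with `med` the local window median (odd window, default
3×3, replicate padding at borders) and `s` the global median absolute
deviation from the local median floored at one grey level,
`d = |x − med|/s` and

$$\mu_N = \frac{d^2}{d^2+1},\qquad \mu_F = 1-\mu_N,\qquad
E = -\mu_F\log\mu_F - \mu_N\log\mu_N .$$

The per-pixel fuzzy entropy `E` (natural log, `0·log 0 = 0`) is zero
exactly where membership is crisp and `log 2` at maximal ambiguity. The
filter is the membership-weighted blend `y = (1−w)x + w·med` with
`w = μ_N`, rounded half-up. Design rationale: the membership shape, window
and rule operator are not fixed by any single convention in the
fuzzy-denoising literature, so we chose the simplest construction with the
properties one wants — crisp impulse noise is replaced by the median
(`w → 1`), constant regions pass through unchanged (`w = 0`), and the
filtering strength grows smoothly with local uncertainty. The sliding
median is computed directly (a nine-shift gather for the default window)
so the border semantics are exactly replicate padding. Full fuzzy
rule-base learning from data pairs is intentionally out of scope; this is
the denoising operator only.

### Brightness-preserving bi-histogram equalization

The histogram is split at `X_m = floor(mean)`, and each sub-histogram is
equalized over its own range: `f_l` maps levels `≤ X_m` onto `[0, X_m]`
via the lower cumulative relative frequency, `f_u` maps levels `> X_m`
onto `[X_m+1, 255]` via the upper one; outputs are rounded half-up. The
range endpoints are the full 8-bit dynamic range (0 and 255), not the
observed min/max — the standard convention, and it makes the operator a
deterministic contract (a constant image maps to itself). The
implementation is cross-checked pixel-for-pixel against a brute-force
counting oracle on random images.

### SMOTE

Minority samples are oversampled by interpolation
`z_new = z_i + γ(z_j − z_i)`, `γ ~ U(0,1)`, with `z_j` drawn among the
k = 5 nearest minority neighbours (Euclidean; k is capped at minority size
minus one). Base points are cycled in random order so the synthetic mass
spreads over the whole minority class, and generation stops at exact class
balance. The generator indices and γ of every synthetic row are returned
as an attribute so segment membership is directly testable.

## The composite tuning objective

Candidates live in `[0,1]^5` and decode to a compact convolutional
configuration: conv blocks ∈ {1,2,3}, filters ∈ {4..32}, kernel ∈ {3,5},
dense units ∈ {8..64}, and a log-uniform learning rate in `[1e-4, 1e-1]`.
The objective is

$$Obj = \alpha_1\,loss + \alpha_2\,E_{rate} + \alpha_3\,\frac{N_{param}}{N_{max}}$$

with the raw weights (0.5, 0.7, 0.2) normalized to sum to one — the error
rate carries half the weight, the loss about 0.36, the complexity term the
rest. Normalizing the parameter count by the largest count in the space
(`N_max` = 60,482) keeps the three terms commensurate. The weights are
fixed run configuration, not decision variables: letting an optimizer tune
the weights of its own objective is degenerate (all weight drifts to the
easiest term).

The scored model is a deliberately compact stand-in classifier: the decoded
architecture determines the analytic parameter count (conv blocks over a
notional 16×16 single-channel input, then the dense head), while the
trainable part on tabular demo features is a one-hidden-layer network
(tanh hidden layer of `dense_units`, softmax output) trained by full-batch
gradient descent with momentum 0.9 at the decoded learning rate for a
fixed 300-epoch budget. Everything — the stratified 70/30 split, weight
initialization — derives from one evaluation seed held fixed across
candidates, so the objective is a deterministic function of the candidate
vector and the optimizer's own stream is never perturbed (evaluation runs
under an isolated RNG scope). The epoch budget was chosen so one
evaluation takes a fraction of a second and even the smallest learning
rate moves the readout layer far enough to classify well-separated
classes; loss and error are reported as-is, not tuned.

The demo problem (600 samples, 200 case / 400 control, separation 6
within-class standard deviations) is small enough that most candidates
classify nearly perfectly; the tuning run then mostly trades complexity
against residual loss, which is exactly the behaviour the composite
objective is designed to exhibit.

## Synthetic data: what it does and does not emulate

`make_phantom()` renders a schematic "knee slice": background, a bright
ellipse (joint), a diagonal band (ligament), optionally interrupted by a
gap (tear), plus Gaussian or salt-and-pepper noise applied after
rendering and clipped to [0, 255]. It gives the denoiser and enhancer
piecewise-constant structure with edges — the regime where median-based
filtering is well understood — and gives classifiers a localized
discriminative feature. It makes no claim of anatomical realism: real MRI
noise is Rician and spatially correlated, real anatomy is textured, and
passing tests on phantoms demonstrates correctness of the operators, not
clinical performance. `make_dataset()` draws class-conditional Gaussian
features at a configurable separation (default 6 sd, near-separable) and
exactly the requested class imbalance; separation 0 produces
indistinguishable classes. All generators are pure functions of their
arguments and a seed.

## Problem sizes used in the checks

The packaged checks run the optimizer at the validation settings (N = 60,
120 iterations, dimension 5) for the reduction, conservation and
effectiveness properties; 8×8 random images (100 of them) for the
bi-histogram oracle; 1000 random confusion matrices for the metric oracle;
a 64×64 phantom over 20 noise seeds for denoising; a 50/200 table for
SMOTE; and a 600-sample demo with population 10 and 15 iterations for the
end-to-end tuning loop. These sizes exercise every code path at full
fidelity while keeping a complete run of the suite comfortably fast on a
single core.

## Known limitations

- Only box constraints; no discrete or combinatorial search spaces.
- The probabilistic fatality reading (weaker members "more likely" to die)
  is documented but not implemented; the cull is deterministic.
- The stand-in classifier trains only on tabular features; convolutional
  layers enter through the parameter count, not through training.
- The denoiser is 2-D and single-channel; volumes would be processed
  slice-wise.
- Prey selection among strictly better members is one of several defensible
  readings (global best, any random member); ours drives convergence while
  preserving diversity, and the choice is isolated in one function.
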