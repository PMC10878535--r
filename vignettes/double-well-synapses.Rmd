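---
title: "Attractor networks with double-well synapses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor networks with double-well synapses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwsyn)
```

## The model

`dwsyn` studies memory in a recurrent network of `N` binary neurons
(`V_i ∈ {0, 1}`) updated in parallel through a threshold rule
`V_i ← Θ(h_i − θ)` with local field
`h_i = (1/N) Σ_j c_ij J_ij V_j`, where `c_ij` is a fixed, asymmetric,
Bernoulli(`c`) connectivity mask with empty diagonal. Synapses are
continuous variables `J_ij` that evolve in a piecewise-quadratic
*double-well potential*

`U(J) = (J − C)²` for `J > 0`, `U(J) = (J + C)²` for `J < 0`,

so each synapse has a low-efficacy state near `−C` and a high-efficacy
state near `+C`, separated by a barrier at `J = 0` of height `C²`. Between
pattern presentations a synapse relaxes exponentially toward the minimum of
the well it occupies, with rate `2 r1` (time constant `τ = 1/(2 r1)` in
units of the presentation interval); the relaxation never crosses the
barrier. At each integer time a random binary pattern `η` (i.i.d.
Bernoulli(`f`) entries) is imposed on the network and every synapse jumps
by `r2 · I(η_i, η_j) + r3 · ε`, with `ε` standard Gaussian plasticity
noise. Three jump rules are implemented: the *balanced* rule
(`I = ±1` by agreement of pre and post states, defined at `f = 1/2`), the
Tsodyks–Feigelman covariance rule `I = (η_i − f)(η_j − f)`, and an
Amit–Fusi-style rule (`I1` for coincident activity, `I2 < 0` for
mismatched activity, nothing when both are silent; defaults `I1 = 2C`,
`I2 = −f(1−f)`).

The model interpolates between two classical regimes. With `C = 0` it is a
single-well palimpsest: weights are Gaussian-like, memories decay
exponentially, and the storage capacity grows only logarithmically with
`N`. With deep wells (`r1` large) it approaches networks of binary
synapses with stochastic-looking transitions. A stored pattern of *age*
`t` (presented `t` patterns ago) is retrieved when initializing the
network at the pattern leads to a fixed point with large overlap
`m_v = Σ_i (η_i − f) V_i / (N f (1−f))`; the storage capacity `p` is the
largest retrievable age.

An exact symmetry of the weight dynamics is worth recording: because the
decay flow `dJ/dt = −2 r1 (J ∓ C)` is linear in `(J, C)`, scaling
`(r2, C, J, r3, θ)` by any `x > 0` maps trajectories onto rescaled
trajectories with `r1` unchanged, so every overlap and capacity is
invariant (this is asserted in the tests). `rescale_params()` also offers
the variant in which `r1` is divided by `x`; that transform changes the
decay rate relative to the presentation clock and is *not* a symmetry of
the capacity — the two variants are kept side by side precisely so that
the difference is visible.

## The master equation for the weight distribution

All analytical results flow from `g(J, t)`, the probability density of a
synapse's strength. One presentation cycle consists of (i) the jump
mixture — the density is shifted by `r2 I` for each plasticity class of
the rule and averaged with the class priors, then convolved with a
Gaussian of std `r3` if noise is on — and (ii) decay transport toward the
wells for one unit of time. `asymptotic_distribution()` iterates full
cycles to the periodic steady state `g∞` (sampled just before a
presentation). Conditioning on the jump a synapse received when a tracked
pattern was stored gives the *conditional* densities
`g_σ(J, t)` (`conditional_distributions()`), whose means and RMS values
drive both the retrieval theory and the SNR analysis.

Numerical choices (all configurable):

* **Grid.** 4000 regularly spaced points on `[−20, 20]` (spacing 0.01) by
  default. The grid is symmetric about 0 with no point at the origin, so
  the mirror map is exact. For shallow potentials the single-well
  stationary spread `σ = r_eff / sqrt(1 − e^{−4 r1})` can approach 20; the
  range is then widened automatically to `C + r2 + 6.5 σ` at the same
  spacing, and a guard refuses to return a density with more than `1e−6`
  mass within five cells of a boundary.
* **Decay transport.** The default (`scheme = "push"`) moves each cell's
  mass to its decayed image and splits it linearly between the two
  bracketing cells: exactly mass-conserving, first-moment accurate, and —
  important below — faithful to the fine structure of the deterministic
  dynamics; single-synapse Monte Carlo ensembles match `g∞` to the
  discretization-plus-sampling bound. The characteristics form
  `g(J, t+Δt) = e^{2 r1 Δt} g(J₀, t)` with linear interpolation at the
  pre-image `J₀` is available as `scheme = "interp"`; it must be
  renormalized after every step and smooths sub-cell structure, which
  changes deep-potential observables (see *Limits of the discretization*).
* **Presentation shifts.** Shifts land between grid points in general and
  are distributed linearly over the two neighbors (with the default grid
  and `r2 = 1` the balanced shifts are exact 100-cell moves). Mass shifted
  past a boundary is absorbed in the edge cell and caught by the boundary
  guard.
* **Noise.** The Gaussian kernel is truncated at `±6 r3`, renormalized,
  and applied with edge folding so mass is conserved exactly.
* **Convergence.** Cycles stop when the L1 change falls below `1e−10`, or
  when it stagnates below `1e−8` — the discretized map can settle into a
  grid-level limit cycle of that amplitude, far below anything of
  interest. The fixed point is unique; the default initial condition is a
  two-Gaussian guess at the wells (a uniform random start, which converges
  to the same density in more cycles, is kept as an option and the
  agreement is asserted in the tests).

## Mean-field theory of retrieval (balanced coding)

For `f = 1/2`, `θ = 0`, the local field of a neuron conditioned on its
states `(s_v, s_u)` in the probed pattern (age `u − v`) and in the most
recent pattern is approximately Gaussian. Its mean couples the conditional
weight moments to the overlaps:

`μ^{s_v s_u} = (c/2) [ ± M(t) m_v ± r2 m_u ]`,

where `M(t)` is the mean of the potentiated-class density at age `t` (the
depressed class is its mirror image), and its std is
`d = Ω sqrt(c f̃ / N)` with `f̃ = 1/2` the mean activity and `Ω` the RMS
weight *at retrieval time*, i.e. including the variance `r2² + r3²` added
by the most recent presentation (the identity of that presentation's jump
only moves the mean). Two derivation details deserve comment because they
are easy to get wrong by a factor of two:

* The conditional probability that a presynaptic neuron is active given
  its states in the two patterns is the Bayes combination
  `P = 2 p_v(s) p_u(s′)` of the two single-pattern conditionals — the
  bare product averages to 1/4 rather than the balanced mean activity 1/2
  and would halve every conditional field mean. With the factor 2 the
  table is self-consistent: pushed back through the overlap definition it
  returns exactly `(m_v, m_u)`, and the resulting
  `μ^{11} = c M m_v / 2` equals the directly computed conditional
  expectation of the field. The package's direct simulator provides the
  independent check: mean-field capacities agree with simulated ones to
  within seed-to-seed scatter (e.g. mean-field 15 vs simulated 12–15 at
  `r1 = 0.1`, `C = 2.5`, `N = 10⁴`).
* The overlap map uses `Φ(x) = erf(x)/2` with argument `μ/(√2 d)`: this
  and only this normalization makes the two `Φ` terms the exact Gaussian
  probabilities `P(h^{11} > 0)` and `P(h^{10} < 0)` for a field of std
  `d`.

Retrieval at age `t` is decided by iterating the overlap map from
`(m_v, m_u) = (1, 0.05)` — a retrieval state perturbed toward the most
recent pattern, perturbation size 0.05 — until both overlaps change by
less than `1e−8` (cap `10⁴` iterations). The pattern is retrievable when
the iteration settles at `m_v > 0` with `m_u ≈ 0`; flows to the most
recent pattern or to zero count as failures. The collapse at the capacity
boundary is abrupt (the overlap falls from ≈ 0.8 to 0 in one age step), so
the classification thresholds (`10⁻²` on both overlaps) are not delicate.

`capacity_meanfield()` brackets the largest stable age exponentially and
bisects, then scans a window beyond the bisection result: the conditional
mean `M(t)` of deep-well synapses can be *non-monotone* at small ages —
probability flux between wells lags the tagged jump — so stable ages can
reappear past the first failure. The conditional moment curves do not
depend on `N` or `c`, so `capacity_sweep_meanfield()` reuses one curve per
potential shape across a whole `N` grid.

Mean-field theory is restricted to balanced coding; for sparse patterns
the Gaussian approximation of the field conditioned on low-probability
activity is poor at realistic sizes, and the package uses direct
simulation only.

## Direct simulation

`simulate_capacity()` realizes the model literally: a connectivity mask is
drawn once per realization, a stream of patterns drives the synapses
(learning is clamped to the patterns; recurrent activity plays no role in
plasticity), and retrieval is probed read-only by initializing at a stored
pattern and running the threshold dynamics to a fixed point or 2-cycle. A
probe counts as retrieved when `m_v ≥ 0.5` (the retrieval branch sits near
1 and the collapsed branch near 0, so the cutoff is not critical — every
probe is logged so other cutoffs can be re-applied) and `m_v > m_u`, since
the network sometimes falls into the most recently shown pattern instead.
Weights start either at zero followed by a burn-in of `20 τ` presentations
(minimum 200, with the RMS monitored across the two halves and a warning
on drift), or — equivalent and much cheaper at small `r1` — as i.i.d.
draws from the master-equation `g∞`, after which only the probe window of
patterns needs presenting. The capacity search mirrors the mean-field one,
including the re-entrant age scan.

For sparse coding the package follows the standard protocol: `c = 1`,
`f = 4 log(N)/N`, and the neuronal threshold `θ` and width `C` optimized
by grid search (`optimize_capacity_sparse()`). The two rules behave very
differently. With the covariance rule the optimum is a single well
(`C = 0`) and capacity is logarithmic in `N` with a prefactor ∝ τ; the
weights have a proper stationary distribution and the equilibrium-draw
initialization applies. With the Amit–Fusi rule at `I1 = 2C` the
potentiation jump maps the bottom of the low well exactly onto `+C`, so a
potentiation *always* switches the synapse up, while the deterministic
depressions (`|I2| = f(1−f) ≪ C`) can never cross back at `r3 = 0`.
Memories are therefore forgotten by *overwriting*: the fraction of
potentiated synapses grows like `f² t`, and a stored pattern stays
retrievable until saturation erases its contrast — giving a capacity on
the `1/f² ∼ (N/log N)²` scale, supralinear in `N`. This regime is a
transient of an initially unsaturated network, so the simulations start
from zero weights with no burn-in (the degenerate stationary state, all
synapses potentiated, carries no memory at all); capacities quoted for
this rule are properties of that protocol, like the reference results
they reproduce.

## Binarized SNR and the matched Markov synapse

Binarizing the weights (`w = sign(J)`) turns the model into an effective
two-state synapse whose transitions depend on the analog position within
the wells. The SNR of the binarized connectivity with respect to the ideal
trace of a pattern of age `t` reduces, at balance, to
`SNR(t) = sqrt(cN) ∫ g_{+}(J, t) sign(J) dJ`. Because decay never changes
the sign of a weight, the curve is piecewise constant between
presentations and is reported at integer ages. The *matched* two-state
Markov synapse copies the equilibrium well-switching probabilities of the
double-well model (mass of `g∞` restricted to one well that ends in the
other after one presentation) into column-stochastic transition matrices
`M_pot`, `M_dep`; its SNR is
`SNR_b(t) = (sqrt(cN)/2) wᵀ e^{tW} (M_pot − M_dep) p∞` with
`W = (M_pot + M_dep)/2 − I`. The two models agree exactly at `t = 0` by
construction — both equal `sqrt(cN)` times the net switching probability —
which the tests assert, and the matrix-exponential form is cross-checked
against a brute-force simulated two-state chain (whose exact mean operator
is `((M_pot + M_dep)/2)^t`; the `"discrete"` method exposes it). The
envelope bound over all two-state Markov models, `sqrt(cN) e^{−t}` for
`t ≤ 1` continued as `sqrt(cN)/(e t)` beyond, is validated by a scan over
transition matrices. The double-well SNR is non-monotone in age at deep
optimal wells and exceeds this envelope at intermediate ages — the analog
depth within a well stores history that no two-state chain can represent.

The overall `sqrt(cN)` normalization is the standard deviation of the
null overlap of `cN` independent `±1` synapses; all comparative statements
(equality at `t = 0`, bound crossing) are independent of this constant.

## Robustness to plasticity noise

With `C` fixed at its noiseless optimum, capacity decreases monotonically
with `r3`. `robustness_R()` normalizes the noise by the stationary weight
scale, `r̃3 = r3/Ω` with `Ω` the RMS of the noiseless `g∞` (the mean is
zero at balance, so the RMS is the natural scale), and reports
`R = |dp/dr̃3|⁻¹`, the reciprocal slope fitted by least squares over the
small-noise window where `p` has dropped by at most 20% of `p(0)` — the
window rule is a declared choice, configurable, since no standard exists.
Deeper potentials trade capacity for robustness: `p(0)` falls and `R`
rises with `r1`. Away from the optimum the picture is richer: for
`C` above the noiseless optimum the Hebbian jumps alone cannot cross the
barrier and a moderate amount of noise *increases* capacity (an interior
maximum in `r3`), which the tests check at `r1 = 0.1`.

## Limits of the discretization, and why they matter

At `r3 = 0` the deterministic deep-well dynamics hide a surprise: the
stationary within-well offsets are a Bernoulli convolution with
contraction ratio `e^{−2 r1}`. For `r1 < ln 2 / 2 ≈ 0.35` this
distribution is continuous and everything is numerically benign. For
deeper wells it is supported on a Cantor set, and the probability `q(C)`
of switching wells under a single jump is a *staircase* in `C` with values
near `2^{−k}` (a switch requires `k` consecutive potentiations). The
capacity-optimal width sits on the stair whose `q` is closest to
`e/sqrt(cN)`, and resolving stair `k` requires grid and `C` resolution of
order `e^{−2k}`. The package therefore: (i) keeps the exactly
mass-conserving push transport as the default, because it reproduces the
true staircase (verified against Monte Carlo) instead of smearing it;
(ii) uses a finer grid (`dx = 5 × 10⁻⁴`) and several rounds of local `C`
refinement for deep-potential capacity sweeps, which resolves the stairs
that carry the capacity at the sizes studied (`N ≤ 10⁵`, stairs `k ≤ 4`);
and (iii) documents that the interpolated transport, while it looks
smoother, both misses the stairs and can manufacture spurious slow modes
through its per-step renormalization.

## What the synthetic patterns do and do not emulate

All inputs are generated in code: i.i.d. Bernoulli(`f`) patterns (with
`f = 4 log(N)/N` for the sparse protocol), Bernoulli(`c`) masks, Gaussian
plasticity noise. This matches the model class exactly — there is no real
data in scope — but it also means that passing tests say nothing about
correlated patterns, heterogeneous synapses, multiple wells or timescales,
learning driven by recurrent activity, or asynchronous dynamics, all of
which are outside the model.

## Problem sizes used in the automated checks

The test-suite and acceptance runs use reduced but structurally faithful
sizes, chosen once: mean-field checks at `N = 10³–10⁵` (the conditional
moment curves are `N`-independent and shared); the mean-field/simulation
comparison at `N = 5 × 10³` with 5 realizations (the reference figure uses
`3 × 10⁴` and 10); sparse-coding scaling on `N ∈ {300, 600, 1200}` with
the flat-potential case run at `r1 = 0.01` rather than `10⁻³` (capacity at
`τ = 500` is `O(500)` at any of these sizes, dominated by the decay
constant rather than `N`; `r1 = 0.01` stays in the single-well regime and
preserves the logarithmic form being tested); and the noise-robustness
contrast between the flat and deep sparse regimes at `N = 300`, compared
on the noise axis beyond the deep rule's deterministic saturation
transient (which exists only at `r3 ≈ 0`). Monte-Carlo oracles use
vectorized ensembles of `≥ 2 × 10⁵` stationary samples.

## Known limitations

* The mean-field theory assumes `cN ≫ 1` Gaussian fields; at `cN ≲ 100`
  its capacities are a pattern or two optimistic relative to simulation.
* Storage capacities are integers; scaling-exponent fits at small `N`
  carry quantization error of order one pattern.
* The critical depth separating single- from double-well optimality is
  determined by capacity differences of 1–2 patterns in ~80, so its value
  is sensitive to the overall signal-to-noise normalization of the
  retrieval theory; the package uses the normalization that its own
  simulations validate.
* Deep-potential results at `r3 = 0` depend on resolving the staircase
  structure described above; quantitative `q(C)` values beyond stair
  `k ≈ 4` are out of reach of any practical grid.
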