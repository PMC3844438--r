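---
title: "Methods: sequence replay under inhomogeneous sparseness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence replay under inhomogeneous sparseness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqreplay)
```

## The model and its assumptions

`seqreplay` studies one-step sequence associations in a recurrent network of
N binary threshold neurons. A memory sequence is an ordered list of random
binary patterns ξ_0 → ξ_1 → … → ξ_P; pattern ξ_k activates M_k = f_k·N
neurons, where f_k is its *coding ratio*. The synaptic weight from neuron j
to neuron i factorizes as J_ij = w_ij·s_ij: a static morphological mask
w_ij ~ Bernoulli(cm) and a binary synaptic state s_ij set by the clipped
Hebbian (Willshaw) rule — potentiated iff j fires in some ξ_k and i in
ξ_{k+1}, with repeated potentiation having no further effect. Inhibition is
instantaneous negative feedback h(x) on the total activity x, subtracted
from the input alongside the firing threshold θ.

The core assumptions inherited from this model family:

* discrete time, synchronous updates (each step one association);
* patterns are uniformly random and independent, so a neuron's role is fully
  captured by its *activation schedule* (the set of patterns it joins);
* inhibition acts within the time step, with weight b = cm·ς by default, so
  that the mean potentiated drive and the inhibitory drive cancel exactly in
  the saturated regime;
* the mean-field description treats hits m_t (active neurons of ξ_t) and
  false alarms n_t (active non-members) as real-valued expectation values
  with Gaussian input statistics.

What is new relative to the homogeneous textbook case is that the coding
ratios f_k are themselves random, drawn from a coding-ratio distribution
p_ϕ with mean ϕ0 and standard deviation σϕ. All connectivity statistics are
then random variables over the realization of ϕ, and the package
distinguishes carefully between per-realization quantities (ς(ϕ), Vς²(ϕ))
and ϕ-ensemble quantities (⟨ς⟩, σς²).

## Coding-ratio distributions

Two families cover the experiments:

* **Gamma**, parameterized by mean ϕ0 and sd σϕ (shape ϕ0²/σϕ², scale
  σϕ²/ϕ0). σϕ = 0 is legal and yields the degenerate, homogeneous
  distribution; every downstream quantity then reduces to its closed
  homogeneous form, which the test suite asserts end-to-end.
* **Triangular**, for controlled skewness: a symmetric triangle with mode
  ϕ_max, or one-sided triangles entirely below (negative skew, an excess of
  small patterns) or above the mode. The one-sided triangles match σϕ
  *exactly*; elementary moment algebra then places their mean at
  ϕ_max ∓ √2·σϕ (≈1.41σϕ off the mode). We deliberately report this achieved
  mean (the `phi0` field of the spec) rather than forcing a nominal 2σϕ
  offset, which a σϕ-exact one-sided triangle cannot have; the skewness
  comparisons in the analysis layer only require that the negative and
  positive cases be exact mirror images, which they are.

Raw moments up to order four are closed-form for the Gamma family (the
rising-factorial formula `scale^k · Γ(shape+k)/Γ(shape)`, verified against
numeric quadrature to 1e−8 in the tests — note the σϕ⁴ coefficient of the
fourth moment is 11, an easy one to get wrong by hand) and quadrature-based
for the triangular family.

Sampling rejects draws with f ≥ 1 or round(f·N) < 1 and resamples, with a
1000-round cap; for the parameter regimes of interest rejections are
essentially never triggered. One master seed spawns counter-derived
sub-streams per realization, so ensembles are reproducible and independent
of evaluation order.

## Connectivity statistics

For a realized ϕ the potentiation probability is the exact product
ς = 1 − Π(1 − f_k f_{k−1}), accumulated via `log1p` so that P in the
thousands costs no precision. The Willshaw rule correlates synapses that
converge on the same neuron; the strength of this correlation is the squared
variation coefficient Vς² of the per-schedule potentiation probability ς_A,
computed from the closed product form of E[ς_A²]. Both are validated against
exhaustive enumeration of all 2^P activation schedules for P ≤ 12.

Ensemble moments over ϕ are available by three routes:

* **moments** — the combinatorial expansion of ⟨ς⟩ and ⟨ς²⟩ in the first
  four raw moments of p_ϕ, organized by maximal runs of adjacent index pairs
  (counts n_j(P,k) = C(P−k+1, j)·C(k−1, k−j), a run-sum recursion S_kj, and
  per-run averages ψ_m split by how many runs touch the chain boundary).
  The alternating sums are evaluated in log-magnitude form with explicit
  cancellation tracking: if fewer than ~6 significant digits survive, the
  function raises an error naming the offending P rather than returning
  noise. In practice the expansion is safe whenever P·⟨f²⟩ stays below 1 and
  is intended for P up to a few hundred (its cost grows as P²–P³).
* **chain** — the same expectations evaluated exactly by a transfer matrix:
  the product couples only *consecutive* i.i.d. coding ratios, so
  ⟨Π(1−f_k f_{k−1})⟩ and its square are 2×2 / 3×3 matrix powers in the first
  four moments. This is O(P), stable at any P, and is the default above
  P = 300 (e.g., for ensemble-mode calibration at P ≈ 7000).
* **mc** — Monte Carlo over sampled ϕ vectors, chunked to bound memory.

The three routes agree to ~10 significant digits (moments vs chain) and
within Monte-Carlo error in the tests; exhaustive expansion over all index
assignments provides the ground truth at small P. The boundary-split form of
ψ_m is subtle enough that we treat the enumeration and Monte-Carlo
equivalence tests as authoritative for it.

## Calibration of the storage load

The experiments hold the mean effective connectivity c = cm·ς fixed (0.05
throughout the standard settings) and let the number P of stored
associations float. `calibrate_P()` supports two readings: per realization
(extend the sampled ϕ pattern by pattern until ς(ϕ) crosses c/cm — the
default for all replay ensembles, so that every run has *exactly* the target
noise connectivity, with overshoot bounded by one pattern's f²) and ensemble
(smallest P whose ⟨ς⟩ crosses the target, by bisection on the monotone
mean). The replay pipelines feed the mean field the realized ς(ϕ) and
Vς²(ϕ) of each sampled vector, not ensemble means, and set b = cm·ς(ϕ)
accordingly.

## Mean-field replay dynamics

One step maps (m_t, n_t) to

* μ_On = cm·m + cm·ς·n,  σ²_On = cm·m(1−cm) + cm·ς·n(1 − cm·ς + Vς²·cm·ς(n−1)),
* μ_Off = cm·ς(m+n),    σ²_Off = cm·ς(m+n)(1 − cm·ς + Vς²·cm·ς(m+n−1)),
* m' = M'·Φ((μ_On − θ_eff)/σ_On),  n' = (N−M')·Φ((μ_Off − θ_eff)/σ_Off),

with θ_eff = θ + h(m_t + n_t). Notes on deliberate choices:

* the Vς² correction enters only the potentiated-noise terms, exactly as in
  the underlying input model; the cross-covariance between the signal and
  noise inputs of the On population is not modeled;
* the inhibition argument is the *pre-step* activity m_t + n_t;
* m, n are propagated as real numbers; pattern sizes are the real-valued
  f_t·N by default (integerized sizes are available for the binary
  simulator, M_k = round(f_k·N) clamped to ≥ 1);
* replay starts from the intact first pattern (m_0 = M_0, n_0 = 0); a
  partial-cue fraction is exposed but unused by the standard analyses;
* σ = 0 is treated as a hard threshold (Φ → step function, value ½ at
  equality), making the all-silent state an exact fixed point for θ > 0;
* variances are floored at 0 against roundoff from the (n−1) factors at
  sub-neuron activities.

**Linear vs supralinear inhibition.** Linear feedback h = b·x with b = cm·ς
cancels the mean potentiated drive exactly: the saturated ("epileptic")
state then pins total activity at Φ(−θ/σ)·N, slightly below N/2 — the tests
assert hit and false-alarm fractions inside [0.4, 0.6] there. The
supralinear option replaces the sub-threshold branch by a sigmoid
κ/(1+e^{−λ(x−ν)}) for x ≤ ϕ0·N with λ = 10⁻⁴/ϕ0 and κ, ν chosen for
continuity and slope b at the operating point ϕ0·N. This requires
λ·ϕ0·N > 1 (equivalently N > 10⁴; the constructor refuses otherwise). Below
the operating point the sigmoid provides *less* inhibition than b·x —
effectively a positive boost after an undersized pattern — at the price of a
reduced noise margin, since θ_eff − μ_Off shrinks by b·x − h(x). That
trade-off is visible in the validation test: a strong dip in pattern size is
carried through by the sigmoid while linear feedback lets the network die
out.

## Binary-network validation

The full simulator stores the sequence explicitly and runs the threshold
dynamics; it is the ground truth against which the mean field is checked.
Implementation choices:

* only the *effective* weights (potentiated ∧ morphological) are
  materialized, as a sparse matrix; the count of never-potentiated
  morphological synapses is drawn as one binomial variable. The joint law of
  everything observable — J, the potentiation fraction, the dynamics — is
  identical to the full construction at a small fraction of the memory;
* self-connections are excluded (autapses would add a self-excitation term
  absent from the mean field);
* a neuron exactly at threshold fires (Θ(0) = 1). With integer synaptic
  input and non-integer inhibition ties are rare, but a fixed, switchable
  convention keeps runs reproducible;
* inhibition shares the exact implementation (and code path) with the mean
  field, evaluated on the integer activity count.

Validation operates at N = 3000–10⁵ depending on the check: potentiation
fractions against ς(ϕ) with a variance that combines binomial thinning and
the Vς² schedule correlation; ensemble means of (m_t, n_t) over 100 networks
against the mean-field trace within 3 ensemble standard errors (plus a
0.1-neuron discreteness floor), in a cell chosen well inside the stable
wedge — near the wedge boundary the Gaussian tail approximation is
systematically off by more than Monte-Carlo error, which is precisely why
the paper-level analyses classify success/failure rather than match moments
there; and success/failure classification agreement in clearly stable and
clearly silent cells.

## Replay analyses

* Retrieval quality Γ_t = m_t/M_t − n_t/(N−M_t); a step is successful iff
  Γ_t > 0.5 (strict).
* The success rate ϱ_t is the fraction of realizations with Γ_t > 0.5,
  each realization drawing a fresh ϕ (and fresh calibrated P).
* T90 is the longest *prefix* with ϱ > 0.9 strictly at every step — one bad
  step ends the credited length. The maximum retrievable length T maximizes
  T90 over an integer threshold grid, default 1..60 (the stable wedges at
  ϕ0 = 0.01 live around θ ≈ 24–33; the wide default grid keeps the maximum
  an interior point).
* The capacity curve T(P) is fitted as log T = const − α·log P on the
  strictly decreasing branch (points past the last maximum with T > 0; the
  fit is skipped and flagged below 3 points). The cutoff capacity Pc is
  operationalized as the intersection of the fitted line with the plateau
  T = Q and is reported alongside the raw curve so other readings can be
  applied post hoc.
* Termination statistics record, per failed realization, the size pair
  (M_τ, M_{τ+1}) around the last successfully replayed step τ; realizations
  that never fail within Q are excluded from the denominator and counted
  separately.
* Phase diagrams evaluate ϱ or mean Γ at t = 100 on a grid of
  (ϕ0 or ϕ_max) × θ, with per-cell ensembles.

## Problem sizes and determinism

The standard study conditions are N = 10⁵, cm = 0.1, ϕ0 = 0.01, c = 0.05,
Q = 100. The package's own test and reproduction runs use: 10⁴ realizations
for the termination scatter; 100 realizations per threshold for capacity
searches (the homogeneous ensemble is deterministic, so one realization
suffices there); 30–40 realizations per cell for phase-diagram grids of
5 × 21–31 cells; and binary-network ensembles of 10–100 networks at
N = 3000–10⁵ with small storage loads, which keep the sparse weight
construction light. These sizes give binomial standard errors comfortably
inside the assertion bands used in the tests; all of them are parameters,
not limits.

Every stochastic function takes a seed; ensembles derive per-realization
sub-seeds by counter from the master seed, so enlarging an ensemble never
reshuffles its earlier members, and identical (config, seed) pairs produce
byte-identical experiment artifacts (the CSV/JSON outputs embed a config
hash).

## Known limitations

* The mean field is an expectation-value description: near wedge boundaries
  its Gaussian input tails misestimate rare-event rates (hence
  classification-level validation there), and it cannot capture
  realization-to-realization variance of the *network* construction at
  fixed ϕ.
* The supralinear inhibition's shape parameter λ = 10⁻⁴/ϕ0 hard-codes an
  absolute activity scale; meaningful sub-threshold behaviour needs
  λ·ϕ0·N ≫ 1, i.e. networks well above 10⁴ neurons.
* No synaptic delays, spiking dynamics, cue degradation studies, palimpsest
  forgetting, or plasticity during replay: the synaptic matrix is frozen
  after learning.
* Coding-ratio families are limited to Gamma, triangular and the degenerate
  point mass; there is no fitting of p_ϕ to data.
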