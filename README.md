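# seqreplay

Sequence memory in recurrent networks of binary neurons degrades in a very
particular way when the stored activity patterns are not all equally sparse.
`seqreplay` is a simulator and analysis library for exactly this question: it
implements a Willshaw-type (clipped Hebbian) sequence-memory network with
instantaneous feedback inhibition, generalized so that each stored pattern k
activates its own number M_k = f_k·N of neurons, with the coding ratios f_k
drawn from a distribution (Gamma or triangular). It is written for
computational neuroscientists who want to quantify how *inhomogeneous
sparseness* affects replay stability, storage capacity, and the mechanisms by
which replay terminates.

## The model

Binary neurons x_i ∈ {0,1} update synchronously,

    x_i(t+1) = Θ( Σ_j w_ij s_ij x_j(t) − θ − h(Σ_j x_j(t)) ),

where w_ij ~ Bernoulli(cm) is the morphological connectivity, s_ij the binary
synaptic state set by the Willshaw rule (potentiated iff neuron j fires in
some pattern ξ_k and neuron i in ξ_{k+1}), θ the firing threshold, and h the
instantaneous feedback inhibition — linear h(x) = b·x with b = cm·ς, or a
supralinear sigmoid that backs off at low activity.

For a coding-ratio vector ϕ = (f_0, …, f_P) the potentiated fraction of
morphological synapses is

    ς(ϕ) = 1 − Π_{k=1..P} (1 − f_k f_{k−1}),

which reduces to the classical capacity relation
P = log(1 − c/cm)/log(1 − f²) in the homogeneous case (effective
connectivity c = cm·ς). The package computes ς exactly per realization, its
activation-schedule second moment E[ς_A²] and variation coefficient Vς²
(the learning-induced synaptic correlations), and the ensemble mean ⟨ς⟩ and
variance σς² over ϕ — by combinatorial moment expansion, by an exact
transfer-matrix evaluation, or by Monte Carlo.

Replay itself is tracked by a two-variable mean-field map for the hits m_t
and false alarms n_t, with Gaussian input statistics and the threshold
substitution θ → θ + h(m_t + n_t), validated against the full binary-network
simulator. Derived analyses include the retrieval quality
Γ_t = m_t/M_t − n_t/(N−M_t), replay success rates ϱ_t (fraction of
realizations with Γ_t > 0.5), the maximum retrievable sequence length
T = max_θ T90, phase diagrams in (ϕ0, θ), power-law capacity fits, and
termination-mechanism scatter plots.

## Worked example

Store a sequence with 20% size inhomogeneity, calibrated to effective
connectivity c = 0.05, and replay it at threshold θ = 28:

```r
library(seqreplay)
spec <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.002)  # sd = 20% of mean
cal <- calibrate_P(spec, c_target = 0.05, cm = 0.1, N = 1e5, seed = 1)
cal$P                      # 6912 associations reach varsigma = 0.5
p <- replay_params(cal$phi, N = 1e5, cm = 0.1, theta = 28)
p
#> mf_params: N = 1e+05, cm = 0.1, theta = 28, varsigma = 0.5, V2 = 0.00717,
#>            b = 0.05, linear inhibition
tr <- run_replay(cal$phi, p, Q = 100)
tail(tr, 3)
#>       t      M      m      n  gamma
#> 99   98  956.6  946.1  32.46 0.9887
#> 100  99 1263.9 1239.8  22.12 0.9807
#> 101 100  938.0  937.3 144.24 0.9979
```

This particular realization replays the full sequence (Γ_t ≈ 0.99
throughout: nearly all pattern neurons active, almost no false alarms). But
single runs are deceptive — over an ensemble of ϕ realizations the success
rate collapses with time at this inhomogeneity:

```r
sc <- success_rate(spec, theta = 28, N = 1e5, cm = 0.1, Q = 100,
                   n_real = 200, seed = 2, c_target = 0.05)
sc$rho[c(5, 20, 100)]      # 0.91 0.525 0.035
t90(sc)                    # 6 — only short prefixes replay reliably
```

So at σϕ/ϕ0 = 20% only the first handful of associations is retrieved with
better than 90% reliability, even though the homogeneous network at the same
connectivity replays all 100 steps with certainty — the central trade-off
the analysis tools quantify.

## Command-line wrapper

`inst/scripts/seqreplay-cli.R` is a thin Rscript over
`run_experiment()`: experiments (`replay`, `success`, `phase`, `capacity`,
`scatter`, `validate_network`) are described by a JSON/YAML config and
written as tidy CSV plus a JSON sidecar embedding the config hash.
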