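# gammalock

Phase locking and macroscopic phase-resetting analysis of coupled
gamma-oscillatory spiking circuits.

## What this package is for

Gamma-band (30–150 Hz) oscillations emerge in cortical circuits from the
interplay of pyramidal cells and interneurons, and distant circuits
holding such rhythms lock to one another at a variety of phase lags —
relationships believed to route information between areas.  `gammalock`
is a toolbox for studying that chain of mechanisms quantitatively in a
tractable model class: all-to-all networks of quadratic
integrate-and-fire (QIF) neurons,

    τ v̇ⱼ = ηⱼ + vⱼ² + I(t),

with Lorentzian-distributed excitability ηⱼ (centre η̄, half-width Δ)
and first-order synapses τₛ ṡ_αβ = −s_αβ + J_αβ r_β.  For this class
the infinite-network limit reduces **exactly** to eight ODEs per circuit
in the population rate r(t) and mean voltage V(t):

    τ ṙ = Δ/(πτ) + 2 r V
    τ V̇ = V² + η̄ + I_ext + τ s_e − τ s_i − τ²π² r²

The package provides, for users in computational neuroscience:

* finite-size spiking-network simulation (single circuits and
  delay-coupled pairs) with a compiled core, plus rate estimation and
  spectral frequency readout;
* the exact mean-field reduction: integration, fixed points, Hopf
  bifurcation scans and oscillation maps for the PING (E–I loop) and
  ING (I–I loop) gamma mechanisms;
* the macroscopic infinitesimal phase-resetting curve (iPRC) of the
  population rhythm via the adjoint equation −Ż = M(t)ᵀZ with
  normalisation Z·Ȯ = 2π/T, validated against direct pulse
  perturbations, and PRC-type classification (monophasic / biphasic /
  null);
* the weakly-coupled-oscillator machinery for two circuits coupled
  through their pyramidal cells with conduction delay d: interaction
  function H(θ), coupling function G(θ) = H(θ+d) − H(−θ+d), locking
  modes (zeros of G, stable where G′ < 0) and bifurcation diagrams over
  delay and coupling strengths;
* direct simulation of the coupled 16-ODE delay system and of twin
  spiking networks, phase-lag extraction, leader/follower
  identification, and the **global PRC** of the locked pair — whose
  leader/follower asymmetry exposes directional signal transfer through
  a structurally symmetric motif.

## A worked example

```r
library(gammalock)

# the PING operating point: tau = 10 ms, tau_s = 1 ms, eta_bar = -5,
# Delta = 1, J_ei = J_ie = 15, E-drive 10
pp <- figure_preset("fig2_ping")

# most neurons are not intrinsic oscillators: the rhythm is emergent
fraction_non_oscillatory(-5, 1)
#> [1] 0.9371670

# the reduced circuit has a stable gamma-band limit cycle
cyc <- find_limit_cycle(pp$e_params, pp$i_params, pp$couplings,
                        drive_values = c(10, 0))
cyc
#> Limit cycle: T = 20.8112 ms (f = 48.05 Hz), 1024 samples, closure residual 3.05e-10

# its macroscopic phase-resetting curve, by the adjoint method
adj <- adjoint_iprc(cyc)
adj
#> Adjoint iPRC: T = 20.8112 ms, 1024 samples, normalization residual 1.91e-06,
#>   periodicity residual 2.08e-09 (8 backward periods)
classify_prc(adj$Z[, "Z_ve"])   # E-cell pulses only advance the rhythm
#> [1] "type I"
classify_prc(adj$Z[, "Z_vi"])   # I-cell pulses advance or delay it
#> [1] "type II"

# couple two such circuits through their pyramidal cells
cf <- interaction_function(adj, cyc, cross = cross_coupling(0.1, 0.5))
locking_modes(coupling_function(cf, delay = 0))
#>   theta_star stable        slope marginal
#> 1     0.0000   TRUE -0.001400009    FALSE
#> 2    10.4056  FALSE  0.001076448    FALSE
locking_modes(coupling_function(cf, delay = 10))
#>   theta_star stable        slope marginal
#> 1     0.0000  FALSE  0.001085836    FALSE
#> 2    10.4056   TRUE -0.001540489    FALSE
```

Without delay the two rhythms can only synchronise (the in-phase lag
θ\* = 0 is the stable zero of G; anti-phase at T/2 = 10.41 ms is
unstable); a 10 ms conduction delay reverses both stabilities and the
pair locks in anti-phase.  At intermediate delays (here d ≈ 5.5–8 ms)
the stable lag glides continuously between the two — spontaneous
symmetry breaking into leader and follower roles, which
`settle_locked_state()`, `identify_leader_follower()` and
`global_prc()` then probe for directional signal transfer.  The same
predictions can be checked against the spiking pair:

```r
sim <- simulate_coupled_spiking(pp$e_params, pp$i_params, pp$couplings,
                                cross_coupling(0.1, 0.5, delay = 10),
                                drive_values = c(10, 0), duration = 900,
                                seed = 42, initial_offset = 0.25 * cyc$period)
extract_phase_lag(sim$rates1, sim$rates2, window = c(600, 900))$lag
#> [1] 9.969            # about T/2: anti-phase, as predicted
```

A thin command-line front end over these functions is installed at
`inst/cli/gammalock.R` (subcommands `simulate-net`, `simulate-mf`,
`bifurcation`, `prc`, `coupling`, `coupled`, `global-prc`,
`preset-list`).

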