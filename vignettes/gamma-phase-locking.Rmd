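---
title: "Gamma rhythms, macroscopic resetting curves and phase locking of coupled E-I circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma rhythms, macroscopic resetting curves and phase locking of coupled E-I circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`gammalock` analyses gamma-band oscillations that emerge in networks of
quadratic integrate-and-fire (QIF) neurons,

$$\tau \dot v_j = \eta_j + v_j^2 + I(t),$$

with spike-and-reset at cut-offs $v_{th}$, $v_r$ (the canonical QIF takes
both at infinity).  Excitabilities $\eta_j$ are quenched draws from a
Lorentzian with centre $\bar\eta$ and half-width $\Delta$.  The heavy
Lorentzian tails mean that for the reference operating points
($\bar\eta = -5$, $\Delta = 1$) roughly 94% of the neurons are *not*
intrinsic oscillators — the rhythm is an emergent network property
carried by the synaptic loop, not synchrony of cellular pacemakers
(`fraction_non_oscillatory()` evaluates the closed form).

Each circuit has an excitatory (E) and an inhibitory (I) population,
all-to-all coupled through first-order current-based synapses
$\tau_s \dot s_{\alpha\beta} = -s_{\alpha\beta} + J_{\alpha\beta} r_\beta$,
with $J_{\alpha\beta}$ the strength of population $\beta$ onto $\alpha$.
Two rhythm mechanisms are covered by the presets:

* **PING** (`fig2_ping`): the E→I→E loop ($J_{ei} = J_{ie} = 15$,
  $J_{ii} = 0$), a low-gamma rhythm (≈ 48 Hz at drive 10);
* **ING** (`fig3_ing`): the I→I loop ($J_{ii} = 15$, $J_{ie} = 0$), a
  fast-gamma rhythm (≈ 117 Hz at drive 25) in which the E-cells are pure
  followers.

Because the Lorentzian is stable under the QIF flow, the infinite-network
limit reduces *exactly* to eight ODEs — firing rate $r$, mean voltage
$V$, and the four synaptic variables:

$$\tau \dot r = \frac{\Delta}{\pi\tau} + 2 r V, \qquad
  \tau \dot V = V^2 + \bar\eta + I^{ext} + \tau s_{e} - \tau s_{i}
  - \tau^2\pi^2 r^2.$$

`mf_vector_field()`, `integrate_mf()`, `find_fixed_point()`,
`find_limit_cycle()`, `bifurcation_scan_1d()` and `stability_region()`
operate on this reduction; `simulate_spiking_network()` runs the
finite-size counterpart.

**Units.** Time is in milliseconds throughout ($\tau = 10$ ms,
$\tau_s = 1$ ms), so frequencies read as $f = 1000/T$ Hz and the
emergent rhythms land in the 30–150 Hz gamma band.

## Macroscopic phase-resetting curves

When the reduced system has a stable limit cycle $O(t)$ of period $T$,
the response of the *population* rhythm to a brief input is captured by
the macroscopic infinitesimal phase-resetting curve (iPRC): the periodic
eight-vector $Z(t)$ solving the adjoint equation
$-\dot Z = M(t)^{\mathsf T} Z$, where $M(t)$ is the Jacobian of the
reduced flow along the cycle (`linearization_matrix()`), normalised so
that $Z \cdot \dot O = 2\pi/T$.

`adjoint_iprc()` integrates the adjoint equation backward in time with
per-period renormalisation: in backward time the cycle's attracting
Floquet directions decay, leaving the unique periodic solution.  The
iteration stops when the per-period change drops below $10^{-8}$
(typically 8–25 periods for these strongly attracting cycles) and errors
out after 200 periods, which signals a marginal or unstable cycle.  The
pointwise constancy of $Z\cdot\dot O$ is not imposed — it is a
structural property of the adjoint flow — so its residual is reported as
an integration-quality check (≈ $10^{-6}$ at the default grid).

`direct_prc()` validates the adjoint route the way an experiment would:
square current pulses at a grid of onset phases, with the asymptotic
shift of the $r_e$ peak times read out after ≥ 20 cycles and converted
to radians (advance positive; phase origin at the $r_e$ maximum).  For
weak pulses the shift equals $Z_{v}\,A D/\tau$ for a pulse of amplitude
$A$ and duration $D$ on the corresponding population's voltage equation.

The two rhythm types have qualitatively different resetting properties,
which `classify_prc()` labels: PING E-pulses give a monophasic (type I)
curve, PING I-pulses a biphasic (type II) curve; ING I-pulses are
monophasic, and ING E-pulses reset nothing at all (null) because with
$J_{ee} = J_{ie} = 0$ the E-subsystem is a slave and its four adjoint
components vanish identically.

## Two circuits, weak coupling and the phase equation

Two identical circuits are coupled bidirectionally and symmetrically
through their pyramidal cells only, with strengths $G_{ee}$, $G_{ie}$
and a conduction delay $d$: the delayed partner rate $r_e^{(2)}(t-d)$
enters the $s_{ee}$ and $s_{ie}$ equations.  `simulate_coupled_reduced()`
integrates the resulting sixteen-dimensional delay system;
`simulate_coupled_spiking()` runs the twin finite-size networks with a
ring buffer of in-flight delayed spikes.

When the cross-coupling is weak (the package flags
$\max(G_{ee}, G_{ie}) > 0.5$ as extrapolation), the pair reduces to a
single equation for the phase difference $\theta$:
$\dot\theta \propto G(\theta)$.  The ingredients are the interaction
function

$$H(\theta) = \frac{G_{ee}}{T}\int_0^T Z_{s_{ee}}(s)\, r_e(s-\theta)\,ds
            + \frac{G_{ie}}{T}\int_0^T Z_{s_{ie}}(s)\, r_e(s-\theta)\,ds,$$

computed by `interaction_function()` on the shared cycle/adjoint grid
(trapezoid quadrature; the circular shift is exact on the grid), and its
odd part under the delay shift, computed by `coupling_function()`:

$$G(\theta) = H(\theta + d) - H(-\theta + d).$$

**On the sign of the delay shift.**  Writing each circuit's state as the
cycle evaluated at $t + \phi_k$ and averaging the delayed perturbation
against the adjoint gives
$\dot\phi_1 \propto H(\phi_1 - \phi_2 + d)$, hence the phase difference
$\theta = \phi_1 - \phi_2$ obeys the form above, with the delay entering
as a *forward* shift.  Because $G$ is odd in $\theta$ by construction,
no relabelling of the circuits changes this form, so the orientation is
not a convention: it is pinned by the coupled equations themselves.  The
package verifies it dynamically — the drift $d\theta/dt$ measured from
the sixteen-dimensional delay system matches $(T/2\pi)\,G(\theta)$
pointwise in the weak-coupling regime — and the tests assert the
consequences (in-phase locking for short delays, a symmetry-broken
window, anti-phase for long delays, re-synchronisation when $d$
approaches $T$).

$H$ is implemented exactly in the cycle-average form above, with no
$1/\tau_s$ factor in front of the synaptic perturbation; a
`rescale_tau_s` flag exposes the alternative normalisation (the two
coincide at the canonical $\tau_s = 1$ ms).

Zeros of $G$ are the phase-locking modes (`locking_modes()`): stable
when $G'(\theta^\ast) < 0$.  $G(0) = G(T/2) = 0$ hold identically — the
in-phase and anti-phase states always exist — and are tested at
$10^{-10}$; zeros with $|G'| < 10^{-8}$ are reported as marginal rather
than silently classified, since bifurcation points sit exactly there.
`locking_bifurcation()` scans the diagram over $d$, $G_{ee}$ or
$G_{ie}$; $H$ is linear in the strengths, so only its two unit
components are recombined.

At the PING reference coupling ($G_{ee} = 0.1$, $G_{ie} = 0.5$) the
diagram over delay shows: in-phase locking for $d \lesssim 5.5$ ms, a
contiguous symmetry-broken window $d \in (5.5, 8)$ ms in which the
stable lag glides from 0 to $T/2$, anti-phase locking up to
$d \approx 16.5$ ms, and re-synchronisation as $d$ approaches the
period $T \approx 20.8$ ms (the diagram is $T$-periodic).  For the ING
pair only the $Z_{s_{ie}}$ pathway is non-trivial, so rescaling the
cross-strengths cannot move the locking modes.

## Leader, follower and the global PRC

In a symmetry-broken state the pair fires in a galloping rhythm; the
circuit firing after the long inter-burst silence is the *leader*, the
one following shortly after is the *follower*
(`identify_leader_follower()`, with $T/20$ guard bands around the
degenerate in-phase/anti-phase lags).  Which circuit takes which role is
set by the initial condition, and a strong pulse can swap them.

`global_prc()` measures how the locked two-circuit rhythm as a whole is
reset by a pulse to one circuit: the pair is settled into its locked
state (`settle_locked_state()`), pulsed at a grid of onset phases, and
the asymptotic shift of circuit 1's $r_e$ peaks against an unperturbed
reference is recorded, with a re-lock check — samples that re-lock to a
different mode (including a leader/follower swap) are flagged and
excluded.  In symmetric states (in-phase, anti-phase) the leader- and
follower-evoked curves coincide up to a circular shift; in the broken
state they differ qualitatively — at the mid-window operating point the
leader-evoked curve is an advance curve with several times the
amplitude of the follower-evoked curve, which is predominantly a delay
curve.  That asymmetry is a causal footprint of directional signal
transfer through a structurally symmetric motif.

## What the simulators emulate, and what they do not

The finite-size simulators are the package's data generators: all-to-all
QIF networks with quenched Lorentzian heterogeneity, current-based
exponential synapses, instantaneous within-circuit transmission, and
(for pairs) a shared conduction delay on the cross projections — exactly
the assumptions under which the eight-dimensional reduction is exact in
the large-N limit.  They do *not* emulate conductance-based synapses,
sparse or distance-dependent connectivity, within-circuit delays,
synaptic-weight heterogeneity, or ongoing stochastic input; agreement of
the reduced model with these simulations therefore validates the
reduction and the phase machinery under the model's own assumptions, not
the biophysics of any particular cortical circuit.

Default generator conditions follow the reference operating points:
$N = 5000$ per population, $\tau = 10$ ms, $\tau_s = 1$ ms,
$\bar\eta = -5$, $\Delta = 1$, cut-offs $\pm 500$.  The step-drive
benchmark protocol (preset `fig1`, $J_{ii} = 10$) holds the network
quiescent for 100 ms, then steps the E-drive through 4, 8 and 12
(100 ms each), partially releases to 6, and switches off — covering the
quiescent, asynchronously tracking and rhythmic regimes in one run.

## Numerical choices

* **Integrators.** Fixed-step RK4 for the reduced (8-ODE) and coupled
  (16-ODE) systems; explicit Euler (default step 0.01 ms) for spiking
  networks with exact exponential synapse decay between spikes and
  jumps $J_{\alpha\beta}/(N_\beta\tau_s)$ per spike.  Fixed steps keep
  runs bit-reproducible and align the delay ring buffer with the step
  grid (the step must divide the delay; delayed stage values are
  cubic-interpolated).
* **Finite cut-offs.** A spike's travel time beyond the cut-offs
  ($\tau/v_{th} + \tau/|v_r| = 0.04$ ms at $\pm 500$) is restored as a
  refractory hold after reset (`cutoff_correction`, default on), making
  the discretised neuron consistent with the infinite-threshold model
  the reduction describes.
* **Initial voltages.** Sub-threshold neurons start at their stable
  rest; supra-threshold neurons are drawn from the invariant density of
  their own firing cycle, avoiding spurious initial coherence.
* **Limit cycles.** Poincaré section at upward crossings of $r_e$
  through its mean; crossing times refined by cubic Hermite
  interpolation inside the step; the period is accepted when successive
  returns agree to $10^{-6}$ relative, and the orbit is resampled on
  $M = 1024$ uniform points (the quadrature grid for $H$; doubling the
  grid changes $H$ by $< 10^{-5}$ relative).  Phase origin: the $r_e$
  maximum.
* **Fixed points.** Damped Newton with the analytic Jacobian, seeded by
  the fixed-point identities $V^\ast = -\Delta/(2\pi\tau r^\ast)$,
  $s^\ast = J r^\ast$ over a small grid of rates, with trajectory
  endpoints as a fallback near bistability.  Stability calls
  $|\mathrm{Re}\,\lambda| < 10^{-8}$ marginal rather than deciding.
* **Zero finding on $G$.** Sign changes on the sample grid refined by
  bisection to $|G| < 10^{-10}$ through a periodic cubic-spline
  interpolant; 0 and $T/2$ are always reported.
* **Problem sizes.** The bundled checks run the spiking benchmarks at
  $N = 5000$ per population for 0.5–0.9 s of model time, weakly coupled
  delay systems for 500 settling cycles, and global-PRC curves on
  12-point phase grids with 60 post-pulse cycles — sizes chosen so the
  whole battery completes on a single CPU in a few minutes while the
  quantities under test are converged at the tolerances asserted.

## Known limitations

* The weak-coupling phase reduction degrades gracefully but measurably
  at the reference cross-strengths ($G_{ie} = 0.5$): stable lags shift
  relative to the weak-coupling prediction (e.g. the symmetry-broken
  window moves within the delay axis), even though the in-phase →
  broken → anti-phase sequence survives.  The weak-coupling checks
  therefore run at one fifth of the reference strengths.
* Finite-size effects set a floor on how closely a single N = 5000
  realisation can track the deterministic reduction through a rhythm
  *onset*: the burst phase is seeded by fluctuations at the transition
  and retains an offset of a few tenths of a millisecond, which
  dominates pointwise trace comparisons during free-running oscillation
  (the discrepancy shrinks roughly as $1/N$; burst *timing* agreement
  is far tighter than pointwise L2 agreement).
* Convergence to a locked state under genuinely weak coupling is slow
  (hundreds of cycles); `settle_locked_state()` exposes the settling
  budget and verifies stationarity rather than assuming it.
* The global PRC is computed by direct perturbation only; an adjoint
  formulation for the delay-coupled pair is not provided (convergence
  of the backward iteration is not guaranteed in the presence of the
  delay).
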