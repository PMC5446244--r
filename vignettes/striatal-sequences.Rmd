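---
title: "Models of variable-speed sequence generation in inhibitory circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of variable-speed sequence generation in inhibitory circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatseq)
```

## The model family

Sparse sequential firing — one cluster of neurons active at a time, handing
activity to the next — is a recurring motif in striatum, cortex and
hippocampus during timekeeping and motor-sequence behaviour.  `striatseq`
implements a family of network models in which such sequences arise from
the competition between **recurrent inhibition** (which enforces a
winner-take-all state) and **short-term synaptic depression** (which makes
the winner's grip weaken over time), with the sequence *speed* controlled by
a single scalar: the level of tonic excitatory drive.

### The rate model

Each unit $i$ (a cluster of medium spiny neurons) carries an activity
$x_i \in (0,1)$ and a depression factor $y_j \in [\beta, 1]$ on its outgoing
synapses:

$$\tau \dot{x}_i = -x_i + \phi\Big(\sum_j W_{ij} x_j y_j + x^{in}_i\Big),
\qquad
\tau_y \dot{y}_j = -(y_j - 1)(1 - x_j) - (y_j - \beta)\, x_j,$$

with $\phi(v) = 1/(1+e^{-\lambda v})$ and inhibitory weights
$W_{ij} \le 0$.  While unit $j$ is active its $y_j$ decays toward the floor
$\beta$; the inhibition it exerts, $W_{ij} y_j$, therefore weakens until the
net input to some other unit turns positive and the activity hands over.
If the link onto unit $j{+}1$ is depotentiated by $\eta$ (weight
$-(1-\eta)$ instead of $-1$), that unit wins the race, and a sequence
unfolds in the wired order.

Balancing the depressed inhibition against the drive gives the switch
condition $y(T) = \hat{x}^{in}$ with the effective input
$\hat{x}^{in} = x^{in}/(1-\eta)$, hence the closed-form switch time
implemented in `switch_time_theory()`:

$$T = \tau_y \,\log\frac{1-\beta}{\hat{x}^{in} - \beta}.$$

$T$ diverges as the drive approaches the depression floor and shrinks
toward zero as it approaches saturation — one global parameter rescales the
whole sequence.  We validate this formula two ways: against direct
numerical integration of the depression equation (an independent ODE
solver), and against full network simulations.

### Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `tau` | membrane/recurrent time constant | 1 (fixed) | time unit |
| `tau_y` | depression recovery | 20 | tau |
| `beta` | depression floor | 0.2 | — |
| `lam` | sigmoid gain | 20 | — |
| `eta` | sequence-link depotentiation | 0.1–0.2 | — |
| `alpha1`, `alpha2` | depotentiation / potentiation rates | 0.05, 0.02 | 1/tau |
| `tau_w` | presynaptic trace | 3 | tau |

All rate-model simulations use explicit Euler with `dt = 0.02` tau
(contractually at most `0.1` tau); the dynamics are non-stiff at these
gains, and halving `dt` changes measured switch times by well under 1%
(this is tested).  Units are indexed 1-based; the successor of unit $j$ in
a cyclic network is `j %% N + 1`.

### How far the idealization carries

The closed-form switch time describes the limit $\tau/\tau_y \to 0$,
$\lambda \to \infty$.  At the operating point $\tau_y = 20\tau$,
$\lambda = 20$, simulations reveal three systematic finite-size effects,
which the test suite measures rather than hides:

* each hand-off costs an extra $\sim$1–2 tau (the winner-take-all race
  resolves on the membrane time scale), so measured inter-onset intervals
  exceed $T$ by that amount — negligible for slow sequences, a large
  relative error for fast ones;
* above $\hat{x}^{in} \approx 0.82$ the interval saturates near
  $7\tau$: the predecessor can only be shut off once the successor is
  strongly active, and that race, not the depression clock, sets the pace;
* near $\hat{x}^{in} \approx 0.9$ a stable two-unit co-active state exists
  and the sequence degrades.

Consequently the *measured* dynamic range of the 10-unit handcrafted
network over effective inputs $[0.3, 0.9]$ is about 5–6-fold, while the
theory ratio for the same window is $\log 8 / \log(8/7) \approx 15.6$; an
order-of-magnitude measured range requires probing closer to the
divergence at $\beta$.  The same effects compress the post-learning probe
scans and the excitatory-network scan below.  These are properties of the
published equations at the published parameters, not of the integrator —
we verified the numbers against an independent reimplementation before
freezing the tests.

## Multiple sequences and operating modes

`build_multi_path_weights()` stores several, possibly overlapping, paths in
one matrix; which one is expressed is chosen by restricting the tonic
drive to a subset of units (the input "spotlight",
`protocol_tonic(mask = ...)`).  The same network also runs in two modes
with no weight change: under tonic drive it expresses the wired order;
under strong unit-specific pulses (`protocol_pulses()`) the activity is
enslaved to the imposed order.

## Learning: anti-Hebbian plasticity

`train_network()` co-integrates the rate dynamics with

$$\dot{W}_{ij} = -\alpha_1 W_{ij}\, x_i \bar{x}_j
              - \alpha_2 (W_{ij} + 1)(1 - x_i)\, \bar{x}_j,$$

where $\bar{x}_j$ is the presynaptic activity low-pass filtered over
$\tau_w$ (first-order exponential filter — the filter form is our choice;
only the time scale is prescribed).  Synapses from a recently active unit
onto units that fire with or right after it are driven toward 0; all its
other synapses are driven back toward $-1$.  Both endpoints of $[-1, 0]$
are fixed points of the flow, so weights stay in range (tested as a
property).  The rule is applied to all entries including the diagonal: the
same mechanism that clears the successor link also clears the active
unit's self-inhibition, matching the learned matrices of the spiking
model.

The learned successor link settles where depotentiation (acting over the
$\sim \tau_w$ co-activity window of each hand-off) balances potentiation
(acting over the presynaptic dwell $D$):
$|W^*| \approx \alpha_2 D / (\alpha_1 \tau_w + \alpha_2 D) \approx 0.72$
for $D \approx \tau_y$.  Two practical consequences, both visible in the
tests: tonic probes of a learned network must be scaled by the learned
link strength (`learned_link_strength()`), and the argmax margin between
the successor ($\approx -0.72$) and the competitors ($-1$) is only
$\approx 0.3$, which bounds how much weight noise the stored order can
survive: multiplicative perturbations at the 2% level never disturb the
expressed sequence, while at the 10% level they usually do.

### What the tutors emulate — and what they do not

The tutoring protocols stand in for temporally patterned cortical input
during learning:

* `protocol_pulses()` — one rectangular pulse per unit per cycle in a
  seeded random order.  Pulse width should be at least $\tau_y$; training
  with much narrower pulses makes the replayed sequence skip units (this
  failure mode is itself tested).
* `protocol_sinusoids()` — the smooth counterpart: one raised-cosine-power
  bump per unit per cycle (a trigonometric polynomial of the cycle
  frequency), at stratified random times with random amplitudes in
  $[0.45, 0.65]$ and a 0.05 floor.

The smooth tutor's design is constrained by the mechanism itself, and we
chose its parameters once, for mechanistic reasons: (i) bump amplitudes
must stay below the full inhibitory weight, so that an active unit always
suppresses a driven competitor — larger amplitudes force co-activation,
and the anti-Hebbian rule then locks the pair together permanently
(potentiation requires the postsynaptic unit to be *off*); (ii) the
falling edge of each bump must release its unit within about $\tau_y$,
otherwise depression hands activity *back* to the predecessor whose drive
is still high and the taught sequence ping-pongs; (iii) bump times are a
jittered random permutation of the cycle slots rather than i.i.d. phases,
keeping dwell times near-uniform — strongly uneven dwells produce strongly
uneven learned link strengths, and the weakest-driven links then stall the
slow end of the post-learning speed range at the effective depression
floor $y_{eq} = 1 - x(1-\beta)$.  A literal low-order random sine
superposition violates (ii) and (iii) and does not teach clean sequences
in this model; real cortical tutoring input is of course richer than
either idealization, so passing these tests demonstrates the learning
mechanism, not robustness to arbitrary input statistics.

## The excitatory network with shared inhibition

`simulate_ei_network()` implements $N$ excitatory units (self-weight 0.6,
feedforward 0.2) coupled to one shared inhibitory unit
($J_{EI} = J_{IE} = 1$, $\tau_I = \tau$,
$\phi_I(v) = \Theta(v)\tanh v$), with the depression factor attached to
every occurrence of presynaptic excitatory activity.  In the limit of fast
linear inhibition the model reduces exactly to the recurrent inhibitory
network with $W = J - J_{EI}J_{IE}$; we test that at $\tau_I = 0.01\tau$
the two trajectories agree to within 0.05 in maximum absolute activity.
We add a cyclic feedforward wrap so the sequence repeats and the period is
measurable in steady state.

The stable-sequence input window is located by bisection
(`bracket_ei_range()`): below it the shared inhibition extinguishes the
hand-off entirely (the sequence dies rather than slowing further, because
the saturating $\tanh$ lets the tonic drive overtake the inhibition
globally), above it sparseness fails.  Within the bracket the period falls
monotonically with drive.  The winner-take-all state is softer than in
the purely inhibitory network: near the slow edge only the winner (and,
briefly, its successor) exceeds 0.5, while at stronger drives background
units ride near threshold and the sequence lives in the argmax of the
activities.  The measured ratio is $\approx 2.8$-fold with
these parameters — in our hands slightly below the nominal four-fold, for
the same finite-$\tau$ reasons discussed above — and clearly narrower than
the purely inhibitory network's, because the inhibitory time constant
caps the fast end.

## The spiking realization

`simulate_spiking()` integrates exponential integrate-and-fire neurons
(C = 300 pF, g$_L$ = 30 nS, E$_L$ = −70 mV, V$_T$ = −50 mV,
Δ$_T$ = 2 mV; Euler, dt = 0.05 ms) grouped into clusters, with
per-synapse depression (release fraction u = 0.5, recovery
τ$_x$ = 200 ms) and delta-synapse delivery: a presynaptic spike deposits
the charge $uQx_{syn}W$ instantaneously.  Spikes are detected at 0 mV —
at this dt the exponential term carries the potential from 0 mV to
divergence within a fraction of a step — and reset to E$_L$; there is no
refractory period.  Because every synapse from neuron $j$ starts fully
recovered and depresses only on $j$'s spikes, one depression variable per
presynaptic neuron represents all its synapses exactly.

The tutoring current to cluster $n$ is
$x_0 + x_1 \sin^8(\pi t/T + \theta_n)$ with $x_0$ = 0.2 nA,
$x_1$ = 0.5 nA, $T$ = 800 ms and $\theta_n = \pi n/8$ — note that a larger
phase offset makes the bump peak *earlier*, so the tutored order descends
cyclically in cluster index.  Gaussian noise (sd 0.02 nA on $x_0$, 0.05 nA
on $x_1$, 0.05 rad on the phases) is redrawn each cycle, plus
higher-frequency sinusoids at $8\pi t/T$ and $12\pi t/T$ with random
amplitudes and phases.  The STDP rule is trace-based and pre-locked:
every presynaptic spike moves its synapse by $-a$ (toward $-1$) plus
$A \times$ the postsynaptic trace (τ$_{post}$ = 5 ms); every postsynaptic
spike adds $A \times$ the presynaptic trace (τ$_{pre}$ = 20 ms); nothing
changes without presynaptic spiking.  Only the amplitudes and time
constants (A = 0.05, a = 0.002) are prescribed; the trace form is the
minimal implementation of the qualitative anti-Hebbian curve, and the rule
is exposed separately (`stdp_update()`) so alternatives can be swapped in.

### Scaled-down study conditions

The full-size network (8 × 100 neurons, connection probability 0.2) is
expensive; the packaged experiments use 8 × 50 with the synaptic charge
scaled as $Q = 1.5\,\mathrm{pC} \times 100/\texttt{cluster\_size}$, which
preserves the total cluster-to-cluster inhibitory charge.  Much smaller
clusters do not work: depression caps each synapse's average throughput at
$1/(u\tau_x) = 10\,s^{-1}$, so the suppression a cluster can deliver is
fixed and the shot noise of only $\sim$5 convergent synapses (at 25
neurons per cluster) destroys the winner-take-all state.  For the same
reason the tonic-replay window is narrow — roughly 0.57–0.62 nA, just
above the rheobase $g_L(V_T - E_L - \Delta_T) = 0.54$ nA.  Tonic runs
start from membrane potentials spread evenly across $[E_L, V_T]$:
identically driven neurons started from a common reset otherwise
synchronize into cluster-wide volleys and suppression fails between
volleys.  Training uses 40 noisy tutor cycles; the block structure of the
learned matrix (within-cluster and taught-successor blocks least negative)
is already present after 20, but clean autonomous replay needs the extra
contrast.  Cluster sequences are read from the raster with 20–25 ms bins
and a winner floor of 4–5 Hz per neuron.

## Degenerate inputs, ties and numerical choices

* Active-unit labelling: argmax of the activities, reported only above
  0.5; exact ties (a measure-zero event) go to the lowest index.  The
  first inter-onset interval of every run is treated as transient and
  excluded from mean switch times.
* During a hand-off the outgoing and incoming units briefly overlap above
  0.5; sequence extraction is unaffected (the argmax is unique) but
  instantaneous "at most one active unit" holds only outside these
  crossing windows.
* Weight updates are clipped to $[-1, 0]$ after each Euler step to guard
  the (provably range-preserving) continuous flow against overshoot.
* `weight_structure_score()` on an all-equal column is flagged degenerate
  rather than scored silently.
* All randomness (protocol draws, connectivity, perturbations, tutor
  noise) is drawn in R under named child seeds of one master seed
  (`child_seed()`), so every experiment is bit-reproducible; the compiled
  integrators are deterministic.

## Problem sizes used by the packaged experiments

Speed scans use the 10-unit handcrafted network; learning experiments use
15 units (25 for the structure-recovery demonstrations), 20 tutor cycles
of 25 τ$_y$ each; the spiking pipeline uses 8 × 50 neurons for 40 cycles
of 800 ms plus five 6 s tonic probes.  These sizes reproduce every
qualitative phenomenon at interactive run times; all of them are plain
arguments, so larger replications are one function call away.

## Known limitations

* The closed-form switch-time theory is asymptotic in
  $\tau/\tau_y \to 0$, $\lambda \to \infty$; at the default operating
  point measured intervals carry a ~1–2 τ hand-off overhead and the fast
  end of every speed scan saturates (quantified above).
* The smooth tutor teaches simple cycles by design; inputs with heavily
  overlapping or multi-bump drives push the network into co-activation
  regimes the anti-Hebbian rule cannot disentangle.
* The spiking model omits conductance-based synapses, transmission
  delays, refractoriness, interneurons, and neurons shared between
  assemblies.
* No reward-modulated or corticostriatal plasticity is modelled; the
  tutors are given, not learned.
```
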