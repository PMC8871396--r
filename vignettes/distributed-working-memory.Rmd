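---
title: "Modelling distributed working memory across the macaque cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling distributed working memory across the macaque cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Persistent, stimulus-selective firing during memory delays has classically
been attributed to strong local recurrent excitation within individual
association areas: an area whose self-coupling exceeds a critical value is
bistable in isolation and can latch a stimulus. Recordings, however, find
delay activity distributed over many cortical areas at once. `wmnet`
implements a multi-area model of the macaque neocortex in which *none* of
the areas needs to be bistable on its own: selective delay activity is a
collective state maintained by inter-areal excitatory loops, shaped by the
anatomical connectivity and by a macroscopic gradient of local synaptic
strength.

## The local circuit

Each area is a reduced three-population firing-rate circuit: two
excitatory pools selective for stimuli A and B whose recurrent drive is
carried by slow NMDA-like gating variables `S_A`, `S_B`
(`dS/dt = -S/tau_N + gamma (1 - S) r`), and one inhibitory pool with fast
GABA-like dynamics (`dS_C/dt = -S_C/tau_G + gamma_I r_C`). Input currents
combine local couplings, background drive, long-range input and an
Ornstein-Uhlenbeck noise current:

    I_A = J_s S_A + J_c S_B + J_EI S_C + I0_A + I_net,A + x_A

and symmetrically for pool B; the inhibitory pool receives
`J_IE (S_A + S_B) + J_II S_C + I0_C`. Rates follow the transfer functions

* excitatory: `phi(I) = (aI - b) / (1 - exp(-d (aI - b)))`, evaluated with
  `expm1` so the removable singularity at `aI = b` (value `1/d`) is exact;
* inhibitory: `phi_C(I) = (c1 I - c0)/g_I + r0`, rectified at zero rate.

The second form deserves a note. The threshold-linear curve can be read
with the baseline `r0` inside or outside the division by `g_I`. The
quasi-steady balance constants (below) decide it: the published offset
`beta = tau_G gamma_I (c1 I0_C + g_I r0 - c0) / (g_I - J_II tau_G gamma_I c1)`
contains `g_I r0`, which only arises when `r0` is added *after* the
division. That reading also places the isolated-area bifurcation at the
documented critical coupling, so the package uses it throughout
(`phi_inhibitory()`).

Rates are integrated with the relaxation equation
`tau_r dr/dt = -r + phi(I)` (`tau_r` = 2 ms) rather than solving
`r = phi(I)` transcendentally at each step; both appear in the literature
and the relaxation form is smooth and cheap. The integrator is fixed-step
Euler-Maruyama with `dt` = 0.5 ms by default; the OU noise increment uses
the standard `sqrt(dt)` scaling so the stationary standard deviation is
`sigma sqrt(tau_noise / 2)`. Gating variables are defensively clipped to
[0, 1] (clipping is counted and reported; it does not occur at default
parameters) and an instability detector aborts when any gating variable
moves by more than 0.2 in a single step.

### Bifurcation structure

`find_fixed_points()` reduces the fixed-point system to the two excitatory
rates (the inhibitory pool has a closed-form steady state on its linear
branch), solves it by damped Newton iteration from a grid of rate guesses,
deduplicates in gating space (tolerance 1e-6) and labels stability by the
eigenvalues of the six-variable Jacobian (the noise currents are decoupled
and always stable, so they are omitted). `critical_coupling_scan()`
brackets and bisects the smallest self-coupling with more than one stable
state; with the balanced `J_IE` co-varied (see below) the transition sits
at J_s = 0.4652 nA, matching the published 0.4655 nA to within the 1e-4 nA
refinement tolerance. The `co_vary_JIE` flag exposes the alternative
(frozen `J_IE`), which places the transition near 0.40 nA.

## The macroscopic gradient

Local recurrent strength increases from sensory to association cortex, as
proxied by basal-dendrite spine counts of layer 2/3 pyramidal neurons. The
packaged table (`macaque_spine_table()`) carries the measured counts and
age-correction factors (about +30% per 10 years for data from old
animals); areas without measurements are filled by regressing corrected
counts on the anatomical-hierarchy rank, and the result is min-max
normalised to `h` in [0, 1] (`spine_hierarchy()`). The local coupling is
then linear in `h`:

    J_s^i = J_min + (J_max - J_min) h_i,   defaults 0.21 .. 0.42 nA.

Raising `J_s` alone would raise an area's spontaneous rate. Eliminating
the fast inhibitory variables at steady state gives the invariant drive
`J_0 = J_s + J_c + 2 J_EI J_IE zeta` (0.2113 nA at baseline); holding it
fixed by co-varying the excitatory-to-inhibitory coupling,

    J_IE = (J_0 - J_s - J_c) / (2 J_EI zeta),

makes every area's isolated spontaneous state identical (`balance_jie()`).
The validity bound `J_s >= J_0 - J_c = 0.2005` nA keeps `J_IE`
non-negative; values below it raise an error. (The literature quotes the
bound as 0.205 nA; the exact arithmetic gives 0.2005, and the default
`J_min = 0.21` is comfortably above either.)

## The anatomical substrate and long-range coupling

The substrate is a directed FLN matrix (fraction of labelled neurons,
rows = target) with an SLN matrix (supragranular fraction; near 1 =
feedforward, near 0 = feedback). FLN spans five orders of magnitude and is
compressed by `W = k1 FLN^k2` with `k1 = 1.2`, `k2 = 0.3`
(`rescale_fln()`). Three normalisation variants are provided; the default
normalises *after* the power transform so each target's incoming weight
sums to `k1`. This choice is a magnitude argument: with ~20 sources per
target, normalising before the power transform inflates row sums roughly
like n^0.7 (~3-4), which puts close to 0.8 nA of long-range current into
memory states (rates far beyond 100 Hz), destabilises the spontaneous
baseline, and makes the "localized" configuration broadly active. With
post-power normalisation memory states sit at the expected tens of Hz and
the spontaneous state is quiet in all named configurations.

Long-range inputs follow the counterstream-inhibitory-bias (CIB) routing:

    I_A,net^x = G sum_y W[x,y] SLN[x,y] S_A^y          (pool B analogous)
    I_C,net^x = G Z sum_y W[x,y] (1 - SLN[x,y]) (S_A^y + S_B^y)

after target-side gradient scaling `W[x,y] -> (J_s^x / J_max) W[x,y]`.
Feedforward projections therefore excite; feedback projections
preferentially recruit local inhibition, graded by `1 - SLN`. `Z` (0.8048
at defaults) balances the two pathways so equal activity in both selective
pools of a source has no net effect downstream. `cib_scale` multiplies the
inhibitory-targeting fraction (0 disables CIB; values above 1 saturate at
1 per projection), and the fraction is capped at `fef_cap = 0.4` for the
frontal-eye-field targets 8l and 8m, which otherwise cannot sustain delay
activity; the cap's source filter is configurable but applies to all
sources by default.

## The synthetic connectome generator

Real tract-tracing data cannot be redistributed, so
`generate_synthetic_connectome()` builds substrates that emulate its
statistical structure:

* heavy-tailed FLN, log-uniform over [1e-6, 1e-1] (>= 4 decades);
* partial density 0.66, with edge probability decaying exponentially in
  rank distance (scale 0.35) as in the exponential distance rule of
  cortical graphs;
* a latent hierarchy warped logarithmically
  (`h = log(1 + 9x)/log(10)` over the uniform rank coordinate), so that
  hierarchical separations are largest among early sensory areas and
  compressed near the top, as in fitted laminar hierarchies;
* SLN as a logistic function of warped-hierarchy differences (slope 6.5),
  so lower-to-higher projections are feedforward (SLN > 0.5); an optional
  beta scatter (`sln_precision`) reproduces the overdispersion of real
  laminar counts.

These defaults were chosen once, for structural realism, and they
reproduce the model's qualitative regimes: a quiet spontaneous baseline, a
cue-evoked distributed delay pattern that excludes early sensory areas,
global activation without CIB, memory confined to the top of the gradient
in the localized configuration, and the silencing/distractor contrasts.
What the generator does *not* reproduce from real data: the idiosyncratic
identity of individual projections (e.g. which frontal pairs are
feedback-classified), distance matrices, and the bowtie core-periphery
structure. Consequences of this are noted under "Limitations".

For canonical 30-area bundles, `build_network()` uses the spine-count
gradient for `J_s` while SLN follows the (distinct) anatomical-hierarchy
order - the same decoupling present in the real data, where e.g. LIP is
high in the laminar hierarchy but low in spine counts.

## Experiment protocols

`simulate()` integrates the coupled stochastic system from the coupled
spontaneous state (computed once at build time by deterministic
relaxation). Stimuli are rectangular current pulses (default 0.3 nA,
0.5 s) to one population of one area; silencing clamps areas to zero rate
and zero outgoing conductance over a window (transient and permanent
silencing differ only in the window); gating multiplies incoming
long-range weights of "open" areas by `1 + g_s` (a flag extends this to
local couplings). Delay activity is summarised over the last 2 s of a
trial; an area is *active* when its cued-pool rate exceeds the isolated
spontaneous rate plus 5 Hz, and *selectively active* when it additionally
exceeds the anti-cued pool by 5 Hz. The threshold is referenced to the
isolated spontaneous rate (identical across areas by construction) rather
than the coupled baseline, because the coupled baseline is itself
condition-dependent - without CIB it runs away, which would make the
active-set measure circular. The ranked-rate gap statistic (largest
adjacent difference in sorted delay rates) quantifies the separation
between the active and inactive groups; at default conditions it exceeds
20 Hz, so the active set is insensitive to the threshold over a wide band.

A note on noise and trial outcomes: the prescribed OU amplitude (0.005 nA)
has a stationary standard deviation of 0.16 pA - far too small to move
firing rates - yet the cue-ignition and distractor transitions pass close
to saddle points, where the noise realization selects the branch. Across
noise seeds the same marginal trial can ignite or fail. The packaged
characterizations (and the reproduction script) therefore run trials in
the noise-free limit, which reports the underlying deterministic dynamics;
stochastic trials at a fixed seed are bit-reproducible and exercised by
their own tests.

Distractor trials deliver a second pulse to the anti-cued pool after a
4 s gap; the outcome is decided by majority over the five top-hierarchy
areas using the selective-activity criterion.
`minimal_strength_search()` bisects pulse amplitudes for the minimal
effective cue or distractor. In the localized configuration the cue
threshold is degenerate (arbitrarily weak selective input eventually picks
the winning pool because contextually bistable areas sit on their fold),
so strength comparisons are reported relative to the standard 0.3 nA cue.

## The attractor census

`enumerate_attractors()` samples random activity seeds - a random subset
of areas (size uniform on 1..N) started at an elevated pool-A gating value
(0.3) - relaxes the noise-free network (default up to 20 s; the reduced
settings used in tests are 10 s at `dt` = 2 ms with a 0.05 Hz convergence
tolerance, verified to reproduce the pattern sets of the careful
settings), binarizes by the activity threshold, and deduplicates on the
binary area vector only (pool identity is recorded but does not define
attractor identity). The all-spontaneous pattern is excluded; samples that
fail to converge are discarded and counted. Survival under silencing
re-relaxes each pattern with the silenced areas clamped; a pattern
survives if any non-silenced area remains active. On two- and three-area
toy networks both procedures match exhaustive enumeration over all binary
seed patterns computed with an independent integrator (`deSolve::ode`).

## The simplified excitatory-node model

`simple_net_spec()` isolates the minimal ingredients: N = 30 excitatory
nodes, `dr_i/dt = -r_i + phi(J_i r_i + (G/(N-1)) sum a_ij r_j + I)` with a
logistic `phi` and feedforward/feedback multipliers `a_ij`. The gradient
is a saturating (hyperbolic) profile mimicking the spine-count shape, or
its least-squares line ("linear"), which overshoots the saturating ceiling
at the top. The first-order mean-field solution
`R = phi((J_eta0 + G) R + I)` is solved by bracketed root finding; its
bistability onset and the simulated network agree within 5% for
homogeneous networks. The sigmoid parameters (max 1, threshold 0.5, width
0.08, background 0.06) place the isolated-node bifurcation at J = 0.70,
above the gradient ceiling 0.64, so isolated nodes are monostable.
Bistable-node counts are measured from partial top-m seeds, which exposes
partial attractors that an all-high initialisation would jump over.

## Numerical choices, in one place

* Euler-Maruyama, `dt` = 0.5 ms for stochastic trials (halving `dt`
  changes traces by well under 1 Hz); 1-2 ms for deterministic
  relaxations.
* Fixed-point Newton tolerance 1e-12 on rate residuals; root dedup 1e-6 in
  gating space; stability threshold on eigenvalue real parts -1e-8.
* Bisection tolerances: 1e-4 nA (critical coupling), 0.01-0.02 nA
  (stimulus strengths).
* Relaxation convergence: max rate change below 0.01-0.05 Hz per 0.25-0.5 s
  check interval.
* One master seed per simulation; a single RNG stream with a fixed draw
  order inside the compiled integrator makes stochastic trajectories
  bit-reproducible.
* Problem sizes in the test suite: 10-12 s trials, censuses of 300-500
  seeds over a five-point coupling grid, toy censuses enumerated
  exhaustively. These sizes were chosen to characterise each regime at the
  resolution the qualitative claims need.

## Limitations

* **Targeted shutdown.** In the source phenomenology a distributed
  attractor is deactivated by a 1 s excitatory pulse to the inhibitory
  pools of four frontal areas. On the synthetic substrate the active set's
  mutual support is spread over ~17 areas and survives any four-area (even
  eight-area) inhibition; the protocol is implemented and tested
  mechanically, but network-wide deactivation does not occur. This
  reflects the generator's homogeneity, not the protocol.
* **Localized-mode baseline.** With feedback projections removed, the top
  of the gradient receives unopposed tonic feedforward drive and several
  frontal areas drift to a symmetrically elevated baseline. Memory-bearing
  comparisons therefore use the selective-activity criterion, and the
  transient-silencing contrast probes the *anchor* area (the lowest-rank
  active area, which has no active upstream feeders) - on the real
  substrate the published probe area has this property because its
  near-tier frontal afferents are feedback-classified.
* **Simplified-model dichotomy.** With the package's logistic transfer the
  saturating-symmetric gradient does not produce a strict "zero or N"
  bistable-count dichotomy (partial patterns appear near the collective
  transition); the robust qualitative claims are tested instead.
* **Census richness.** Attractor counts on the synthetic substrate are far
  smaller than on the real graph (units to tens rather than hundreds);
  the coupling-dependence and size-rate trends are qualitative.
* Passing tests on the synthetic substrate show that the *mechanisms*
  behave as described; area-by-area quantitative predictions require the
  real tract-tracing matrices, which can be supplied to
  `load_connectome()`.
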