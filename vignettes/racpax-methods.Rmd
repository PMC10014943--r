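---
title: "Modelling migration phenotypes with multi-timescale Rac-Rho-paxillin dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling migration phenotypes with multi-timescale Rac-Rho-paxillin dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(racpax)
```

## The biological problem

Mesenchymal cells such as CHO-K1 fibroblast-like cells migrate by
extending protrusions where the small GTPase Rac is active and retracting
where Rho dominates. The two GTPases inhibit each other, and the adaptor
protein paxillin -- phosphorylated at its serine-273 residue by
RacGTP-bound PAK -- feeds activation back onto Rac through the GIT-PIX-PAK
complex. Mutating S273 to alanine (S273A, nonphosphorylatable) or aspartate
(S273D, phosphomimetic) respectively impairs or enhances motility.

`racpax` implements a hierarchy of models of this circuit and the analysis
stack used to compare simulated and experimental cells:

* **kinetics** -- the six-variable (6V) reaction system for
  active/inactive Rac and Rho and phosphorylated/unphosphorylated
  paxillin; its two-variable (2V) reduction under quasi-steady-state (QSS)
  assumptions; and the four-variable (4V) three-timescale extension whose
  slow variables are the maximum paxillin phosphorylation rate $B$ and its
  recovery rate $k_B$.
* **reaction_diffusion** -- the same kinetics on a 1D periodic domain with
  fast inactive and slow active diffusion, producing wave-pinning.
* **cpm** -- a single-cell Cellular Potts simulator whose protrusion
  energy is the membrane active-Rac field.
* **track_analysis / mask_analysis** -- instantaneous speed, MSD exponent
  ($\alpha$-value), directionality ratio (DR), membrane activity,
  event detection.
* **classifier** -- a small fully-connected network assigning WT-like /
  S273A-like / S273D-like labels from four track metrics.

## The 4V model

Active Rac $R$ and inactive Rac $R_i$ obey

$$\partial_t R = \big(I_R + I_K^*\big)
  \frac{L_\rho^n}{L_\rho^n + \rho^n}\, R_i - \delta_R R + D_R \partial_x^2 R,
  \qquad
  \partial_t R_i = -\,[\text{reaction}] + D_{R_i} \partial_x^2 R_i,$$

with Rho $\rho(R)$ and phosphopaxillin $P(B, K)$ slaved to Rac through
their quasi-steady-state expressions, $K(R)$ the scaled active-PAK
concentration, and $I_K^*(P)$ the complex-dependent activation rate (see
`pak_active_fraction()`, `rho_quasi_steady()`, `paxillin_quasi_steady()`,
`git_pix_pak_activation()`). The production term is proportional to the
inactive pool $R_i$; on the conserved manifold $R_i = 1 - R - \gamma K$
this coincides with the conservation-substituted form of the 2V
reduction, and keeping $R_i$ explicit is what preserves total Rac mass
exactly under unequal diffusion -- the property wave-pinning rests on.

The two slow equations are

$$\frac{dB}{dt} = \varepsilon\Big(1 - \gamma_R R - k_B (B - B_r)
  + \frac{1}{\eta (B + \varepsilon_B)}\Big), \qquad
  \frac{dk_B}{dt} = \varepsilon_L (\gamma_K - R),$$

with $\varepsilon_L \ll \varepsilon \ll 1$ (three timescales; validated on
parameter load). The barrier term $1/(\eta(B+\varepsilon_B))$ makes $B < 0$
unreachable. Because $dk_B/dt = 0$ forces $R = \gamma_K$ at any full
equilibrium, $\gamma_K$ selects where on the fast subsystem's fold
structure the equilibrium sits, which is what separates mixed-mode
oscillations (MMOs) from relaxation oscillations (ROs) and steady states.

## Parameter provenance and calibration

Default parameters ship in `inst/extdata/kinetic_params.yaml`. The
fast-subsystem constants (Hill coefficient $n = 4$, the association
constants $k_X, k_G, k_C$, the GIT/PIX/paxillin concentrations, the
half-maxima $L_\rho = L_R = 0.34$ and $L_K = 5.77$) follow the published
Rac-Rho-paxillin model lineage this model extends. The remaining rates and
the phenomenological slow-timescale constants
($\varepsilon, \varepsilon_L, \varepsilon_B, \eta, \gamma_R, \gamma_K$,
$\delta_P$, $I_K$, $I_R$, $\delta_R$, PIX) were calibrated **once**, before
any acceptance measurement, so that the 4V model reproduces the regime
structure that defines the three paxillin phenotypes:

* $L_K = 5.77$ (WT-like): MMOs -- small-amplitude loops interleaved with
  large relaxation excursions;
* $L_K = 7$ (S273A-like): a stable steady state;
* $L_K = 4.5$ (S273D-like): relaxation oscillations.

They were then frozen; every other quantity the package reports is
measured, not tuned. The calibration is robust to halving the integrator
tolerances and to the initial condition (checked in the test suite). At
the frozen defaults the mixed-mode band spans $L_K \in [4.8, 6.2]$: it is
wider towards low $L_K$ than the band the three anchors imply, a known
limitation of this reconstruction -- the single-amplitude (RO) regime
does not persist above $L_K \approx 4.8$, so the RO-to-MMO transition
sits near 4.75 rather than halfway between the RO and MMO anchors.

```{r regimes, eval = FALSE}
p <- kinetic_params()
classify_regime(integrate_ode(p, 80000))                     # MMO
classify_regime(integrate_ode(kinetic_params(L_K = 7), 80000))   # steady
classify_regime(integrate_ode(kinetic_params(L_K = 4.5), 80000)) # RO
```

## Numerical choices

* **ODE integration** uses the stiff BDF method (`deSolve::ode`) with
  `rtol = 1e-8`, `atol = 1e-10`: the small-amplitude MMO loops are
  tolerance-sensitive, and peak counts must be reproducible.
* **Regime classification** (`classify_regime()`) discards the first 20%
  of the window, finds local maxima of $R$, and splits peak heights by
  two-means clustering. An MMO call requires the cluster gap to exceed 3x
  the within-cluster spread *and* 20% of the signal amplitude (guarding
  against splitting a single noisy amplitude class), with small peaks
  interleaved between large ones. A post-transient amplitude below
  `steady_eps = 1e-3` (scaled concentration), or a monotone/ringing-down
  tail, is steady. Parameter-scan transitions are reported as grid
  midpoints.
* **The PDE solver** (`simulate_field()`) is method-of-lines with
  second-order central differences on the ring and explicit stepping
  (Heun by default) under the diffusive stability limit
  $dt \le dx^2 / 2 D_{\max}$, checked on every step. Conserved-pair mass
  drift beyond $10^{-6}$ relative aborts the run.
* **Wave-pinning detection** (`detect_wave_pinning()`) reports a pinned
  profile when the half-maximum front positions move less than one grid
  cell over the last quarter of the simulation and the profile contrast
  exceeds 0.05.
* **The default wave-pinning setup** holds the 2V model at $B = 4$
  (inside the bistable window) with $D_R = 0.1$, $D_{R_i} = 10$, and a
  high-Rac arc over 30% of a 128-site ring. The fast-diffusing inactive
  pool is depleted as the high-Rac region grows, which is what stalls the
  fronts.

## The Cellular Potts simulator

The Hamiltonian is
$H = \lambda_P (p - P_{target})^2 + \lambda_S (s - S_{target})^2 + H_{Act}$
with perimeter defined as the cell-medium 4-edge count. Copy attempts are
drawn uniformly from ordered boundary-adjacent site pairs (one sweep of
as many attempts as there are such pairs per MCS) and accepted with
probability $\min(1, e^{-\Delta H / T})$. The protrusion term compares
geometric means of the Act field over Moore neighbourhoods restricted to
sites sharing the focal site's label (a bare product would be annihilated
by a single zero); the Act field equals membrane active Rac on the
membrane, the nearest membrane value inside the cell, and zero outside.
Copies that would 4-disconnect the cell locally are rejected outright;
the lattice is toroidal so a migrating cell never meets a border.

Per MCS the 4V kinetics advance by `dt` (default one time unit) on the
membrane ring, with diffusion of $R$ and $R_i$ along the membrane and
per-site ODEs for $B$ and $k_B$. After each sweep the ring is remapped
onto the deformed membrane: surviving sites keep their values, gained
sites take the walk-order interpolation of their surviving neighbours,
and $R$, $R_i$ are rescaled multiplicatively so total Rac mass is
conserved exactly. The ring is treated as a **fixed physical length**
$L_0$ (the initial membrane size) discretized by however many membrane
sites currently exist ($dx = L_0/m$): the Moore-membrane site count
fluctuates 15-25% with boundary ruffling even at constant perimeter, and
tying $dx$ to 1 lattice unit would dilute the conserved per-site Rac pool
out of the oscillatory regime. With fixed $L_0$, concentrations stay in
the calibrated regime while mass conservation remains exact.

CPM weights, temperature, lattice size and sampling cadence are
configuration with defaults chosen once to give a mid-sized cell
(450 sites, target perimeter 96) whose jitter and drive reproduce the
relative behaviour of the three phenotypes; one recorded track step spans
`mcs_per_step` MCS. These choices, like the kinetic calibration, were
frozen before the acceptance measurements.

## Track and mask metrics

* `instantaneous_speed()`: mean per-interval displacement over the
  sampling interval.
* `msd()` is origin-referenced, $\mathrm{MSD}(t) = \|x(t) - x(0)\|_2^2$,
  exactly as defined -- not the more common time-lag average.
* `alpha_value()` fits log MSD against log lag by OLS within contiguous
  segments (50 steps for simulated cells, 20 min for experimental
  recordings), each segment re-originated at its first point, and
  averages the slopes. Ballistic tracks give exactly 2; diffusive tracks
  give 1 in expectation.
* `directionality_ratio()` is net displacement over path length;
  `rolling_dr()` slides a 50-step (simulated) or 60-min (experimental)
  window one sample at a time.
* `detect_events()` smooths the rolling-DR series by locally weighted
  regression (span 0.15 of the series) and reports pronounced dips:
  prominence at least 0.1, level below 0.9, separated by at least half a
  window. The level threshold admits turns of 60 degrees and sharper,
  whose windowed DR dips to about $\cos(30^\circ) \approx 0.87$.
  Detection refuses inactive tracks ($\alpha < 1.4$).
* Classes: $\alpha < 1.4$ inactive; active simulated cells split at
  DR $= 0.8$ into directed ($\ge$) and oscillatory ($<$). Boundary values
  go to the upper class.
* `membrane_activity()` counts the symmetric difference of consecutive
  masks without recentring, so both the protruding front and the
  retracting rear are counted.
* `normalize_event_counts()` z-scores event counts against the WT sample
  using the $n-1$ standard deviation.

## The classifier

`train_classifier()` fits a fully-connected network (three hidden ReLU
layers of 16 units -- four layers in all -- and a softmax output) on four
metrics: pooled-z-scored speed, $\alpha$, DR and event count. Training is
single-batch BFGS on the cross-entropy with L2 penalty $10^{-5}$,
deterministic under its seed. No installed R package provides a
multi-hidden-layer ReLU perceptron, so the forward pass, backpropagation
and persistence are implemented here and verified against a manual
forward pass in the tests.

## What the synthetic generators emulate -- and what they do not

`gen_track()` produces stationary-jitter, Brownian, ballistic and
piecewise-ballistic tracks with known ground truth (turn times, expected
$\alpha$ regime); `gen_mask_sequence()` produces translating blobs with
exact expected membrane activity; `gen_condition_table()` produces three
Gaussian clusters in metric space standing in for simulated cohorts.
These fixtures validate the *analysis* operations exactly, but they do
not reproduce the shape irregularity, the burst-quiescence alternation,
or the heavy-tailed displacement statistics of real cells; passing tests
on them certifies the metrics and the classifier plumbing, not biological
realism. Biological structure enters only through the lattice simulator
driven by the kinetics.

## Problem sizes

The packaged defaults for study-scale quantities are: 80 000 time units
per ODE regime classification (about 6-10 oscillation cycles), 128-site
rings for wave-pinning, and lattice runs of 20 000 MCS by default
(40 000 MCS, about 30 oscillation cycles, for the cohort studies, which
use 7 cells per condition) recorded every 55 MCS. Classifier cohorts use
smaller cells (200 sites, 6 000 MCS) since only class separability is at
stake. Full-scale cohorts (20 cells per condition) change standard
errors, not means, and can be run by raising the cohort size and
`mcs_total`.

## What the lattice coupling changes

On the membrane ring the kinetics do not simply replay the non-spatial
cycle. The spatially polarized (wave-pinned) configuration coexists with
the homogeneous oscillation, and the lattice noise of copy attempts kicks
the membrane into it; once an arc of high Rac exists, the cell protrudes
at the arc, newly gained membrane sites inherit interpolated
(arc-flavoured) state, and the arc effectively migrates onto freshly
replenished membrane faster than the local slow-field depletion that
would terminate it in the well-mixed model. Active cells are therefore
persistently polarized for long stretches, and at the WT-like $L_K$ two
long-lived modes coexist across seeds (a slower cycling mode and a faster
arc-locked mode). This is why cohort mean speeds of the active conditions
sit well above the inactive jitter floor, while the inactive condition
(no oscillation, no arc) reproduces its reference speed closely. The
ordering of condition means -- S273A-like below WT-like below S273D-like
-- is robust at the packaged cohort sizes.

## Known limitations

* The default parameter set is a reconstruction calibrated to the regime
  structure, not a transcription of an external table; absolute rates
  (time units) are therefore only meaningful relative to each other.
* The 2V/4V bookkeeping total $R + R_i + \gamma K$ is not exactly
  invariant (only $R + R_i$ is); its drift is bounded by
  $\gamma\,\mathrm{range}(K) \approx 0.05$.
* The CPM acceptance rate and speed scale depend on the Metropolis
  temperature, which is a free parameter of this implementation.
* Event detection assumes piecewise-directed motion with turns sharper
  than about 60 degrees; gentle curvature is not an "event".
* The classifier is a small MLP on four summary metrics; it does not see
  raw tracks or masks.
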