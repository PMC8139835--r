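---
title: "Model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(v1rex)
```

## The model and its assumptions

`v1rex` models an embryonic V1 interneuron (Renshaw cell) as a single
electrically compact compartment. At this developmental stage the cell
expresses a small current repertoire: a leak, a transient sodium current
(INat), a persistent sodium current (INap), a delayed-rectifier potassium
current (IKdr) and a transient A-type potassium current (IA); no calcium or
calcium-activated currents are included because none are detected at these
ages. Voltage obeys

$$C_{in}\frac{dV}{dt} = G_{in}(V_r - V) + G_{Nat}\,m^3 h\,(E_{Na}-V) +
G_{Nap}\,m_p^3 s\,(E_{Na}-V) + G_{Kdr}\,n^3\,(E_K-V) +
G_A\,m_{A\infty}(V)\,h_A\,(E_K-V) + I$$

with Boltzmann steady states and first-order kinetics for every gate. Three
variants share one code path: the basic model (no IA, `s = 1`), the basic
model plus IA (`GA = GKdr`, hA dynamic, mA instantaneous), and the
slow-inactivation model in which `s` relaxes with `tau_s = 2 s` and IA is
never included. The working hypothesis the package exists to explore is that
the GNap/GKdr balance alone organizes the firing phenotypes: single spiking
(SS), repetitive spiking (RS), mixed events (ME) and plateau potentials
(PP).

The unit system is fixed (mV, ms, nS, pF, pA), so `pF * mV / ms = pA` holds
without conversion factors anywhere.

## Parameters

Defaults (`v1r_params()`): `Cin = 13` pF (18 pF in the E14.5 preset),
`Gin = 1` nS, `Vr = -60` mV, `ENa = 60` mV, `EK = -96` mV, `GNat = 20` nS.
Gates: m (-26 mV, 9.5 mV, 1.5 ms, exponent 3), h (-45 mV, -5 mV,
voltage-dependent `tau_h(V) = 16.5 - 13.5 tanh((V+20)/15)` ms), mp (-36 mV,
9.5 mV, 1.5 ms, exponent 3), s (-30 mV, -5 mV, 2000 ms), n (-20 mV, 15 mV,
10 ms, exponent 3), mA (-30 mV, 12 mV, instantaneous), hA (-70 mV, -7 mV,
23 ms). `GNap` and `GKdr` are the free axes of the analysis; experimentally
realistic ranges are roughly 0-2.5 nS and 0-25 nS.

Three readings of ambiguous conventions are built in deliberately:

- The persistent-current activation applies the fitted sigmoid
  (-36 mV, 9.5 mV) to the per-gate variable `mp`, which enters the current
  as `mp^3`, exactly as the voltage equation is written. We checked this
  reading numerically: it reproduces the published bifurcation positions of
  both one-parameter diagrams to three significant figures, which the
  alternative (sigmoid describing the effective activation `mp^3`) does not.
- The A-current activation steepness is taken as +12 mV so that `mA_inf` is
  an increasing activation curve, per the stated sign convention.
- `tau_s` defaults to 2 s. A figure legend elsewhere mentions 2 ms for
  up/down states of comparable durations, but with `tau_s = 2` ms the
  slow/fast separation disappears and the model sits on a stable plateau
  with no bursting at all (easily checked with `current_step()` after
  `v1r_params(..., tau_s = 2)`); the "ms" is evidently a typo for "s". With
  the default 2 s the up and down states are already of comparable duration
  at GNap = 2.5 nS, GKdr = 5 nS, I = 10 pA.

## Numerics

**Integration.** Fixed-step fourth-order Runge-Kutta in C++ with
`dt = 0.01` ms (spikes rise on the 1.5 ms activation time constant, so this
resolves them by two orders of magnitude; the test suite checks that halving
`dt` changes a 2 s spiking trace by under 1e-3 mV, and that the passive
response matches the closed-form RC solution to 1e-6 mV). Segment boundaries
are aligned to exact step multiples to avoid floating-point drift. Initial
conditions come from the gate steady state at the holding command followed
by a 2 s settling run, so the same code path serves the slow-inactivation
variant.

**Fixed points and stability.** With gates at steady state the fixed points
are roots of a scalar current balance in V; they are bracketed on a
2001-point grid over [-100, 40] mV and bisected to 1e-6 mV, which guarantees
all branches of an S-shaped curve are found. Stability comes from the
eigenvalues of a central-finite-difference Jacobian (step 1e-6); real parts
below 1e-9 in magnitude are flagged marginal. With slow inactivation the
gate `s` is frozen (fast-subsystem analysis).

**Hopf points.** The branch (lowest- or highest-voltage fixed point) is
tracked over a 101-point scan; each sign change of the leading
complex-pair real part is bisected to 1e-3 nS (1e-2 pA on current sweeps).
A simulation cross-check (growth or decay of a 0.1 mV perturbation) guards
the eigenvalue machinery in the tests.

**Folds of limit cycles.** Stable cycles are followed by attractor
continuation: the initial condition at each parameter value is inherited
from the neighbouring converged cycle, a 2 s transient is discarded, and a
sustained oscillation is declared when every 250 ms subwindow of the last
second spans more than 20 mV peak-to-trough. The 20 mV criterion separates
full spiking from subthreshold ringing near the subcritical Hopf points and
is exposed as an argument. The fold is bisected to 1e-3 nS from a 26-point
coarse grid. Unstable cycle branches are out of numerical scope; bistable
windows are still identified correctly because both stable attractors are
found. An independent dense-grid attractor census (independent initial
conditions, no inheritance) brackets the same folds in the tests.

**Firing rates.** 10 s on the cycle, 2 s discarded, rate from the mean
interval between upward crossings of the mid-range voltage. Rates quoted
"at" a fold are measured at the located fold parameter itself, i.e. at the
last point where the stable cycle exists at the scan resolution.

**Stochastic engine.** Channels are discrete Markov populations with 10 pS
unitary conductance: an 8-state m^3 h scheme for INat, independent mp
(4-state) and s (2-state) gating sharing channel identity for INap (open iff
all three mp subunits and s are open), a 4-state n^3 scheme for IKdr.
Per-subunit rates are `alpha = x_inf(V)/tau_x`, `beta = (1-x_inf(V))/tau_x`.
Because exact SSA requires constant rates while the membrane equation makes
them voltage-dependent, a hybrid scheme is used: rates are frozen, the next
transition time is drawn exactly, and the voltage is advanced by the exact
exponential solution of the (then linear) membrane equation; rates are
refreshed after every advance and at least every 0.025 ms. IA is not
included in the stochastic variant. Runs are seeded explicitly and are
reproducible bit-for-bit given the seed. The deterministic limit is
verified by scaling the unitary conductance down tenfold.

**Event detection.** The baseline is the mean voltage over the 100 ms before
the pulse. The detection level for excursions is baseline + (command step /
Gin) + 10 mV: the middle term discounts the passive leak depolarization
(about 20 mV at 20 pA into 1 nS), and the 10 mV offset stays clear of
channel-noise fluctuations of a few mV. Without this correction the passive
envelope itself would be scored as a long event. Within an excursion,
events are sub-excursions above the excursion's half-amplitude level (which
separates spikes riding on a depolarized envelope), and each event's 1/2Ad
is the time spent above half of its own amplitude between the bounding
troughs. Events with 1/2Ad >= 100 ms are plateaus: the empirical duration
centroids of spike-like and plateau-like events differ by almost two orders
of magnitude (about 10-24 ms versus about 833 ms), so the threshold sits in
a wide empty gap and is exposed as an argument. Classification: 1-3 APs and
no plateau is SS; four or more APs is RS; a plateau with at most one AP is
PP; a plateau with two or more APs is ME; no events at all is "quiescent",
kept distinct from SS because real recordings always used suprathreshold
pulses. CV of 1/2Ad is forced to zero at three or fewer events.

**Burst segmentation.** Up/down states are found by hysteresis thresholding
of a running-median-smoothed voltage (40 ms window; thresholds at 60%/40%
of the smoothed range), states shorter than 50 ms are merged, and phases
are labelled by the sign of the slow-gate drift in each state (inactivation
during plateaus, de-inactivation during quiescence).

## Population analysis

Clustering standardizes (log10 mean 1/2Ad, CV 1/2Ad, log10 ddr) to zero
mean and unit sample (n-1) standard deviation, then applies
complete-linkage agglomeration on Euclidean distances (`hclust`) and cuts
at k clusters. The cluster number is selected by the mean silhouette width
over k = 2..12, with singleton silhouettes set to 0 (the standard
convention). The dose-response model is the Hill remaining-current curve
`(100 - Imin)/(1 + (c/IC50)^nH) + Imin`, fitted by bounded
Levenberg-Marquardt least squares (`minpack.lm`) with `Imin` in [0, 100),
`IC50 > 0`, `nH` in (0, 10], initial guesses Imin = min response, IC50 =
dose nearest the midpoint, nH = 1. 4-AP pharmacology scales GKdr by the
Hill remaining fraction (defaults Imin = 5%, IC50 = 2.9 uM, nH = 1), and
Gin by a factor interpolated linearly in log-concentration from 1 at
0.3 uM (the lowest applied concentration; the source reports only the
300 uM endpoint of a 23% mean reduction) to 0.77 at 300 uM; the
rheobase-matched flag rescales the injected current by the same factor,
mimicking the experimental re-adjustment of the stimulus.

## The synthetic cohort: what it emulates and what it does not

`generate_feature_table()` emulates the 163-cell feature table behind the
five-cluster structure: group sizes 46 (SS), 69 (RS), 35 (PP), 4 (ME with
short plateaus), 9 (ME with long plateaus), with the published group
centroids and dispersions reconstructed from the reported SEMs
(SD = SEM * sqrt(n)). Durations and duty-cycle ratios are log-normal
(clustering operates in decimal-log space) with the log-scale location
corrected so the arithmetic means match the published values; CV is normal
truncated at zero, and exactly zero for the SS and PP groups (the
three-or-fewer-events rule, and single plateaus). Two choices are ours
because the source does not constrain them: (i) the 1/2Ad and ddr centroids
of the two ME groups, reported only as not significantly different from
each other, are placed between the RS and PP centroids and separated along
the plateau-duration axis (90 ms/0.16 versus 280 ms/0.30) with dispersions
small enough that the five groups remain resolvable in at least 90% of
seeds - the separability the real cohort demonstrably had, given its clear
silhouette maximum at five clusters; (ii) log 1/2Ad and log ddr are drawn
with a weak positive within-group correlation (rho = 0.2, exposed as an
argument), since the two are functionally linked through the event count
but their empirical correlation is unreported.

`sample_conductance_population()` draws (GNap, GKdr) pairs from boxes
respecting the observed zonation of the conductance plane (SS below
GNap = 0.6 nS; above it, RS for GKdr > 3.5 nS and PP below; ME in a narrow
band at the RS/PP boundary), with box interiors kept away from the
bifurcation lines so that simulating a sampled pair through the full
simulate-and-phenotype path recovers the generating label in at least 80%
of SS/RS/PP cells; misclassifications concentrate at zone boundaries, as
they must. The E14.5 preset multiplies GNap by 0.6 and GKdr by 1.8,
mirroring the developmental decrease in sodium-channel density and growth
of the delayed rectifier with cell size.

None of the generators emulate recording artefacts (electrode drift, series
resistance, junction potentials) or cell-to-cell variation in passive
properties; passing tests therefore certify the analysis pipeline on clean,
model-like data, not robustness to the full messiness of recordings.

## Problem sizes used by the tests

The suite runs at desk scale: 2 s pulses (12-15 s for bursting runs),
26-point continuation grids with 1e-3 nS bisection, 101-point Hopf scans,
100-seed Monte-Carlo sweeps for cluster-number recovery, 200-fit recovery
studies for the Hill model, and a tenfold channel-number scaling for the
stochastic limit. A full two-parameter activity map at publication
resolution (101 x 101 with boundary continuation) is supported but tested
at coarse resolution.

## Known limitations

- Unstable periodic orbits and Floquet multipliers are not computed; the
  dashed branches of the published diagrams have no counterpart here.
- The stochastic scheme is a hybrid, not a full SSA of the coupled system,
  and the original stochastic implementation is unspecified; noise-induced
  plateau/quiescence duration statistics are therefore matched
  qualitatively only (noise shortens both, as expected).
- At very low GKdr the quiescent-to-plateau transition is gradual, with no
  intervening bifurcation; any event-based classifier (including this one)
  becomes convention-dependent there.
- Voltage clamp is ideal (no series resistance or space clamp); the offline
  IA subtraction protocol is exact only up to the decaying n-gate mismatch
  inherited from the different prepulses, and the slow-ramp INap estimate
  carries the window component of INat (a few pA), both faithful to the
  real protocols' limitations.
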