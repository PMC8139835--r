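# v1rex

Conductance-based modelling of embryonic V1 interneuron (Renshaw cell)
excitability.

Embryonic Renshaw cells express only a handful of voltage-gated currents, yet
display four distinct firing phenotypes in response to a 2 s depolarizing
current step: single spiking (SS), repetitive spiking (RS), mixed events (ME,
plateaus alternating with spike trains) and plateau potentials (PP). `v1rex`
implements the single-compartment model in which this diversity is controlled
by the balance between a persistent sodium conductance (GNap) and a
delayed-rectifier potassium conductance (GKdr), together with the complete
analysis built on it. It is aimed at cellular electrophysiologists and
computational neuroscientists who want to reproduce, probe or extend the
model's bifurcation structure and the population-level analysis.

## The model

Membrane voltage obeys

```
Cin dV/dt = Gin (Vr - V) + GNat m^3 h (ENa - V) + GNap mp^3 s (ENa - V)
          + GKdr n^3 (EK - V) + GA mA_inf(V) hA (EK - V) + I
```

with first-order gating kinetics `tau_x dx/dt = x_inf(V) - x`, Boltzmann
steady states `x_inf(V) = 1/(1 + exp(-(V - Vx)/kx))`, a voltage-dependent
transient-sodium inactivation time constant
`tau_h(V) = 16.5 - 13.5 tanh((V + 20)/15)` ms, and (in the slow-inactivation
variant) a slow inactivation gate `s` of the persistent sodium current with
`tau_s = 2 s`. Default passive properties are Cin = 13 pF, Gin = 1 nS,
Vr = -60 mV (E12.5 medians; an E14.5 preset uses Cin = 18 pF). Units are
fixed to mV, ms, nS, pF, pA.

The package provides:

- **Deterministic simulation** — fixed-step RK4 (C++), current-clamp steps
  and families, ideal voltage-clamp steps and slow ramps, pharmacology as
  parameter scalings (TTX, 4-AP via a Hill block of GKdr).
- **Stochastic simulation** — discrete Markov channel populations (10 pS
  unitary conductance) advanced by a hybrid Gillespie algorithm with exact
  voltage relaxation between transitions.
- **Bifurcation analysis** — Hopf points by eigenvalue bisection on
  fixed-point branches, folds of limit cycles by attractor-following
  continuation, firing-rate curves, the two-parameter GNap-GKdr activity
  map, and the quiescence/plateau bistability region in the I-GNap plane.
- **Phenotyping** — event detection with half-amplitude durations (1/2Ad),
  the descriptors (mean 1/2Ad, CV 1/2Ad, ddr), SS/RS/ME/PP classification,
  and burst segmentation of the slow-inactivation limit cycle.
- **Population analysis** — complete-linkage hierarchical clustering of
  standardized log-features, silhouette-based selection of the cluster
  number, and Hill dose-response fitting.
- **Synthetic data** — seed-deterministic generators for feature cohorts
  (matching the published five-cluster structure: 46/69/35/4/9 cells),
  conductance-pair populations with the observed GNap-GKdr zonation, and
  noisy dose-response tables.

## Worked example

```r
library(v1rex)

# firing phenotype of three conductance pairs (2 s step, 20 pA)
for (g in list(c(0.2, 10), c(1.2, 10), c(1.2, 2.5))) {
  p <- v1r_params("basic", GNap = g[1], GKdr = g[2])
  cat(sprintf("GNap = %.1f nS, GKdr = %4.1f nS -> %s\n",
              g[1], g[2], classify_point(p, 20)))
}
#> GNap = 0.2 nS, GKdr = 10.0 nS -> SS
#> GNap = 1.2 nS, GKdr = 10.0 nS -> RS
#> GNap = 1.2 nS, GKdr =  2.5 nS -> PP

# bifurcation structure of the GNap sweep at GKdr = 10 nS, I = 20 pA
p <- v1r_params("basic", GKdr = 10, I = 20)
limit_cycle_fold_scan(p, "GNap", c(0.3, 2.6), side = "onset")$value
#> [1] 0.647875
hopf_scan(p, "GNap", c(0.1, 2.5))
#>   kind param     value         V     direction
#> 1 Hopf  GNap 0.8095805 -35.64531 destabilizing
#> 2 Hopf  GNap 2.1275888 -21.31815   stabilizing
```

Repetitive firing appears through a fold of limit cycles at GNap ≈ 0.648 nS
(before the quiescent state destabilizes at the subcritical Hopf point at
0.810 nS, so quiescence and firing coexist between them), and the plateau
state is stable beyond the second Hopf point at 2.128 nS.

```r
# cluster a synthetic 163-cell cohort and select the cluster number
res <- run_pipeline(list(seed = 1))
res$silhouette$best_k
#> [1] 5
```

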