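---
title: "Modeling heterocyst patterning in growing cyanobacterial filaments"
author: "HetPattern authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heterocyst patterning in growing cyanobacterial filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HetPattern)
```

## The biological problem

Filamentous cyanobacteria such as *Anabaena* grow as one-dimensional
chains of photosynthetic vegetative cells. When combined nitrogen is
removed from the medium, roughly one cell in ten terminally
differentiates into a *heterocyst* — a non-dividing cell that fixes
atmospheric nitrogen for its neighbours. The resulting quasi-regular
pattern (about ten vegetative cells between consecutive heterocysts) is
maintained while the filament keeps growing and dividing, which makes it
a classic model of developmental patterning under growth.

HetPattern implements a stochastic gene-regulatory-network model of this
process on a growing cell lattice, together with the observables,
calibration machinery, a continuum toy analogue, and a batch/CLI layer.

## The model

Each cell $j$ carries six concentrations: the master activator HetR
($R$), its enhancer PatA ($A$), the diffusible inhibitor precursors
PatS+PatX ($S$) produced by vegetative cells, HetN ($N$) produced by
heterocysts, the processed mobile inhibitor hexapeptide ($I$), and fixed
nitrogen ($G$). All HetR-regulated genes share one promoter-activity
function

$$ g(R, A, I, G) \;=\;
   \frac{F_R R^{h} \left(1 + A/\tau_A\right)}
        {1 + F_R R^{h} \left(1 + A/\tau_A\right)
           + I^2/K_d^2 + G/K_G}, $$

with $h = 2$ (dimer regulation; $h = 4$ selects the tetramer variant).
It is increasing in the activators $R$ and $A$ and decreasing in the
inhibitors $I$ and $G$ (`regulatoryActivity()`).

The per-cell dynamics (`computeDrift()`) are, writing
$\delta_{Hc} \in \{0,1\}$ for the heterocyst indicator:

* $\dot R = \beta_R + g\,\rho_R - \alpha_R R (1 + 2\mu R)$ — basal plus
  regulated production; the quadratic loss lumps degradation through
  dimerization, $\mu = (k_b/\alpha_R)\,(1 - k_u/(k_u + \alpha_d))$
  (`muFromKinetics()`).
* $\dot A = g\,\rho_A - \alpha_A A$.
* $\dot S = (1 - \delta_{Hc})\, g\,\rho_S - (2 c_S + \alpha_S) S$ —
  vegetative cells only; the $2 c_S S$ term is export-and-processing
  into hexapeptide in the two neighbours.
* $\dot N = \delta_{Hc}\, \rho_N - (2 c_N + \alpha_N) N$ — heterocysts
  only.
* $\dot I = c_S (S_{j-1} + S_{j+1}) + c_N (N_{j-1} + N_{j+1})
  + d_I \Delta_j I - \alpha_I I$ — conversion influx from the
  neighbours plus nearest-neighbour diffusion
  ($\Delta_j$ is the discrete Laplacian).
* $\dot G = \delta_{Hc}\, \rho_G + d_G \Delta_j G - \alpha_G G$.

**Boundaries.** A terminal cell has a single neighbour; its open face
leaks $I$ and $G$ to the medium at the reduced rate $d_{border} \cdot
d_I$ (resp. $d_G$). This leakage lowers the inhibitor level at filament
ends and is the model's mechanism for terminal heterocysts in the
*patA* background; a single-cell filament leaks through both faces.

HetF is produced at a constant rate and degraded linearly, so it enters
only through its equilibrium $F_{eq} = \beta_F/\alpha_F$
(`hetfEquilibrium()`), lumped into
$F_R = F_{eq} K_F K_R / 2$ (`frFromConstants()`).

## Stochastic simulation

Concentrations follow chemical-Langevin dynamics integrated by
Euler–Maruyama (Itô): with production $P \ge 0$ and degradation
$D \le 0$ split termwise (`DriftDecomposition`),

$$ x(t + \mathrm{d}t) = x(t) + (P + D)\,\mathrm{d}t
   + \sqrt{\Omega_\Phi\,(P + |D|)\,\mathrm{d}t}\;\xi, $$

with independent standard normal $\xi$ per cell and species; negative
excursions are clipped to zero (`langevinStep()`).

**Commitment.** Each cell draws private thresholds
$T_{R,j} \sim \mathcal N(T_R, T_R^2 \Omega_\Phi)$ and
$M_{R,j} \sim \mathcal N(M_R, M_R^2 \Omega_\Phi)$. While $R \ge T_{R,j}$
the integral $\int R\,\mathrm{d}t$ accumulates; any dip below the
threshold resets it. The cell differentiates when the integral reaches
$M_{R,j}$ and at least $T_{min} = 5$ h have passed above threshold
(`updateCommitment()`). Under the convention $M_R = 12\,T_R$, a
noiseless cell held exactly at threshold commits after 12 h
(`commitmentTime()`).

**Growth and division.** Sizes grow as
$\dot\Lambda = \lambda (1 + \omega_\Lambda)$ with
$\lambda = 0.08\ \mu m/h$; a vegetative cell reaching its private
maximum size $M_{\Lambda,i} \sim \mathcal N(M_\Lambda,
M_\Lambda^2 \Omega_\Lambda)$, $M_\Lambda = 4\ \mu m$, splits into two
half-size daughters with identical concentrations, fresh thresholds and
reset commitment; heterocysts stop growing at their maximum size and
never divide (`growAndDivide()`). Starting from 30 cells this yields
roughly 50/100/200 cells at 24/48/72 h.

**Mutants.** Deletions are overlays on the production rates
(`mutantSpec()`, `applyMutant()`): `dpatS` keeps 10% of $\rho_S$ (the
PatX redundancy), `dpatX` removes only that 10%, `dpatSdpatX` removes
all of it, `dhetN` zeroes $\rho_N$, `dpatA` zeroes $\rho_A$, and `dhetF`
zeroes $\beta_F$ — which propagates to $F_R$ through the equilibrium
reduction and abolishes all regulated production. Factors compose
multiplicatively for double mutants (`combineMutants()`), and
`no_border_leak = TRUE` zeroes $d_{border}$ (the control showing that
terminal heterocysts require leakage).

## Parameters: units, defaults, rationale

Time is in hours, cell size in micrometers, and concentrations in
arbitrary units scaled so the commitment threshold is $T_R = 1$.
`wildTypeParameters()` returns the shipped preset. Its commitment and
growth block is fixed by design ($\lambda = 0.08$, $M_\Lambda = 4$,
$T_R = 1$, $M_R = 12$, $T_{min} = 5$, and $K_d$ held during annealing);
the remaining rates are *calibrated stand-ins*, fitted with the
package's own machinery (grid exploration plus `simulatedAnnealing()`)
against the study conditions the model is known to satisfy:

* wild type: mean vegetative interval near ten cells and roughly ten
  percent heterocysts from 24 h to 72 h, filament growth
  30 → ~50/~100/~200 cells;
* *hetF* deletion: no heterocysts at all;
* *patS* and *patS patX* deletions: strongly elevated heterocyst
  percentage, in that order;
* *patA* deletion: rare, predominantly terminal heterocysts that
  disappear when border leakage is turned off, with elevated vegetative
  HetR, and higher still when *hetN* is also deleted.

The noise amplitudes ($\Omega_\Phi$, $\Omega_\Lambda$, in
`noiseSettings()`) were chosen in the same calibration: genetic noise
sets how often cells escape lateral inhibition (interval tightness),
while growth noise desynchronizes division; very low growth noise
produces artificial division-synchrony oscillations in the cell count.

## Observables and batch statistics

`vegetativeIntervals()` measures maximal vegetative runs bounded by
heterocysts on both sides (end runs are excluded); `clusterSizes()`,
`heterocystPercentage()`, `terminalHeterocystCount()` and
`meanVegetativeHetR()` complete the per-filament summary
(`summarizePattern()`). Distributions are compared with the two-sample
Kolmogorov–Smirnov distance on raw samples (`ksDistance()`).
`batchStatistics()` pools samples within a batch and reports the mean
and sample (n−1) standard deviation across batches; the default design
is 15 batches of 10 runs (`runBatch()`), with per-run seeds derived
reproducibly from one base seed (`deriveSeed()`).

## Calibration machinery

`patternEnergy()` scores a parameter set against a
`ReferenceDataset`: ordinary ("O") entries contribute
$w_1 \mathrm{KS}^2 + w_2[(m_E - m_S)^2 + (p_E - p_S)^2]$, no-pattern
("N") entries (the *patA* backgrounds) contribute
$w_3 \mathrm{KS}^2 + w_4\, p_{Sim}$, and a rescue term
$(\bar R_{WT} - T_R)^2$ applies when the simulated wild type forms no
heterocysts, with default weights $(1000, 10, 500, 1)$.
`simulatedAnnealing()` minimizes it with multiplicative log-space
proposals on one random free parameter, Metropolis acceptance and
geometric cooling (0.98 every 50 proposals, 5000 proposals by default).
`parameterSensitivity()` implements the relative sensitivity
$S = (\Delta Y / Y)/(\Delta X / X)$; for example $Y = X^2$ at a +10%
perturbation gives $S = 2.1$ exactly.

## Continuum toy model

To isolate the boundary effect, `steadyStateProfiles()` integrates a
minimal continuum activator–inhibitor pair — non-diffusing $r$,
diffusing $s$ — by the method of lines (second-order central
differences) to steady state with `deSolve`. With zero-flux boundaries
the steady state is spatially uniform; with absorbing boundaries the
inhibitor drains at the ends and the activator peaks there — the
continuum analogue of terminal-cell leakage. For a constant source the
absorbing profile has the closed form
$s(x) = (f_0 \rho_s / \alpha_s)\,[1 - \cosh(\kappa(x - L/2)) /
\cosh(\kappa L/2)]$, $\kappa = \sqrt{\alpha_s/d}$
(`absorbingCoshProfile()`), used as the solver's oracle.

## Numerical choices and problem sizes

* Integrator step `dt = 0.01` h; first-order (Euler–Maruyama) accuracy
  is verified against closed-form decay with step-halving tests.
* A 72 h wild-type run (30 → ~200 cells) takes on the order of one to
  two seconds; the default 15×10 batch design takes a few minutes on a
  single CPU.
* The continuum solver converges at second order in the grid spacing;
  201 nodes resolve the default domain comfortably.
* All stochastic entry points are reproducible from a single integer
  seed; batch designs derive per-run seeds with a splitmix-style hash.

## A short worked example

```{r example, eval = FALSE}
params <- wildTypeParameters()
cfg <- simulationConfig(t_end = 48)
traj <- runSimulation(cfg, params, mutantSpec("WT"),
                      noiseSettings(seed = 1))
summarizePattern(snapshotAt(traj, 48))

## batch statistics with error bars across 3 batches of 5 runs
res <- runBatch(cfg, params, n_batches = 3L, runs_per_batch = 5L,
                base_seed = 1L, times_h = c(24, 48))
res$stats$t48
```

## Limitations

* Parameters are calibrated stand-ins reproducing the documented
  qualitative and quantitative study conditions, not a published table;
  absolute concentrations are in arbitrary units.
* The filament is strictly one-dimensional with nearest-neighbour
  transport; periplasmic continuity beyond nearest neighbours is not
  modeled.
* The external-data histogram comparisons used in the original study
  are out of scope; the calibration machinery is exercised against
  simulator-generated synthetic references instead.
* The continuum model is a deliberately minimal analogy for boundary
  effects, not a quantitative reduction of the cell-based model.
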