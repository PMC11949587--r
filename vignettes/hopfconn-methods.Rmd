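---
title: "Whole-brain Hopf modelling of phase-lag-index connectivity: methods and design"
author: "hopfconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain Hopf modelling of phase-lag-index connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hopfconn` simulates resting-state MEG-like phase dynamics as a network of
Hopf normal forms (Stuart–Landau oscillators) coupled on a weighted
structural connectome $W$:

$$\dot z_i \;=\; z_i\left(\lambda + i\,\omega_i - |z_i|^2\right)
  \;+\; g_i\,K \tanh\!\Big(C\sum_j w_{ij}\,x_j\Big),
  \qquad z_i = x_i + i\,y_i .$$

Each region $i$ is a two-dimensional oscillator whose real part $x_i$
stands in for the regional MEG signal. The **excitability** (Hopf
bifurcation parameter) $\lambda$ controls the local dynamics: for
$\lambda < 0$ an isolated node spirals into rest; at $\lambda = 0$ it
undergoes a Hopf bifurcation; for $\lambda > 0$ it self-oscillates on a
limit cycle of radius $\sqrt{\lambda}$ at angular frequency $\omega_i$.
The **global coupling strength** $K \ge 0$ scales a sigmoidal interaction
through the real parts only, without delays or noise. The structural
scaling $C$ compensates for the arbitrary units of tractography-derived
weights; once $C$ is large enough that the sigmoid saturates, the fit is
insensitive to it, and it is fixed at $C = 20$ throughout. The per-region
gain $g_i$ (default 1) is used only by the synthetic-cohort generator to
emulate tumor pathology (below).

Because the amplitude scale of the local dynamics is $\sqrt{\lambda}$,
rescaling $\tilde z = z/\sqrt{\lambda}$ shows that the *phase* dynamics
are governed by the **normalized coupling strength**

$$k = K / \sqrt{\lambda},$$

the ratio of interregional forcing to the amplitude of the local
oscillation. For excitability well above the bifurcation, parameter pairs
with matched $k$ produce statistically equivalent phase-locking patterns;
the square-root law fails near and below criticality, where amplitude
dynamics are slow and feed back into the phases. `rescaledEquivalent()`
and `rescaleInitialCondition()` construct matched pairs, and the
acceptance suite verifies that matched pairs at $\lambda = 10$ and
$\lambda = 40$ yield PLI matrices correlating above 0.9.

## Simulation protocol

Simulations follow the MEG-matched protocol: 14.5 s of model time,
first 1 s discarded as initial-condition transient, output sampled at
1250 Hz — giving 13.5 s epochs, the empirical epoch length. Integration
uses an adaptive Dormand–Prince Runge–Kutta 4(5) scheme at absolute
tolerance $10^{-6}$ and relative tolerance $10^{-3}$, with dense output
interpolated onto the uniform sampling grid and the step size capped at
the output interval (free steps at these loose tolerances drift
measurably on fast limit cycles). The integrator is compiled C
(`engine = "native"`); an independent route through `deSolve`
(`engine = "deSolve"`, same method and tolerances) is retained, and the
test suite checks both against a fixed-step RK4 reference on a two-node
system. Initial conditions draw each $\mathrm{Re}\,z_i(0)$,
$\mathrm{Im}\,z_i(0)$ independently from $U[-1, 1]$ under a caller-supplied
seed: bounded, unbiased, and scale-neutral across the $\lambda$ range
(the distribution is a package choice; only the analysis of the real
parts is prescribed by the protocol).

## From signals to PLI

The phase-lag index of regions $i, j$ is

$$\mathrm{PLI}_{ij} = \left|\;\big\langle \operatorname{sign}
  \sin\!\big(\varphi_i(t) - \varphi_j(t)\big) \big\rangle_t \;\right|,$$

the absolute time-average asymmetry of the phase-difference distribution:
0 for a symmetric distribution (including identical signals;
$\operatorname{sign}(0)$ contributes 0) and 1 for a consistent lead/lag.
Phases come from the analytic signal (Hilbert transform) of the
band-passed signal. Processing choices, where the protocol leaves them
open, are:

* **Filter**: 4th-order Butterworth band-pass (8–12 Hz alpha band by
  default), applied forward–backward so filtering is zero-phase and does
  not distort relative phase.
* **Edge handling**: 0.5 s trimmed from each end of the phase series
  before the PLI, suppressing filter and Hilbert edge artifacts; the
  analytic signal is computed on a zero-padded 2-3-5-smooth length for
  FFT efficiency, which only perturbs the (trimmed) edges.
* **Epochs**: a subject's PLI is the entrywise mean over epoch PLIs,
  computed before any thresholding.

Empirical PLI matrices are noisy relative to the noiseless model and are
thresholded before fitting: either the lowest $X\%$ of off-diagonal pairs
by magnitude set to zero (ties broken by a stable pair ordering so counts
are deterministic), or all entries strictly below the off-diagonal median
set to zero. `selectOptimalThreshold()` scans a threshold grid and keeps
the one whose best mean fit is largest.

Natural frequencies $\omega_i$ are parameterized from spectral peaks:
per region, the Welch density (2 s Hann segments, 50% overlap — 0.5 Hz
resolution at 1250 Hz) is scanned for the frequency above 4 Hz with the
highest density; peaks below twice the background level are rejected,
with background defined as the mean density over 4–48 Hz excluding
±1 Hz around the candidate (the simplest reading of "average background
density"; it is a package choice). Per-region medians are taken over
accepted peaks, regions with no accepted peak falling back to the global
median. The median (not the mean) is used when pooling across subjects
and epochs, exposed as the default of `medianPeakFrequencies()`.

## Fitting

The goodness of fit between a simulated and an empirical PLI matrix is
the Pearson correlation over off-diagonal upper-triangle entries.
Thresholded zeros count as data points (excluding them would change the
number of pairs per threshold level); `includeZeros = FALSE` is available
as a switch. `gridSearch()` fills a $(K, \lambda)$ grid, evaluating every
cell with the *same* seeded initial-condition ensemble so that cells are
paired and per-initial-condition optimal-K curves are well defined.
Cells whose simulated PLI has zero variance (fully locked networks at
extreme coupling) record `NA` rather than aborting the scan.

Defaults: $\lambda \in \{0, 5, \dots, 50\}$ and a 31-point
log-spaced $K$ grid on $[0.1, 30]$ (`defaultKGrid()`); production-scale
grids (e.g. $\lambda$ step 0.1) are configuration-reachable. The optimal
coupling per excitability is the per-initial-condition argmax, ties
broken toward the smallest $K$ (the weakest coupling consistent with the
optimum). The normalized coupling is fitted by closed-form least squares
through the origin on $(\sqrt{\lambda}, \bar K_\lambda)$:
$\hat k = \sum \bar K_\lambda \sqrt{\lambda} \big/ \sum \lambda$,
excluding $\lambda$ below `lambdaMin` (default 5) where the square-root
law does not hold.

## Functional connectotomy

The connectotomy removes a subject's tumor regions from the *objective*:
rows and columns of both the empirical and simulated PLI matrices are
dropped, the model itself is untouched, and the optimal $K$ at fixed
$\lambda = 40$ is recomputed. `simulatePLIBank()` materializes the
simulated PLIs per $(K, \text{initial condition})$ once; the same bank
serves the before/after objectives and the patient/control arms, making
the per-initial-condition change $\Delta K$ and the difference of changes
$\Delta K_\text{patient} - \Delta K_\text{control}$ exactly seed-paired.
The control arm fits the control-average PLI with the same mask, grid and
bank. Following the empirical protocol, patient-level fits use
median-thresholded patient PLI and the control arm uses the
median-thresholded control average.

## Statistics

Optimal-parameter distributions over initial conditions are compared
nonparametrically: `wilcoxonRankSum()` for independent distributions
(exact enumeration when $\min(n, m) \le 7$ without ties, normal
approximation with tie correction otherwise) and `wilcoxonSignedRank()`
for seed-paired connectotomy differences (zeros dropped, exact for
$n \le 15$ without ties). The protocol's description of the tests is
ambiguous between the two families; both are provided, with the paired
test the default wherever the design pairs seeds. `poolAcrossLambda()`
concatenates per-excitability samples preserving provenance.

## The synthetic-cohort generator

No public recordings accompany the study design this package implements,
so `makeCohort()` generates every input from scratch, reproducibly from a
master seed:

* **Connectome**: Erdős–Rényi topology at density 0.3 with log-normal
  weights normalized to maximum 1, resampled until connected; region
  centroids uniform in the unit sphere (so spatial tumor clustering is
  exercised). At $C = 20$ the sigmoid is deeply saturated, matching the
  scaling-insensitivity of the fit.
* **Frequencies**: regional peak frequencies uniform in 9–11 Hz
  (centre of the alpha analysis band), converted to rad/s.
* **Subjects**: "empirical" PLIs are generated by the model itself at
  known ground truth — default $K^\ast = 8$, $\lambda^\ast = 40$
  ($k^\ast = 8/\sqrt{40} \approx 1.26$) — from 3 epochs with distinct
  initial conditions, epoch-averaged, plus symmetric Gaussian observation
  noise (sd 0.02) truncated to $[0, 1]$.
* **Cohorts**: 33 controls and 10 patients share one connectome and
  frequency profile. Patients carry a tumor mask (3 regions by default)
  whose **coupling input is multiplied by a gain** $g = 1.5$: the tumor
  pathway is modelled as regional coupling inflation, since the
  phenomenon being emulated is an increased influence of interregional
  interactions, not a frequency shift. A global-$K$ patient pathway
  ($K^\ast_p > K^\ast_c$) is also available.

What the generator does *not* emulate: beamforming and source leakage,
volume conduction, sensor noise spectra, inter-subject anatomical
variability (one shared connectome), and non-stationarity within epochs.
Passing recovery tests on this generator therefore demonstrates the
correctness and sensitivity of the *pipeline*, not performance on real
MEG.

## Problem sizes and numerical choices

The tested configuration uses $N = 20$ regions (the 78-region scale is
configuration-reachable), 10 initial conditions for surface/recovery
checks, and 100 paired initial conditions for the connectotomy check;
these sizes were chosen so the full suite runs on a single desk-scale
CPU. Degenerate inputs are handled explicitly: all-zero channels have
undefined phase (error), fully thresholded matrices have an undefined
objective (error at 100%), zero-variance PLI vectors yield `NA` cells
inside scans and errors when correlated directly, and all-zero paired
differences make the signed-rank test degenerate (error).

A note on detectability: model-side coupling inflation propagates through
network feedback, so part of a synthetic patient's elevation survives in
the non-tumor block of the PLI and masking recovers only the localized
share of the effect. The connectotomy check therefore follows the
empirical protocol (median-thresholded patient PLI against the
median-thresholded control average), which sharpens the contrast the
objective sees.

## Known limitations

* The Hopf model here is deterministic and delay-free by design;
  dynamic functional connectivity and metastability are out of scope.
* Log-spaced coupling grids quantize optimal-$K$ estimates to ~21% steps
  at the default resolution; differences well below one grid step are
  not resolvable by the argmax.
* The fitted $k$ inherits an upward bias of order half a grid step from
  argmax quantization on flat goodness-of-fit surfaces.
* Exact Wilcoxon enumeration is only used at small sample sizes; at the
  connectotomy scale the normal approximation with tie correction
  applies.
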