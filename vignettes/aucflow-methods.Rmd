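---
title: "Models and numerical methods behind aucflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind aucflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aucflow)
```

# Scope

`aucflow` is a headless sedimentation-velocity (SV) pipeline for analytical
ultracentrifugation (AUC) under Good Manufacturing Practices (GMP)
constraints. It covers the complete life of an SV experiment: a simulator
standing in for the instrument, second-by-second rotor bookkeeping
(the *timestate*), conversion of intensity scans to pseudo-absorbance against
an air-region reference, automated boundary editing, a grid-based
least-squares decomposition with systematic noise removal, tolerance-based
Pass/Fail reporting against a reference dataset, and an *autoflow* supervisor
that tracks each run through the staged workflow with session locking and
crash reattachment.

Interacting or non-ideal systems, interference optics, genetic-algorithm and
parametrically-constrained refinement stages, and multi-wavelength spectral
decomposition are out of scope; the two refinement stages exist as explicit
"not implemented" stubs in the workflow vocabulary.

# The transport model

All flow in a sector-shaped AUC cell follows the sedimentation-diffusion
equation

$$\frac{\partial c}{\partial t} =
  \frac{1}{r}\frac{\partial}{\partial r}
  \left[ r \left( D \frac{\partial c}{\partial r}
  - s\,\omega^2 r\, c \right) \right],$$

with zero-flux walls at the meniscus $r_m$ and the cell bottom $r_b$. Species
are assumed non-interacting, so multi-species solutions superpose.

## Discretization

`solveLamm()` uses a vertex-centred finite volume on a uniform radial grid
(default step 0.001 cm; boundary cells carry half width so the walls sit
exactly at $r_m$ and $r_b$ for every resolution). Face fluxes use
Scharfetter–Gummel exponential fitting: with face Péclet number
$\mathrm{Pe} = s\omega^2 r_f\,h/D$ and $B(x) = x/(e^x-1)$, the flux through a
face is $J_f = (D/h)\,[B(-\mathrm{Pe})\,c_L - B(\mathrm{Pe})\,c_R]$. This
reduces to central differencing for small Pe and to upwinding for large Pe,
so the scheme is stable at arbitrary cell Péclet numbers without a separate
refinement check, and it is *locally conservative*: the discrete sector mass
$\sum_i c_i r_i w_i$ is constant to round-off (the tests require 1e-6 over a
two-hour run; the scheme delivers ~1e-14).

Time stepping is Crank–Nicolson with the rotor speed profile — including the
linear acceleration ramp — evaluated at substep midpoints. Substeps obey an
advective Courant limit (default 0.8) and a 10 s cap; the first ten substeps
use backward Euler (a Rannacher start) to damp Crank–Nicolson ringing on
sharp initial profiles. The tridiagonal systems are solved by the Thomas
algorithm in compiled code.

Verified properties (see `test-lamm.R` and the acceptance suite): exact
initial condition at $t=0$, mass conservation, non-negativity within $-10^{-8}$,
the vanishing-diffusion front tracking $r_m e^{s\omega^2 t}$ within half a
grid step, the rotor-off limit matching the analytic erf diffusion profile
within $10^{-3} c_0$, and second-order spatial convergence (error ratio ≈ 4
per step halving).

# The timestate

The instrument's system log is modelled as one record per second from
$t = 1$ s: set and actual rotor speed, cumulative $\omega^2 t$, temperature
and stage index. $\omega^2 t$ accumulates by per-second trapezoids of
$\omega(t)^2$ over the ramp/hold profile; for a linear ramp of duration
$t_a$ the closed form is $\omega_f^2 t_a/3$ and the trapezoidal error bound
$\omega_f^2/(6 t_a)$ is met exactly. `verifyScans()` cross-checks every scan
header three ways: the recorded $\omega^2 t$ against the interpolated log
(relative, floor of 1 on the denominator), the rotor speed against the
actual speed at that second, and the scan time against the time implied by
*inverting* the $\omega^2 t$ integral — the "separate timer" check. Default
tolerances (1 s, 1e-4 relative, 5 rpm) sit above the 1-second discretization
error at 60000 rpm. Note that a corrupted $\omega^2 t$ shifts the implied
time as well, so isolating the $\omega^2 t$ tolerance in tests requires
widening the time tolerance.

# Simulation of the instrument

`simulateExperiment()` emits what the detector would record. For each
channel the true meniscus is placed at the volume-derived position (below),
the bottom at $r_{b,0} + \mathrm{stretch(rpm)}$ from the rotor calibration
polynomial, and the recorded intensity is

$$I(r,t) = I_{\mathrm{ref},\lambda}\,
  10^{-[A_{\mathrm{true}}(r,t) + \beta(r) + \gamma(t)]} + \epsilon .$$

* $\beta(r)$ — time-invariant radial baseline: a sum of five random-phase
  sinusoids scaled to sd `tiAmplitude`, mimicking window scratches and dust.
* $\gamma(t)$ — radially-invariant per-scan offset, i.i.d. normal with sd
  `riAmplitude`, mimicking lamp flicker.
* $\epsilon$ — detector noise, scaled multiplicatively
  ($\epsilon = Z \cdot \sigma \ln 10 \cdot I$) so that the *induced
  pseudo-absorbance noise* has sd `stochasticSd` to first order; every
  downstream quality number is phrased in absorbance units, which makes this
  the natural parameterization.
* The air region above the meniscus transmits $I_{\mathrm{ref},\lambda}$
  unattenuated, and a narrow Gaussian absorbance spike (default 0.8 AU,
  sigma 0.002 cm) marks the meniscus — the optical artifact that real
  detectors record and that the editing stage exploits.

A single RNG stream is seeded per experiment and per-triple substreams are
drawn from it, so the same seed reproduces the experiment bit-for-bit, and
the baseline generator consumes a fixed number of draws regardless of
amplitude so that experiments differing only in one noise amplitude share
the rest of the noise realization (used by the noise-recovery tests).

What the simulator deliberately does **not** emulate: optical convolution
(finite beam width), chromatic aberration, temperature drift, concentration
dependence of $s$ and $D$, and reacting systems. Passing tests therefore
demonstrate correctness of the pipeline's numerics and logic on idealized
single- and multi-species data, not robustness to every pathology of real
instruments.

# Import: intensity to pseudo-absorbance

The per-wavelength reference intensity is the mean over the air-region grid
points across *all* scans (the all-scan mean has lower variance than a
first-scan estimate; the choice is recorded here because either convention
is defensible). The default region is $[\hat r_m - 0.10, \hat r_m - 0.02]$ cm
left of the volume-derived meniscus estimate. Conversion is
$A = \log_{10}(I_{\mathrm{ref}}/I)$; intensities below
$I_{\mathrm{ref}}\,10^{-3.5}$ (beyond instrument linearity) clamp at 3.5 OD
and the clamp count is reported. Converting twice is a guarded error.

# Automated editing

The meniscus estimate comes from the loading volume $v$ (µl) through the
sector geometry: a channel of pathlength $h$ (cm) and sector angle $\theta$
(degrees) holds $v = 1000\,h\,(\theta\pi/180)(r_b^2-r_m^2)/2$ µl between
$r_m$ and $r_b$, so

$$r_m = \sqrt{r_b^2 - 0.36\,v/(h\,\theta\,\pi)}.$$

The detector then searches a ±0.05 cm window around the estimate in the last
$\lceil 0.2 n\rceil$ scans (minimum 2 — late scans are depleted near the
meniscus, so the artifact stands out), takes each scan's in-window maximum as
its meniscus, and averages. A maximum counts as *prominent* only if it
exceeds the window median by ≥ 5 robust (MAD) noise units; if a majority of
used scans lack a prominent peak the stage raises (or falls back to the
estimate when configured). The per-scan maximum — rather than an inflection
criterion — was chosen because the simulated artifact is symmetric and the
maximum is robust under the MAD gate.

The left data limit snaps to the grid 0.03 cm right of the meniscus (so a
meniscus fit can never move the boundary condition into the data), the right
limit comes from the protocol, the baseline is the mean of 20 grid points
centred at the left limit in the last scan (10 each side), and the per-scan
plateau is the mean of 20 points ending 0.03 cm left of the right limit.
"20 points" means 20 grid samples at whatever step the instrument used. In
multi-wavelength channels the meniscus and range propagate to every triple
of the same cell/channel; baseline and plateau are recomputed per triple.

# The grid fit

The decomposition models the edited data as a non-negative combination of
unit-loading solutions on a two-dimensional grid of sedimentation
coefficient $s$ (log-spaced by default) and frictional ratio $k = f/f_0$.
Each grid point converts to $(D, M)$ through standard hydrodynamics
($f_0 = 6\pi\eta(3M\bar v/4\pi N_A)^{1/3}$, $s = M(1-\bar v\rho)/N_A f$,
Svedberg relation for $D$; closed-form solve for $M$).

Time-invariant (per-radius) and radially-invariant (per-scan, zero-mean)
offsets augment the linear system. Because they enter linearly and
unconstrained, they concentrate out exactly: both the data and every design
column are projected onto the complement of the offset subspace (row/column
centering of the radii × scans reshape), a single NNLS solves for the
concentrations, and the offsets are recovered from the residual means. The
zero-mean constraint on the per-scan offset resolves its degeneracy with the
per-radius vector. The NNLS itself is an active-set solver on the normal
equations (Bro–de Jong style), cross-checked in the tests against the
Lawson–Hanson reference implementation in `pracma`.

The meniscus fit repeats the full fit for an odd number of candidate
positions spanning ±`meniscusSpan` around the edited meniscus, takes the
RMSD minimum (ties break to the lowest radius), refines by a parabola
through the three lowest points, and refits at the vertex; a minimum on the
span edge raises a warning. The iterative stage refits until the RMSD
change drops below 1e-6 AU or the iteration cap; with the exact offset
solve it converges immediately and is retained for workflow fidelity.
Monte Carlo uses a residual bootstrap — refit on fitted model plus
resampled residuals, seed-controlled — and reports mean ± sd of the
signal-weighted statistics.

`runWorkflow()` executes the stages in the canonical order — grid fit with
TI noise, meniscus fit with TI+RI, iterative refinement, Monte Carlo — gated
by the workflow flags, persists every stage model when a store is supplied,
and records failures in the stage log (later stages are skipped).

## Default grid resolution and study sizes

Defaults: $s \in [1, 10]$ S with 32 log-spaced points, $k \in [1, 2.5]$ with
5 points, 3 meniscus candidates at ±0.004 cm, 3 refinement iterations. The
s-resolution matters: with ~12 % spacing (20 points) a fast, weakly
diffusing species between grid points cannot be represented by its
neighbours — their boundaries sit measurably apart — which inflates the
recovered frictional ratio error; ~7.7 % spacing (32 points) represents
every single species in the covered range to well within the fit noise. The
`subgridSize` protocol field is accepted for compatibility but inert, since
the desk-scale fit solves one NNLS on the full grid rather than partitioned
subgrids.

The recovery studies in the tests use: 50000 rpm, 400 rpm/s ramp, 40 scans
at 90 s intervals, 450 µl loading (column ≈ 1.3 cm), loading signal 0.6 AU,
radial step 0.0025 cm for fitting studies and the instrument-like 0.001 cm
for editing studies, and noise amplitudes 0.02 / 0.005 / 0.003 AU
(TI / RI / stochastic) — values a practitioner would call a clean but
realistic intensity experiment. The editing study runs 50 seeded
experiments, the fit study 20; Monte Carlo (B = 20) is exercised on a single
run, as its per-replicate cost multiplies the whole fit.

# Reporting

`extractMetrics()` computes the reportable properties: loading volume
(sector-volume inverse of the detected meniscus — the exact inverse of the
meniscus formula), loading concentration (plateau of the earliest used scan;
the operational definition is a package choice since several are plausible,
and only consistency between runs matters for comparisons), duration, rotor
speed, scan count, column length $r_b - r_m$, fit RMSD, and the fitted
signal fractions over $s$ ranges (bins, default 0–2–5–10–∞ S; binning rather
than one-to-one species pairing because fitted species counts vary between
runs). `compareToReference()` computes percent deviations
($100|m-r|/\max(|r|,\varepsilon)$; species bins in absolute percentage
points), flags deviations beyond their tolerances, and grades Pass/Fail —
or AsIs, with no flags and no grade line, when no reference exists. Default
tolerances: volume 2 %, concentration 5 %, duration 1 %, rotor speed and
scan count exact, column length 2 %, RMSD 25 %, species fractions ±5
points; all overridable per report and deliberately conservative, since
instrument-specific values must come from validation campaigns.
`renderReport()` is deterministic: identical records render byte-identical
documents.

# Autoflow

Each run is one record walking
DESIGN → LIVE_UPDATE → IMPORT → EDITING → ANALYSIS → REPORT → DONE, one
stage per event, with out-of-order events rejected without side effects.
Submission requires a frozen, complete profile and an idle instrument (one
live record per instrument). A session GUID locks a record against
concurrent access; locks persist on disk across process restarts and
release is idempotent. Every transition appends one tab-separated line
(timestamp, run, event, old, new, session) to an append-only journal — the
audit trail — while the current state lives in one JSON file per run, so a
crashed client reattaches by reading the store. Abandonment is admin-only
and limited to LIVE_UPDATE/IMPORT, before data are committed.

# GMP data semantics

Profiles freeze under a GUID: field writes through the API and store
overwrites then become permission errors, and any derived change requires a
new GUID *and* run name — identity of a GMP protocol is its GUID, so even a
content-identical derivation gets a fresh one (conservative reading).
Signal data round-trip bit-exactly through the store as little-endian
8-byte doubles; a legacy whitespace-delimited ASCII dialect (description
line, header line, radius/value rows) is supported for interchange with
older instruments, with parse errors naming the offending line. User levels
gate mutating operations: operators read and import, designers freeze,
admins delete (cascading over an experiment's children; frozen profiles
live outside the cascade).

# Known limitations

* Single NNLS over the full grid: memory grows with grid × data size; the
  defaults are desk-scale, not cluster-scale.
* The frictional ratio of species outside the diffusion-informative regime
  (very fast *and* very anisotropic at short run times) is intrinsically
  weakly determined; the grid resolution note above sets where recovery is
  reliable.
* The simulator's noise model is stationary; drifting baselines between
  scans are representable only through the RI component.
* Bottom-region data (beyond the right data limit) routinely exceed the
  3.5 OD linearity cap and are clamped on import; analyses never use them.
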