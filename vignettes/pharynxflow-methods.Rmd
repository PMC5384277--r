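---
title: "Models and methods: pharyngeal airflow after incisor retraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pharyngeal airflow after incisor retraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`pharynxflow`: what is modelled, what is deliberately simplified, which
parameters matter, and what a passing test does and does not establish.

## 1. The question being modelled

Large incisor retraction narrows the pharyngeal airway. The functional
consequence during inspiration is a larger pressure drop between the
choana and the narrowed segment: by the Bernoulli mechanism, faster flow
through a smaller lumen lowers internal pressure and makes the airway
more collapsible. The package reproduces, at desk scale, the complete
workflow of a clinical computational-fluid-dynamics (CFD) study of this
effect: paired pre/post anatomies, segmentation, meshing with a
grid-independence check, a steady laminar solve at peak inspiratory flow,
slice-based outcome metrics, and paired statistics with multiplicity
correction.

## 2. The axisymmetric idealization

Real airways are non-circular and tortuous. The phantom is a body of
revolution: a circular cross-section of smoothly varying area A(z), with
z = 0 at the choana increasing inferiorly (mm). Every outcome metric
(region volume, minimum area, slice-averaged pressure) is defined
identically for this idealization, while the flow problem becomes exactly
two-dimensional (axisymmetric), which keeps a full finite-volume
Navier–Stokes solve in the range of seconds. The price is physical:
a smooth circular duct dissipates far less energy than a real airway, so
desk-scale pressure drops are a few Pa against tens of Pa clinically.
All cross-cohort comparisons are therefore interpreted in sign and
ordering, never in absolute magnitude.

## 3. Phantom construction

`build_phantom()` needs to satisfy four targets at once: three region
volumes, a prescribed global minimum area `a_min` at a prescribed
location, and the inlet-face area. The base area profile interpolates
region-mean areas (at region midpoints, plus pinned end controls) with
the Fritsch–Carlson shape-preserving cubic. An ordinary cubic spline was
rejected after testing: on strongly contrasting random anatomies it
overshoots between controls, silently relocating the global minimum. A
C1 cosine-squared constriction bump is multiplied in; its depth is solved
by bisection so the profile minimum equals `a_min`; region volumes are
re-normalized and the two steps iterated to joint convergence (volume
error ≤ 0.5%). Controls are clamped above `a_min` during iteration; a
spec whose volumes cannot be matched under that constraint is reported as
infeasible rather than silently distorted.

The two landmark planes separating nasopharynx / oropharynx / hypopharynx
are fixed axial positions. Default lengths (18 / 62 / 29.31 mm) were
chosen once so that the whole-column mean area V/L of the reference
pre-treatment anatomy equals A_min/0.69, the reported area-ratio at
baseline, with a clinically plausible split.

### The pre/post pair

The reference pre-treatment anatomy carries the cohort-mean values
(V = 5.68/20.83/8.50 cm³, A_min = 2.21 cm² in the hypopharynx). The
reference post-treatment anatomy (5.37/15.64/6.04 cm³, A_min = 1.51 cm²)
relocates the constriction to the tongue-base level: the inferior
oropharynx (fractional position 0.85), with a broad window (0.55 of the
oropharynx length). Both choices are anatomical: the treatment-induced
narrowing is a long stretch of backward tongue displacement peaking at
the tongue root, not a localized notch. A narrow notch was tried first
and produced an artifact — conserving region volume around a deep narrow
bump forces the rest of the oropharynx to *widen*, which leaks a spurious
systematic change into the nasopharyngeal metrics.

### A_min/A_mean

The source table reports the area ratio rising after treatment while
volumes and A_min both fall — mutually inconsistent, and the
accompanying text says the ratio fell. The generator reproduces the
primitive measurements (volumes, A_min); the derived ratio therefore
falls in the synthetic world. This discrepancy is surfaced here rather
than resolved.

## 4. Synthetic cohorts

`sample_cohort()` draws pre-treatment variables from truncated normals
(lower bound 10% of the mean — the published SDs are large enough that
unbounded draws go non-physical). The incisor retraction amount is
ICE ~ N(6.84, 1.68²) mm truncated at 0. Post-treatment anatomy follows a
linear sensitivity model, fractional reduction = s·ICE + ε, with
sensitivities calibrated so the expected post anatomy at the mean
retraction reproduces the reference post-treatment means; the
nasopharynx is unchanged in expectation. Independent draws of A_min and
region volumes can be jointly infeasible for a tube (the minimum must
undercut every region's mean area); feasibility is restored by shrinking
region *lengths* per patient and flooring the inlet area — lengths carry
no cohort-level target, so the tracked marginals (V_or, V_hy, A_min,
ICE) are untouched. Genuinely infeasible draws (a few percent) are
excluded and logged, mirroring scan-quality exclusions in clinical
cohorts.

The study's manual double-measurement protocol is also emulated
(`measure_cohort()`): every metric is "measured" twice with the published
method-error magnitudes (0.47 Pa pressures, 0.31 mm² areas, 0.15 mm³
volumes, 0.24 mm ICE) and the session average carried forward. Without
this layer the phantom world is unrealistically noise-free: sub-0.1-Pa
systematic geometry effects reach statistical significance that no
measurement protocol could resolve.

What the generator does **not** emulate: non-circular sections, airway
curvature, the nasal cavity upstream of the choana, inter-variable
correlations beyond the ICE coupling, soft-tissue compliance. A green
cohort test establishes that the pipeline machinery reproduces the
expected sign structure in a world with the published first and second
moments — not that the generator is anatomically realistic.

## 5. Grids and grid independence

Grids are structured and body-fitted through the mapping η = r/R(z):
axial faces are flat annuli, radial grid lines follow the wall. Radial
spacing is geometrically graded (default ratio 1.15 toward the wall) to
resolve the laminar boundary layer; defaults are 200 × 32 cells with a
√2 refinement series of five levels. The independence protocol solves
every level and accepts the coarsest whose plane-averaged pressure and
velocity at the probe plane (default: the A_min station) change by <1%
against the next finer level.

An optional straight outlet extension (default 30 mm in
`phantom_metrics()`) continues the duct beyond the hypopharynx bottom
with the wall slope blended to zero — the standard tracheal-extension
practice. Without it, the separation bubble behind a hypopharyngeal
constriction interacts with the extraction boundary and the steady solve
limit-cycles. Metrics never sample the extension.

## 6. The flow solver

Finite volumes on a staggered arrangement (pressure at cell centres,
velocities on faces) avoid checkerboarding without Rhie–Chow
interpolation. Convection is first-order upwind implicit plus a deferred
second-order correction — minmod-limited linear upwind — and diffusion is
central; the non-orthogonal cross-diffusion on the gently sloped η faces
is neglected (slender-geometry assumption; the straight-tube benchmark is
exactly orthogonal). Pressure–velocity coupling is SIMPLE with
under-relaxation 0.7 (velocity) / 0.3 (pressure); inner solves are
Gauss–Seidel sweeps for momentum and alternating-direction line-TDMA for
the pressure correction.

Boundary conditions: uniform (optionally parabolic) extraction velocity
at the inferior face computed from V = Q/A; no-slip wall; symmetry axis;
and at the choana a plug inflow at the exact flow rate with the converged
pressure shifted so the choana-plane mean equals the ambient value. A
literal static-pressure inflow with extrapolated velocity was tried first
and produced a persistent feedback limit cycle at airway Reynolds
numbers; for a duct flow driven by a prescribed flow rate the two
formulations are physically equivalent up to entrance detail.

Convergence: residuals are L2 imbalances scaled by the largest value over
the first five iterations (a plug initial guess has zero radial-momentum
residual at iteration one, so a strict first-iteration scale would be
meaningless). The stopping rule is tolerance 10⁻⁴ or the iteration cap
(default 1000), whichever first; the published fallback criterion (0.2%)
is recorded in the documentation but not used as the convergence flag.

### Marginally unsteady solves

At the study's peak flow (≈28 L/min) the throat jet of a narrow
post-treatment airway reaches Reynolds numbers of 2500–4000 —
transitional. A genuinely steady solution then need not exist: residuals
stall in a small limit cycle. The solver detects the stall (no
divergence, tolerance not reached), iterates an extra averaging window
(default 600 iterations) and returns the iterate-averaged fields — the
desk equivalent of a time-mean flow. Such a field is accepted for metric
extraction (`field_usable()`) only if its mass imbalance stays within 2%;
the `converged` flag remains honest. A throat-Reynolds warning
(threshold 2300) flags every such run. `phantom_metrics()` additionally
retries stalled or diverging solves with a damped relaxation pair and
finally with the first-order scheme, the usual manual rescue sequence.

Gravity is included by default as an axial body force; reported slice
pressures are hydrostatic-corrected (p − ρgz) so ΔP metrics reflect flow
resistance only, with a flag to disable.

## 7. Outcome metrics

Slices are taken every millimetre from choana to hypopharynx bottom;
slice quantities are area-weighted averages with the axisymmetric area
element. ΔP_max is the choana-slice mean pressure minus the A_min-slice
mean pressure (floored at zero with a warning if a pathological field
inverts it); regional ΔP is max − min of slice mean pressure within the
region; ties in A_min resolve to the most superior slice. Resistance is
computed as R = ΔP/Q (the printed formula R = Q/ΔP is dimensionally a
conductance; the accompanying statement that ΔP tracks resistance at
constant flow pins down ΔP/Q) — recorded in the metric output. Velocity
is averaged as a magnitude (speed), matching how velocity fields are
displayed in such studies.

### A known red result

In the published cohort the hypopharyngeal pressure drop *rises* after
treatment even though the minimum moved to the oropharynx. That behaviour
is driven by non-recovering transitional jets: the real post-treatment
pressure falls monotonically from choana to hypopharynx. A smooth
axisymmetric *laminar* model recovers pressure downstream of the throat
(Bernoulli recovery), so once the constriction leaves the hypopharynx the
regional max−min span there shrinks. The desk cohort accordingly shows a
non-significant *decrease* in Hy-ΔP, and the corresponding component of
the cohort acceptance test fails by design rather than being masked.

## 8. Statistics layer

Paired two-sided t tests (n−1 df); Holm step-down correction (sort
ascending, multiply the i-th smallest by m−i+1, enforce monotonicity, cap
at 1) which reproduces eight of the nine published corrected P values
exactly from the printed raw values, the ninth differing by 0.001 from
rounding of the inputs; Pearson correlation with the t transform (n−2
df); Dahlberg ME = sqrt(Σd²/2n); and ICC(3,1) — two-way mixed,
single-measure, consistency — as the intra-examiner reliability variant
(the source does not name its ICC model; 3,1 is the standard choice, and
the variant is isolated in one function). Correlation tables relate
T2−T1 changes of the pressure metrics to changes of the anatomic
covariates and to ICE; all tests are two-sided.

## 9. Units and reproducibility

Geometry is mm/cm²/cm³ (matching clinical tables), the waveform mL and s,
the solver SI; every conversion lives in one file. All randomness flows
from a single integer seed; the pipeline writes its resolved
configuration, seed and wall-clock into a manifest beside its outputs,
and identical configurations produce byte-identical CSV output.

## 10. Known limitations

Steady flow only (the peak-flow steady approximation is standard and was
validated against unsteady simulation in the source literature at the
~2 Pa level); no turbulence model — transitional throats are handled by
iterate averaging, not resolved; rigid walls (no fluid–structure
interaction); no nasal cavity; axisymmetric geometry; desk-scale pressure
magnitudes an order below clinical values.
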