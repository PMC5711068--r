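---
title: "Collapsed versus rotated IMRT QA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsed versus rotated IMRT QA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imrtqa)
```

## The measurement problem

Patient-specific IMRT QA includes an absolute point-dose measurement: an
ionization chamber in a homogeneous phantom, placed in a high-dose,
low-gradient region, compared against the planned dose. Two delivery
conventions coexist in clinics. In *rotated* delivery the plan's beams are
delivered at their planned gantry angles; in *collapsed* (single-gantry-angle
composite) delivery every beam is fired from one angle, so all apertures
stack along a single axis. Collapsed delivery is operationally convenient,
but the stacked in-plane gradients make the dose in the chamber less
homogeneous, the measurement more sensitive to positioning, and the chamber's
response further from its calibration conditions.

This package quantifies that trade-off with the metric set used in this
line of QA research — plan complexity scores, DVH metrics over the chamber
volume, a beam-chamber intersection fraction, and the small-field output
correction factor — and exercises the full analysis on synthetic paired
deliveries from a deterministic toy dose engine.

## Plan complexity: MCS, LSV, AAV

For a segment (one static MLC aperture with an MU weight), the *leaf
sequence variability* (LSV) measures, per bank, how variable adjacent open
leaves are relative to the bank's positional range
$\mathrm{pos}_{\max} = \max(\mathrm{pos}) - \min(\mathrm{pos})$:

$$
\mathrm{LSV} \;=\;
\prod_{\text{banks}}
\frac{\sum_{n=1}^{N-1}\bigl(\mathrm{pos}_{\max} - |\mathrm{pos}_n -
\mathrm{pos}_{n+1}|\bigr)}{(N-1)\,\mathrm{pos}_{\max}},
$$

over the $N$ open leaves of the bank. The sum runs over the $N-1$ adjacent
pairs with an absolute difference; printed forms of this score sometimes
state an upper limit of $N$ (which would require a nonexistent
$\mathrm{pos}_{N+1}$) and omit the absolute value, and the $N-1$
adjacent-pair reading is the only self-consistent one — it also matches the
score's original construction. A bank with one open leaf or with all open
leaves aligned ($\mathrm{pos}_{\max}=0$) is perfectly regular and
contributes a factor of 1; this convention avoids a 0/0 and makes the
static rectangular field score exactly 1.

The *aperture area variability* (AAV) is the segment's summed per-leaf
opening divided by the summed per-leaf *maximal* opening reached over all
segments of the same beam (per-beam, matching the beam-wise aggregation
that follows). The *modulation complexity score* is then the MU-weighted
mean of $\mathrm{AAV}\times\mathrm{LSV}$ over segments (per beam) and of
beam scores over beams (per plan). MCS is 1 for an unmodulated static
rectangular plan and decreases with modulation; no gantry, collimator or
couch angle enters it, so it is exactly invariant under the collapsed
transform — a property the test suite checks over seeded random plans.

A leaf pair counts as *open* when its gap exceeds `gap_threshold`
(default 0.05 cm): closed pairs parked behind the jaws carry no fluence
but would otherwise dominate the LSV. A fully closed segment contributes
score 0 to the beam (its aperture area is zero; its LSV is undefined and
never needed).

## Dose metrics over the chamber

All DVH quantities use the exact voxel-rank convention with no binning or
interpolation: $D_{x\%}$ is the largest dose received by at least $x\%$ of
the structure's voxels, i.e. the $\lceil x n/100\rceil$-th voxel dose in
descending order. This makes every value testable bit-for-bit against a
brute-force sort, which the suite does on grids up to $50^3$.

* **Homogeneity index** $\mathrm{HI} = (D_{2\%}-D_{98\%})/D_{\mathrm{avg}}$
  over the chamber contour; 0 is perfectly uniform.
* **Conformity index** with reference isodose RI equal to the mean chamber
  dose: $\mathrm{COIN} = (V_{\mathrm{ch}\ge RI}/V_{\mathrm{ch}})\times
  (V_{\mathrm{ch}\ge RI}/V_{\mathrm{shell}\ge RI})$, where the shell is the
  chamber dilated by 1.5 cm (Euclidean dilation of voxel centers). The
  shell *includes* the chamber: with an annulus the ideal value 1 (isodose
  covering exactly the chamber) would be undefined.
* **Beam-chamber intersection**: a beam counts as crossing the chamber when
  some chamber voxel receives at least a fraction `frac_of_max` of the
  beam's maximum dose. The protocol this emulates used visual inspection;
  a quantitative surrogate needs a threshold. The default is 0.25: in this
  phantom a beam passing straight through the chamber from the side
  retains only $\sim$0.35 of its entry maximum after $\sim$30 cm of water
  (attenuation plus inverse square), while beams whose aperture misses the
  chamber leave penumbra tails an order of magnitude lower, so any
  threshold between those separates the two cases and 0.5 would
  misclassify lateral through-beams as misses.
* **Combined uncertainty** of a plan dose from per-beam Type-A
  uncertainties: $\sqrt{\sum_i \sigma_i^2}/n$, the quadrature combination
  for a sum of $n$ comparable beam doses expressed in percent of the
  total. For equal $\sigma_i$ it reduces to $\sigma/\sqrt{n}$.
* **Percent relative RMS difference** between computed and reference dose
  sets: RMS of the per-pair percent differences.

## The small-field correction factor

A chamber calibrated in a 10×10 cm² field under-reports or over-reports in
small, irregular composite fields because the water-to-cavity dose ratio
shifts away from reference conditions. The output correction factor is the
double ratio

$$
k_{Q_\mathrm{clin}} \;=\;
\frac{D_w^{\,f_\mathrm{clin}}/D_\mathrm{air}^{\,f_\mathrm{clin}}}
     {D_w^{\,f_\mathrm{ref}}/D_\mathrm{air}^{\,f_\mathrm{ref}}},
$$

with $D_w$ the dose to a water sphere of the cavity's volume and
$D_\mathrm{air}$ the dose to the air cavity, each for the clinical and the
reference field. The measured dose is then
$D_w = M \cdot N_{D,w} \cdot k_{Q,Q_0} \cdot k_{Q_\mathrm{clin}}$. The
factor is exactly 1 when clinical equals reference conditions and is
invariant under a common rescaling of all four doses; uncertainties are
propagated in quadrature assuming independence (no correlation structure
is modelled). Plan-level factors use the summed-field dose quadruple —
the definition is per field — and per-beam factors apply the same
operation to per-beam quadruples.

In the synthetic pipeline the four doses cannot come from particle
transport, so the package uses a volume-averaging surrogate: the "cavity"
dose is the mean toy-engine dose over the Farmer-like cylinder
(radius 0.3 cm, length 2.3 cm, 0.65 cm³) and the "water sphere" dose the
mean over the equal-volume sphere (radius ≈ 0.54 cm) at the isocenter.
Under a homogeneous field both averages agree and $k = 1$; under
chamber-scale gradients they differ, reproducing the empirical coupling
between dose homogeneity and the correction factor. This is a geometric
surrogate for a perturbation-theoretic quantity: its magnitudes are not
dosimetric predictions, only its qualitative behaviour is.

## The toy dose engine and the phantom

The engine is a deterministic geometric emulator, not a dose calculation:
for each segment every voxel center is projected along the divergent ray
from the gantry-dependent source (100 cm SAD) to the isocenter plane, and
the segment deposits

$$
\frac{\mathrm{MU}}{100}\cdot \Phi(u, w)\cdot e^{-\mu\, d}\cdot
\left(\frac{\mathrm{SAD}}{r}\right)^2 ,
$$

where $\Phi$ is the aperture indicator of the voxel's leaf pair with
Gaussian-smoothed edges in the leaf-travel direction
(`penumbra_sigma`, default 0.3 cm) and a three-row Gaussian mixture across
leaf rows (the penumbra is approximately isotropic; without cross-row
smoothing, leaf-edge jitter along the chamber axis — which gantry rotation
cannot average away — would dominate every homogeneity comparison),
$d$ is the water-equivalent depth from the phantom surface along the ray,
$\mu$ an effective attenuation coefficient (0.049 cm⁻¹, 6 MV-like), and
$r$ the source-voxel distance. There is no scatter, no leaf transmission,
no spectral hardening. Two closed-form checks pin the engine down: the
central-axis depth dose of an open field equals
$e^{-\mu \Delta d} (\mathrm{SAD}/r)^2$ to 1e-6, and opposed beams on a
symmetric phantom are exact mirror images.

The phantom is the standard QA setup: a 30×30×17 cm³ water box, 0.3 cm
dose voxels, chamber at the isocenter at 8.5 cm depth, axis along the
gantry rotation axis. Two chamber structures coexist, as they do in
practice: the *active air cavity* (radius 0.3 cm, length 2.3 cm,
0.65 cm³), which enters the correction-factor quadruple, and the *chamber
contour* (outer wall, radius 0.36 cm, length 2.4 cm), which is what gets
contoured on a dose grid and what the DVH metrics (HI, COIN, intersection)
are evaluated on. The distinction is forced by the lattice: a 0.3 cm
cavity radius rasterizes to a single voxel layer with *no extent along the
dose gradients* (a 0.3 cm lattice cannot resolve the cavity — the very
pixelization problem that motivates detailed chamber modelling in this QA
literature), whereas the 0.36 cm contour spans three voxel layers and
sees depth gradients. Because 0.3 does not divide 17, the lattice is
quantized to whole voxels and *centered on the chamber* (surface depth
8.55 cm effective): an off-center lattice would make the cylinder and
sphere masks sample dose gradients asymmetrically and inject a spurious,
angle-dependent bias of several tenths of a percent into the $k$ surrogate,
larger than the effect under study.

## The synthetic cohort

`generate_plan()` interpolates between a static rectangular 8×8 cm² field
(`modulation = 0`, MCS exactly 1) and a discretized sliding-window pattern
(`modulation = 1`): a slit narrowing to a quarter of the field sweeps
across it from segment to segment, with per-leaf edge jitter (up to
0.5 cm), a per-segment lateral shift, log-normal segment MU weights — and,
crucially, a per-beam aperture offset (up to ±2.5 cm): each clinical beam
conforms to the target from its own direction, so its fluence envelope is
systematically off-axis. Collapsed delivery stacks these per-beam
gradients along one axis while rotated delivery distributes them around
the circle; this is the geometric origin of the homogeneity contrast the
cohort tests reproduce.

`simulate_cohort()` draws 20 patients with 7–19 beams (uniformly) and
per-patient modulation depths from 0.4–0.8, emulating a mixed-site
clinical cohort spanning a range of plan complexities; every quantity is a
pure function of one integer seed. Beam counts, phantom and chamber
geometry follow the study conditions stated above; the modulation range
was chosen once so that the cohort's homogeneity indices span the
clinically reported range — HIs up to ≈0.1-0.2, with most rotated
deliveries below 0.05 and almost no collapsed ones — and was not
revisited.

Pseudo-measurements emulate an *uncorrected* chamber-derived dose: the
cavity-average dose scaled by the reference-field water-to-cavity ratio,
times $(1+\varepsilon)$ with $\varepsilon \sim N(0, 0.5\%)$ — the order of
the output-stability drift monitored in clinical QA sessions. Multiplying
the pseudo-measurement by $k_{Q_\mathrm{clin}}$ recovers the water-sphere
dose up to noise, so applying the correction improves the percent-RMS
agreement, mirroring the structure of the clinical comparison. Per-beam
Type-A uncertainties follow a particle-statistics-like rule
$u_i = u_0\sqrt{\bar{D}/D_i}$ (capped at 10%, $u_0 = 0.25\%$): beams
missing the chamber contribute little dose and large relative uncertainty.

What the generator does *not* emulate: measurement setup errors,
polarity/leakage effects, TPS dose calculation error, chamber perturbation
physics, scatter. Passing cohort tests therefore show that the analysis
chain reproduces the *geometric* mechanism of the rotated/collapsed
contrast, not that it predicts clinical correction factors.

## Numerical conventions and degenerate inputs

* Grids are corner-origin, half-open voxels; masks live on voxel centers.
* $D_{x\%}$ uses voxel ranks; on a uniform grid every $D_{x\%}$ equals the
  uniform dose.
* `expand_mask(margin = 0)` is the identity; dilation is monotone in the
  margin.
* An all-zero beam dose never "intersects" the chamber.
* `k_qclin` rejects non-positive doses; `mc_efficiency` rejects
  non-positive time or uncertainty.
* The collapsed target angle defaults to 0° (a convention, not a
  measurement prescription) and is configurable.
* Dynamic-delivery RTPLAN control points are discretized into segments by
  averaging adjacent control-point leaf positions, with MU weights from
  cumulative meterset differences; collimator and couch angles are carried
  but ignored by every metric (none uses them).

## Problem sizes

The default phantom lattice is 100×100×57 voxels. Unit and property tests
that do not probe resolution run on a 0.6 cm lattice with a proportionally
enlarged surrogate chamber (the 0.3 cm cavity radius falls below a 0.6 cm
lattice's resolution); the cohort-level analyses use the full-resolution
lattice with 20 patients, the study's cohort size.

## Worked example

```{r example, eval = FALSE}
case <- simulate_patient(list(n_beams = 9), seed = 3)
report <- run_comparison(case)
report

reports <- simulate_cohort(n_patients = 20, seed = 1)
cohort <- cohort_summary(reports)
cohort
plot(cohort)   # HI versus |k - 1| per patient and mode
```

## Known limitations

* The $k$ surrogate is volume averaging, not cavity perturbation theory;
  its scale is smaller than clinically reported factors.
* The engine's lack of scatter makes the conformity index of broad
  synthetic fields uniformly low; COIN is computed faithfully but its
  synthetic distribution is narrower than clinical ones.
* The DICOM reader covers the explicit-VR little-endian RTPLAN/RTDOSE
  subset listed in its documentation; RTSTRUCT contours are out of scope
  (chamber masks come from geometry or raster fixtures).
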