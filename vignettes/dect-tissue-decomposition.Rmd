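---
title: "Dual-energy CT tissue decomposition and proton SPR estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-energy CT tissue decomposition and proton SPR estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectspr)
```

## The problem

Proton therapy dose verification techniques that observe secondary
radiation (prompt gamma rays, PET) need voxelwise maps of elemental
composition — above all carbon and oxygen — and of the proton
stopping-power ratio to water (SPR). A CT scanner does not measure
composition directly: a single-energy scan (SECT) is conventionally
mapped to density and composition through a piecewise-linear Hounsfield
look-up table (HLUT), while a dual-energy scan (DECT) supports a richer
voxelwise decomposition. `dectspr` implements that DECT decomposition
chain, the SECT comparator, the supporting calibration machinery, ROI
statistics, the range-based SPR ground-truth formula, and a synthetic
phantom generator so that every stage can be validated end-to-end
against known ground truth without any scanner data.

## Tissue compositions and the reference basis

A material is a set of elemental weight fractions $w_i$ (closure
$\sum_i w_i = 1$ enforced to $10^{-6}$) plus a mass density $\rho_m$
(g/cm³). Three derived quantities drive everything else:

* relative electron density
  $\hat\rho_e = \rho_m \sum_i w_i Z_i/A_i \,/\, (\rho \sum w Z/A)_\mathrm{water}$,
* the effective atomic number at exponent $x$,
  $Z_\mathrm{eff} = (\sum_i \lambda_i Z_i^x)^{1/x}$ with electron
  fractions $\lambda_i$,
* the mean excitation energy $I$ by Bragg additivity
  ($\ln I = \sum_i \lambda_i \ln I_i$ over ICRU-style elemental values),
  shifted by a constant in $\ln I$ so that water evaluates exactly to
  the adopted $I_w = 78$ eV. The shift is the usual condensed-phase
  correction; applying the same convention to ground truth and pipeline
  keeps the closed-form and map-based SPR routes comparable.

Mixtures are formed two ways, chosen for self-consistency because no
single convention is universal: mixing **by mass** combines weight
fractions linearly and densities by inverse-density volume additivity
$\rho = (\sum_k f_k/\rho_k)^{-1}$; mixing **by volume** combines
densities linearly and mass-weights the fractions. The two coincide
when all components share one density (a property test asserts
agreement to $10^{-12}$). Rehydration of a dried specimen is mass
mixing with pure water.

The package ships a reference table of published-style human tissues
(Woodard–White/ICRU-44 lineage soft tissues, lung, marrow, cortical
bone, plus water and dry air at N/O/Ar = 0.755/0.232/0.013,
$1.205\times10^{-3}$ g/cm³). Spongiosa entries — trabecular bone plus
marrow — are *generated* as volumetric cortical-bone/red-marrow
mixtures and tagged `mixture-derived`, rather than transcribed: the
construction is documented, reproducible, and spans the soft/bone gap
monotonically. `expand_basis()` likewise fills the low-CT-number gap
with lung–air volumetric mixtures at evenly spaced volume fractions and
the high-CT-number range with a bone series (bone/marrow mixtures plus
a configurable multiplicative density ramp on the densest bone, default
1.02–1.10 in 5 steps). Configured at scale, the expansion adds 135 or
more reference tissues; the exact membership is parameterized because
the published augmentation is not enumerated anywhere we can reproduce.

## The stoichiometric CT-number model

Predicted CT numbers use the Schneider-style three-term parametrization

$$\mathrm{HU} = 1000\,(u - 1),\qquad
u = \hat\rho_e\,
\frac{1 + k_1 \tilde Z^{3.62} + k_2 \hat Z^{1.86}}
     {1 + k_1 \tilde Z_w^{3.62} + k_2 \hat Z_w^{1.86}},$$

with $\tilde Z$, $\hat Z$ the effective atomic numbers at the
photoelectric (3.62) and coherent-scatter (1.86) exponents. Water maps
to 0 HU for any $(k_1, k_2)$. The two coefficients per beam quality are
fitted to calibration-insert measurements by least squares on the HU
residuals: multiplying through by the water denominator makes the
problem exactly linear in $(k_1,k_2)$, and that solution seeds a
bounded quasi-Newton polish (relative tolerance $10^{-14}$, $k \ge 0$).
Noise-free forward–inverse recovery is exact to machine precision;
approximate standard errors from the residual Jacobian support
Monte-Carlo bounds under noise. A calibration whose inserts span a
single effective atomic number is rejected as rank-deficient.

## The dual-energy conversion chain

Each voxel of a co-registered (HU$_{80}$, HU$_{140}$) pair is processed
as:

1. **Composition assignment.** The voxel takes the composition of the
   nearest reference tissue in the (HU_low, HU_high) plane — unscaled
   Euclidean distance, no interpolation. Both axes are in HU, so raw
   distance keeps them commensurate. Exact ties resolve to the lowest
   basis index; the basis order is therefore part of the contract, and
   assignment is permutation-invariant whenever no exact tie occurs.
2. **Electron density.**
   $\hat\rho_e = a\,[(1+\alpha)\,\mathrm{HU_h} - \alpha\,\mathrm{HU_l}]/1000 + b$,
   the weighted dual-energy combination. With the default water anchor
   the offset is constrained to $b = 1$ so HU = (0,0) maps to exactly 1.
3. **Effective atomic number.**
   $(Z_\mathrm{eff}/Z_{\mathrm{eff},w})^n = c\,u_L/\hat\rho_e + d$ with
   $u_L = \mathrm{HU_l}/1000 + 1$ and $d = 1 - c$ under the water
   anchor. Dividing the low-energy attenuation by the electron density
   isolates its composition dependence before the linear fit. We
   evaluated the alternative of regressing
   $Z_\mathrm{eff}^n\hat\rho_e$ directly on $\mathrm{HU_l}$ and found it
   structurally unable to serve soft tissues and bone with one line on
   stoichiometric forward data (soft-tissue $Z_\mathrm{eff}$ errors of
   4–9% for every exponent and weighting we scanned); the
   density-reduced regressor brings the same fit within 0.3% for soft
   tissue and 1.6% overall. The exponent default $n = 3.3$ was
   confirmed empirically as the minimizer on this forward model.
   Voxels with $\hat\rho_e$ below the air floor (default 0.05) or a
   negative radicand are flagged, not errors.
4. **Ionization potential.** $\ln I$ is mapped from $Z_\mathrm{eff}$ by
   a piecewise-linear map fitted over the reference tissues. The
   default interpolates through every reference $(Z_\mathrm{eff}, \ln I)$
   point; a coarser two-segment soft/bone fit split at
   $Z_\mathrm{eff} = 8.5$ is available (`i_map_method = "two_segment"`)
   but leaves SPR errors up to 1.5% on spongiosa, which is why
   interpolation is the default. Outside the fitted range the
   bordering segment's line is continued. Air-like reference entries
   are excluded from the map; air voxels bypass it anyway.
5. **SPR.** The Bethe ratio
   $\mathrm{SPR} = \hat\rho_e \,
   \frac{\ln[2 m_e c^2 \beta^2 / I(1-\beta^2)] - \beta^2}
        {\ln[2 m_e c^2 \beta^2 / I_w(1-\beta^2)] - \beta^2}$
   with $m_ec^2 = 0.510999$ MeV. The default $\beta = 0.4282$ follows
   from relativistic kinematics at the configured 100 MeV reference
   energy; the literal constant 0.482 sometimes quoted for that energy
   is kinematically inconsistent with it, so both are supported and the
   choice is explicit (`beta = 0.482` reproduces the literal
   convention). $I = I_w$ collapses the ratio to $\hat\rho_e$ exactly.
6. **Mass density.**
   $\rho_m = \hat\rho_e\,(\sum w Z/A)_\mathrm{water} / (\sum w Z/A)_\mathrm{assigned}$,
   so a water voxel at $\hat\rho_e = 1$ gives exactly 1.000 g/cm³.

Because every stage is water-anchored, a noise-free water phantom
passes the full chain with SPR $\equiv 1$ to better than $10^{-6}$ —
one of the package's acceptance properties. For arbitrary basis tissues
at their noise-free coordinates, pipeline SPR agrees with the direct
closed-form Bethe evaluation within 0.5%; the residual is dominated by
the electron-density fit, whose two linear coefficients cannot be exact
for every composition simultaneously (insert recovery is within 0.5%,
typically 0.05% for soft tissue). Mass density correspondingly carries
an error up to about $5\times10^{-3}$ g/cm³ at the compositional
extremes (adipose, yellow marrow), which is the bound the consistency
tests assert.

## The SECT comparator

`build_hlut()` pairs each basis tissue's density and composition with a
node CT number — predicted by the stoichiometric model at the
high-energy beam (calibrated flavor) or supplied verbatim from a
published node table (HLUT flavor). Duplicate-HU nodes are averaged;
conversion interpolates density and each weight fraction linearly in HU
between consecutive nodes, renormalizes the fractions to unit sum
(independent linear interpolation leaves closure violations of order
$10^{-3}$), and clamps CT numbers outside the node range to the end
nodes. The clamp rule and consecutive-node interval structure are this
package's documented choices; nothing in the source method prescribes
out-of-range behavior.

## ROI statistics and the range formula

ROIs are cylinders along a grid axis (the proton-beam path) or
half-open boxes, rasterized by voxel-center inclusion with world
coordinates in mm anchored at the corner of voxel (1,1,1) — bit-stable
conventions chosen once. ROI composition is the mass-weighted mean
$w^X = \sum_i w_i^X \rho_i^m / \sum_i \rho_i^m$, which is exactly
additive over disjoint masks; CT statistics use the population standard
deviation (descriptive spread). The shift-sensitivity analysis
re-evaluates an ROI under per-axis offsets (default ±2, ±5, ±10 mm,
configurable placeholders) and reports deviations from baseline,
flagging off-grid shifts rather than failing.

The ground-truth SPR of a boxed sample follows from three distal-80%
ranges (sample, water, air fillings):
$\mathrm{SPR} = \frac{R^{80}_s - R^{80}_a}{R^{80}_w - R^{80}_a}(1 -
\mathrm{SPR}_a) + \mathrm{SPR}_a$. $R^{80}$ is extracted by linear
interpolation on the distal side of the Bragg peak, taking the deepest
crossing when noise produces several; whether the source measurements
interpolated or fitted the falloff is unstated, so linear interpolation
is this package's documented choice. The dry-air SPR is a required
input rather than a hardcoded database value.

## The synthetic phantom world

The generator emulates the validation experiments: PMMA boxes (default
220×120×120 mm outer, 10 mm walls, 2.5 mm divider for double boxes)
filled with one or two materials, forward-projected per voxel with the
stoichiometric model at two beam qualities, plus iid Gaussian noise per
energy. Default beam constants ($k_1/k_2 = 6\times10^{-5}/1.5\times10^{-3}$
at 80 kV, $2\times10^{-5}/8\times10^{-4}$ at 140 kV) place cortical
bone near 2080/1280 HU and air near −999 HU — magnitudes a clinical
head protocol produces. Default noise $\sigma = (5, 3)$ HU matches the
spread observed for a homogeneous soft-tissue sample; inhomogeneity is
modeled as seeded air bubbles, whose effect on ROI variance follows the
two-component mixture formula
$\sigma^2_\mathrm{ROI} = \sigma^2 + p(1-p)\,\Delta\mathrm{HU}^2$
(asserted within 10% in the tests). All randomness flows from one
integer seed; identical configurations produce bit-identical volumes.

What the generator deliberately omits: reconstruction physics (beam
hardening, scatter, iterative-reconstruction noise correlation),
partial-volume averaging at interfaces, and registration error between
the two energies. Passing the recovery tests therefore demonstrates
the *self-consistency* of the conversion chain — calibration, forward
model and inversion agreeing with each other — not robustness to the
artifacts of real scans, which is why measured-data RMSEs are expected
to be larger than the synthetic ones.

`run_recovery_experiment()` packages the full study design — synthetic
calibration, model fits, per-tissue phantoms, conversion, ROI
comparison — into one deterministic report. The default problem sizes
(interior grids of roughly $40^3$ voxels at 2.5 mm spacing, twelve
calibration inserts) were chosen as the smallest configuration whose
sampling error is negligible against the 5 wt% composition and 0.5%
SPR bounds being tested.

## Numerical choices and edge cases

* Composition closure tolerance $10^{-6}$; table readers renormalize
  rows within 0.02 of closure (published tables are rounded) and
  reject worse.
* Tie-breaks: nearest-reference assignment keeps the lowest basis
  index; duplicate HLUT nodes are averaged before interpolation.
* Degenerate inputs: water-only calibrations are rank-deficient errors;
  truncated depth-dose curves (no distal crossing) are errors; empty
  ROI masks are errors, while empty *shifted* ROIs are flagged rows.
* Air voxels ($\hat\rho_e <$ floor) receive the air composition, air
  density and $\mathrm{SPR} = \hat\rho_e$ — the Bethe logarithm is not
  evaluated at pathological $I$.
* Volume I/O is NIfTI (via RNifti), carrying grid spacing through all
  output maps.

## Known limitations

The reference table is a compact transcription, not an exhaustive
library; age-, disease- or site-specific compositions are out of scope.
The Z_eff→I map is only as good as the reference set it is fitted on,
and the bone series is a parameterized construction rather than a
reproduction of any published augmentation. Noise is spatially white;
real iterative reconstructions correlate it. SECT SPR is limited to
density and composition lookup (the Bethe step can be applied to
SECT-derived inputs explicitly if desired).
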