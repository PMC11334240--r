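# dectspr

Dual-energy CT (DECT) tissue decomposition and proton stopping-power
estimation for radiotherapy range-verification workflows.

Proton dose-verification techniques that read secondary radiation
(prompt gamma rays, PET) need voxelwise maps of elemental composition —
chiefly carbon and oxygen — and of the proton stopping-power ratio to
water (SPR). `dectspr` provides the full analysis chain for deriving
those maps from a pair of co-registered CT volumes acquired at two tube
potentials, together with the single-energy (HLUT) comparator, the
calibration machinery, ROI statistics, the range-based SPR ground-truth
formula, and a synthetic phantom generator that makes the whole
pipeline testable end-to-end without scanner data.

## The model

CT numbers for arbitrary materials are predicted with the
Schneider-style stoichiometric parametrization

    HU = 1000 (u − 1),   u = ρ̂_e (1 + k₁ Z̃^3.62 + k₂ Ẑ^1.86) / (water term)

whose two coefficients per beam quality are fitted to
calibration-insert scans. The voxelwise DECT chain is then:

1. nearest-reference **composition assignment** in the
   (HU_low, HU_high) plane (no interpolation; lowest-index tie-break);
2. **electron density** ρ̂_e = a[(1+α)HU_h − αHU_l]/1000 + b
   (water-anchored, b = 1);
3. **effective atomic number**
   (Z_eff/Z_eff,w)ⁿ = c·u_L/ρ̂_e + d with u_L = HU_l/1000 + 1,
   n = 3.3, d = 1 − c;
4. **ionization potential** via a piecewise-linear ln I vs Z_eff map
   fitted on the reference tissues (water anchored at I_w = 78 eV);
5. **SPR** from the Bethe ratio
   SPR = ρ̂_e [ln(2m_ec²β²/I(1−β²)) − β²] / [ln(2m_ec²β²/I_w(1−β²)) − β²];
6. **mass density** ρ_m = ρ̂_e (ΣwZ/A)_water / (ΣwZ/A)_assigned.

A Schneider-style SECT conversion (`build_hlut()` / `sect_convert()`)
interpolates density and composition linearly in HU between reference
nodes, and `spr_from_ranges()` implements the multi-layer ionization
chamber ground truth
SPR = (R⁸⁰_sample − R⁸⁰_air)/(R⁸⁰_water − R⁸⁰_air)·(1 − SPR_air) + SPR_air.

See the methods vignette
(`vignettes/dect-tissue-decomposition.Rmd`) for assumptions, parameter
defaults and numerical conventions.

## Worked example

Simulate the full study design — synthetic calibration scans, model
fitting, boxed tissue phantoms with realistic noise, conversion, and
ROI comparison against ground truth:

```r
library(dectspr)

basis <- default_tissue_basis(with_spongiosa = 4)
report <- run_recovery_experiment(list(
  basis = basis,
  k_low  = stoich_params(6e-5, 1.5e-3, "80kV"),
  k_high = stoich_params(2e-5, 8e-4, "140kV"),
  fill_names = c("muscle", "adipose", "brain"),
  outer_mm = c(100, 60, 60), wall_mm = 10, spacing = 2.5,
  roi_diameter_mm = 30, seed = 42))
report[, c("name", "hu_low_mean", "hu_high_mean", "spr_mean", "spr_true",
           "wC", "wC_true", "wO", "wO_true")]
#>      name hu_low_mean hu_high_mean spr_mean spr_true    wC wC_true    wO wO_true
#> 1  muscle       45.33        41.81   1.0394   1.0402 14.32    14.3 71.06    71.0
#> 2 adipose      -92.36       -67.55   0.9601   0.9647 59.80    59.8 27.80    27.8
#> 3   brain       40.23        36.71   1.0343   1.0361 14.46    14.5 71.16    71.2
```

Each row is one simulated boxed sample scanned at 80/140 kV with
per-energy Gaussian noise: `hu_*_mean` are the CT numbers in the
beam-path ROI, `spr_mean` the pipeline SPR against the closed-form
Bethe truth `spr_true`, and `wC`/`wO` the mass-weighted ROI carbon and
oxygen content (wt%) against the fill tissue's true fractions — here
recovered to within 0.1 wt% despite the noise, with SPR within 0.5%.

A command-line front end over the same functions is installed at
`inst/cli/dect-tools.R` (subcommands `calibrate`, `convert-dect`,
`convert-sect`, `roi-stats`, `mlic-spr`, `simulate`).

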