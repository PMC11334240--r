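#' Synthetic phantom specification
#'
#' Describes a boxed sample as scanned in the validation experiments: a
#' PMMA box (10 mm walls; double boxes add a 2.5 mm divider) filled with
#' one or two materials, imaged at two energies with independent
#' per-energy Gaussian noise, optionally with air bubbles emulating an
#' inhomogeneous fill.
#'
#' @param fills List of one or two [tissue()] fill materials (two fills
#'   split the box into compartments along axis 2).
#' @param outer_mm Outer box dimensions in mm (default
#'   `c(220, 120, 120)`, the single-box geometry; use
#'   `c(220, 220, 120)` for the double box).
#' @param wall_mm Wall thickness in mm (default 10).
#' @param divider_mm Divider thickness for double boxes (default 2.5).
#' @param sigma Per-energy noise standard deviations in HU,
#'   `c(low, high)`; the default `c(5, 3)` matches the CT-number spread
#'   observed for a homogeneous soft-tissue sample (muscle) at 80 and
#'   140 kV.
#' @param bubbles List with `count`, `radius_range` (mm); bubbles are
#'   air spheres carved into the fill at seeded random interior
#'   positions.
#' @param seed Integer seed; all randomness of the phantom flows from
#'   it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(fills, outer_mm = c(220, 120, 120), wall_mm = 10,
                         divider_mm = 2.5, sigma = c(5, 3),
                         bubbles = list(count = 0, radius_range = c(2, 6)),
                         seed = 1L) {
  if (is_tissue(fills)) fills <- list(fills)
  stopifnot(is.list(fills), length(fills) %in% 1:2,
            all(vapply(fills, is_tissue, TRUE)),
            length(outer_mm) == 3L, all(outer_mm > 0),
            wall_mm > 0, wall_mm < min(outer_mm) / 2,
            length(sigma) == 2L, all(sigma >= 0),
            bubbles$count >= 0, all(bubbles$radius_range > 0))
  structure(list(fills = fills, outer_mm = as.numeric(outer_mm),
                 wall_mm = wall_mm, divider_mm = divider_mm,
                 sigma = sigma, bubbles = bubbles,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic dual-energy phantom scan
#'
#' Builds the voxelized box geometry (PMMA walls, fill compartments,
#' optional air bubbles), evaluates the noiseless forward model
#' [predict_hu()] per voxel material at both beams, and adds independent
#' Gaussian noise per energy. Ground truth (material identity, nominal
#' density, relative electron density and closed-form Bethe SPR) is
#' emitted before noise.
#'
#' @param spec A [phantom_spec()].
#' @param params_low,params_high [stoich_params()] per beam.
#' @param spacing Voxel spacing in mm (must not exceed the wall
#'   thickness).
#' @param beta,I_w Bethe constants for the ground-truth SPR.
#' @param elements Element table.
#' @return List with `dect` (a [dect_volume()]) and `truth`: a list with
#'   `material` (index array), `materials` (list of [tissue()]),
#'   `density`, `rho_e`, `spr` (per-voxel arrays) and `interior`
#'   (logical mask of unperturbed fill voxels).
#' @export
make_box_phantom <- function(spec, params_low, params_high,
                             spacing = c(2.5, 2.5, 2.5),
                             beta = beta_from_energy(100), I_w = 78,
                             elements = element_table()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing > spec$wall_mm))
    stop("voxel spacing exceeds the wall thickness", call. = FALSE)
  set.seed(spec$seed)
  dims <- pmax(round(spec$outer_mm / spacing), 3L)
  ctr <- lapply(1:3, function(ax) (seq_len(dims[ax]) - 0.5) * spacing[ax])

  materials <- c(spec$fills, list(pmma_composition(elements),
                                  air_composition(elements)))
  i_pmma <- length(spec$fills) + 1L
  i_air <- length(spec$fills) + 2L

  in_wall_ax <- lapply(1:3, function(ax)
    ctr[[ax]] < spec$wall_mm | ctr[[ax]] > spec$outer_mm[ax] - spec$wall_mm)
  wall <- outer(outer(in_wall_ax[[1]], in_wall_ax[[2]], `|`),
                in_wall_ax[[3]], `|`)
  mat <- array(1L, dims)
  if (length(spec$fills) == 2L) {
    mid <- spec$outer_mm[2] / 2
    div <- abs(ctr[[2]] - mid) <= spec$divider_mm / 2
    second <- ctr[[2]] > mid
    mat[, div, ] <- i_pmma
    mat[, second & !div, ] <- 2L
  }
  mat[wall] <- i_pmma
  fill_mask <- mat <= length(spec$fills)

  if (spec$bubbles$count > 0) {
    rr <- spec$bubbles$radius_range
    lo <- spec$wall_mm + max(rr)
    hi <- spec$outer_mm - spec$wall_mm - max(rr)
    for (b in seq_len(spec$bubbles$count)) {
      cen <- stats::runif(3, lo, hi)
      rad <- stats::runif(1, rr[1], rr[2])
      d2 <- outer(outer((ctr[[1]] - cen[1])^2, (ctr[[2]] - cen[2])^2, `+`),
                  (ctr[[3]] - cen[3])^2, `+`)
      mat[d2 <= rad^2 & fill_mask] <- i_air
    }
  }

  hu_l <- vapply(materials, predict_hu, 0, params = params_low,
                 elements = elements)
  hu_h <- vapply(materials, predict_hu, 0, params = params_high,
                 elements = elements)
  rho_e <- vapply(materials, relative_electron_density, 0,
                  elements = elements)
  dens <- vapply(materials, `[[`, 0, "density")
  ion <- vapply(materials, tissue_ionization_potential, 0,
                elements = elements, I_water = I_w)
  spr <- spr_bethe(rho_e, ion, beta = beta, I_w = I_w)

  nv <- prod(dims)
  hu_low <- array(hu_l[mat], dims) +
    array(stats::rnorm(nv, 0, spec$sigma[1]), dims)
  hu_high <- array(hu_h[mat], dims) +
    array(stats::rnorm(nv, 0, spec$sigma[2]), dims)

  interior <- fill_mask & mat <= length(spec$fills)
  list(dect = dect_volume(hu_low, hu_high, spacing),
       truth = list(material = mat, materials = materials,
                    density = array(dens[mat], dims),
                    rho_e = array(rho_e[mat], dims),
                    spr = array(spr[mat], dims),
                    interior = interior))
}

#' Generate synthetic calibration measurements
#'
#' Forward-predicts the mean CT number of each insert at both beams and
#' perturbs it by `sigma / sqrt(n_eff)` -- the standard error of an ROI
#' mean over `n_eff` effectively independent voxels.
#'
#' @param inserts List of [tissue()] inserts.
#' @param params_low,params_high [stoich_params()] per beam.
#' @param sigma Per-energy voxel noise in HU, `c(low, high)`.
#' @param n_eff Effective ROI voxel count (default 100).
#' @param seed Integer seed.
#' @param elements Element table.
#' @return List with elements `low` and `high`, each a list of
#'   [calibration_measurement()].
#' @export
make_calibration_set <- function(inserts, params_low, params_high,
                                 sigma = c(0, 0), n_eff = 100, seed = 1L,
                                 elements = element_table()) {
  stopifnot(length(inserts) >= 1L, all(vapply(inserts, is_tissue, TRUE)))
  set.seed(as.integer(seed))
  one_beam <- function(params, s) {
    mu <- vapply(inserts, predict_hu, 0, params = params,
                 elements = elements)
    meas <- mu + stats::rnorm(length(mu), 0, s / sqrt(n_eff))
    lapply(seq_along(inserts), function(i)
      calibration_measurement(inserts[[i]], meas[i], hu_std = s))
  }
  list(low = one_beam(params_low, sigma[1]),
       high = one_beam(params_high, sigma[2]))
}

#' Generate an analytic Bragg-like depth-dose curve
#'
#' A proximal plateau rising into a Gaussian peak whose distal falloff
#' is constructed, by inversion of the Gaussian, so that the exact
#' distal-80% depth equals `r80_true`. Optional multiplicative noise.
#'
#' @param r80_true Target distal-80% depth in mm.
#' @param peak_width Gaussian sigma of the peak in mm.
#' @param step Sampling step in mm.
#' @param noise Relative (multiplicative) noise standard deviation.
#' @param seed Integer seed (used when `noise > 0`).
#' @param entrance Proximal plateau dose relative to the peak.
#' @return A [depth_dose()] with attribute `r80_true`.
#' @export
make_bragg_curve <- function(r80_true, peak_width = 5, step = 0.5,
                             noise = 0, seed = 1L, entrance = 0.3) {
  stopifnot(r80_true > 0, peak_width > 0, step > 0,
            entrance >= 0, entrance < 0.8)
  peak <- r80_true - peak_width * sqrt(2 * log(1 / 0.8))
  if (peak <= 0)
    stop("inconsistent geometry: r80_true must exceed the peak offset ",
         "implied by peak_width", call. = FALSE)
  depths <- seq(0, r80_true + 4 * peak_width, by = step)
  g <- exp(-(depths - peak)^2 / (2 * peak_width^2))
  dose <- ifelse(depths <= peak, entrance + (1 - entrance) * g, g)
  if (noise > 0) {
    set.seed(as.integer(seed))
    dose <- pmax(dose * (1 + stats::rnorm(length(dose), 0, noise)), 0)
  }
  out <- depth_dose(depths, dose)
  attr(out, "r80_true") <- r80_true
  out
}

#' Run a full forward-inverse recovery experiment
#'
#' Simulates the complete study design: synthetic calibration scans,
#' stoichiometric and dual-energy model fitting, phantom generation per
#' fill tissue, voxelwise conversion, and ROI comparison against the
#' known ground truth. Deterministic for a given seed.
#'
#' @param config List with entries `basis` (a [tissue_basis()]),
#'   `k_low`, `k_high` (true [stoich_params()]), `fill_names` (basis
#'   tissues to phantom), and optionally `insert_names` (calibration
#'   subset; default all basis tissues), `sigma` (voxel noise HU,
#'   default `c(5, 3)`), `cal_sigma` (calibration noise, default
#'   `sigma`), `n_eff` (default 100), `outer_mm`
#'   (default `c(100, 60, 60)`), `wall_mm` (default 5), `spacing`
#'   (default 2.5), `roi_diameter_mm` (default 40), `seed` (default 1),
#'   `beta`, `I_w`.
#' @param elements Element table.
#' @return Data frame, one row per fill tissue, with ROI CT statistics,
#'   predicted vs true SPR / density / carbon / oxygen content (wt%),
#'   relative RMSEs and assignment accuracy. The fitted models are
#'   attached as attributes `params` and `spr_model`.
#' @export
run_recovery_experiment <- function(config, elements = element_table()) {
  basis <- config$basis
  stopifnot(inherits(basis, "tissue_basis"))
  seed <- as.integer(config$seed %||% 1L)
  sigma <- config$sigma %||% c(5, 3)
  cal_sigma <- config$cal_sigma %||% sigma
  n_eff <- config$n_eff %||% 100
  outer_mm <- config$outer_mm %||% c(100, 60, 60)
  wall_mm <- config$wall_mm %||% 5
  spacing <- config$spacing %||% 2.5
  roi_d <- config$roi_diameter_mm %||% 40
  beta <- config$beta %||% beta_from_energy(100)
  I_w <- config$I_w %||% 78

  nm <- basis_names(basis)
  insert_names <- config$insert_names %||% nm
  inserts <- basis$tissues[match(insert_names, nm)]

  cal <- make_calibration_set(inserts, config$k_low, config$k_high,
                              sigma = cal_sigma, n_eff = n_eff,
                              seed = seed, elements = elements)
  fit_l <- fit_stoich_params(cal$low, elements, beam_label = "low")
  fit_h <- fit_stoich_params(cal$high, elements, beam_label = "high")
  table <- predict_basis_table(basis, fit_l, fit_h, elements)
  hu_l <- vapply(cal$low, `[[`, 0, "mean_hu")
  hu_h <- vapply(cal$high, `[[`, 0, "mean_hu")
  model <- fit_spr_model(inserts, hu_l, hu_h, basis = basis,
                         beta = beta, I_w = I_w, elements = elements)

  rows <- lapply(seq_along(config$fill_names), function(i) {
    fname <- config$fill_names[i]
    fill <- basis$tissues[[match(fname, nm)]]
    spec <- phantom_spec(list(fill), outer_mm = outer_mm,
                         wall_mm = wall_mm, sigma = sigma,
                         seed = seed + i)
    ph <- make_box_phantom(spec, fit_l, fit_h, spacing = spacing,
                           beta = beta, I_w = I_w, elements = elements)
    maps <- convert_dect(ph$dect, table, model, elements)
    inner_len <- outer_mm[1] - 2 * wall_mm
    roi <- roi_cylinder(1, outer_mm / 2, roi_d, 0.8 * inner_len)
    mask <- roi_mask(dim(ph$dect$hu_low), ph$dect$spacing, roi) &
      ph$truth$interior
    stats_hu <- roi_hu_stats(ph$dect, mask)
    wc <- mass_weighted_composition(maps$weights[c("C", "O")],
                                    maps$density, mask)
    truth_w <- vapply(c("C", "O"), function(s) {
      v <- fill$fractions[s]; if (is.na(v)) 0 else unname(v)
    }, 0)
    true_name <- fname
    acc <- mean(table$name[maps$assignment[mask]] == true_name)
    data.frame(
      name = fname,
      hu_low_mean = stats_hu$mean_hu[1], hu_low_sd = stats_hu$sd_hu[1],
      hu_high_mean = stats_hu$mean_hu[2], hu_high_sd = stats_hu$sd_hu[2],
      spr_mean = mean(maps$spr[mask]),
      spr_true = ph$truth$spr[mask][1],
      density_mean = mean(maps$density[mask]),
      density_true = fill$density,
      wC = 100 * wc[["C"]], wC_true = 100 * truth_w[["C"]],
      wO = 100 * wc[["O"]], wO_true = 100 * truth_w[["O"]],
      spr_rmse_rel = rmse(maps$spr[mask], ph$truth$spr[mask],
                          relative = TRUE),
      density_rmse_rel = rmse(maps$density[mask], ph$truth$density[mask],
                              relative = TRUE),
      assign_accuracy = acc,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(low = fit_l, high = fit_h)
  attr(out, "spr_model") <- model
  out
}
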