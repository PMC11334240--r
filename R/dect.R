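#' Dual-energy CT volume
#'
#' Two co-registered scalar volumes in Hounsfield units on a common grid.
#'
#' @param hu_low,hu_high 3-D arrays of CT numbers (HU) with identical
#'   dimensions.
#' @param spacing Voxel spacing in mm (length 3, positive).
#' @return An object of class `dect_volume`.
#' @export
dect_volume <- function(hu_low, hu_high, spacing = c(1, 1, 1)) {
  stopifnot(is.array(hu_low), is.array(hu_high),
            identical(dim(hu_low), dim(hu_high)),
            length(dim(hu_low)) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 spacing = as.numeric(spacing)),
            class = "dect_volume")
}

#' @export
print.dect_volume <- function(x, ...) {
  cat("<dect_volume> ", paste(dim(x$hu_low), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Assign the nearest reference composition to every voxel
#'
#' Each voxel is assigned the basis tissue whose predicted
#' (HU_low, HU_high) coordinate is closest in unscaled Euclidean distance
#' in the dual-energy plane -- no interpolation between reference points.
#' Exact ties go to the lowest basis index (the basis order is part of
#' the contract).
#'
#' @param dect A [dect_volume()].
#' @param table A [predict_basis_table()] result.
#' @return Integer array of basis indices (same shape as the volume),
#'   with the table carried in attribute `basis_table`.
#' @export
assign_composition <- function(dect, table) {
  stopifnot(inherits(dect, "dect_volume"), inherits(table, "basis_table"),
            nrow(table) >= 1L)
  l <- as.vector(dect$hu_low)
  h <- as.vector(dect$hu_high)
  best <- rep.int(1L, length(l))
  bestd <- (l - table$hu_low[1])^2 + (h - table$hu_high[1])^2
  for (k in seq_len(nrow(table))[-1]) {
    d <- (l - table$hu_low[k])^2 + (h - table$hu_high[k])^2
    upd <- d < bestd            # strict: ties keep the lower index
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  idx <- array(best, dim = dim(dect$hu_low))
  attr(idx, "basis_table") <- table
  idx
}

#' Voxelwise relative electron density
#'
#' `rho_e = a * ((1+alpha)*HU_high - alpha*HU_low)/1000 + b`.
#'
#' @param dect A [dect_volume()].
#' @param model An [spr_model()].
#' @return Array of `rho_e` (dimensionless).
#' @export
electron_density_map <- function(dect, model) {
  stopifnot(inherits(dect, "dect_volume"), inherits(model, "spr_model"))
  model$a * ((1 + model$alpha) * dect$hu_high -
               model$alpha * dect$hu_low) / 1000 + model$b
}

#' Voxelwise effective atomic number
#'
#' `Z_eff = Z_eff,w * (c * u_L / rho_e + d)^(1/n)` with
#' `u_L = HU_low/1000 + 1` the reduced low-energy attenuation. Dividing
#' `u_L` by the electron density isolates the composition dependence of
#' the low-energy scan, which is what the effective atomic number
#' parametrizes; with the water anchor `c + d = 1`, a water voxel maps
#' exactly to `Z_eff,w`. Voxels with `rho_e` below the model's floor
#' (air) or a negative radicand (artifacts) are returned as `NA` --
#' flagged, not an error.
#'
#' @param rho_e Electron-density array from [electron_density_map()].
#' @param hu_low Low-energy HU array.
#' @param model An [spr_model()].
#' @return Array of `Z_eff` with `NA` at flagged voxels.
#' @export
zeff_map <- function(rho_e, hu_low, model) {
  stopifnot(inherits(model, "spr_model"))
  rad <- model$c * (hu_low / 1000 + 1) / rho_e + model$d
  flag <- rho_e < model$rho_e_floor | rad < 0
  z <- model$zeff_w * (pmax(rad, 0))^(1 / model$n)
  z[flag] <- NA_real_
  z
}

#' Voxelwise ionization potential
#'
#' Evaluates the model's piecewise-linear `ln I` vs `Z_eff` map;
#' outside the fitted range the bordering segment's line is continued.
#' `NA` (flagged) voxels pass through.
#'
#' @param zeff Array (or vector) of effective atomic numbers.
#' @param model An [spr_model()] with a fitted `i_map`.
#' @return Mean excitation energies in eV, same shape as `zeff`.
#' @export
ionization_potential <- function(zeff, model) {
  stopifnot(inherits(model, "spr_model"))
  m <- model$i_map
  if (is.null(m)) stop("spr_model has no fitted i_map", call. = FALSE)
  if (identical(m$method, "two_segment")) {
    v_split <- m$ln_iw + m$m_soft * (m$split - m$zeff_w)
    ln_i <- ifelse(zeff <= m$split,
                   m$ln_iw + m$m_soft * (zeff - m$zeff_w),
                   v_split + m$m_bone * (zeff - m$split))
  } else {
    ln_i <- stats::approx(m$zeff, m$ln_i, xout = pmin(pmax(zeff,
                            min(m$zeff)), max(m$zeff)))$y
    # continue end segments linearly beyond the outermost knots
    k <- length(m$zeff)
    lo <- !is.na(zeff) & zeff < m$zeff[1]
    hi <- !is.na(zeff) & zeff > m$zeff[k]
    s1 <- (m$ln_i[2] - m$ln_i[1]) / (m$zeff[2] - m$zeff[1])
    s2 <- (m$ln_i[k] - m$ln_i[k - 1]) / (m$zeff[k] - m$zeff[k - 1])
    ln_i[lo] <- m$ln_i[1] + s1 * (zeff[lo] - m$zeff[1])
    ln_i[hi] <- m$ln_i[k] + s2 * (zeff[hi] - m$zeff[k])
  }
  out <- exp(ln_i)
  if (is.array(zeff)) out <- array(out, dim = dim(zeff))
  out
}

#' Voxelwise stopping-power ratio
#'
#' Applies [spr_bethe()] per voxel. Flagged voxels (`NA` ionization
#' potential, e.g. air) and voxels whose `I` would drive the Bethe
#' logarithm non-positive fall back to `SPR = rho_e` (the `I = I_w`
#' limit), which is negligible at air densities.
#'
#' @param rho_e Electron-density array.
#' @param I Ionization-potential array (eV) from
#'   [ionization_potential()].
#' @param model An [spr_model()].
#' @return SPR array.
#' @export
spr_map <- function(rho_e, I, model) {
  stopifnot(inherits(model, "spr_model"))
  arg_floor <- 2 * ME_C2_EV * model$beta^2 / (1 - model$beta^2)
  bad <- !is.finite(I) | I <= 0 | I >= arg_floor * exp(-model$beta^2)
  I2 <- ifelse(bad, model$I_w, I)
  spr_bethe(rho_e, I2, beta = model$beta, I_w = model$I_w)
}

#' Voxelwise mass density
#'
#' Converts relative electron density to mass density using the assigned
#' composition: `rho_m = rho_e * (Z/A)_water / (Z/A)_assigned` in g/cm3,
#' where `(Z/A)` denotes `sum_i w_i Z_i / A_i`. A water voxel at
#' `rho_e = 1` yields exactly 1.000 g/cm3.
#'
#' @param rho_e Electron-density array.
#' @param assignment Index array from [assign_composition()].
#' @param table The [predict_basis_table()] used for the assignment.
#' @param elements Element table.
#' @return Mass-density array (g/cm3).
#' @export
mass_density_map <- function(rho_e, assignment, table,
                             elements = element_table()) {
  stopifnot(inherits(table, "basis_table"))
  if (anyNA(assignment)) stop("unassigned voxel(s)", call. = FALSE)
  basis <- attr(table, "basis")
  za <- vapply(basis$tissues, function(t) za_sum(t$fractions, elements), 0)
  za_w <- za_sum(water_composition(1, elements)$fractions, elements)
  arr <- rho_e * za_w / za[assignment]
  array(arr, dim = dim(rho_e))
}

#' Per-element weight-fraction maps from an assignment
#'
#' @param assignment Index array from [assign_composition()].
#' @param table The corresponding [predict_basis_table()].
#' @param symbols Element symbols to extract.
#' @return Named list of arrays, one per element.
#' @export
weight_fraction_maps <- function(assignment, table,
                                 symbols = c("H", "C", "N", "O", "P", "Ca")) {
  stopifnot(inherits(table, "basis_table"))
  basis <- attr(table, "basis")
  out <- lapply(symbols, function(s) {
    w <- vapply(basis$tissues, function(t) {
      v <- t$fractions[s]
      if (is.na(v)) 0 else unname(v)
    }, 0)
    array(w[assignment], dim = dim(assignment))
  })
  stats::setNames(out, symbols)
}

#' Run the full dual-energy conversion chain
#'
#' Nearest-reference composition assignment, electron density, effective
#' atomic number, ionization potential, SPR and mass density for one
#' dual-energy volume. Voxels flagged as air (`rho_e` below the model
#' floor) are reassigned to the basis's air entry when one exists and
#' receive `SPR = rho_e`.
#'
#' @param dect A [dect_volume()].
#' @param table A [predict_basis_table()].
#' @param model An [spr_model()].
#' @param elements Element table.
#' @param symbols Elements for the weight-fraction maps.
#' @return List with `assignment`, `rho_e`, `zeff`, `I`, `spr`,
#'   `density`, `weights` (list of per-element arrays) and `flagged`
#'   (logical air/artifact mask).
#' @export
convert_dect <- function(dect, table, model,
                         elements = element_table(),
                         symbols = c("H", "C", "N", "O", "P", "Ca")) {
  rho_e <- electron_density_map(dect, model)
  idx <- assign_composition(dect, table)
  flagged <- rho_e < model$rho_e_floor
  air_idx <- match("air", table$name)
  if (!is.na(air_idx)) idx[flagged] <- air_idx
  zeff <- zeff_map(rho_e, dect$hu_low, model)
  I <- ionization_potential(zeff, model)
  spr <- spr_map(rho_e, I, model)
  density <- mass_density_map(rho_e, idx, table, elements)
  attr(idx, "basis_table") <- table
  list(assignment = idx, rho_e = rho_e, zeff = zeff, I = I, spr = spr,
       density = density,
       weights = weight_fraction_maps(idx, table, symbols),
       flagged = flagged)
}
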