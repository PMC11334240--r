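#' Region-of-interest specifications
#'
#' Two ROI shapes cover the analysis protocols: a cylinder along a grid
#' axis (the proton-beam path used for SPR statistics) and an axis-aligned
#' box (the irradiated target region or the whole sample). World
#' coordinates are in mm with the origin at the corner of voxel
#' (1, 1, 1); a voxel belongs to an ROI iff its center does. Boxes use
#' the half-open convention `[corner, corner + extents)`.
#'
#' @param axis Cylinder axis: 1, 2 or 3.
#' @param center Cylinder center (mm, length 3).
#' @param diameter,length Cylinder diameter and length (mm, positive).
#' @return An object of class `roi_spec`.
#' @export
roi_cylinder <- function(axis, center, diameter, length) {
  stopifnot(axis %in% 1:3, base::length(center) == 3L,
            diameter > 0, length > 0)
  structure(list(kind = "cylinder", axis = as.integer(axis),
                 center = as.numeric(center), diameter = diameter,
                 length = length),
            class = "roi_spec")
}

#' @rdname roi_cylinder
#' @param corner Box corner (mm, length 3).
#' @param extents Box edge lengths (mm, length 3, positive).
#' @export
roi_box <- function(corner, extents) {
  stopifnot(base::length(corner) == 3L, base::length(extents) == 3L,
            all(extents > 0))
  structure(list(kind = "box", corner = as.numeric(corner),
                 extents = as.numeric(extents)),
            class = "roi_spec")
}

#' Rasterize an ROI to a voxel mask
#'
#' @param dim Grid dimensions (length 3).
#' @param spacing Voxel spacing in mm (length 3).
#' @param roi An [roi_cylinder()] or [roi_box()] spec.
#' @return Logical array; errors if the ROI selects no voxel.
#' @export
roi_mask <- function(dim, spacing, roi) {
  stopifnot(inherits(roi, "roi_spec"), length(dim) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  ctr <- lapply(1:3, function(ax) (seq_len(dim[ax]) - 0.5) * spacing[ax])
  if (roi$kind == "box") {
    inside <- lapply(1:3, function(ax)
      ctr[[ax]] >= roi$corner[ax] &
        ctr[[ax]] < roi$corner[ax] + roi$extents[ax])
  } else {
    perp <- setdiff(1:3, roi$axis)
    inside <- vector("list", 3)
    inside[[roi$axis]] <-
      abs(ctr[[roi$axis]] - roi$center[roi$axis]) <= roi$length / 2
    # radial test needs the joint distance; build full mask below
  }
  if (roi$kind == "box") {
    mask <- outer(outer(inside[[1]], inside[[2]], `&`), inside[[3]], `&`)
  } else {
    perp <- setdiff(1:3, roi$axis)
    d1 <- ctr[[perp[1]]] - roi$center[perp[1]]
    d2 <- ctr[[perp[2]]] - roi$center[perp[2]]
    r2 <- outer(d1^2, d2^2, `+`)
    radial <- r2 <= (roi$diameter / 2)^2
    ax_in <- inside[[roi$axis]]
    mask <- array(FALSE, dim)
    # place radial (perp1 x perp2) and axial masks into the grid order
    full <- list(NULL, NULL, NULL)
    full[[roi$axis]] <- ax_in
    full[[perp[1]]] <- seq_len(dim[perp[1]])
    full[[perp[2]]] <- seq_len(dim[perp[2]])
    g <- array(FALSE, dim)
    idx <- which(radial, arr.ind = TRUE)
    if (nrow(idx) > 0 && any(ax_in)) {
      for (k in which(ax_in)) {
        coords <- matrix(0L, nrow(idx), 3)
        coords[, perp[1]] <- idx[, 1]
        coords[, perp[2]] <- idx[, 2]
        coords[, roi$axis] <- k
        g[coords] <- TRUE
      }
    }
    mask <- g
  }
  if (!any(mask))
    stop("ROI does not intersect the grid", call. = FALSE)
  mask
}

#' Mass-weighted mean elemental composition in an ROI
#'
#' `w^X = sum_i w_i^X rho_i^m / sum_i rho_i^m` over the masked voxels,
#' per element.
#'
#' @param weights Named list of per-element weight-fraction arrays.
#' @param density Mass-density array (g/cm3, positive on the mask).
#' @param mask Logical array.
#' @return Named numeric vector of ROI weight fractions.
#' @export
mass_weighted_composition <- function(weights, density, mask) {
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  if (any(density[mask] <= 0))
    stop("non-positive density inside the ROI", call. = FALSE)
  rho <- density[mask]
  vapply(weights, function(w) sum(w[mask] * rho) / sum(rho), 0)
}

#' Per-energy CT-number statistics in an ROI
#'
#' Means and population standard deviations (divisor N -- descriptive
#' spread of the ROI itself) of the low- and high-energy CT numbers.
#'
#' @param dect A [dect_volume()].
#' @param mask Logical array.
#' @return Data frame with columns `energy`, `mean_hu`, `sd_hu`, `n`.
#' @export
roi_hu_stats <- function(dect, mask) {
  stopifnot(inherits(dect, "dect_volume"))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  lo <- dect$hu_low[mask]
  hi <- dect$hu_high[mask]
  data.frame(energy = c("low", "high"),
             mean_hu = c(mean(lo), mean(hi)),
             sd_hu = c(pop_sd(lo), pop_sd(hi)),
             n = length(lo))
}

#' Root-mean-square error
#'
#' `sqrt(mean((predicted - reference)^2))`; with `relative = TRUE` the
#' differences are divided by the reference first (the convention used
#' for SPR and density comparisons).
#'
#' @param predicted,reference Equal-length numeric vectors.
#' @param relative Divide differences by `reference` first.
#' @return RMSE in the input units (or dimensionless if relative).
#' @export
rmse <- function(predicted, reference, relative = FALSE) {
  if (length(predicted) != length(reference) || length(predicted) < 1L)
    stop("predicted and reference must have equal length >= 1",
         call. = FALSE)
  d <- predicted - reference
  if (relative) d <- d / reference
  sqrt(mean(d^2))
}

#' ROI-shift sensitivity analysis
#'
#' Re-evaluates an ROI statistic after shifting the ROI along each axis
#' by each requested distance, quantifying sensitivity to sample
#' inhomogeneity and positioning error. Shifted ROIs that leave the grid
#' are flagged rather than fatal.
#'
#' @param map Scalar field (3-D array) to summarize.
#' @param spacing Voxel spacing (mm).
#' @param roi An [roi_cylinder()] or [roi_box()].
#' @param shifts Signed shift distances in mm (default
#'   `c(-10, -5, -2, 2, 5, 10)`), applied one axis at a time.
#' @return Data frame with one baseline row (axis 0, shift 0) and one
#'   row per (axis, shift): `mean`, `sd`, `n`, `deviation` from
#'   baseline, `flagged`. Attribute `max_abs_deviation` summarizes.
#' @export
shift_sensitivity <- function(map, spacing, roi,
                              shifts = c(-10, -5, -2, 2, 5, 10)) {
  stopifnot(is.array(map), length(dim(map)) == 3L)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  eval_roi <- function(r) {
    mask <- tryCatch(roi_mask(dim(map), spacing, r), error = function(e) NULL)
    if (is.null(mask)) return(c(NA_real_, NA_real_, 0))
    x <- map[mask]
    c(mean(x), pop_sd(x), length(x))
  }
  shift_roi <- function(r, ax, d) {
    if (r$kind == "box") r$corner[ax] <- r$corner[ax] + d
    else r$center[ax] <- r$center[ax] + d
    r
  }
  base <- eval_roi(roi)
  rows <- list(data.frame(axis = 0L, shift_mm = 0, mean = base[1],
                          sd = base[2], n = base[3], deviation = 0,
                          flagged = FALSE))
  for (ax in 1:3) for (d in shifts) {
    v <- eval_roi(shift_roi(roi, ax, d))
    rows[[length(rows) + 1L]] <-
      data.frame(axis = ax, shift_mm = d, mean = v[1], sd = v[2],
                 n = v[3], deviation = v[1] - base[1],
                 flagged = is.na(v[1]))
  }
  out <- do.call(rbind, rows)
  attr(out, "max_abs_deviation") <- max(abs(out$deviation), na.rm = TRUE)
  out
}

#' Convert elemental densities to weight fractions
#'
#' Voxelwise ratio of an elemental density map (g/cm3 of one element) to
#' the mass-density map. Values above 1 are physically impossible but
#' are returned (not clipped) to preserve diagnostic content.
#'
#' @param elemental_density Array of elemental densities (g/cm3).
#' @param mass_density Array of mass densities (g/cm3, positive).
#' @return Weight-fraction array.
#' @export
weights_from_densities <- function(elemental_density, mass_density) {
  if (any(mass_density <= 0))
    stop("mass density must be positive everywhere", call. = FALSE)
  elemental_density / mass_density
}
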