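#' Depth-dose curve
#'
#' A sampled Bragg curve from a multi-layer ionization chamber: strictly
#' increasing depths with non-negative dose, at least 3 samples.
#'
#' @param depths Depths in mm, strictly increasing.
#' @param dose Dose in arbitrary units (>= 0), same length.
#' @return An object of class `depth_dose`.
#' @export
depth_dose <- function(depths, dose) {
  stopifnot(length(depths) == length(dose), length(depths) >= 3L,
            all(diff(depths) > 0), all(dose >= 0))
  structure(list(depths = as.numeric(depths), dose = as.numeric(dose)),
            class = "depth_dose")
}

#' Distal 80% range of a Bragg curve
#'
#' Depth at which the dose falls to `frac` (default 80%) of the curve
#' maximum on the distal (post-peak) side, by linear interpolation
#' between the two bracketing samples. With noisy tails producing
#' several crossings the deepest one is returned.
#'
#' @param curve A [depth_dose()].
#' @param frac Threshold fraction of the maximum (default 0.8).
#' @return Depth in mm.
#' @export
r80_distal <- function(curve, frac = 0.8) {
  stopifnot(inherits(curve, "depth_dose"), frac > 0, frac < 1)
  d <- curve$depths
  y <- curve$dose
  imax <- which.max(y)
  thr <- frac * y[imax]
  n <- length(y)
  if (imax == n || y[n] >= thr)
    stop("truncated curve: distal tail does not cross ",
         format(frac * 100), "% of the maximum", call. = FALSE)
  for (i in (n - 1L):imax) {
    if (y[i] >= thr && y[i + 1L] < thr) {
      return(d[i] + (y[i] - thr) / (y[i] - y[i + 1L]) * (d[i + 1L] - d[i]))
    }
  }
  stop("truncated curve: no distal crossing found", call. = FALSE)
}

#' SPR from three distal-80% ranges
#'
#' Range-based stopping-power ratio of a boxed sample from repeated
#' range measurements with the box filled by the sample, water and air:
#' `SPR_sample = (R_sample - R_air)/(R_water - R_air) * (1 - SPR_air)
#'  + SPR_air`. `SPR_air` is a required input (PSTAR-derived dry-air
#' value at the beam energy); no database value is hardcoded.
#'
#' @param r_sample,r_water,r_air Distal-80% ranges in mm.
#' @param spr_air SPR of dry air, in (0, 0.01).
#' @return The sample SPR (dimensionless).
#' @export
spr_from_ranges <- function(r_sample, r_water, r_air, spr_air) {
  if (!(spr_air > 0 && spr_air < 0.01))
    stop("spr_air must lie in (0, 0.01)", call. = FALSE)
  if (r_water == r_air)
    stop("r_water and r_air must differ", call. = FALSE)
  (r_sample - r_air) / (r_water - r_air) * (1 - spr_air) + spr_air
}
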