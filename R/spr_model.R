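#' Proton speed from kinetic energy
#'
#' Relativistic kinematics: `gamma = 1 + T/m_p c^2`,
#' `beta = sqrt(1 - 1/gamma^2)` with `m_p c^2 = 938.272 MeV`. 100 MeV
#' protons have `beta = 0.4282`.
#'
#' @param energy_mev Proton kinetic energy in MeV.
#' @return `beta = v/c` (dimensionless, in (0, 1)).
#' @export
beta_from_energy <- function(energy_mev) {
  stopifnot(energy_mev > 0)
  gamma <- 1 + energy_mev / 938.272
  sqrt(1 - 1 / gamma^2)
}

# electron rest energy in eV, used in the Bethe logarithm
ME_C2_EV <- 0.510999e6

#' Dual-energy SPR conversion model parameters
#'
#' Bundles the fitted Saito-Sagara-style coefficients with the Bethe
#' constants. The voxelwise chain is:
#' `rho_e = a*((1+alpha)*HU_high - alpha*HU_low)/1000 + b`;
#' `Z_eff = Z_eff,w * (c*(HU_low/1000 + 1)/rho_e + d)^(1/n)`;
#' `ln I` piecewise-linear in `Z_eff` (`i_map`); and the Bethe
#' stopping-power ratio of [spr_bethe()].
#'
#' @param a,alpha,b Electron-density coefficients (slope, energy-mixing
#'   weight, offset; `b = 1` anchors water).
#' @param c_,d Effective-atomic-number coefficients.
#' @param n Z_eff power-mean exponent (default 3.3).
#' @param i_map Mapping `Z_eff -> ln I`; a list as produced by
#'   [fit_spr_model()] (`two_segment` or `interpolate` form).
#' @param beta Proton speed ratio in (0, 1); default for 100 MeV. The
#'   literal constant 0.482 may be supplied to follow that convention.
#' @param I_w Water ionization potential in eV (default 78).
#' @param rho_e_floor Voxels with `rho_e` below this are flagged air and
#'   bypass the Z_eff/I chain (default 0.05).
#' @param elements Element table (fixes `Z_eff,w` and water `Z/A`).
#' @return An object of class `spr_model`.
#' @export
spr_model <- function(a, alpha, b, c_, d, n = 3.3, i_map = NULL,
                      beta = beta_from_energy(100), I_w = 78,
                      rho_e_floor = 0.05, elements = element_table()) {
  stopifnot(beta > 0, beta < 1, I_w > 0, n > 0)
  w <- water_composition(1, elements)
  a <- unname(a); alpha <- unname(alpha); b <- unname(b)
  c_ <- unname(c_); d <- unname(d)
  structure(list(a = a, alpha = alpha, b = b, c = c_, d = d, n = n,
                 i_map = i_map, beta = beta, I_w = I_w,
                 rho_e_floor = rho_e_floor,
                 zeff_w = effective_atomic_number(w, n, elements),
                 za_water = za_sum(w$fractions, elements)),
            class = "spr_model")
}

#' @export
print.spr_model <- function(x, ...) {
  cat("<spr_model> rho_e: a=", format(x$a), " alpha=", format(x$alpha),
      " b=", format(x$b), "; zeff: c=", format(x$c), " d=", format(x$d),
      " n=", format(x$n), "; beta=", format(x$beta), " I_w=", x$I_w,
      " eV\n", sep = "")
  invisible(x)
}

#' Bethe stopping-power ratio to water
#'
#' `SPR = rho_e * [ln(2 m_e c^2 beta^2 / (I (1-beta^2))) - beta^2] /
#'               [ln(2 m_e c^2 beta^2 / (I_w (1-beta^2))) - beta^2]`
#' with `m_e c^2 = 0.510999 MeV`. Vectorized over `rho_e` and `I`.
#'
#' @param rho_e Electron density relative to water.
#' @param I Mean excitation energy in eV.
#' @param beta Proton speed ratio.
#' @param I_w Water mean excitation energy in eV.
#' @return The stopping-power ratio (same shape as `rho_e`).
#' @export
spr_bethe <- function(rho_e, I, beta = beta_from_energy(100), I_w = 78) {
  stopifnot(beta > 0, beta < 1, all(I > 0), I_w > 0)
  num <- log(2 * ME_C2_EV * beta^2 / (I * (1 - beta^2))) - beta^2
  den <- log(2 * ME_C2_EV * beta^2 / (I_w * (1 - beta^2))) - beta^2
  rho_e * num / den
}

#' Fit the dual-energy SPR conversion model
#'
#' Three sequential least-squares fits against inserts of known
#' composition: (1) relative electron density on the weighted
#' dual-energy combination (linear in transformed coefficients); (2)
#' `(Z_eff/Z_eff,w)^n` against the density-reduced low-energy
#' attenuation `u_L / rho_e` (`u_L = HU_low/1000 + 1`); (3) the
#' `Z_eff -> ln I` map over a reference tissue set, by default
#' piecewise-linear interpolation through all reference points
#' (`"interpolate"`), or a coarser two-segment log-linear fit split at
#' `zeff_split` (soft/bone regimes).
#' With `anchor_water = TRUE` (default) the offsets are constrained so
#' that HU = (0, 0) maps exactly to water (`rho_e = 1`, `Z_eff,w`,
#' `I_w`). Air-like reference entries (density below the model floor,
#' taken as g/cm3) are excluded from the ionization-potential map: such
#' voxels bypass the Z_eff chain anyway.
#'
#' @param inserts List of [tissue()] inserts (>= 4, spanning soft and
#'   bone surrogates).
#' @param hu_low,hu_high Measured (or predicted) mean CT numbers of the
#'   inserts at the two beams.
#' @param rho_e,zeff Known insert electron densities and effective
#'   atomic numbers; by default computed from the insert compositions.
#' @param basis [tissue_basis()] whose tissues define the `Z_eff -> ln I`
#'   map (defaults to the inserts).
#' @param n Z_eff exponent.
#' @param zeff_split Z_eff boundary between the soft and bone segments.
#' @param anchor_water Constrain the model through the water point.
#' @param i_map_method `"two_segment"` (default) or `"interpolate"`.
#' @param beta,I_w,rho_e_floor Passed to [spr_model()].
#' @param elements Element table.
#' @return An [spr_model()] with attribute `diagnostics` (`rho_e` and
#'   `zeff` fit RMSEs, `ln I` residual RMSE over the reference set).
#' @export
fit_spr_model <- function(inserts, hu_low, hu_high, rho_e = NULL,
                          zeff = NULL, basis = NULL,
                          n = 3.3, zeff_split = 8.5, anchor_water = TRUE,
                          i_map_method = c("interpolate", "two_segment"),
                          beta = beta_from_energy(100), I_w = 78,
                          rho_e_floor = 0.05, elements = element_table()) {
  i_map_method <- match.arg(i_map_method)
  stopifnot(is.list(inserts), length(inserts) == length(hu_low),
            length(hu_low) == length(hu_high))
  if (length(inserts) < 4L)
    stop("at least 4 inserts are required", call. = FALSE)
  rho <- rho_e %||%
    vapply(inserts, relative_electron_density, 0, elements = elements)
  zeff <- zeff %||%
    vapply(inserts, effective_atomic_number, 0, exponent = n,
           elements = elements)
  if (diff(range(zeff)) < 1e-3 || diff(range(rho)) < 1e-6)
    stop("rank-deficient calibration: inserts are water-like", call. = FALSE)

  ul <- hu_low / 1000
  uh <- hu_high / 1000
  # rho_e = p*uh + q*ul + b with p = a(1+alpha), q = -a*alpha
  if (anchor_water) {
    X <- cbind(uh, ul)
    cf <- stats::lm.fit(X, rho - 1)$coefficients
    b <- 1
  } else {
    X <- cbind(uh, ul, 1)
    cf <- stats::lm.fit(X, rho)$coefficients
    b <- cf[3]
  }
  if (anyNA(cf)) stop("rank-deficient calibration", call. = FALSE)
  a <- cf[1] + cf[2]
  alpha <- -cf[2] / a
  rho_hat <- a * ((1 + alpha) * uh - alpha * ul) + b

  w <- water_composition(1, elements)
  zeff_w <- effective_atomic_number(w, n, elements)
  y <- (zeff / zeff_w)^n
  f <- (ul + 1) / rho
  if (anchor_water) {
    c_ <- sum((f - 1) * (y - 1)) / sum((f - 1)^2)
    d <- 1 - c_
  } else {
    cc <- stats::lm.fit(cbind(f, 1), y)$coefficients
    c_ <- cc[1]
    d <- cc[2]
  }
  zeff_hat <- zeff_w * pmax(c_ * f + d, 0)^(1 / n)

  map_tissues <- if (is.null(basis)) inserts else basis$tissues
  map_dens <- vapply(map_tissues, `[[`, 0, "density")
  map_tissues <- map_tissues[map_dens >= rho_e_floor]
  mz <- vapply(map_tissues, effective_atomic_number, 0, exponent = n,
               elements = elements)
  mi <- log(vapply(map_tissues, tissue_ionization_potential, 0,
                   elements = elements, I_water = I_w))
  ln_iw <- log(I_w)
  if (i_map_method == "two_segment") {
    soft <- mz <= zeff_split
    fit_slope <- function(z0, l0, z, l) {
      if (length(z) == 0L || all(abs(z - z0) < 1e-9)) return(0)
      sum((z - z0) * (l - l0)) / sum((z - z0)^2)
    }
    m_soft <- fit_slope(zeff_w, ln_iw, mz[soft], mi[soft])
    v_split <- ln_iw + m_soft * (zeff_split - zeff_w)
    m_bone <- fit_slope(zeff_split, v_split, mz[!soft], mi[!soft])
    if (all(soft)) m_bone <- m_soft
    i_map <- list(method = "two_segment", split = zeff_split,
                  zeff_w = zeff_w, ln_iw = ln_iw,
                  m_soft = m_soft, m_bone = m_bone)
  } else {
    ord <- order(mz)
    zk <- mz[ord]; lk <- mi[ord]
    keep <- !duplicated(round(zk, 9))
    i_map <- list(method = "interpolate", zeff = zk[keep],
                  ln_i = lk[keep])
    if (length(i_map$zeff) < 2L)
      stop("need at least two distinct Z_eff reference points",
           call. = FALSE)
  }
  model <- spr_model(a, alpha, b, c_, d, n = n, i_map = i_map,
                     beta = beta, I_w = I_w, rho_e_floor = rho_e_floor,
                     elements = elements)
  i_resid <- log(ionization_potential(mz, model)) - mi
  attr(model, "diagnostics") <- list(
    rho_e_rmse = sqrt(mean((rho_hat - rho)^2)),
    zeff_rmse = sqrt(mean((zeff_hat - zeff)^2)),
    ln_i_rmse = sqrt(mean(i_resid^2)))
  model
}
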