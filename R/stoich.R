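#' Stoichiometric beam-quality parameters
#'
#' The two free parameters of the stoichiometric CT-number model at one
#' tube potential: `k1` scales the photoelectric term (effective-Z
#' exponent 3.62) and `k2` the coherent-scatter term (exponent 1.86).
#' Both are fitted per scanner and protocol from calibration-insert
#' scans.
#'
#' @param k1,k2 Non-negative coefficients.
#' @param beam_label Identifier such as `"80kV"` or `"140kV"`.
#' @return An object of class `stoich_params`.
#' @export
stoich_params <- function(k1, k2, beam_label = "beam") {
  stopifnot(is.numeric(k1), is.numeric(k2), length(k1) == 1L,
            length(k2) == 1L, k1 >= 0, k2 >= 0)
  structure(list(k1 = unname(k1), k2 = unname(k2),
                 beam_label = beam_label),
            class = "stoich_params")
}

#' @export
print.stoich_params <- function(x, ...) {
  cat("<stoich_params> ", x$beam_label, ": k1 = ", format(x$k1),
      ", k2 = ", format(x$k2), "\n", sep = "")
  invisible(x)
}

#' A calibration-insert measurement
#'
#' Pairs an insert of known composition with its mean CT number (and
#' optionally the ROI standard deviation, usable as a fit weight).
#'
#' @param insert A [tissue()].
#' @param mean_hu Mean CT number within the insert ROI (HU).
#' @param hu_std Optional ROI standard deviation (HU, `>= 0`).
#' @return An object of class `calibration_measurement`.
#' @export
calibration_measurement <- function(insert, mean_hu, hu_std = NA_real_) {
  stopifnot(is_tissue(insert), is.numeric(mean_hu), length(mean_hu) == 1L)
  if (!is.na(hu_std) && hu_std < 0)
    stop("hu_std must be >= 0", call. = FALSE)
  structure(list(insert = insert, mean_hu = mean_hu, hu_std = hu_std),
            class = "calibration_measurement")
}

# Photoelectric / coherent power-mean terms for one composition.
stoich_terms <- function(comp, elements = element_table()) {
  c(p = effective_atomic_number(comp, 3.62, elements)^3.62,
    q = effective_atomic_number(comp, 1.86, elements)^1.86)
}

#' Predict the CT number of a material
#'
#' Schneider-style three-term attenuation model:
#' `u = rho_e * (1 + k1*Zt^3.62 + k2*Zc^1.86) /
#'      (1 + k1*Zt_w^3.62 + k2*Zc_w^1.86)` and `HU = 1000*(u - 1)`,
#' with `Zt`, `Zc` the effective atomic numbers at exponents 3.62 and
#' 1.86 and `rho_e` the electron density relative to water. Water maps to
#' 0 HU for any parameters.
#'
#' @param comp A [tissue()].
#' @param params A [stoich_params()].
#' @param elements Element table.
#' @return Predicted CT number in HU.
#' @export
predict_hu <- function(comp, params, elements = element_table()) {
  stopifnot(inherits(params, "stoich_params"))
  t <- stoich_terms(comp, elements)
  tw <- stoich_terms(water_composition(1, elements), elements)
  rho_e <- relative_electron_density(comp, elements)
  u <- rho_e * (1 + params$k1 * t["p"] + params$k2 * t["q"]) /
    (1 + params$k1 * tw["p"] + params$k2 * tw["q"])
  unname(1000 * (u - 1))
}

#' Fit stoichiometric parameters from calibration measurements
#'
#' Minimizes the sum of squared HU residuals between [predict_hu()] and
#' the measured mean CT numbers over `k1, k2 >= 0`. The problem
#' linearizes exactly in (k1, k2) after multiplying through by the water
#' denominator; that linear solution seeds a bounded quasi-Newton polish
#' of the true HU-residual objective (relative tolerance 1e-14).
#'
#' @param measurements List of [calibration_measurement()] (at least 3,
#'   spanning at least two distinct effective atomic numbers).
#' @param elements Element table.
#' @param weighted If `TRUE`, residuals are weighted by `1/hu_std^2`.
#' @param beam_label Label for the fitted parameters.
#' @return A [stoich_params()] with attribute `diagnostics`: a list with
#'   `rmse_hu` (residual RMSE in HU), `se` (approximate standard errors
#'   of k1 and k2) and `n`.
#' @export
fit_stoich_params <- function(measurements, elements = element_table(),
                              weighted = FALSE, beam_label = "beam") {
  stopifnot(is.list(measurements))
  if (length(measurements) < 3L)
    stop("at least 3 calibration measurements are required", call. = FALSE)
  stopifnot(all(vapply(measurements, inherits, TRUE,
                       "calibration_measurement")))
  comps <- lapply(measurements, `[[`, "insert")
  hu <- vapply(measurements, `[[`, 0, "mean_hu")
  rho <- vapply(comps, relative_electron_density, 0, elements = elements)
  terms <- t(vapply(comps, stoich_terms, c(p = 0, q = 0),
                    elements = elements))
  zt <- terms[, "p"]^(1 / 3.62)
  if (length(unique(round(zt, 6))) < 2L)
    stop("rank-deficient calibration: inserts span a single effective ",
         "atomic number", call. = FALSE)
  wts <- rep(1, length(hu))
  if (weighted) {
    sd <- vapply(measurements, `[[`, 0, "hu_std")
    if (anyNA(sd) || any(sd <= 0))
      stop("weighted fit requires positive hu_std for every measurement",
           call. = FALSE)
    wts <- 1 / sd^2
  }
  tw <- stoich_terms(water_composition(1, elements), elements)
  u <- 1 + hu / 1000
  # linearized system: k1*(rho*p - u*p_w) + k2*(rho*q - u*q_w) = u - rho
  A <- cbind(rho * terms[, "p"] - u * tw["p"],
             rho * terms[, "q"] - u * tw["q"])
  if (qr(A)$rank < 2L)
    stop("rank-deficient calibration", call. = FALSE)
  k0 <- stats::lm.wfit(A, u - rho, wts)$coefficients
  k0[!is.finite(k0) | k0 < 0] <- 0
  obj <- function(k) {
    pred <- 1000 * (rho * (1 + k[1] * terms[, "p"] + k[2] * terms[, "q"]) /
                      (1 + k[1] * tw["p"] + k[2] * tw["q"]) - 1)
    sum(wts * (pred - hu)^2)
  }
  fit <- stats::nlminb(pmax(k0, 0), obj, lower = c(0, 0),
                       control = list(rel.tol = 1e-14, x.tol = 1e-14,
                                      iter.max = 500))
  k <- fit$par
  pred <- 1000 * (rho * (1 + k[1] * terms[, "p"] + k[2] * terms[, "q"]) /
                    (1 + k[1] * tw["p"] + k[2] * tw["q"]) - 1)
  res <- pred - hu
  n <- length(hu)
  # numeric Jacobian for approximate parameter standard errors
  eps <- pmax(abs(k), 1e-6) * 1e-6
  J <- vapply(1:2, function(j) {
    kp <- k; kp[j] <- kp[j] + eps[j]
    (1000 * (rho * (1 + kp[1] * terms[, "p"] + kp[2] * terms[, "q"]) /
               (1 + kp[1] * tw["p"] + kp[2] * tw["q"]) - 1) - pred) / eps[j]
  }, numeric(n))
  sigma2 <- sum(wts * res^2) / max(n - 2, 1)
  JtJ <- crossprod(J * sqrt(wts))
  se <- if (qr(JtJ)$rank == 2L) sqrt(diag(solve(JtJ)) * sigma2)
        else c(NA_real_, NA_real_)
  out <- stoich_params(k[1], k[2], beam_label)
  attr(out, "diagnostics") <- list(rmse_hu = sqrt(mean(wts * res^2) /
                                                    mean(wts)),
                                   se = stats::setNames(se, c("k1", "k2")),
                                   n = n)
  out
}

#' Predicted dual-energy CT-number table for a basis
#'
#' One (HU_low, HU_high) coordinate per basis tissue, in basis order;
#' this is the nearest-neighbour search space of the voxelwise
#' composition assignment.
#'
#' @param basis A [tissue_basis()].
#' @param params_low,params_high [stoich_params()] for the low- and
#'   high-energy beams.
#' @param elements Element table.
#' @return A data frame of class `basis_table` with columns `name`,
#'   `hu_low`, `hu_high`; the basis is carried in attribute `basis`.
#' @export
predict_basis_table <- function(basis, params_low, params_high,
                                elements = element_table()) {
  stopifnot(inherits(basis, "tissue_basis"))
  hu_l <- vapply(basis$tissues, predict_hu, 0, params = params_low,
                 elements = elements)
  hu_h <- vapply(basis$tissues, predict_hu, 0, params = params_high,
                 elements = elements)
  out <- data.frame(name = basis_names(basis), hu_low = hu_l,
                    hu_high = hu_h, stringsAsFactors = FALSE)
  attr(out, "basis") <- basis
  class(out) <- c("basis_table", "data.frame")
  out
}
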