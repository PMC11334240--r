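# Voxelwise dual-energy conversion: assignment, electron density,
# effective atomic number, ionization potential, SPR and mass density.

arr3 <- function(x) array(x, dim = c(length(x), 1, 1))

test_that("composition assignment is nearest-point with stable tie-breaks", {
  w <- fix_world()
  tab <- w$table

  # voxels exactly at reference coordinates map to those entries
  pick <- c(1L, 4L, 12L)
  dect <- dect_volume(arr3(tab$hu_low[pick]), arr3(tab$hu_high[pick]))
  idx <- assign_composition(dect, tab)
  expect_identical(as.vector(idx), pick)

  # equidistant voxel between entries 2 and 5 resolves to entry 2
  toy <- data.frame(name = paste0("t", 1:5),
                    hu_low = c(-500, 0, 300, 700, 100),
                    hu_high = c(-500, 0, 300, 700, 100))
  class(toy) <- c("basis_table", "data.frame")
  attr(toy, "basis") <- NULL
  mid <- dect_volume(arr3(50), arr3(50))
  expect_identical(as.vector(assign_composition(mid, toy)), 2L)

  # permutation invariance in the absence of exact ties
  set.seed(1)
  hu_l <- runif(200, -900, 1900)
  hu_h <- runif(200, -900, 1200)
  dect2 <- dect_volume(arr3(hu_l), arr3(hu_h))
  perm <- sample(nrow(tab))
  tab_p <- tab[perm, ]
  class(tab_p) <- c("basis_table", "data.frame")
  attr(tab_p, "basis") <- attr(tab, "basis")
  i1 <- assign_composition(dect2, tab)
  i2 <- assign_composition(dect2, tab_p)
  expect_identical(tab$name[as.vector(i1)], tab_p$name[as.vector(i2)])

  expect_error(assign_composition(
    dect_volume(arr3(0), arr3(0)), data.frame()), "basis_table")
})

test_that("electron density map is the anchored dual-energy combination", {
  w <- fix_world()
  m <- w$model
  d0 <- dect_volume(arr3(0), arr3(0))
  expect_equal(as.vector(electron_density_map(d0, m)), 1)

  # alpha = 0 makes the map depend on the high-energy image only
  m0 <- spr_model(1.1, 0, 1, m$c, m$d, i_map = m$i_map)
  dA <- dect_volume(arr3(c(-100, 500)), arr3(c(40, 40)))
  expect_equal(electron_density_map(dA, m0)[1, 1, 1],
               electron_density_map(dA, m0)[2, 1, 1])

  # calibrated fit recovers insert electron densities within 0.5%
  hu_l <- vapply(w$inserts, predict_hu, 0, params = w$fit_l)
  hu_h <- vapply(w$inserts, predict_hu, 0, params = w$fit_h)
  rho_hat <- as.vector(electron_density_map(
    dect_volume(arr3(hu_l), arr3(hu_h)), m))
  rho_true <- vapply(w$inserts, relative_electron_density, 0)
  expect_lt(max(abs(rho_hat - rho_true) / rho_true), 0.005)
})

test_that("effective atomic number map reproduces the power-mean oracle", {
  w <- fix_world()
  m <- w$model

  # water voxel maps exactly to the water effective atomic number
  zw <- effective_atomic_number(water_composition(), m$n)
  expect_equal(as.vector(zeff_map(arr3(1), arr3(0), m)), zw,
               tolerance = 1e-9)
  # the 3.3-power convention puts water near 7.477
  expect_equal(zw, 7.477, tolerance = 1e-3)

  # below the density floor the voxel is flagged, not an error
  expect_true(is.na(zeff_map(arr3(0.01), arr3(-990), m)))

  # noise-free inserts: map within 2% of the direct power mean
  hu_l <- vapply(w$inserts, predict_hu, 0, params = w$fit_l)
  hu_h <- vapply(w$inserts, predict_hu, 0, params = w$fit_h)
  rho <- electron_density_map(dect_volume(arr3(hu_l), arr3(hu_h)), m)
  z_hat <- as.vector(zeff_map(rho, arr3(hu_l), m))
  z_true <- vapply(w$inserts, effective_atomic_number, 0, exponent = m$n)
  expect_lt(max(abs(z_hat - z_true) / z_true, na.rm = TRUE), 0.02)
})

test_that("ionization potential map is water-anchored and log-linear", {
  w <- fix_world()
  m <- w$model
  expect_equal(as.vector(ionization_potential(m$zeff_w, m)), 78,
               tolerance = 1e-9)

  # single-segment map: the midpoint yields the geometric mean
  m1 <- m
  m1$i_map <- list(method = "interpolate", zeff = c(7, 9),
                   ln_i = log(c(70, 110)))
  expect_equal(as.vector(ionization_potential(8, m1)), sqrt(70 * 110),
               tolerance = 1e-12)

  # reference-tissue fit recovers the tissue I values within 5%
  keep <- vapply(w$basis$tissues, `[[`, 0, "density") >= m$rho_e_floor
  z_ref <- vapply(w$basis$tissues[keep], effective_atomic_number, 0,
                  exponent = m$n)
  i_ref <- vapply(w$basis$tissues[keep], tissue_ionization_potential, 0,
                  I_water = m$I_w)
  i_hat <- ionization_potential(z_ref, m)
  expect_lt(max(abs(i_hat - i_ref) / i_ref), 0.05)

  m_empty <- m
  m_empty$i_map <- NULL
  expect_error(ionization_potential(7.5, m_empty), "i_map")
})

test_that("the Bethe ratio collapses correctly and is monotone in I", {
  # I = I_w collapses the ratio to rho_e
  expect_equal(spr_bethe(1.23, 78), 1.23, tolerance = 1e-12)
  expect_equal(spr_bethe(1, 78), 1)

  # independent scalar evaluation at 100 MeV
  beta <- beta_from_energy(100)
  expect_equal(beta, 0.4282, tolerance = 1e-4)
  num <- log(2 * 0.510999e6 * beta^2 / (70 * (1 - beta^2))) - beta^2
  den <- log(2 * 0.510999e6 * beta^2 / (78 * (1 - beta^2))) - beta^2
  expect_equal(spr_bethe(1.05, 70), 1.05 * num / den, tolerance = 1e-12)

  # strictly decreasing in I at fixed rho_e and beta
  ivals <- seq(40, 200, by = 5)
  spr <- spr_bethe(1, ivals)
  expect_true(all(diff(spr) < 0))

  # the paper-convention beta override is usable
  expect_equal(spr_bethe(1.4, 78, beta = 0.482), 1.4)
})

test_that("spr_map flags pathological I values instead of erroring", {
  w <- fix_world()
  m <- w$model
  out <- spr_map(arr3(c(1, 1.0e-3)), arr3(c(78, NA)), m)
  expect_equal(out[1, 1, 1], 1)
  expect_equal(out[2, 1, 1], 1.0e-3)  # falls back to rho_e
})

test_that("mass density combines electron density with assigned Z/A", {
  w <- fix_world()
  tab <- w$table
  widx <- match("water", tab$name)

  assignment <- array(widx, dim = c(2, 1, 1))
  attr(assignment, "basis_table") <- tab
  rho <- arr3(c(1, 2))
  dens <- mass_density_map(rho, assignment, tab)
  expect_equal(as.vector(dens), c(1, 2), tolerance = 1e-9)

  # doubling rho_e doubles the density at fixed assignment
  aidx <- array(match("cortical_bone", tab$name), dim = c(1, 1, 1))
  d1 <- mass_density_map(arr3(1.0), aidx, tab)
  d2 <- mass_density_map(arr3(2.0), aidx, tab)
  expect_equal(as.vector(d2), 2 * as.vector(d1))

  # basis tissue at its own noise-free HU pair: nominal density within
  # the rho_e-residual-consistent bound
  hu_l <- tab$hu_low
  hu_h <- tab$hu_high
  m <- w$model
  rho_hat <- electron_density_map(
    dect_volume(arr3(hu_l), arr3(hu_h)), m)
  self_idx <- array(seq_len(nrow(tab)), dim = dim(rho_hat))
  dens_hat <- mass_density_map(rho_hat, self_idx, tab)
  dens_true <- vapply(attr(tab, "basis")$tissues, `[[`, 0, "density")
  keep <- tab$name != "air"
  expect_lt(max(abs(as.vector(dens_hat) - dens_true)[keep]), 5e-3)

  expect_error(mass_density_map(arr3(1), array(NA_integer_, c(1, 1, 1)),
                                tab), "unassigned")
})

test_that("SPR model fitting recovers a generating parameter set exactly", {
  # synthetic inserts drawn from the model equations themselves
  a <- 1.02; alpha <- 0.55; b <- 1; c_ <- 11.5; d <- 1 - c_
  n <- 3.3
  zw <- effective_atomic_number(water_composition(), n)
  hu_l <- c(-700, -80, 0, 60, 450, 1500)
  hu_h <- c(-690, -60, 0, 50, 290, 950)
  rho <- a * ((1 + alpha) * hu_h - alpha * hu_l) / 1000 + b
  zeff <- zw * (c_ * (hu_l / 1000 + 1) / rho + d)^(1 / n)
  inserts <- fix_inserts()[seq_along(hu_l)]  # compositions only carry I
  fit <- fit_spr_model(inserts, hu_l, hu_h, rho_e = rho, zeff = zeff,
                       basis = fix_basis())
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$alpha, alpha, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-12)
  expect_equal(fit$c, c_, tolerance = 1e-6)
  expect_equal(fit$d, d, tolerance = 1e-6)

  # water-like-only inserts are rejected
  wlike <- lapply(1:4, function(i) water_composition(1))
  expect_error(fit_spr_model(wlike, rep(0, 4), rep(0, 4)),
               "rank-deficient|water-like")
})

test_that("noisy SPR-model calibration keeps held-out rho_e error below 1%", {
  basis <- fix_basis()
  fit_set <- fix_inserts(basis)
  cal <- make_calibration_set(fit_set, fix_k_low(), fix_k_high(),
                              sigma = c(2, 2), n_eff = 1, seed = 31)
  model <- fit_spr_model(fit_set,
                         vapply(cal$low, `[[`, 0, "mean_hu"),
                         vapply(cal$high, `[[`, 0, "mean_hu"),
                         basis = basis)
  held_names <- c("spongiosa_01", "spongiosa_03", "yellow_marrow", "skin")
  held <- lapply(held_names, fix_tissue, basis = basis)
  hu_l <- vapply(held, predict_hu, 0, params = fix_k_low())
  hu_h <- vapply(held, predict_hu, 0, params = fix_k_high())
  rho_hat <- as.vector(electron_density_map(
    dect_volume(arr3(hu_l), arr3(hu_h)), model))
  rho_true <- vapply(held, relative_electron_density, 0)
  expect_lt(rmse(rho_hat, rho_true, relative = TRUE), 0.01)
})

test_that("end-to-end SPR of basis tissues matches the closed form", {
  w <- fix_world()
  m <- w$model
  tab <- w$table
  keep <- tab$name != "air"
  dect <- dect_volume(arr3(tab$hu_low), arr3(tab$hu_high))
  rho_hat <- electron_density_map(dect, m)
  z_hat <- zeff_map(rho_hat, dect$hu_low, m)
  spr_hat <- as.vector(spr_map(rho_hat, ionization_potential(z_hat, m), m))
  rho_true <- vapply(w$basis$tissues, relative_electron_density, 0)
  i_true <- vapply(w$basis$tissues, tissue_ionization_potential, 0,
                   I_water = m$I_w)
  spr_true <- spr_bethe(rho_true, i_true, beta = m$beta, I_w = m$I_w)
  expect_lt(max(abs(spr_hat - spr_true)[keep] / spr_true[keep]), 0.005)
})

test_that("SPR model round-trips through JSON", {
  w <- fix_world()
  path <- withr::local_tempfile(fileext = ".json")
  write_spr_model(w$model, path)
  back <- read_spr_model(path)
  expect_equal(back$a, w$model$a, tolerance = 1e-12)
  expect_equal(back$alpha, w$model$alpha, tolerance = 1e-12)
  z <- seq(6, 13, by = 0.5)
  expect_equal(ionization_potential(z, back),
               ionization_potential(z, w$model), tolerance = 1e-9)
})
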