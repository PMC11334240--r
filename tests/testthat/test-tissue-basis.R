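# Composition arithmetic: electron density, effective Z, mixing rules,
# rehydration and basis expansion.

test_that("relative electron density matches independent scalar arithmetic", {
  expect_equal(relative_electron_density(water_composition()), 1)
  expect_equal(relative_electron_density(water_composition(density = 2)), 2)

  # PMMA C5H8O2 at 1.19 g/cm3, recomputed from raw atomic constants
  m <- c(C = 5 * 12.011, H = 8 * 1.008, O = 2 * 15.999)
  w <- m / sum(m)
  za <- w[["C"]] * 6 / 12.011 + w[["H"]] * 1 / 1.008 + w[["O"]] * 8 / 15.999
  wh <- 2 * 1.008 / (2 * 1.008 + 15.999)
  za_w <- wh * 1 / 1.008 + (1 - wh) * 8 / 15.999
  expect_equal(relative_electron_density(pmma_composition()),
               1.19 * za / za_w, tolerance = 1e-12)

  expect_error(relative_electron_density(
    structure(list(name = "x", fractions = c(Xx = 1), density = 1,
                   category = "other"), class = "tissue")),
    "unknown element")
})

test_that("effective atomic number is the electron-fraction power mean", {
  pure_o <- tissue("oxygen", c(O = 1), 1.14)
  for (x in c(1, 2, 3.3, 3.62)) {
    expect_equal(effective_atomic_number(pure_o, x), 8)
  }

  # exponent 1 reduces to the electron-fraction-weighted mean Z
  t <- fix_co_tissue(0.3)
  lam_c <- 0.3 * 6 / 12.011
  lam_o <- 0.7 * 8 / 15.999
  lam <- c(lam_c, lam_o) / (lam_c + lam_o)
  expect_equal(effective_atomic_number(t, 1), sum(lam * c(6, 8)),
               tolerance = 1e-12)

  # water at the photoelectric exponent, brute-force oracle
  wh <- 2 * 1.008 / (2 * 1.008 + 15.999)
  lh <- wh / 1.008
  lo <- (1 - wh) * 8 / 15.999
  lam_w <- c(lh, lo) / (lh + lo)
  expect_equal(effective_atomic_number(water_composition(), 3.62),
               sum(lam_w * c(1, 8)^3.62)^(1 / 3.62), tolerance = 1e-12)

  # bounded by min and max Z present
  expect_gt(effective_atomic_number(t, 3.3), 6)
  expect_lt(effective_atomic_number(t, 3.3), 8)
})

test_that("mass mixing obeys identities and the cortical-bone recipe", {
  t <- fix_co_tissue(0.4, 1.3)
  expect_equal(mix_by_mass(list(t), 1)$fractions, t$fractions)
  expect_equal(mix_by_mass(list(t), 1)$density, t$density)

  halves <- mix_by_mass(list(t, t), c(0.5, 0.5))
  expect_equal(halves$fractions[c("C", "O")], t$fractions[c("C", "O")])
  expect_equal(halves$density, t$density)

  expect_error(mix_by_mass(list(t, t), c(0.6, 0.6)), "sum to 1")

  # water-hydroxyapatite mixture pinned to 16.16 wt% Ca reproduces the
  # bone-mimicking sample's P, O, H fractions to two decimals
  ha <- hydroxyapatite_composition()
  f <- 0.1616 / ha$fractions[["Ca"]]
  mix <- mix_by_mass(list(ha, water_composition()), c(f, 1 - f), "cortical")
  expect_equal(round(100 * mix$fractions[["Ca"]], 2), 16.16)
  expect_equal(round(100 * mix$fractions[["P"]], 2), 7.49)
  expect_equal(round(100 * mix$fractions[["O"]], 2), 69.61)
  expect_equal(round(100 * mix$fractions[["H"]], 2), 6.74)
})

test_that("volume mixing interpolates density linearly", {
  basis <- fix_basis()
  lung <- fix_tissue(basis, "lung")
  air <- air_composition()
  expect_equal(mix_by_volume(lung, air, 1)$fractions, lung$fractions)
  expect_equal(mix_by_volume(lung, air, 0)$density, air$density)

  half <- mix_by_volume(lung, air, 0.5)
  expect_equal(half$density, (lung$density + air$density) / 2)
  # composition is mass-dominated by the denser lung component
  mass_frac_lung <- 0.5 * lung$density / half$density
  expect_gt(mass_frac_lung, 0.99)
  expect_equal(half$fractions[["H"]],
               mass_frac_lung * lung$fractions[["H"]], tolerance = 1e-12)
})

test_that("mass and volume mixing agree in the equal-density limit", {
  a <- fix_co_tissue(0.2, 1.07, "a")
  b <- tissue("b", c(H = 0.1, O = 0.9), 1.07)
  for (f in c(0.25, 0.5, 0.9)) {
    mv <- mix_by_volume(a, b, f)
    mm <- mix_by_mass(list(a, b), c(f, 1 - f))
    expect_equal(mv$density, mm$density, tolerance = 1e-12)
    expect_equal(mv$fractions[names(mm$fractions)], mm$fractions,
                 tolerance = 1e-12)
  }
})

test_that("rehydration mixes the dry residue with pure water", {
  dry <- tissue("dry_c", c(C = 1), 1.5)
  expect_equal(rehydrate(dry, 1)$fractions, dry$fractions)

  # the dried residue made up 13 wt% of the wet sample
  wet <- rehydrate(dry, 0.13)
  wo <- 1 - 2 * 1.008 / (2 * 1.008 + 15.999)
  expect_equal(wet$fractions[["C"]], 0.13, tolerance = 1e-12)
  expect_equal(wet$fractions[["O"]], 0.87 * wo, tolerance = 1e-12)

  # limit towards full dehydration loss -> water
  almost_water <- rehydrate(dry, 1e-9)
  expect_equal(almost_water$fractions[["O"]], wo, tolerance = 1e-6)
  expect_error(rehydrate(dry, 0), "0, 1")
  expect_error(rehydrate(dry, 1.2), "0, 1")
})

test_that("hydroxyapatite P/Ca mass ratio is mixing-invariant", {
  ha <- hydroxyapatite_composition()
  expected <- 6 * 30.974 / (10 * 40.078)
  for (f in c(0.05, 0.3, 0.7)) {
    mix <- mix_by_mass(list(ha, water_composition()), c(f, 1 - f))
    expect_equal(mix$fractions[["P"]] / mix$fractions[["Ca"]], expected,
                 tolerance = 1e-12)
  }
})

test_that("every generated tissue satisfies composition closure", {
  basis <- expand_basis(fix_basis(), n_low_density = 9,
                        bone_series = list(n_mix = 5))
  for (t in basis$tissues) {
    expect_lt(abs(sum(t$fractions) - 1), 1e-6)
    expect_true(all(t$fractions >= 0))
  }
})

test_that("basis expansion appends the configured gap fillers", {
  base <- fix_basis()
  expect_identical(length(expand_basis(base)), length(base))

  ex <- expand_basis(base, n_low_density = 9)
  lam <- ex$provenance == "lung-air-mixture"
  expect_identical(sum(lam), 9L)
  dens <- vapply(ex$tissues[lam], `[[`, 0, "density")
  expect_true(all(diff(dens) > 0))

  # configured to match the published augmentation scale: >= 135 extras
  sp <- lapply(1:40, function(i)
    mix_by_volume(fix_tissue(base, "cortical_bone"),
                  fix_tissue(base, "red_marrow"), i / 41,
                  name = sprintf("sp_extra_%02d", i),
                  category = "spongiosa"))
  big <- expand_basis(base, spongiosa = sp, n_low_density = 45,
                      bone_series = list(
                        n_mix = 45,
                        density_ramp = seq(1.02, 1.1, length.out = 5)))
  expect_gte(length(big) - length(base), 135L)

  # name collisions are rejected
  expect_error(expand_basis(ex, n_low_density = 9), "duplicate")
})

test_that("tissue tables round-trip through CSV and JSON", {
  basis <- fix_basis()
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_tissue_table(basis, path)
    back <- read_tissue_table(path)
    expect_identical(length(back), length(basis))
    for (i in seq_along(basis$tissues)) {
      a <- basis$tissues[[i]]
      b <- back$tissues[[i]]
      expect_identical(a$name, b$name)
      expect_equal(a$density, b$density, tolerance = 1e-9)
      expect_equal(b$fractions[names(a$fractions)], a$fractions,
                   tolerance = 1e-9)
    }
  }
})

test_that("invalid compositions are rejected", {
  expect_error(tissue("bad", c(H = 0.5, O = 0.6), 1), "sum to")
  expect_error(tissue("bad", c(H = -0.1, O = 1.1), 1), "negative")
  expect_error(tissue("bad", c(H = 0.112, O = 0.888), 0), "density")
})
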