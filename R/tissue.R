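#' Tissue composition objects
#'
#' A `tissue` is a named material: elemental weight fractions plus a mass
#' density. Weight fractions must be non-negative and close to unit sum
#' (closure within 1e-6). Densities must exceed 1e-4 g/cm3 (the near-zero
#' air entry is permitted at its physical 1.205e-3 g/cm3).
#'
#' @param name Material identifier (unique within a basis).
#' @param fractions Named numeric vector of elemental weight fractions
#'   (names are element symbols).
#' @param density Mass density in g/cm3.
#' @param category One of `"soft"`, `"spongiosa"`, `"bone"`,
#'   `"low_density"`, `"other"`.
#' @return An object of class `tissue`.
#' @export
#' @examples
#' water_composition()
tissue <- function(name, fractions, density,
                   category = c("other", "soft", "spongiosa", "bone",
                                "low_density")) {
  category <- match.arg(category)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("weight fractions must be a named vector of element symbols",
         call. = FALSE)
  fractions <- fractions[fractions != 0]
  if (any(fractions < 0))
    stop("negative weight fraction in '", name, "'", call. = FALSE)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-6)
    stop("weight fractions of '", name, "' sum to ", format(s),
         ", not 1 (tolerance 1e-6)", call. = FALSE)
  if (!is.numeric(density) || length(density) != 1L || density <= 1e-4)
    stop("mass density of '", name, "' must exceed 1e-4 g/cm3",
         call. = FALSE)
  structure(list(name = name, fractions = fractions,
                 density = density, category = category),
            class = "tissue")
}

#' @export
print.tissue <- function(x, ...) {
  cat("<tissue> ", x$name, " (", x$category, "), ",
      format(x$density), " g/cm3\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

is_tissue <- function(x) inherits(x, "tissue")

#' Built-in simple materials
#'
#' Water (from atomic weights of H2O), standard dry air
#' (N/O/Ar = 0.755/0.232/0.013 by mass, 1.205e-3 g/cm3), PMMA (C5H8O2,
#' 1.19 g/cm3) and hydroxyapatite Ca10(PO4)6(OH)2 (3.16 g/cm3).
#'
#' @param density Mass density in g/cm3 (water only; default 1).
#' @param elements Element table, see [element_table()].
#' @return A [tissue()] object.
#' @export
water_composition <- function(density = 1, elements = element_table()) {
  tissue("water", formula_fractions(c("H", "O"), c(2, 1), elements),
         density, "soft")
}

#' @rdname water_composition
#' @export
air_composition <- function(elements = element_table()) {
  tissue("air", c(N = 0.755, O = 0.232, Ar = 0.013), 1.205e-3,
         "low_density")
}

#' @rdname water_composition
#' @export
pmma_composition <- function(elements = element_table()) {
  tissue("pmma", formula_fractions(c("C", "H", "O"), c(5, 8, 2), elements),
         1.19, "other")
}

#' @rdname water_composition
#' @export
hydroxyapatite_composition <- function(elements = element_table()) {
  tissue("hydroxyapatite",
         formula_fractions(c("Ca", "P", "O", "H"), c(10, 6, 26, 2),
                           elements),
         3.16, "bone")
}

#' Electron density relative to water
#'
#' Computes `rho_m * sum(w_i Z_i / A_i)` for the material divided by the
#' same expression for water at 1 g/cm3. Linear in mass density at fixed
#' composition.
#'
#' @param comp A [tissue()].
#' @param elements Element table.
#' @return Dimensionless ratio to water (strictly positive).
#' @export
relative_electron_density <- function(comp, elements = element_table()) {
  stopifnot(is_tissue(comp))
  w <- water_composition(1, elements)
  comp$density * za_sum(comp$fractions, elements) /
    za_sum(w$fractions, elements)
}

#' Effective atomic number (power-mean convention)
#'
#' `(sum_i lambda_i Z_i^x)^(1/x)` with `lambda_i` the electron fractions.
#' The photoelectric and coherent-scatter terms of the stoichiometric CT
#' model use exponents 3.62 and 1.86; the dual-energy Z_eff maps use 3.3.
#'
#' @param comp A [tissue()].
#' @param exponent Positive power-mean exponent.
#' @param elements Element table.
#' @return Dimensionless effective atomic number, bounded by the smallest
#'   and largest Z present.
#' @export
effective_atomic_number <- function(comp, exponent,
                                    elements = element_table()) {
  stopifnot(is_tissue(comp), exponent > 0)
  if (length(comp$fractions) == 0L)
    stop("empty composition", call. = FALSE)
  lam <- electron_fractions(comp$fractions, elements)
  z <- elem_rows(names(comp$fractions), elements)$Z
  sum(lam * z^exponent)^(1 / exponent)
}

#' Mix materials by mass
#'
#' Weight fractions combine linearly in the mass fractions; the mixture
#' density follows ideal volume additivity,
#' `rho = 1 / sum_k(f_k / rho_k)`.
#'
#' @param tissues List of [tissue()] components.
#' @param fractions Mass fractions (non-negative, sum to 1 within 1e-6).
#' @param name Name for the mixture.
#' @param category Category for the mixture (default from first component).
#' @return A [tissue()].
#' @export
mix_by_mass <- function(tissues, fractions, name = "mixture",
                        category = NULL) {
  stopifnot(length(tissues) == length(fractions), length(tissues) >= 1L)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-6)
    stop("mass fractions must be non-negative and sum to 1 (tolerance 1e-6)",
         call. = FALSE)
  syms <- unique(unlist(lapply(tissues, function(t) names(t$fractions))))
  w <- stats::setNames(numeric(length(syms)), syms)
  for (k in seq_along(tissues)) {
    fk <- tissues[[k]]$fractions
    w[names(fk)] <- w[names(fk)] + fractions[k] * fk
  }
  density <- 1 / sum(fractions / vapply(tissues, `[[`, 0, "density"))
  if (is.null(category)) category <- tissues[[1L]]$category
  tissue(name, w, density, category)
}

#' Mix two materials by volume
#'
#' Densities combine linearly in the volume fraction; weight fractions are
#' the density-weighted mass average
#' `w_i = (f rho_a w_ia + (1-f) rho_b w_ib) / rho`.
#'
#' @param a,b [tissue()] components.
#' @param vol_fraction_a Volume fraction of `a` in `[0, 1]`.
#' @param name Name for the mixture.
#' @param category Category for the mixture (default from `a`).
#' @return A [tissue()].
#' @export
mix_by_volume <- function(a, b, vol_fraction_a, name = "mixture",
                          category = NULL) {
  stopifnot(is_tissue(a), is_tissue(b),
            vol_fraction_a >= 0, vol_fraction_a <= 1)
  f <- vol_fraction_a
  rho <- f * a$density + (1 - f) * b$density
  if (rho <= 0) stop("mixture density is zero", call. = FALSE)
  syms <- unique(c(names(a$fractions), names(b$fractions)))
  w <- stats::setNames(numeric(length(syms)), syms)
  w[names(a$fractions)] <- w[names(a$fractions)] +
    f * a$density * a$fractions
  w[names(b$fractions)] <- w[names(b$fractions)] +
    (1 - f) * b$density * b$fractions
  if (is.null(category)) category <- a$category
  tissue(name, w / rho, rho, category)
}

#' Rehydrate a dried sample
#'
#' Combustion analysis works on dehydrated material; the lost weight is
#' assumed to be pure water, so the wet composition is a mass mixture of
#' the dry residue (at `dry_mass_fraction`) with water.
#'
#' @param dry Dry-residue [tissue()].
#' @param dry_mass_fraction Dry mass fraction of the wet sample, in (0, 1].
#' @param name Name for the rehydrated tissue.
#' @param elements Element table.
#' @return A [tissue()].
#' @export
rehydrate <- function(dry, dry_mass_fraction, name = paste0(dry$name, "_wet"),
                      elements = element_table()) {
  if (!(dry_mass_fraction > 0 && dry_mass_fraction <= 1))
    stop("dry_mass_fraction must lie in (0, 1]", call. = FALSE)
  mix_by_mass(list(dry, water_composition(1, elements)),
              c(dry_mass_fraction, 1 - dry_mass_fraction),
              name = name, category = dry$category)
}

#' Ionization potential of a material by Bragg additivity
#'
#' `ln I = sum_i lambda_i ln I_i` over electron fractions, using the
#' elemental mean excitation energies of [element_table()]. Raw Bragg
#' additivity underestimates condensed-phase values; when `I_water` is
#' given, all results are scaled (a constant shift in `ln I`) so that
#' water evaluates exactly to `I_water` (the conventional anchor is
#' 78 eV).
#'
#' @param comp A [tissue()].
#' @param elements Element table.
#' @param I_water Optional water anchor in eV (e.g. 78); `NULL` returns
#'   the raw Bragg-additivity value.
#' @return Mean excitation energy in eV.
#' @export
tissue_ionization_potential <- function(comp, elements = element_table(),
                                        I_water = NULL) {
  stopifnot(is_tissue(comp))
  lam <- electron_fractions(comp$fractions, elements)
  ivals <- elem_rows(names(comp$fractions), elements)$I_eV
  ln_i <- sum(lam * log(ivals))
  if (!is.null(I_water)) {
    w <- water_composition(1, elements)
    lam_w <- electron_fractions(w$fractions, elements)
    i_w <- elem_rows(names(w$fractions), elements)$I_eV
    ln_i <- ln_i + (log(I_water) - sum(lam_w * log(i_w)))
  }
  exp(ln_i)
}
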