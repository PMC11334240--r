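#' Reference table of chemical elements
#'
#' Atomic numbers, IUPAC standard atomic weights and elemental mean
#' excitation energies for the elements that occur in human-tissue
#' composition tables. The mean excitation energies (`I_eV`) follow the
#' ICRU-37-style elemental values used for Bragg-additivity estimates of a
#' compound's ionization potential.
#'
#' @return A data frame with columns `symbol`, `Z` (atomic number),
#'   `A` (standard atomic weight, g/mol) and `I_eV` (mean excitation
#'   energy, eV).
#' @export
#' @examples
#' head(element_table())
element_table <- function() {
  data.frame(
    symbol = c("H", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P",
               "S", "Cl", "Ar", "K", "Ca", "Fe", "I"),
    Z = c(1L, 6L, 7L, 8L, 9L, 11L, 12L, 13L, 14L, 15L,
          16L, 17L, 18L, 19L, 20L, 26L, 53L),
    A = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305, 26.982,
          28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078, 55.845,
          126.904),
    I_eV = c(19.2, 78, 82, 95, 115, 149, 156, 166, 173, 173,
             180, 174, 188, 190, 191, 286, 491),
    stringsAsFactors = FALSE
  )
}

# Look up rows of the element table for a vector of symbols, with an
# explicit error naming any unknown symbol.
elem_rows <- function(symbols, elements = element_table()) {
  idx <- match(symbols, elements$symbol)
  if (anyNA(idx)) {
    bad <- symbols[is.na(idx)]
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  elements[idx, , drop = FALSE]
}

# Sum_i w_i Z_i / A_i for a named fraction vector (electrons per gram,
# in units of mol/g).
za_sum <- function(fractions, elements = element_table()) {
  rows <- elem_rows(names(fractions), elements)
  sum(fractions * rows$Z / rows$A)
}

# Electron fractions lambda_i = w_i Z_i/A_i / sum_j w_j Z_j/A_j.
electron_fractions <- function(fractions, elements = element_table()) {
  rows <- elem_rows(names(fractions), elements)
  x <- fractions * rows$Z / rows$A
  x / sum(x)
}

# Weight fractions of a chemical formula given element symbols and counts.
formula_fractions <- function(symbols, counts, elements = element_table()) {
  rows <- elem_rows(symbols, elements)
  m <- counts * rows$A
  stats::setNames(m / sum(m), symbols)
}
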