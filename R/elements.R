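# Periodic-table data used for validation, electron counting and bond
# perception. Radii are the Cordero et al. (2008) single-bond covalent radii
# in Angstrom (high-spin values for Mn/Fe/Co); they parameterize the
# distance-heuristic connectivity rules, which have no formally standardized
# values and are therefore explicit, versioned configuration here.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm"
)

.element_radii <- c(
  0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
  1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
  1.70, 1.60, 1.53, 1.39, 1.61, 1.52, 1.50, 1.24, 1.32, 1.22,
  1.22, 1.20, 1.19, 1.20, 1.20, 1.16, 2.20, 1.95, 1.90, 1.75,
  1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44, 1.42, 1.39,
  1.39, 1.38, 1.39, 1.40, 2.44, 2.15, 2.07, 2.04, 2.03, 2.01,
  1.99, 1.98, 1.98, 1.96, 1.94, 1.92, 1.92, 1.89, 1.90, 1.87,
  1.87, 1.75, 1.70, 1.62, 1.51, 1.44, 1.41, 1.36, 1.36, 1.32,
  1.45, 1.46, 1.48, 1.40, 1.50, 1.50, 2.60, 2.21, 2.15, 2.06,
  2.00, 1.96, 1.90, 1.87, 1.80, 1.69
)

#' Is a string a valid periodic-table element symbol?
#'
#' @param symbol character vector of candidate symbols.
#' @return logical vector.
#' @export
is_element <- function(symbol) {
  symbol %in% .element_symbols
}

#' Atomic number of an element symbol
#'
#' @param symbol character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(symbol) {
  idx <- match(symbol, .element_symbols)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  as.integer(idx)
}

#' Single-bond covalent radii
#'
#' Returns the bundled covalent radius table (Cordero et al. 2008 values,
#' Angstrom) used by [perceive_connectivity()]. The distance heuristic for
#' bond perception is not a formal standard, so the table is exposed as
#' replaceable configuration rather than hidden inside the perception code.
#'
#' @return named numeric vector, element symbol -> radius in Angstrom.
#' @export
covalent_radii <- function() {
  stats::setNames(.element_radii, .element_symbols)
}
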