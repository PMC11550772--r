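# Standard atomic weights (IUPAC 2021, conventional values) for the elements
# that occur in the built-in material library.
.element_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  Si = 28.0855, S = 32.06, Ge = 72.63, Mo = 95.95, W = 183.84,
  He = 4.0026, Ne = 20.1797, Ar = 39.948, Fe = 55.845, Cu = 63.546,
  Al = 26.9815, P = 30.9738, Se = 78.971, Te = 127.60
)

#' Atomic mass lookup
#'
#' @param species character vector of element symbols.
#' @return numeric vector of atomic masses in amu.
#' @keywords internal
element_mass <- function(species) {
  m <- .element_masses[species]
  if (anyNA(m)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(species[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Check element symbols
#' @keywords internal
is_valid_element <- function(species) {
  grepl("^[A-Z][a-z]?$", species)
}
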