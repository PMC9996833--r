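# element symbols, indexed by atomic number
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

#' Atomic number of an element symbol
#'
#' @param symbol character vector of element symbols (case sensitive, e.g.
#'   `"Fe"`).
#' @return integer vector of atomic numbers.
#' @export
element_number <- function(symbol) {
  z <- match(symbol, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  z
}
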