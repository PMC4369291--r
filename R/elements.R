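#' Periodic-table element symbols
#'
#' The 118 IUPAC element symbols. An atom whose element token is not in this
#' set (and carries no inline abbreviation) makes the record a template or a
#' query rather than a molecule; the data model itself never rejects such
#' tokens -- chemical meaning is assigned only by formula inference and
#' validation.
#'
#' @format Character vector of length 118.
#' @export
PERIODIC_TABLE <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Is a token a periodic-table element symbol?
#'
#' @param token Character vector of element tokens.
#' @return Logical vector.
#' @export
is_element <- function(token) token %in% PERIODIC_TABLE

ALKALI_METALS <- c("Li", "Na", "K", "Rb", "Cs", "Fr")
HALOGENS <- c("F", "Cl", "Br", "I", "At")
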