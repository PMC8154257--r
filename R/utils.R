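## Shared constants and small helpers.

## Bohr radius in Angstrom (CODATA); all Slater exponents are stored in
## bohr^-1, all user-facing coordinates and distances are in Angstrom.
BOHR_A <- 0.529177210903

#' Bohr radius in Angstrom
#'
#' Conversion constant used throughout: exponents are handled in bohr^-1
#' (atomic units), coordinates in Angstrom.
#'
#' @return The Bohr radius in Angstrom (scalar).
#' @export
bohr_radius <- function() BOHR_A

## Element symbols indexed by atomic number, H..U. Used to resolve the
## atomic numbers N_L / N_E that enter the normalisation term.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U"
)

#' Atomic number of an element symbol
#'
#' @param element Character vector of element symbols (case-normalised
#'   internally, e.g. `"CL"` resolves to chlorine).
#' @param extra_elements Optional named integer vector assigning atomic
#'   numbers to non-standard (pseudo) element symbols, as used by the
#'   synthetic fixtures.
#' @return Integer vector of atomic numbers; unknown symbols raise an error.
#' @export
atomic_number <- function(element, extra_elements = NULL) {
  sym <- paste0(toupper(substr(element, 1, 1)), tolower(substr(element, 2, 2)))
  z <- match(sym, .ELEMENTS)
  if (!is.null(extra_elements)) {
    miss <- is.na(z)
    z[miss] <- unname(extra_elements[element[miss]])
  }
  if (anyNA(z)) {
    stop("unsupported element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

## format a numeric for deterministic text export: 6 significant digits
.fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
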