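# Atomic numbers for the elements that occur in DNA-stabilized cluster work
# (organics, common counter-ions, coinage metals and halides). Used as the
# Q -> 0 scattering weight f = Z.
.atomic_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30,
  Br = 35, Rb = 37, Sr = 38, Pd = 46, Ag = 47, Cd = 48, I = 53, Cs = 55,
  Ba = 56, Pt = 78, Au = 79, Hg = 80, Pb = 82
)

#' Scattering weight of an element
#'
#' Returns the per-element scattering weight used to weight atom pairs in the
#' PDF. The weight is the atomic number Z, i.e. the Q -> 0 limit of the X-ray
#' form factor; in real space the relative weighting of e.g. Ag-Ag against
#' Ag-Cl pairs is dominated by Z.
#'
#' @param element Character vector of element symbols (case-sensitive, e.g.
#'   `"Ag"`, `"Cl"`).
#' @return Numeric vector of weights (dimensionless, > 0).
#' @examples
#' element_weight(c("Ag", "Cl"))
#' @export
element_weight <- function(element) {
  z <- .atomic_numbers[element]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    abort(paste0("Unknown element symbol(s): ", paste(bad, collapse = ", ")),
          class = "clusterpdf_validation_error")
  }
  unname(z)
}

.known_element <- function(element) element %in% names(.atomic_numbers)
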