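# Element data used across the package.
#
# Covalent radii are Pyykko & Atsumi single-bond radii (Angstrom). The table
# covers the elements realistically seen in TS conformer work; anything absent
# is treated as an unknown element by the Structure validator.

.element_radii <- c(
  H = 0.32, He = 0.46,
  Li = 1.33, Be = 1.02, B = 0.85, C = 0.75, N = 0.71, O = 0.63, F = 0.64,
  Ne = 0.67, Na = 1.55, Mg = 1.39, Al = 1.26, Si = 1.16, P = 1.11, S = 1.03,
  Cl = 0.99, Ar = 0.96, K = 1.96, Ca = 1.71, Sc = 1.48, Ti = 1.36, V = 1.34,
  Cr = 1.22, Mn = 1.19, Fe = 1.16, Co = 1.11, Ni = 1.10, Cu = 1.12, Zn = 1.18,
  Ga = 1.24, Ge = 1.21, As = 1.21, Se = 1.16, Br = 1.14, Kr = 1.17,
  Rb = 2.10, Sr = 1.85, Zr = 1.54, Mo = 1.38, Ru = 1.25, Rh = 1.25,
  Pd = 1.20, Ag = 1.28, Cd = 1.36, In = 1.42, Sn = 1.40, Sb = 1.40,
  Te = 1.36, I = 1.33, Xe = 1.31, Cs = 2.32, Ba = 1.96,
  W = 1.37, Re = 1.31, Os = 1.29, Ir = 1.22, Pt = 1.23, Au = 1.24,
  Hg = 1.33, Tl = 1.44, Pb = 1.44, Bi = 1.51
)

# Elements the organic (MMFF94-class) parameter tier accepts; everything in
# .element_radii is accepted by the universal (UFF-class) tier.
.organic_elements <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# Standard valences used by bond-order perception (smallest listed value that
# is >= the observed degree is targeted).
.standard_valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

#' Look up covalent radii
#'
#' Single-bond covalent radii (Pyykko) for a vector of element symbols.
#'
#' @param symbols character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @keywords internal
covalent_radius <- function(symbols) {
  r <- .element_radii[symbols]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

is_known_element <- function(symbols) symbols %in% names(.element_radii)

is_heavy <- function(symbols) symbols != "H"
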