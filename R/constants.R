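# Unit conversions and element data.  All package-internal energies are in
# eV and distances in Angstrom; conversions live here and nowhere else.

#' Physical constants used throughout the package
#'
#' `coulomb_ev_angstrom` is e^2/(4 pi eps0) expressed in eV * Angstrom, the
#' large-distance limit of the two-center repulsion integral.
#'
#' @format Named list with elements `coulomb_ev_angstrom`, `hartree_ev`,
#'   `bohr_angstrom`.
#' @export
pppConstants <- list(
  coulomb_ev_angstrom = 14.397,
  hartree_ev          = 27.2114,
  bohr_angstrom       = 0.529177
)

# Single-bond covalent radii (Angstrom), Cordero-type values.  Connectivity
# perception bonds two atoms when their distance is below
# cutoff_scale * (r_i + r_j).
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.73, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

.supported_elements <- function() names(.covalent_radii)

.covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(.supported_elements(), collapse = ", "),
         call. = FALSE)
  }
  unname(r)
}
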