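# Overlap integrals between Slater 2p orbitals, evaluated exactly via the
# classical auxiliary-integral recursions in prolate spheroidal coordinates:
#   A_k(p) = int_1^inf  x^k exp(-p x) dx
#   B_k(q) = int_-1^1   x^k exp(-q x) dx
# For 2p-2p pairs with exponents za, zb at distance R (p = R(za+zb)/2,
# q = R(za-zb)/2):
#   S_pi    = (za zb)^{5/2} R^5 / 32 * [A4(B0-B2) - A2(B0-B4) - A0(B4-B2)]
#   S_sigma = (za zb)^{5/2} R^5 / 16 * [A4 B2 - A2 B4 - A2 B0 + A0 B2]
# (sigma with both lobes along the +z internuclear axis, so S_sigma -> 1 as
# R -> 0 for equal exponents).

.aux_A <- function(kmax, p) {
  A <- numeric(kmax + 1L)
  ep <- exp(-p)
  A[1L] <- ep / p
  for (k in seq_len(kmax)) A[k + 1L] <- (ep + k * A[k]) / p
  A
}

.aux_B <- function(kmax, q) {
  B <- numeric(kmax + 1L)
  if (abs(q) < 1e-6) {
    # series around q = 0 to avoid catastrophic cancellation
    for (k in 0:kmax) {
      s <- 0
      for (t in 0:12) {
        if ((k + t) %% 2L == 0L) s <- s + (-q)^t / factorial(t) * 2 / (k + t + 1)
      }
      B[k + 1L] <- s
    }
  } else {
    eq <- exp(q); emq <- exp(-q)
    B[1L] <- (eq - emq) / q
    for (k in seq_len(kmax)) {
      B[k + 1L] <- (k * B[k] + (-1)^k * eq - emq) / q
    }
  }
  B
}

#' Overlap of two Slater 2p orbitals
#'
#' Exact evaluation via the auxiliary-integral recursion; this is the
#' default path for the resonance integral.  `orientation = "pi"` is the
#' side-by-side overlap relevant for planar conjugation; `"sigma"` is the
#' head-on overlap of p orbitals aligned with the internuclear axis.
#'
#' @param za,zb Slater exponents (1/Angstrom).
#' @param r Internuclear distance (Angstrom).
#' @param orientation `"pi"` or `"sigma"`.
#' @return Dimensionless overlap in \[-1, 1\].
#' @export
#' @examples
#' slater2pOverlap(1.28, 1.28, 1.4)          # C-C pi overlap at bond distance
#' slater2pOverlap(1.28, 1.28, 0)            # self-overlap = 1
slater2pOverlap <- function(za, zb, r, orientation = c("pi", "sigma")) {
  orientation <- match.arg(orientation)
  if (za <= 0 || zb <= 0) stop("Slater exponents must be positive", call. = FALSE)
  if (r < 0) stop("negative distance", call. = FALSE)
  if (r < 1e-10) {
    # same-center limit: 1 for equal exponents, else the radial overlap
    return((2 * sqrt(za * zb) / (za + zb))^5)
  }
  p <- r * (za + zb) / 2
  q <- r * (za - zb) / 2
  A <- .aux_A(4L, p)
  B <- .aux_B(4L, q)
  pref <- (za * zb)^2.5 * r^5
  if (orientation == "pi") {
    pref / 32 * (A[5] * (B[1] - B[3]) - A[3] * (B[1] - B[5]) - A[1] * (B[5] - B[3]))
  } else {
    pref / 16 * (A[5] * B[3] - A[3] * B[5] - A[3] * B[1] + A[1] * B[3])
  }
}

#' Overlap between two parameterized pi-center types
#'
#' Resolves Slater exponents from the valence-state table and calls
#' [slater2pOverlap()] (or the spline fast path).
#'
#' @param vt_r,vt_s Valence-type keys, e.g. `"C.sp2"`.
#' @param r Distance (Angstrom).
#' @param orientation `"pi"` or `"sigma"`.
#' @param table Valence-state table.
#' @param method `"exact"` (default) or `"spline"`.
#' @export
slaterOverlap <- function(vt_r, vt_s, r, orientation = c("pi", "sigma"),
                          table = defaultValenceTable(),
                          method = c("exact", "spline")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  za <- .valence_entry(vt_r, table)$zeta
  zb <- .valence_entry(vt_s, table)$zeta
  if (method == "exact") {
    slater2pOverlap(za, zb, r, orientation)
  } else {
    splineOverlap(za, zb, r, orientation)
  }
}

# Spline fast path: one interpolant per (za, zb, orientation) triple,
# cached across calls.  Outside the tabulated grid we fall back to the
# exact recursion.
.spline_cache <- new.env(parent = emptyenv())
.spline_grid <- seq(0.5, 6, by = 0.02)

#' Spline-interpolated Slater 2p overlap
#'
#' Fast path over a precomputed distance grid (0.5-6 Angstrom, natural
#' cubic spline through exact values).  Distances outside the grid fall
#' back to the exact recursion.
#'
#' @inheritParams slater2pOverlap
#' @export
splineOverlap <- function(za, zb, r, orientation = c("pi", "sigma")) {
  orientation <- match.arg(orientation)
  if (r < min(.spline_grid) || r > max(.spline_grid)) {
    return(slater2pOverlap(za, zb, r, orientation))
  }
  key <- sprintf("%.6f|%.6f|%s", za, zb, orientation)
  fn <- .spline_cache[[key]]
  if (is.null(fn)) {
    vals <- vapply(.spline_grid, function(d) slater2pOverlap(za, zb, d, orientation),
                   numeric(1L))
    fn <- stats::splinefun(.spline_grid, vals, method = "natural")
    .spline_cache[[key]] <- fn
  }
  fn(r)
}
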