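# Deterministic model-system generators.  All generators are pure
# functions of their arguments; regeneration is bit-identical.

#' Idealized D2h pentalene
#'
#' Eight sp2 carbons as two regular pentagons fused on one edge, planar,
#' all nine C-C bonds exactly equal to `bond`.  This is the classic
#' model system whose vertical singlet-triplet gap is inverted.
#'
#' @param bond C-C bond length in Angstrom (default 1.4).
#' @return A [geometry()] object.
#' @export
pentaleneD2h <- function(bond = 1.4) {
  if (bond <= 0) stop("bond length must be positive", call. = FALSE)
  Rc <- bond / (2 * sin(pi / 5))   # pentagon circumradius
  ap <- bond / (2 * tan(pi / 5))   # pentagon apothem
  pts <- rbind(c(0, bond / 2), c(0, -bond / 2))  # shared edge on the y axis
  for (sgn in c(1, -1)) {
    cx <- sgn * ap
    ang0 <- atan2(bond / 2, -cx)   # angle of shared vertex (0, b/2) from center
    for (k in 1:4) {
      ang <- ang0 - sgn * 2 * pi * k / 5
      p <- c(cx + Rc * cos(ang), Rc * sin(ang))
      if (abs(p[1]) < 1e-9 && abs(p[2] + bond / 2) < 1e-9) next  # other shared vertex
      pts <- rbind(pts, p)
    }
  }
  geometry(rep("C", 8), cbind(pts, 0), id = "pentalene_D2h")
}

#' Regular polygon ring
#'
#' @param n Number of atoms (>= 3).
#' @param bond Edge length in Angstrom.
#' @param element Element symbol for every vertex.
#' @return A [geometry()] object (e.g. n = 4 gives square cyclobutadiene,
#'   n = 6 benzene).
#' @export
ringPolygon <- function(n, bond = 1.4, element = "C") {
  if (n < 3L) stop("need at least 3 atoms", call. = FALSE)
  Rc <- bond / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  geometry(rep(element, n), cbind(Rc * cos(ang), Rc * sin(ang), 0),
           id = sprintf("ring_%s%d", element, n))
}

#' All-trans polyene chain
#'
#' Planar zigzag carbon chain with equal bond lengths and 120-degree
#' internal angles; `n = 4` is s-trans butadiene.
#'
#' @param n Number of carbons (>= 2).
#' @param bond Bond length in Angstrom.
#' @return A [geometry()] object.
#' @export
polyeneChain <- function(n = 4L, bond = 1.4) {
  if (n < 2L) stop("need at least 2 atoms", call. = FALSE)
  xs <- cumsum(c(0, rep(bond * cos(pi / 6), n - 1L)))
  ys <- bond * sin(pi / 6) * (seq_len(n) %% 2L)
  geometry(rep("C", n), cbind(xs, ys, 0), id = sprintf("polyene_C%d", n))
}

#' Twisted two-ene fixture
#'
#' Four-carbon chain in which the terminal CC units are rotated against
#' each other by `theta` degrees about the central bond; the central
#' bond's twist angle equals `theta` exactly (one dihedral on each side,
#' both equal).  Used to exercise the twist-angle attenuation of the
#' resonance integral.
#'
#' @param theta Twist angle in degrees.
#' @param bond Bond length in Angstrom.
#' @export
twistedDiene <- function(theta = 45, bond = 1.4) {
  c2 <- c(0, 0, 0)
  c3 <- c(bond, 0, 0)
  d <- bond * c(-cos(pi / 3), sin(pi / 3), 0)           # in-plane substituent
  th <- theta * pi / 180
  rot <- function(v) c(v[1], cos(th) * v[2], sin(th) * v[2])  # about the x axis
  c1 <- c2 + d
  c4 <- c3 + rot(c(-d[1], d[2], 0))
  geometry(rep("C", 4), rbind(c1, c2, c3, c4), id = sprintf("diene_%gdeg", theta))
}

#' Idealized cyclazine (synthetic azaphenalene stand-in)
#'
#' Cyclazine-type azaphenalene built on an ideal honeycomb patch: a
#' central pyrrole-type nitrogen fused into three six-membered rings of
#' sp2 carbons, all bonds equal to `bond`.  This is a synthetic idealized
#' geometry for demonstrations and heteroatom tests -- published gap
#' values for azaphenalene refer to DFT-optimized structures, which this
#' deliberately is not.
#'
#' @param bond Bond length in Angstrom (default 1.40).
#' @return A [geometry()] object with 13 heavy atoms and 14 pi electrons
#'   downstream.
#' @export
cyclazineIdealized <- function(bond = 1.40) {
  pts <- matrix(numeric(0), 0, 2)
  for (ca in c(pi / 6, 5 * pi / 6, 3 * pi / 2)) {  # three fused hexagons
    cx <- bond * cos(ca); cy <- bond * sin(ca)
    for (k in 0:5) {
      a <- ca + pi + k * pi / 3
      p <- c(cx + bond * cos(a), cy + bond * sin(a))
      if (!any(abs(pts[, 1] - p[1]) < 1e-6 & abs(pts[, 2] - p[2]) < 1e-6)) {
        pts <- rbind(pts, p)
      }
    }
  }
  stopifnot(nrow(pts) == 13L)
  ord <- order(round(sqrt(rowSums(pts^2)), 6), atan2(pts[, 2], pts[, 1]))
  pts <- pts[ord, , drop = FALSE]   # central atom first
  geometry(c("N", rep("C", 12)), cbind(pts, 0), id = "cyclazine_idealized")
}
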