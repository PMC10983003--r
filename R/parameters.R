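# The four PPP parameters, all derived from valence-state IP/EA data:
#   U_r       = -IP_v - (n_r - 1) gamma_rr      atomic valence-state potential
#   gamma_rr  = IP_v - EA_v                     Pariser-Parr one-center repulsion
#   gamma_rs  = k_e / sqrt(r^2 + a_rs^2),       a_rs = 2 k_e / (gamma_rr+gamma_ss)
#   beta_rs   = -C S_rs (IP_r + IP_s)/2 cos(theta_rs),   C = 0.545
# with k_e = 14.397 eV Angstrom.  The core matrix is
#   H_rr = U_r - sum_{s != r} Z_s gamma_rs,   H_rs = beta_rs.

#' One-center electron repulsion integral
#'
#' Pariser-Parr approximation: `gamma_rr = IP_v - EA_v`.
#'
#' @param vt Valence-type key (e.g. `"C.sp2"`).
#' @param table Valence-state table.
#' @return gamma_rr in eV.
#' @export
#' @examples
#' oneCenterRepulsion("C.sp2")   # 11.13 eV
oneCenterRepulsion <- function(vt, table = defaultValenceTable()) {
  e <- .valence_entry(vt, table)
  e$ip_ev - e$ea_ev
}

# numeric core used by the matrix assembly
.gamma_rs <- function(g_rr, g_ss, r) {
  ke <- pppConstants$coulomb_ev_angstrom
  a <- 2 * ke / (g_rr + g_ss)
  ke / sqrt(r^2 + a^2)
}

#' Two-center electron repulsion integral
#'
#' Ohno-type interpolation between the one-center limit
#' `(gamma_rr + gamma_ss)/2` at r = 0 and the bare Coulomb law
#' `14.397/r` eV at large separation; smooth and strictly decreasing
#' in the distance.
#'
#' @param vt_r,vt_s Valence-type keys.
#' @param r Distance in Angstrom (>= 0).
#' @param table Valence-state table.
#' @return gamma_rs in eV.
#' @export
twoCenterRepulsion <- function(vt_r, vt_s, r, table = defaultValenceTable()) {
  if (any(r < 0)) stop("negative distance", call. = FALSE)
  .gamma_rs(oneCenterRepulsion(vt_r, table), oneCenterRepulsion(vt_s, table), r)
}

#' Two-center resonance integral
#'
#' Beveridge-Hinze/Ohno form scaled by the twist attenuation:
#' `beta = -C * S_pi * (IP_r + IP_s)/2 * cos(theta)`, negative for bonded
#' pairs (bonding stabilization, Hueckel sign convention) and zero at
#' theta = 90 degrees.
#'
#' @param vt_r,vt_s Valence-type keys.
#' @param r Bond distance (Angstrom).
#' @param theta Twist angle between the two p orbitals in degrees
#'   (default 0).
#' @param C Empirical scale constant (default 0.545).
#' @param table Valence-state table.
#' @param method Overlap path, `"exact"` or `"spline"`.
#' @return beta_rs in eV.
#' @export
resonanceIntegral <- function(vt_r, vt_s, r, theta = 0, C = 0.545,
                              table = defaultValenceTable(),
                              method = c("exact", "spline")) {
  method <- match.arg(method)
  er <- .valence_entry(vt_r, table); es <- .valence_entry(vt_s, table)
  S <- if (method == "exact") slater2pOverlap(er$zeta, es$zeta, r, "pi")
       else splineOverlap(er$zeta, es$zeta, r, "pi")
  -C * S * (er$ip_ev + es$ip_ev) / 2 * cos(theta * pi / 180)
}

#' Assemble the full PPP parameter set for a pi system
#'
#' @param ps A `ppp_pi_system` from [perceivePiSystem()].
#' @param g The parent [geometry()].
#' @param table Valence-state table.
#' @param overlap_method `"exact"` or `"spline"` path for the resonance
#'   integrals.
#' @param C Resonance-integral scale constant.
#' @return Object of class `ppp_parameters` with elements `n`, `U`, `Z`,
#'   `gamma`, `beta`, `Hcore`, `coords`, `n_electrons`, `types`.
#' @export
buildParameterSet <- function(ps, g, table = defaultValenceTable(),
                              overlap_method = c("exact", "spline"),
                              C = 0.545) {
  overlap_method <- match.arg(overlap_method)
  ent <- .valence_entry(ps$types, table)
  n <- length(ps$centers)
  coords <- g$coords[ps$centers, , drop = FALSE]
  g_rr <- ent$ip_ev - ent$ea_ev
  Z <- as.numeric(ent$n_pi)
  U <- -ent$ip_ev - (ent$n_pi - 1) * g_rr

  d <- .distance_matrix(coords)
  gamma <- matrix(0, n, n)
  for (r in seq_len(n)) for (s in seq_len(n)) {
    gamma[r, s] <- if (r == s) g_rr[r] else .gamma_rs(g_rr[r], g_rr[s], d[r, s])
  }

  beta <- matrix(0, n, n)
  for (r in seq_len(n)) for (s in seq_len(n)) {
    if (s > r && ps$adjacency[r, s]) {
      S <- if (overlap_method == "exact") {
        slater2pOverlap(ent$zeta[r], ent$zeta[s], d[r, s], "pi")
      } else {
        splineOverlap(ent$zeta[r], ent$zeta[s], d[r, s], "pi")
      }
      b <- -C * S * (ent$ip_ev[r] + ent$ip_ev[s]) / 2 *
        cos(ps$twist[r, s] * pi / 180)
      beta[r, s] <- beta[s, r] <- b
    }
  }

  Hcore <- beta
  diag(Hcore) <- U - (gamma %*% Z - diag(gamma) * Z)

  structure(list(n = n, U = U, Z = Z, gamma = gamma, beta = beta,
                 Hcore = Hcore, coords = coords,
                 n_electrons = ps$n_electrons, types = ps$types),
            class = "ppp_parameters")
}

#' @export
print.ppp_parameters <- function(x, ...) {
  cat("<ppp_parameters> ", x$n, " centers, ", x$n_electrons, " electrons; ",
      sum(x$beta[upper.tri(x$beta)] != 0), " bonded pairs\n", sep = "")
  cat(sprintf("  gamma_rr range: %.2f..%.2f eV; beta range: %.2f..%.2f eV\n",
              min(diag(x$gamma)), max(diag(x$gamma)),
              min(x$beta), max(x$beta[x$beta != 0], 0)))
  invisible(x)
}
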