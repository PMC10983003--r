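# Independent brute-force oracles.  These deliberately avoid the
# production code paths: excited states are built in an explicit
# determinant basis with Slater-Condon rules and classified by total spin,
# exchange integrals are direct quadruple sums, the transition dipole is
# assembled by operator algebra over determinants, and the Slater overlap
# is a 3D numerical quadrature.  They exist to validate the fast
# implementations on small systems.

# ---- determinant machinery -------------------------------------------------
# Spin orbitals: 2p-1 = p(alpha), 2p = p(beta), p = spatial MO index.
# A determinant is a sorted integer vector of occupied spin orbitals.

.so_spatial <- function(so) (so + 1L) %/% 2L
.so_spin <- function(so) so %% 2L          # 1 = alpha, 0 = beta

# remove listed spin orbitals from a sorted det, tracking the fermionic sign
.det_align <- function(det, moved) {
  ph <- 1
  for (m in moved) {
    k <- match(m, det)
    ph <- ph * (-1)^(k - 1L)
    det <- det[-k]
  }
  list(rest = det, phase = ph)
}

# <d1|H|d2> by the Slater-Condon rules; h is the MO one-electron matrix,
# eri(p,q,r,s) the chemists' (pq|rs) over spatial MOs
.sc_element <- function(d1, d2, h, eri) {
  diff1 <- setdiff(d1, d2); diff2 <- setdiff(d2, d1)
  nd <- length(diff1)
  if (nd > 2L) return(0)
  a1 <- .det_align(d1, diff1); a2 <- .det_align(d2, diff2)
  ph <- a1$phase * a2$phase
  common <- a1$rest
  phys <- function(P, Q, R, S) {   # <PQ|RS> over spin orbitals
    if (.so_spin(P) != .so_spin(R) || .so_spin(Q) != .so_spin(S)) return(0)
    eri(.so_spatial(P), .so_spatial(R), .so_spatial(Q), .so_spatial(S))
  }
  if (nd == 0L) {
    E <- sum(vapply(d1, function(p) h[.so_spatial(p), .so_spatial(p)], 0))
    for (ii in seq_along(d1)) {
      for (jj in seq_len(ii - 1L)) {
        p <- d1[ii]; q <- d1[jj]
        E <- E + phys(p, q, p, q) - phys(p, q, q, p)
      }
    }
    return(E)
  }
  if (nd == 1L) {
    p <- diff1; q <- diff2
    if (.so_spin(p) != .so_spin(q)) return(0)
    v <- h[.so_spatial(p), .so_spatial(q)]
    for (k in common) v <- v + phys(p, k, q, k) - phys(p, k, k, q)
    return(ph * v)
  }
  p1 <- diff1[1L]; p2 <- diff1[2L]; q1 <- diff2[1L]; q2 <- diff2[2L]
  ph * (phys(p1, p2, q1, q2) - phys(p1, p2, q2, q1))
}

# apply a_q^dagger a_p to a sorted det; NULL when annihilated
.sc_excite <- function(det, p, q) {
  k <- match(p, det)
  if (is.na(k) || q %in% det) return(NULL)
  ph <- (-1)^(k - 1L)
  rest <- det[-k]
  pos <- sum(rest < q)
  ph <- ph * (-1)^pos
  list(det = sort(c(rest, q)), phase = ph)
}

.det_key <- function(d) paste(d, collapse = ",")

# ---- brute-force CIS -------------------------------------------------------

#' Brute-force CIS oracle in an explicit determinant basis
#'
#' Builds every singly excited determinant with M_s = 0, evaluates all
#' Hamiltonian matrix elements with Slater-Condon rules from the ZDO
#' integral table, diagonalizes, and classifies the eigenstates as
#' singlet or triplet through the total-spin operator S^2 (applied as
#' S-S+ over determinants).  Completely independent of the spin-adapted
#' production [cis()] build.
#'
#' @param scf A `ppp_scf` result.
#' @param params Parameter set.
#' @param multiplicity `"singlet"` or `"triplet"`.
#' @param max_orbitals Refuse larger systems (default 10).
#' @return Ascending excitation energies (eV) of the requested spin.
#' @export
bruteForceCis <- function(scf, params = scf$params,
                          multiplicity = c("singlet", "triplet"),
                          max_orbitals = 10L) {
  multiplicity <- match.arg(multiplicity)
  n <- params$n
  if (n > max_orbitals) {
    stop("brute-force oracle refuses systems with more than ", max_orbitals,
         " orbitals", call. = FALSE)
  }
  nocc <- scf$n_occ
  C <- scf$C; G <- params$gamma
  h <- crossprod(C, params$Hcore %*% C)
  eri <- function(p, q, r, s) {
    drop(crossprod(C[, p] * C[, q], G %*% (C[, r] * C[, s])))
  }
  ground <- sort(c(2L * seq_len(nocc) - 1L, 2L * seq_len(nocc)))
  dets <- list()
  for (i in seq_len(nocc)) {
    for (a in seq(nocc + 1L, n)) {
      for (spin in c(1L, 0L)) {   # alpha, beta
        p <- 2L * i - (spin == 1L)
        q <- 2L * a - (spin == 1L)
        ex <- .sc_excite(ground, p, q)
        dets[[length(dets) + 1L]] <- ex$det   # phase irrelevant for the basis
      }
    }
  }
  N <- length(dets)
  H <- matrix(0, N, N)
  for (I in seq_len(N)) for (J in I:N) {
    H[I, J] <- H[J, I] <- .sc_element(dets[[I]], dets[[J]], h, eri)
  }
  E0 <- .sc_element(ground, ground, h, eri)
  # S^2 = S-S+ in the Ms = 0 space: build S+ into the Ms = 1 det space
  plus_map <- new.env(parent = emptyenv())
  triplets <- list()
  Sp <- list()
  for (I in seq_len(N)) {
    terms <- list()
    for (p in seq_len(n)) {
      ex <- .sc_excite(dets[[I]], 2L * p, 2L * p - 1L)  # beta -> alpha
      if (is.null(ex)) next
      key <- .det_key(ex$det)
      if (is.null(plus_map[[key]])) {
        triplets[[length(triplets) + 1L]] <- ex$det
        plus_map[[key]] <- length(triplets)
      }
      terms[[length(terms) + 1L]] <- c(plus_map[[key]], ex$phase)
    }
    Sp[[I]] <- terms
  }
  M <- length(triplets)
  SpM <- matrix(0, M, N)
  for (I in seq_len(N)) for (t in Sp[[I]]) SpM[t[1L], I] <- SpM[t[1L], I] + t[2L]
  S2 <- crossprod(SpM)
  # diagonalize H + mu*S2 so eigenvectors stay spin-pure even when a
  # singlet and a triplet root are accidentally degenerate
  mu <- 17.23
  ev <- eigen(H + mu * S2, symmetric = TRUE)
  s2val <- vapply(seq_len(N), function(k) {
    v <- ev$vectors[, k]; drop(crossprod(v, S2 %*% v))
  }, 0)
  energies <- vapply(seq_len(N), function(k) {
    v <- ev$vectors[, k]; drop(crossprod(v, H %*% v))
  }, 0)
  keep <- if (multiplicity == "singlet") s2val < 1 else s2val >= 1
  sort(energies[keep] - E0)
}

#' Brute-force exchange integral by direct summation
#'
#' Explicit quadruple loop over centers, independent of the vectorized
#' production path.
#'
#' @param C MO coefficient matrix (or a `ppp_scf`).
#' @param gamma Electron-repulsion matrix.
#' @param i,j MO indices.
#' @export
bruteForceExchange <- function(C, gamma, i, j) {
  if (inherits(C, "ppp_scf")) C <- C$C
  n <- nrow(C)
  K <- 0
  for (r in seq_len(n)) {
    for (s in seq_len(n)) {
      K <- K + C[r, i] * C[r, j] * gamma[r, s] * C[s, i] * C[s, j]
    }
  }
  K
}

#' Oscillator strength oracle via determinant operator algebra
#'
#' Re-derives the transition dipole of a singlet CIS root by applying the
#' second-quantized excitation operators to the ground determinant and
#' evaluating the one-electron dipole operator with Slater-Condon rules,
#' then forms f = (2/3) dE |mu|^2 in atomic units.
#'
#' @param scf A `ppp_scf` result.
#' @param params Parameter set.
#' @param cis_result Singlet `ppp_cis`.
#' @param root Root index.
#' @export
oscillatorStrengthOracle <- function(scf, params, cis_result, root = 1L) {
  stopifnot(cis_result$multiplicity == "singlet")
  n <- params$n; nocc <- scf$n_occ
  C <- scf$C
  mo_dip <- lapply(1:3, function(ax) crossprod(C, params$coords[, ax] * C))
  ground <- sort(c(2L * seq_len(nocc) - 1L, 2L * seq_len(nocc)))
  # <0| mu |d> for a det d differing by one spin orbital
  dip_elem <- function(d) {
    diff1 <- setdiff(ground, d); diff2 <- setdiff(d, ground)
    if (length(diff1) != 1L) return(c(0, 0, 0))
    if (.so_spin(diff1) != .so_spin(diff2)) return(c(0, 0, 0))
    a1 <- .det_align(ground, diff1); a2 <- .det_align(d, diff2)
    ph <- a1$phase * a2$phase
    p <- .so_spatial(diff1); q <- .so_spatial(diff2)
    ph * vapply(mo_dip, function(m) m[p, q], 0)
  }
  mu <- c(0, 0, 0)
  pr <- cis_result$pairs
  for (k in seq_len(nrow(pr))) {
    t_k <- cis_result$amplitudes[k, root]
    for (spin in c(1L, 0L)) {
      p <- 2L * pr$i[k] - (spin == 1L)
      q <- 2L * pr$a[k] - (spin == 1L)
      ex <- .sc_excite(ground, p, q)
      mu <- mu + t_k / sqrt(2) * ex$phase * dip_elem(ex$det)
    }
  }
  de <- cis_result$roots[root] / pppConstants$hartree_ev
  (2 / 3) * de * sum((mu / pppConstants$bohr_angstrom)^2)
}

#' Slater 2p overlap by 3D numerical quadrature
#'
#' Independent check of the closed-form recursion: integrates the orbital
#' product in cylindrical coordinates with nested adaptive quadrature,
#' splitting the axial integral at the two nuclear cusps.
#'
#' @inheritParams slater2pOverlap
#' @export
slaterOverlapQuadrature <- function(za, zb, r, orientation = c("pi", "sigma")) {
  orientation <- match.arg(orientation)
  Na <- sqrt(za^5 / pi); Nb <- sqrt(zb^5 / pi)
  L <- 14 / min(za, zb)
  radial <- if (orientation == "pi") {
    function(rho, z) {
      ra <- sqrt(rho^2 + z^2); rb <- sqrt(rho^2 + (z - r)^2)
      Na * Nb * rho^3 * pi * exp(-za * ra - zb * rb)
    }
  } else {
    function(rho, z) {
      ra <- sqrt(rho^2 + z^2); rb <- sqrt(rho^2 + (z - r)^2)
      Na * Nb * z * (z - r) * 2 * pi * rho * exp(-za * ra - zb * rb)
    }
  }
  slice <- function(z) {
    vapply(z, function(zz) {
      stats::integrate(radial, 0, L, z = zz, rel.tol = 1e-11,
                       abs.tol = 1e-13, subdivisions = 200L)$value
    }, numeric(1L))
  }
  cuts <- sort(unique(c(-L, 0, r, r + L)))
  total <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    total <- total + stats::integrate(slice, cuts[k], cuts[k + 1L],
                                      rel.tol = 1e-10, abs.tol = 1e-12,
                                      subdivisions = 200L)$value
  }
  total
}
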