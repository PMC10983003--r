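# Closed-shell self-consistent field solution of the ZDO Roothaan
# equations F C = C E (the overlap matrix is the identity under ZDO).
# Fock elements:
#   F_rr = H_rr + P_rr gamma_rr / 2 + sum_{s != r} P_ss gamma_rs
#   F_rs = H_rs - P_rs gamma_rs / 2
# Plain damped iteration from a Hueckel guess; no DIIS or level shifting
# is needed at these system sizes.

#' Hueckel starting orbitals
#'
#' Eigenvectors of the core matrix (alpha on the diagonal, beta on bonded
#' off-diagonals), which is exactly the geometry-parameterized Hueckel
#' model of the pi system.
#'
#' @param params A `ppp_parameters` object.
#' @return List with `C` (orbital coefficients, columns ascending in
#'   energy) and `eps` (eigenvalues, eV).
#' @export
huckelGuess <- function(params) {
  e <- eigen(params$Hcore, symmetric = TRUE)
  ord <- order(e$values)
  list(C = e$vectors[, ord, drop = FALSE], eps = e$values[ord])
}

#' Build the PPP Fock matrix for a given density
#'
#' @param P Symmetric density matrix (trace = electron count).
#' @param params A `ppp_parameters` object.
#' @return Fock matrix (eV).
#' @export
buildFock <- function(P, params) {
  n <- params$n
  if (!is.matrix(P) || any(dim(P) != n)) stop("density matrix has wrong shape",
                                              call. = FALSE)
  gam <- params$gamma
  F <- params$Hcore - 0.5 * P * gam
  diag(F) <- diag(params$Hcore) + 0.5 * diag(P) * diag(gam) +
    (gam %*% diag(P) - diag(gam) * diag(P))
  F
}

#' Solve the PPP SCF equations
#'
#' Iterates density/Fock builds until the RMS change of the density matrix
#' drops below `tol`.  Oscillation is detected from a non-decreasing
#' density residual and rescued with linear damping.  Non-convergence is
#' reported through the `converged` flag -- never as an error -- so batch
#' drivers stay robust.
#'
#' Within degenerate orbital blocks the gauge is fixed deterministically by
#' diagonalizing a coordinate-moment operator in the block, then forcing
#' the largest-magnitude coefficient of every orbital positive; this makes
#' downstream exchange/overlap values on degenerate systems reproducible
#' across linear-algebra backends.
#'
#' @param params A `ppp_parameters` object.
#' @param tol RMS density convergence threshold (default 1e-8).
#' @param max_iter Maximum number of iterations (default 200).
#' @param damping Mixing factor in \[0, 1) applied after oscillation is
#'   detected (default 0.5); 0 disables damping.
#' @return Object of class `ppp_scf`: `C`, `eps`, `P`, `F`, `n_occ`,
#'   `converged`, `n_iter`, `energy_trace` (electronic energy per
#'   iteration, eV), plus the input `params`.
#' @export
scfSolve <- function(params, tol = 1e-8, max_iter = 200, damping = 0.5) {
  n <- params$n
  nel <- params$n_electrons
  if (nel %% 2L != 0L) stop("odd electron count; closed-shell SCF only",
                            call. = FALSE)
  nocc <- nel %/% 2L
  if (nocc > n) stop("more electron pairs than orbitals", call. = FALSE)

  C <- huckelGuess(params)$C
  P <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  trace <- numeric(0)
  prev_res <- Inf
  damp <- 0
  converged <- FALSE
  it <- 0L
  eps <- numeric(n); F <- buildFock(P, params)
  while (it < max_iter) {
    it <- it + 1L
    F <- buildFock(P, params)
    trace <- c(trace, 0.5 * sum(P * (params$Hcore + F)))
    e <- eigen(F, symmetric = TRUE)
    ord <- order(e$values)
    C <- e$vectors[, ord, drop = FALSE]
    eps <- e$values[ord]
    Pn <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    res <- sqrt(mean((Pn - P)^2))
    if (res < tol) {
      P <- Pn
      converged <- TRUE
      break
    }
    if (res >= prev_res && damp == 0) damp <- damping  # oscillation rescue
    prev_res <- res
    P <- (1 - damp) * Pn + damp * P
  }
  F <- buildFock(P, params)
  C <- .fix_gauge(C, eps, params$coords)

  structure(list(C = C, eps = eps, P = P, F = F, n_occ = nocc,
                 converged = converged, n_iter = it, energy_trace = trace,
                 params = params),
            class = "ppp_scf")
}

#' @export
print.ppp_scf <- function(x, ...) {
  cat("<ppp_scf> ", x$params$n, " orbitals, ", 2 * x$n_occ, " electrons; ",
      if (x$converged) sprintf("converged in %d iterations", x$n_iter)
      else sprintf("NOT converged after %d iterations", x$n_iter), "\n", sep = "")
  h <- x$n_occ; l <- x$n_occ + 1L
  cat(sprintf("  HOMO %.4f eV, LUMO %.4f eV, gap %.4f eV\n",
              x$eps[h], x$eps[l], x$eps[l] - x$eps[h]))
  invisible(x)
}

# Deterministic gauge inside degenerate eigenvalue blocks: rotate the block
# to diagonalize a fixed coordinate-moment operator, then sign-fix every
# column by its largest-magnitude coefficient (first index on ties).
.fix_gauge <- function(C, eps, coords, tol_deg = 1e-6) {
  n <- length(eps)
  w <- coords[, 1] + exp(1) * coords[, 2] + pi * coords[, 3] +
    0.1 * (coords[, 1]^2 + exp(1) * coords[, 2]^2 + pi * coords[, 3]^2)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && abs(eps[j + 1L] - eps[i]) < tol_deg) j <- j + 1L
    if (j > i) {
      B <- C[, i:j, drop = FALSE]
      M <- crossprod(B, w * B)
      ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
      C[, i:j] <- B %*% ev$vectors[, order(ev$values), drop = FALSE]
    }
    i <- j + 1L
  }
  for (k in seq_len(ncol(C))) {
    m <- which.max(abs(C[, k]))
    if (C[m, k] < 0) C[, k] <- -C[, k]
  }
  C
}

# HOMO / LUMO indices
.homo <- function(scf) scf$n_occ
.lumo <- function(scf) scf$n_occ + 1L
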