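# Excited-state machinery: exchange integrals, configuration interaction
# singles, dipole-length oscillator strengths, and the perturbative
# dynamic-spin-polarization (DSP) correction to the singlet-triplet gap.

# ZDO two-electron integral in the MO basis (chemists' notation):
#   (pq|rs) = sum_{u,v} C_up C_uq gamma_uv C_vr C_vs
.mo_eri <- function(C, gamma, p, q, r, s) {
  drop(crossprod(C[, p] * C[, q], gamma %*% (C[, r] * C[, s])))
}

#' Exchange integral between two molecular orbitals
#'
#' `K_ij = sum_rs (c_ri c_rj) gamma_rs (c_si c_sj)`; a positive
#' semidefinite quadratic form, so K >= 0.  Twice the HOMO/LUMO exchange
#' is the singlet-triplet gap at the SCF level.
#'
#' @param scf A `ppp_scf` result.
#' @param i,j MO indices (1 = lowest orbital).
#' @param gamma Electron-repulsion matrix; defaults to the one stored with
#'   the SCF result.
#' @return K in eV.
#' @export
exchangeIntegral <- function(scf, i, j, gamma = scf$params$gamma) {
  n <- ncol(scf$C)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("MO index out of range",
                                                  call. = FALSE)
  .mo_eri(scf$C, gamma, i, j, i, j)
}

#' Spatial overlap of HOMO and LUMO densities
#'
#' `O = sum_r |c_r,HOMO| |c_r,LUMO|`, in \[0, 1\].  Small values signal a
#' small exchange interaction (and, unfortunately, a small oscillator
#' strength).
#'
#' @param scf A `ppp_scf` result.
#' @export
homoLumoOverlap <- function(scf) {
  sum(abs(scf$C[, .homo(scf)]) * abs(scf$C[, .lumo(scf)]))
}

#' Configuration interaction singles over the full occ x virt space
#'
#' Spin-adapted CIS on the converged SCF reference.  Under ZDO the
#' Hamiltonian blocks are
#'   singlet: `A = delta (eps_a - eps_i) + 2 (ia|jb) - (ij|ab)`
#'   triplet: `A = delta (eps_a - eps_i) - (ij|ab)`
#'
#' @param scf A `ppp_scf` result (must be converged unless `force`).
#' @param params Parameter set; defaults to the one stored with `scf`.
#' @param multiplicity `"singlet"` or `"triplet"`.
#' @param force Accept a non-converged reference (default FALSE).
#' @return Object of class `ppp_cis`: `roots` (ascending excitation
#'   energies, eV), `amplitudes` (matrix, one normalized column per root),
#'   `pairs` (data frame of occ/virt indices for the amplitude rows),
#'   `multiplicity`, and for singlets `f` (oscillator strengths).
#' @export
cis <- function(scf, params = scf$params,
                multiplicity = c("singlet", "triplet"), force = FALSE) {
  multiplicity <- match.arg(multiplicity)
  if (!scf$converged && !force) {
    stop("SCF reference not converged; pass force = TRUE to override",
         call. = FALSE)
  }
  n <- params$n; nocc <- scf$n_occ
  occ <- seq_len(nocc); virt <- seq(nocc + 1L, n)
  pairs <- expand.grid(i = occ, a = virt)
  N <- nrow(pairs)
  # precompute charge-distribution vectors q_pq = C_p * C_q (over centers)
  A <- matrix(0, N, N)
  Qia <- lapply(seq_len(N), function(k) scf$C[, pairs$i[k]] * scf$C[, pairs$a[k]])
  G <- params$gamma
  GQ <- lapply(Qia, function(q) G %*% q)
  for (I in seq_len(N)) {
    for (J in I:N) {
      i <- pairs$i[I]; a <- pairs$a[I]; j <- pairs$i[J]; b <- pairs$a[J]
      ijab <- .mo_eri(scf$C, G, i, j, a, b)
      v <- -ijab
      if (multiplicity == "singlet") v <- v + 2 * drop(crossprod(Qia[[I]], GQ[[J]]))
      if (I == J) v <- v + scf$eps[a] - scf$eps[i]
      A[I, J] <- A[J, I] <- v
    }
  }
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  res <- structure(list(roots = e$values[ord],
                        amplitudes = e$vectors[, ord, drop = FALSE],
                        pairs = pairs[, c("i", "a")],
                        multiplicity = multiplicity, f = NULL),
                   class = "ppp_cis")
  if (multiplicity == "singlet") {
    res$f <- vapply(seq_len(N), function(k) oscillatorStrength(scf, params, res, k),
                    numeric(1L))
  }
  res
}

#' @export
print.ppp_cis <- function(x, ...) {
  cat("<ppp_cis> ", x$multiplicity, ", ", length(x$roots), " roots; lowest ",
      sprintf("%.4f eV", x$roots[1]), "\n", sep = "")
  invisible(x)
}

#' Oscillator strength of a singlet CIS root (dipole length form)
#'
#' `f = (2/3) dE |mu|^2` in atomic units, with the transition dipole from
#' ZDO point-charge sums over the pi centers:
#' `mu = sqrt(2) sum_ia t_ia sum_r c_ri c_ra R_r`.
#'
#' @param scf A `ppp_scf` result.
#' @param params Parameter set (for the center coordinates).
#' @param cis_result A singlet `ppp_cis`.
#' @param root Root index (1 = S1).
#' @return Dimensionless f >= 0.
#' @export
oscillatorStrength <- function(scf, params, cis_result, root = 1L) {
  if (cis_result$multiplicity != "singlet") {
    stop("oscillator strengths are defined for singlet roots", call. = FALSE)
  }
  t <- cis_result$amplitudes[, root]
  pr <- cis_result$pairs
  mu <- c(0, 0, 0)  # e * Angstrom
  for (k in seq_len(nrow(pr))) {
    q <- scf$C[, pr$i[k]] * scf$C[, pr$a[k]]
    mu <- mu + sqrt(2) * t[k] * drop(crossprod(q, params$coords))
  }
  de <- cis_result$roots[root] / pppConstants$hartree_ev
  mu2 <- sum((mu / pppConstants$bohr_angstrom)^2)
  (2 / 3) * de * mu2
}

# ---------------------------------------------------------------------------
# Dynamic spin polarization.
#
# With x = HOMO, y = LUMO, the open-shell singlet is stabilized over the
# triplet by coupling to determinants that are doubly excited with respect
# to the ground state: a spectator excitation i -> a (i doubly occupied
# below the HOMO, a virtual above the LUMO) on top of x -> y.  Second-order
# perturbation theory with exchange-operator numerators gives, per pair,
#   dE_ia = -[ 3/2 (Kx_ia - Ky_ia)^2 - 1/2 (Kx_ia + Ky_ia)^2 ] / D_ia
# with Kx_ia = (ix|xa), Ky_ia = (iy|ya).  At the SCF reference the
# denominator is the single-excitation energy D = eps_a - eps_i (the x->y
# part is common to state and intermediate); at the CIS reference the
# intermediates are referenced to the ground determinant, so
# D = eps_a - eps_i + eps_LUMO - eps_HOMO.
# ---------------------------------------------------------------------------

.dsp_sum <- function(scf, params, denom_shift, denom_floor = 1e-6) {
  C <- scf$C; G <- params$gamma; eps <- scf$eps
  x <- .homo(scf); y <- .lumo(scf)
  n <- params$n
  below <- seq_len(x - 1L)
  above <- if (y < n) seq(y + 1L, n) else integer(0)
  rows <- list(); dropped <- 0L
  for (i in below) {
    for (a in above) {
      Kx <- .mo_eri(C, G, i, x, x, a)
      Ky <- .mo_eri(C, G, i, y, y, a)
      den <- eps[a] - eps[i] + denom_shift
      if (abs(den) < denom_floor) {
        dropped <- dropped + 1L
        next
      }
      val <- -(1.5 * (Kx - Ky)^2 - 0.5 * (Kx + Ky)^2) / den
      rows[[length(rows) + 1L]] <- data.frame(i = i, a = a, value = val)
    }
  }
  contrib <- if (length(rows)) do.call(rbind, rows)
             else data.frame(i = integer(0), a = integer(0), value = numeric(0))
  list(total = sum(contrib$value), contributions = contrib, dropped = dropped)
}

.dsp_result <- function(sum_out, reference) {
  structure(list(total = sum_out$total, contributions = sum_out$contributions,
                 reference = reference, n_dropped = sum_out$dropped),
            class = "ppp_dsp")
}

#' Dynamic-spin-polarization correction at the SCF reference
#'
#' Sums perturbative contributions from all spectator excitations i -> a
#' with i below the HOMO and a above the LUMO.  Near-singular denominators
#' (|D| < `denom_floor`) are dropped and counted in `n_dropped` rather
#' than propagated as infinities.
#'
#' @param scf A `ppp_scf` result.
#' @param params Parameter set.
#' @param denom_floor Denominator threshold in eV (default 1e-6).
#' @return Object of class `ppp_dsp`: `total` (eV, expected <= 0),
#'   `contributions` (data frame i, a, value), `reference`, `n_dropped`.
#' @export
dspCorrectionScf <- function(scf, params = scf$params, denom_floor = 1e-6) {
  .dsp_result(.dsp_sum(scf, params, 0, denom_floor), "SCF")
}

#' Dynamic-spin-polarization correction at the CIS reference
#'
#' Same exchange numerators as [dspCorrectionScf()], with the doubly
#' excited intermediates referenced to the ground determinant
#' (`D = eps_a - eps_i + eps_LUMO - eps_HOMO`).  Added to the CIS gap this
#' yields the CIS+DSP singlet-triplet gap.
#'
#' @inheritParams dspCorrectionScf
#' @export
dspCorrectionCis <- function(scf, params = scf$params, denom_floor = 1e-6) {
  shift <- scf$eps[.lumo(scf)] - scf$eps[.homo(scf)]
  .dsp_result(.dsp_sum(scf, params, shift, denom_floor), "CIS")
}

#' @export
print.ppp_dsp <- function(x, ...) {
  cat(sprintf("<ppp_dsp> reference %s: total %.4f eV over %d excitations",
              x$reference, x$total, nrow(x$contributions)))
  if (x$n_dropped > 0) cat(sprintf(" (%d dropped, near-zero denominator)",
                                   x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Ranked orbital decomposition of a DSP correction
#'
#' @param dsp A `ppp_dsp` result.
#' @param scf The parent `ppp_scf` (unused beyond validation; orbital
#'   labels follow the energy-ladder numbering, 1 = lowest MO).
#' @return Data frame with columns `label` ("i -> a"), `i`, `a`, `value`
#'   (eV), sorted by decreasing magnitude.
#' @export
dspDecomposition <- function(dsp, scf = NULL) {
  d <- dsp$contributions
  d <- d[order(-abs(d$value)), , drop = FALSE]
  rownames(d) <- NULL
  cbind(label = sprintf("%d -> %d", d$i, d$a), d)
}

#' Published linear correction to the CIS+DSP gap
#'
#' Affine map `slope * x + intercept`, defaulting to the fit published for
#' wide screening (0.53 x - 0.15).
#'
#' @param gap_cis_dsp Gap value(s) in eV.
#' @param slope,intercept Correction coefficients.
#' @return Corrected gap(s) in eV.
#' @export
#' @examples
#' linearCorrection(0)     # -0.15
linearCorrection <- function(gap_cis_dsp, slope = 0.53, intercept = -0.15) {
  slope * gap_cis_dsp + intercept
}
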