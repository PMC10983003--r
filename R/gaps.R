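# The full singlet-triplet gap ladder for one molecule:
#   gap_scf         = 2K                         (SCF, exchange only)
#   gap_scf_dsp     = 2K + dE_DSP(SCF)
#   gap_cis         = E(S1) - E(T1) from CIS
#   gap_cis_dsp     = gap_cis + dE_DSP(CIS)
#   gap_cis_dsp_lc  = 0.53 * gap_cis_dsp - 0.15  (published linear fit)
# Positive gaps are the usual Hund ordering; negative gaps are inverted.

#' Compute all singlet-triplet gap estimates for one molecule
#'
#' Runs exchange, DSP, and CIS on a converged SCF result and assembles the
#' complete gap ladder together with the HOMO-LUMO overlap, the S1
#' oscillator strength, and warning flags.  Negative CIS excitation
#' energies (a signature of restricted-unrestricted instability of the
#' ground state) are propagated with warnings, never altered.
#'
#' @param scf A `ppp_scf` result.
#' @param params Parameter set; defaults to the one stored with `scf`.
#' @param lc_slope,lc_intercept Linear-correction coefficients.
#' @param force Proceed on a non-converged SCF reference.
#' @return Object of class `ppp_gaps` with fields `two_K`, `dsp_scf`,
#'   `gap_scf`, `gap_scf_dsp`, `E_S1`, `E_T1`, `gap_cis`, `dsp_cis`,
#'   `gap_cis_dsp`, `gap_cis_dsp_lc`, `f_S1`, `homo_lumo_overlap`,
#'   `warnings` (character vector), and the underlying `dsp`/`cis`
#'   objects.
#' @export
gapEstimates <- function(scf, params = scf$params, lc_slope = 0.53,
                         lc_intercept = -0.15, force = FALSE) {
  warnings <- character()
  if (!scf$converged) {
    if (!force) stop("SCF not converged; pass force = TRUE to proceed",
                     call. = FALSE)
    warnings <- c(warnings, "not_converged")
  }
  K <- exchangeIntegral(scf, .homo(scf), .lumo(scf))
  dsp_s <- dspCorrectionScf(scf, params)
  dsp_c <- dspCorrectionCis(scf, params)
  if (dsp_s$n_dropped + dsp_c$n_dropped > 0) {
    warnings <- c(warnings, "dsp_denominator_dropped")
  }
  cs <- cis(scf, params, "singlet", force = force)
  ct <- cis(scf, params, "triplet", force = force)
  if (ct$roots[1] < 0) warnings <- c(warnings, "negative_T1")
  if (cs$roots[1] < 0) warnings <- c(warnings, "negative_S1")
  gap_cis <- cs$roots[1] - ct$roots[1]
  gap_cis_dsp <- gap_cis + dsp_c$total
  structure(list(
    two_K = 2 * K,
    dsp_scf = dsp_s$total,
    gap_scf = 2 * K,
    gap_scf_dsp = 2 * K + dsp_s$total,
    E_S1 = cs$roots[1], E_T1 = ct$roots[1],
    gap_cis = gap_cis,
    dsp_cis = dsp_c$total,
    gap_cis_dsp = gap_cis_dsp,
    gap_cis_dsp_lc = linearCorrection(gap_cis_dsp, lc_slope, lc_intercept),
    f_S1 = cs$f[1],
    homo_lumo_overlap = homoLumoOverlap(scf),
    warnings = warnings,
    dsp = list(scf = dsp_s, cis = dsp_c),
    cis = list(singlet = cs, triplet = ct)
  ), class = "ppp_gaps")
}

#' @export
print.ppp_gaps <- function(x, ...) {
  cat("<ppp_gaps>  (eV; negative = inverted singlet-triplet gap)\n")
  cat(sprintf("  HOMO-LUMO overlap  %8.3f\n", x$homo_lumo_overlap))
  cat(sprintf("  2K        (SCF)    %8.3f\n", x$two_K))
  cat(sprintf("  DSP(SCF)           %8.3f   -> gap SCF+DSP  %8.3f\n",
              x$dsp_scf, x$gap_scf_dsp))
  cat(sprintf("  S1 %.3f / T1 %.3f  -> gap CIS      %8.3f\n",
              x$E_S1, x$E_T1, x$gap_cis))
  cat(sprintf("  DSP(CIS)           %8.3f   -> gap CIS+DSP  %8.3f\n",
              x$dsp_cis, x$gap_cis_dsp))
  cat(sprintf("  linear-corrected                 -> gap CIS+DSP+LC %6.3f\n",
              x$gap_cis_dsp_lc))
  cat(sprintf("  f(S1) %.4f\n", x$f_S1))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a gap value as inverted
#'
#' @param gaps A `ppp_gaps` object (or numeric gap).
#' @param level Which ladder level to classify on (default `gap_cis_dsp`).
#' @param use_lc Apply the linear correction level instead.
#' @param threshold Classification threshold (default 0; strictly below is
#'   inverted).
#' @export
isInverted <- function(gaps, level = "gap_cis_dsp", use_lc = FALSE,
                       threshold = 0) {
  v <- if (is.numeric(gaps)) gaps
       else gaps[[if (use_lc) "gap_cis_dsp_lc" else level]]
  v < threshold
}
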