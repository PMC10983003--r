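# One-call pipeline: geometry in, gap ladder out.

#' Compute the singlet-triplet gap ladder for a structure
#'
#' Convenience wrapper chaining [loadGeometry()] (when given a path),
#' [perceiveConnectivity()], [perceivePiSystem()], [buildParameterSet()],
#' [scfSolve()] and [gapEstimates()].
#'
#' @param x A file path (XYZ/SDF) or a [geometry()] object.
#' @param config Configuration list from [pppConfig()]/[readConfig()].
#' @param force Proceed on non-converged SCF.
#' @return A `ppp_gaps` object; the SCF result is attached as
#'   `attr(, "scf")`.
#' @export
#' @examples
#' g <- pentaleneD2h()
#' computeGaps(g)
computeGaps <- function(x, config = pppConfig(), force = TRUE) {
  g <- if (inherits(x, "ppp_geometry")) x else loadGeometry(x)
  table <- .config_table(config)
  ps <- perceivePiSystem(g, table = table, cutoff_scale = config$cutoff_scale)
  params <- buildParameterSet(ps, g, table = table,
                              overlap_method = config$overlap$method)
  scf <- scfSolve(params, tol = config$scf$tol, max_iter = config$scf$max_iter,
                  damping = config$scf$damping)
  gaps <- gapEstimates(scf, params, lc_slope = config$lc$slope,
                       lc_intercept = config$lc$intercept, force = force)
  attr(gaps, "scf") <- scf
  gaps
}
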