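# Shared fixtures built in code; nothing is read from disk except what a
# test itself writes to a tempdir.

# two-carbon pi system (ethylene-like): the minimal closed-shell case
ethylene2 <- function(bond = 1.33) polyeneChain(2L, bond)

# planar pyrrole: regular C4N pentagon plus the N-H hydrogen
pyrroleGeometry <- function(bond = 1.37) {
  ring <- ringPolygon(5L, bond)
  el <- c("N", rep("C", 4L), "H")
  # N at the first vertex; H radially outward from N
  nh <- ring$coords[1, ] + c(1.01, 0, 0) * ring$coords[1, ] / sqrt(sum(ring$coords[1, ]^2))
  geometry(el, rbind(ring$coords, nh), id = "pyrrole")
}

# full pipeline shortcut with tight SCF convergence for invariance checks
solveMolecule <- function(g, tol = 1e-12) {
  ps <- perceivePiSystem(g)
  params <- buildParameterSet(ps, g)
  scfSolve(params, tol = tol, max_iter = 400)
}

# random 3D rotation matrix from a fixed seed
randomRotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

applyRotation <- function(g, R, shift = c(0, 0, 0)) {
  geometry(g$elements, sweep(g$coords %*% t(R), 2, -shift), bonds = g$bonds,
           id = g$id)
}

permuteAtoms <- function(g, perm) {
  bonds <- g$bonds
  if (!is.null(bonds)) {
    inv <- order(perm)
    bonds[, 1:2] <- matrix(inv[bonds[, 1:2]], ncol = 2)
  }
  geometry(g$elements[perm], g$coords[perm, , drop = FALSE], bonds = bonds,
           id = g$id)
}

# printed benchmark confusion matrices (TP, TN, FP, FN) and the metric
# cells published alongside them (2 decimals)
publishedMetricRows <- function() {
  rows <- list(
    list(name = "azaphenalenes SCF",  cm = c(128, 32, 2, 94),
         f1 = 0.73, roc = 0.76, acc = 0.62, rec = 0.58, spec = 0.94),
    list(name = "azaphenalenes CIS",  cm = c(125, 33, 1, 97),
         f1 = 0.72, roc = 0.77, acc = 0.62, rec = 0.56, spec = 0.97),
    list(name = "azaazulenes SCF",    cm = c(0, 133, 0, 5),
         f1 = 0.00, roc = 0.50, acc = 0.96, rec = 0.00, spec = 1.00),
    list(name = "azaazulenes CIS",    cm = c(0, 133, 0, 5),
         f1 = 0.00, roc = 0.50, acc = 0.96, rec = 0.00, spec = 1.00),
    list(name = "rational SCF+DSP",   cm = c(2073, 60490, 561, 5566),
         f1 = 0.40, roc = 0.63, acc = 0.91, rec = 0.27, spec = 0.99),
    list(name = "rational CIS+DSP",   cm = c(1227, 60736, 315, 6412),
         f1 = 0.27, roc = 0.58, acc = 0.90, rec = 0.16, spec = 0.99),
    list(name = "rational CIS+DSP+LC", cm = c(3867, 58592, 2459, 3772),
         f1 = 0.55, roc = 0.73, acc = 0.91, rec = 0.51, spec = 0.96),
    list(name = "external nonalternants", cm = c(2, 75, 0, 2),
         f1 = 0.67, roc = 0.75, acc = 0.97, rec = 0.50, spec = 1.00),
    list(name = "external avoided symmetry", cm = c(12, 30, 2, 3),
         f1 = 0.83, roc = 0.87, acc = 0.89, rec = 0.80, spec = 0.94),
    list(name = "external substituted", cm = c(14, 50, 2, 5),
         f1 = 0.80, roc = 0.85, acc = 0.90, rec = 0.74, spec = 0.96)
  )
  rows
}

asConfusion <- function(v) {
  structure(list(TP = v[1], TN = v[2], FP = v[3], FN = v[4]),
            class = "ppp_confusion")
}
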