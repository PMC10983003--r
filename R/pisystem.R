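# Pi-system perception: which heavy atoms carry a p orbital, how many
# electrons each contributes, and how strongly neighboring p orbitals are
# twisted out of alignment.
#
# Electron-count rule table (sigma neighbors count hydrogens):
#   C with 3 or 2 neighbors      -> 1 electron  (sp2 / sp carbon)
#   N with 2 neighbors           -> 1 electron  (pyridine-type)
#   N with 3 neighbors           -> 2 electrons (pyrrole/amine-type)
#   O with 1 neighbor            -> 1 electron  (carbonyl)
#   O with 2 neighbors           -> 2 electrons (ether/hydroxyl)
# Saturated centers (4 sigma neighbors) are excluded; anything else
# (four-coordinate P, unknown valences) raises an unsupported-center error.

#' Identify the pi system of a conjugated molecule
#'
#' Assigns one 2p orbital to every conjugated sp2/sp heavy atom, resolves
#' each center's valence-state type from element plus sigma-neighbor count,
#' and computes per-bond twist angles from the dihedral geometry.
#'
#' @param g A [geometry()] object.
#' @param bonds Optional bond matrix; defaults to the explicit bonds of `g`
#'   or distance-based [perceiveConnectivity()].
#' @param table Valence-state table ([defaultValenceTable()]).
#' @param cutoff_scale Passed to [perceiveConnectivity()] when bonds are
#'   perceived here.
#' @return Object of class `ppp_pi_system`: `centers` (atom indices),
#'   `types` (valence keys), `n_pi` (electrons per center), `adjacency`
#'   (symmetric logical matrix over centers), `twist` (matrix of twist
#'   angles in degrees, nonzero only on bonds), `n_electrons`, and
#'   `warnings`.
#' @export
perceivePiSystem <- function(g, bonds = NULL, table = defaultValenceTable(),
                             cutoff_scale = 1.15) {
  if (is.null(bonds)) bonds <- perceiveConnectivity(g, cutoff_scale)
  n <- length(g$elements)
  deg <- tabulate(c(bonds[, 1L], bonds[, 2L]), nbins = n)
  warnings <- character()

  heavy <- which(g$elements != "H")
  keys <- rep(NA_character_, n)
  for (a in heavy) {
    el <- g$elements[a]; d <- deg[a]
    keys[a] <- if (el == "C" && d == 3L) "C.sp2"
      else if (el == "C" && d <= 2L) "C.sp"   # includes H-less skeleton input
      else if (el == "C" && d >= 4L) NA_character_   # saturated, not a pi center
      else if (el == "N" && d <= 2L) "N.pyridine"
      else if (el == "N" && d == 3L) "N.pyrrole"
      else if (el == "O" && d == 1L) "O.carbonyl"
      else if (el == "O" && d == 2L) "O.ether"
      else if (el %in% c("N", "O")) NA_character_
      else "UNSUPPORTED"
  }
  if (any(keys %in% "UNSUPPORTED")) {
    bad <- which(keys %in% "UNSUPPORTED")
    stop("unsupported pi center(s): atom ",
         paste(sprintf("%d (%s, %d neighbors)", bad, g$elements[bad], deg[bad]),
               collapse = ", "),
         "; the parameter table covers ", paste(table$key, collapse = ", "),
         call. = FALSE)
  }
  centers <- which(!is.na(keys))
  if (length(centers) < 2L) stop("fewer than 2 pi centers perceived", call. = FALSE)
  entries <- .valence_entry(keys[centers], table)
  n_pi <- entries$n_pi
  total <- sum(n_pi)
  if (total %% 2L != 0L) {
    stop("odd pi-electron count (", total, "); closed-shell PPP requires an ",
         "even number of pi electrons", call. = FALSE)
  }

  m <- length(centers)
  adj <- matrix(FALSE, m, m)
  idx <- match(seq_len(n), centers)
  for (b in seq_len(nrow(bonds))) {
    ci <- idx[bonds[b, 1L]]; cj <- idx[bonds[b, 2L]]
    if (!is.na(ci) && !is.na(cj)) adj[ci, cj] <- adj[cj, ci] <- TRUE
  }
  comp <- .components(adj)
  if (max(comp) > 1L) {
    warnings <- c(warnings, sprintf("pi system has %d disconnected components",
                                    max(comp)))
    warning(warnings[length(warnings)], call. = FALSE)
  }

  ps <- structure(list(centers = centers, types = keys[centers], n_pi = n_pi,
                       adjacency = adj, twist = NULL, n_electrons = total,
                       warnings = warnings),
                  class = "ppp_pi_system")
  ps$twist <- twistAngles(ps, g)
  ps
}

#' @export
print.ppp_pi_system <- function(x, ...) {
  cat("<ppp_pi_system> ", length(x$centers), " centers, ", x$n_electrons,
      " pi electrons\n", sep = "")
  cat("  types:", paste(sprintf("%s x%d", names(table(x$types)), table(x$types)),
                        collapse = ", "), "\n")
  mx <- max(x$twist)
  cat(sprintf("  max twist angle: %.1f deg\n", mx))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

.components <- function(adj) {
  m <- nrow(adj); comp <- integer(m); k <- 0L
  for (s in seq_len(m)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Twist angles between bonded p orbitals
#'
#' For each bonded pair of pi centers (r, s) the twist angle is the average
#' over all dihedrals a-r-s-b, where a and b are pi neighbors of r and s,
#' each dihedral folded to \[0, 90\] degrees (the attenuation of the
#' resonance integral depends only on |cos theta|).  Bonds without any
#' flanking dihedral (e.g. ethylene) get theta = 0 by convention.
#'
#' @param ps A `ppp_pi_system`.
#' @param g The parent [geometry()].
#' @return Symmetric matrix of twist angles (degrees) over pi centers.
#' @export
twistAngles <- function(ps, g) {
  m <- length(ps$centers)
  th <- matrix(0, m, m)
  for (r in seq_len(m)) {
    for (s in seq_len(m)) {
      if (s <= r || !ps$adjacency[r, s]) next
      nb_r <- setdiff(which(ps$adjacency[r, ]), s)
      nb_s <- setdiff(which(ps$adjacency[s, ]), r)
      if (!length(nb_r) || !length(nb_s)) next
      angs <- c()
      for (a in nb_r) for (b in nb_s) {
        d <- .dihedral(g$coords[ps$centers[a], ], g$coords[ps$centers[r], ],
                       g$coords[ps$centers[s], ], g$coords[ps$centers[b], ])
        if (!is.na(d)) angs <- c(angs, .fold_angle(d))
      }
      if (length(angs)) th[r, s] <- th[s, r] <- mean(angs)
    }
  }
  th
}

# dihedral angle a-b-c-d in degrees, NA for degenerate (collinear) frames
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- .cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# fold an arbitrary dihedral into [0, 90] degrees
.fold_angle <- function(deg) {
  a <- abs(deg) %% 180
  min(a, 180 - a)
}
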