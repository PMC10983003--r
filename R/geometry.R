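# Structure input: XYZ and MDL MOL/SDF (V2000) readers, an XYZ writer, and
# distance-based connectivity perception.

#' Construct a molecular geometry object
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param bonds Optional integer matrix with columns `i`, `j` (1-based atom
#'   indices) and optionally `order`; explicit bonds always override
#'   distance-based perception downstream.
#' @param id Identifier string.
#' @return Object of class `ppp_geometry`.
#' @export
geometry <- function(elements, coords, bonds = NULL, id = "molecule") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 2L) stop("a geometry needs at least 2 atoms", call. = FALSE)
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be a length(elements) x 3 matrix", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  unknown <- setdiff(unique(elements), .supported_elements())
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(.supported_elements(), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, order = 1L)
    colnames(bonds) <- c("i", "j", "order")
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > length(elements))) {
      stop("bond indices out of range", call. = FALSE)
    }
  }
  structure(list(elements = elements, coords = coords, bonds = bonds, id = id),
            class = "ppp_geometry")
}

#' @export
print.ppp_geometry <- function(x, ...) {
  cat("<ppp_geometry> ", x$id, ": ", length(x$elements), " atoms (",
      paste(names(sort(table(x$elements), decreasing = TRUE)), collapse = ","),
      ")", if (!is.null(x$bonds)) sprintf(", %d explicit bonds", nrow(x$bonds)),
      "\n", sep = "")
  invisible(x)
}

#' Read a molecular geometry from file
#'
#' Supports plain XYZ (atom count, comment, `El x y z` lines) and MDL
#' MOL/SDF V2000.  For SDF the explicit bond block is retained and takes
#' precedence over distance-based connectivity perception.
#'
#' @param path File path.
#' @param format `"xyz"` or `"sdf"`; guessed from the file extension when
#'   omitted.
#' @return A [geometry()] object.
#' @export
loadGeometry <- function(path, format = c("auto", "xyz", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", sdf = , mol = "sdf",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") .parse_xyz(lines, path) else .parse_sdf(lines, path)
}

.parse_xyz <- function(lines, path) {
  if (length(lines) < 3L) stop("XYZ parse error in ", path, ": fewer than 3 lines",
                               call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("XYZ parse error in ", path, " at line 1: atom count expected",
                     call. = FALSE)
  if (length(lines) < n + 2L) {
    stop("XYZ parse error in ", path, ": expected ", n, " atom lines", call. = FALSE)
  }
  el <- character(n); xyz <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    ln <- n_line <- k + 2L
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(f) < 4L) stop("XYZ parse error in ", path, " at line ", n_line,
                             ": need 'El x y z'", call. = FALSE)
    el[k] <- f[1L]
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(v)) stop("XYZ parse error in ", path, " at line ", n_line,
                       ": non-numeric coordinate", call. = FALSE)
    xyz[k, ] <- v
  }
  geometry(el, xyz, id = sub("\\.[^.]*$", "", basename(path)))
}

.parse_sdf <- function(lines, path) {
  if (length(lines) < 4L) stop("SDF parse error in ", path, ": truncated header",
                               call. = FALSE)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds)) {
    stop("SDF parse error in ", path, " at line 4: bad counts line", call. = FALSE)
  }
  if (length(lines) < 4L + natoms + nbonds) {
    stop("SDF parse error in ", path, ": truncated atom/bond block", call. = FALSE)
  }
  el <- character(natoms); xyz <- matrix(NA_real_, natoms, 3L)
  for (k in seq_len(natoms)) {
    ln <- lines[4L + k]
    v <- suppressWarnings(as.numeric(c(substr(ln, 1L, 10L), substr(ln, 11L, 20L),
                                       substr(ln, 21L, 30L))))
    sym <- trimws(substr(ln, 31L, 34L))
    if (anyNA(v) || sym == "") {
      stop("SDF parse error in ", path, " at line ", 4L + k, call. = FALSE)
    }
    el[k] <- sym; xyz[k, ] <- v
  }
  bonds <- NULL
  if (nbonds > 0L) {
    bonds <- matrix(NA_integer_, nbonds, 3L)
    for (k in seq_len(nbonds)) {
      ln <- lines[4L + natoms + k]
      b <- suppressWarnings(as.integer(c(substr(ln, 1L, 3L), substr(ln, 4L, 6L),
                                         substr(ln, 7L, 9L))))
      if (anyNA(b[1:2])) {
        stop("SDF parse error in ", path, " at line ", 4L + natoms + k, call. = FALSE)
      }
      if (is.na(b[3L])) b[3L] <- 1L
      bonds[k, ] <- b
    }
    colnames(bonds) <- c("i", "j", "order")
  }
  geometry(el, xyz, bonds = bonds, id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a geometry as XYZ
#'
#' @param g A [geometry()] object.
#' @param path Output file path.
#' @param digits Coordinate precision (default 8).
#' @export
writeXYZ <- function(g, path, digits = 8) {
  fmt <- paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f")
  lines <- c(as.character(length(g$elements)), g$id,
             sprintf(fmt, g$elements, g$coords[, 1], g$coords[, 2], g$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Perceive bonding connectivity from interatomic distances
#'
#' Two atoms are bonded when their distance is below
#' `cutoff_scale * (r_i + r_j)` with single-bond covalent radii.  Explicit
#' bonds stored on the geometry (e.g. from an SDF bond block) win and are
#' returned unchanged.
#'
#' @param g A [geometry()] object.
#' @param cutoff_scale Dimensionless scale on the covalent-radii sum
#'   (default 1.15).
#' @return Integer matrix with columns `i`, `j` (i < j), one row per bond.
#' @export
perceiveConnectivity <- function(g, cutoff_scale = 1.15) {
  if (!is.null(g$bonds)) return(g$bonds[, c("i", "j"), drop = FALSE])
  n <- length(g$elements)
  radii <- .covalent_radius(g$elements)
  d <- as.matrix(stats::dist(g$coords))
  cut <- cutoff_scale * outer(radii, radii, "+")
  sel <- which(upper.tri(d) & d < cut, arr.ind = TRUE)
  bonds <- cbind(i = sel[, 1L], j = sel[, 2L])
  heavy <- g$elements != "H"
  deg <- tabulate(bonds, nbins = n)
  if (any(heavy & deg == 0L)) {
    warning("isolated heavy atom(s): ",
            paste(which(heavy & deg == 0L), collapse = ", "), call. = FALSE)
  }
  bonds
}

.distance_matrix <- function(coords) as.matrix(stats::dist(coords))
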