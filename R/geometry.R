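#' Molecular geometry in Cartesian coordinates
#'
#' A minimal container for an XYZ-style structure: element symbols plus an
#' n x 3 matrix of Cartesian coordinates in Angstrom.
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric matrix, n x 3, Angstrom.
#' @param name free-text label.
#' @return An object of class `geometry`.
#' @export
geometry <- function(atoms, coords, name = "") {
  atoms <- as.character(atoms)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be an n x 3 numeric matrix")
  if (nrow(coords) != length(atoms))
    stop("coordinate count (", nrow(coords), ") does not match atom count (",
         length(atoms), ")")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords, name = as.character(name)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("<geometry>", if (nzchar(x$name)) x$name else "(unnamed)",
      "-", length(x$atoms), "atoms\n")
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ convention: an atom-count line, a comment line, then one
#' `element x y z` row per atom.
#'
#' @param path path to an XYZ file.
#' @return A [geometry()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("XYZ parse error at line 1: file too short for count + comment lines")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 0L)
    stop("XYZ parse error at line 1: malformed atom count '", lines[1L], "'")
  if (length(lines) < 2L + n)
    stop("XYZ parse error: count line declares ", n, " atoms but only ",
         max(0L, length(lines) - 2L), " atom rows present")
  atoms <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- 2L + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L)
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    atoms[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  geometry(atoms, coords, name = trimws(lines[2L]))
}

#' Write an XYZ file
#'
#' @param g a [geometry()].
#' @param path output path.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(g, path, digits = 8) {
  stopifnot(inherits(g, "geometry"))
  rows <- sprintf("%s %.*f %.*f %.*f", g$atoms,
                  digits, g$coords[, 1], digits, g$coords[, 2],
                  digits, g$coords[, 3])
  writeLines(c(as.character(length(g$atoms)), g$name, rows), path)
  invisible(path)
}

.check_indices <- function(g, idx) {
  n <- nrow(g$coords)
  if (any(idx < 1L | idx > n))
    stop("atom index out of range 1..", n)
  if (anyDuplicated(idx))
    stop("atom indices must be distinct")
}

#' Interatomic distance
#'
#' Euclidean distance between two atoms, in Angstrom. `i == j` is allowed
#' and returns 0.
#'
#' @param g a [geometry()].
#' @param i,j atom indices (1-based).
#' @return distance in Angstrom.
#' @export
interatomic_distance <- function(g, i, j) {
  stopifnot(inherits(g, "geometry"))
  n <- nrow(g$coords)
  if (any(c(i, j) < 1L | c(i, j) > n))
    stop("atom index out of range 1..", n)
  sqrt(sum((g$coords[i, ] - g$coords[j, ])^2))
}

#' Dihedral (torsional) angle
#'
#' The angle between the plane through atoms i-j-k and the plane through
#' j-k-l, under the IUPAC sign convention: looking from j towards k, a
#' clockwise rotation of the far bond relative to the near bond is
#' positive; the antiperiplanar arrangement is +180. The value lies in
#' (-180, 180].
#'
#' @param g a [geometry()].
#' @param i,j,k,l four distinct atom indices defining the torsion.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(g, i, j, k, l) {
  stopifnot(inherits(g, "geometry"))
  .check_indices(g, c(i, j, k, l))
  p <- g$coords
  b1 <- p[j, ] - p[i, ]
  b2 <- p[k, ] - p[j, ]
  b3 <- p[l, ] - p[k, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: three consecutive atoms are colinear, ",
         "dihedral plane undefined")
  # atan2 formulation is numerically stable near 0 and 180
  ang <- atan2(sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  deg <- ang * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fold angles into the principal window (-180, 180]
#'
#' @param x angles in degrees.
#' @return angles mapped by `((x + 180) mod 360) - 180`, with the seam
#'   value mapped to +180.
#' @export
fold_angle <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out <= -180] <- out[out <= -180] + 360
  out
}
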