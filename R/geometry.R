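# Internal vector geometry and periodic-boundary helpers. All coordinates in
# angstroms; boxes are orthorhombic (three edge lengths).

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Minimum-image displacement(s). `d` is an m x 3 matrix (or length-3 vector)
# of raw displacements; returns the same shape with each component wrapped
# into (-box/2, box/2].
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    sweep_box <- matrix(box, nrow(d), 3, byrow = TRUE)
    d - round(d / sweep_box) * sweep_box
  } else {
    d - round(d / box) * box
  }
}

# Lattice shift that maps points `b` (m x 3) into the image nearest `a`
# (m x 3 or length 3). Returns the m x 3 shift to ADD to b's coordinates.
.image_shift <- function(a, b, box) {
  if (is.null(box)) return(matrix(0, NROW(b), 3))
  if (!is.matrix(a)) a <- matrix(a, NROW(b), 3, byrow = TRUE)
  d <- b - a
  bx <- matrix(box, NROW(b), 3, byrow = TRUE)
  -round(d / bx) * bx
}

# Pairwise minimum-image distances between one point and rows of a matrix.
.dist_to <- function(p, m, box = NULL) {
  d <- sweep(m, 2, p)
  d <- .min_image(d, box)
  sqrt(rowSums(d^2))
}

# An orthonormal vector perpendicular to v.
.perp <- function(v) {
  v <- .unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.cross(v, ref))
}

.is_box <- function(box) {
  !is.null(box) && is.numeric(box) && length(box) == 3 &&
    all(is.finite(box)) && all(box > 0)
}

.check_box <- function(box) {
  if (is.null(box)) return(invisible(NULL))
  if (!.is_box(box)) {
    stop("box must be three strictly positive orthorhombic edge lengths (angstrom)")
  }
  invisible(NULL)
}
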