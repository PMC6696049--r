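#' Construct a water frame
#'
#' A frame is one saved trajectory snapshot: an ordered set of rigid 3-site
#' waters (one oxygen, two hydrogens) plus an optional orthorhombic box.
#' Coordinates are stored in angstroms. When a box is present, each water's
#' hydrogens are unwrapped to the oxygen's periodic image on construction so
#' molecules are never split across a boundary.
#'
#' @param o,h1,h2 n x 3 numeric matrices of oxygen and hydrogen coordinates
#'   (angstrom).
#' @param resid character or integer vector of source residue identifiers
#'   (default `seq_len(n)`).
#' @param box three orthorhombic box edge lengths in angstrom, or `NULL` when
#'   the frame is aperiodic.
#' @param index integer frame number.
#' @param time frame time in ps, or `NULL`.
#' @param other optional data frame of retained non-water atoms
#'   (columns `element`, `x`, `y`, `z`, `resname`).
#' @param validate check water geometry (O--H distances in \[0.5, 1.5\]
#'   angstrom after unwrapping, three distinct sites).
#' @return An object of class `twn_frame`.
#' @seealso [read_frames()], [water()], [n_waters()]
#' @export
new_frame <- function(o, h1, h2, resid = NULL, box = NULL, index = 1L,
                      time = NULL, other = NULL, validate = TRUE) {
  o <- .as_coord_matrix(o, "o")
  h1 <- .as_coord_matrix(h1, "h1")
  h2 <- .as_coord_matrix(h2, "h2")
  n <- nrow(o)
  if (nrow(h1) != n || nrow(h2) != n) {
    stop("o, h1 and h2 must have one row per water")
  }
  .check_box(box)
  if (is.null(resid)) resid <- seq_len(n)
  if (length(resid) != n) stop("resid must have one entry per water")
  if (!is.null(box) && n > 0) {
    h1 <- h1 + .image_shift(o, h1, box)
    h2 <- h2 + .image_shift(o, h2, box)
  }
  fr <- structure(
    list(o = o, h1 = h1, h2 = h2, resid = resid, box = box,
         index = as.integer(index), time = time, other = other),
    class = "twn_frame"
  )
  if (validate && n > 0) .validate_frame(fr)
  fr
}

.as_coord_matrix <- function(m, what) {
  if (is.null(m) || length(m) == 0) return(matrix(numeric(0), 0, 3))
  if (!is.matrix(m)) m <- matrix(m, ncol = 3, byrow = FALSE)
  if (ncol(m) != 3) stop(what, " must be an n x 3 coordinate matrix")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

.validate_frame <- function(fr) {
  if (any(!is.finite(fr$o)) || any(!is.finite(fr$h1)) || any(!is.finite(fr$h2))) {
    stop("frame ", fr$index, ": non-finite water coordinates")
  }
  d1 <- sqrt(rowSums((fr$h1 - fr$o)^2))
  d2 <- sqrt(rowSums((fr$h2 - fr$o)^2))
  bad <- which(d1 < 0.5 | d1 > 1.5 | d2 < 0.5 | d2 > 1.5)
  if (length(bad)) {
    stop("frame ", fr$index, ": O-H distance outside [0.5, 1.5] angstrom for residue(s) ",
         paste(utils::head(fr$resid[bad], 5), collapse = ", "))
  }
  invisible(fr)
}

#' Number of waters in a frame
#' @param frame a `twn_frame`.
#' @return Integer count.
#' @export
n_waters <- function(frame) {
  stopifnot(inherits(frame, "twn_frame"))
  nrow(frame$o)
}

#' Extract one water molecule from a frame
#' @param frame a `twn_frame`.
#' @param i water index (1-based).
#' @return A `twn_water`: list with `o`, `h1`, `h2` coordinate vectors and
#'   `resid`.
#' @export
water <- function(frame, i) {
  stopifnot(inherits(frame, "twn_frame"))
  i <- as.integer(i)
  if (length(i) != 1 || is.na(i) || i < 1 || i > n_waters(frame)) {
    stop("water index out of range")
  }
  structure(
    list(o = frame$o[i, ], h1 = frame$h1[i, ], h2 = frame$h2[i, ],
         resid = frame$resid[i]),
    class = "twn_water"
  )
}

#' Merge water fragments into one frame
#'
#' Concatenates the waters of several frames (e.g. planted ring fragments
#' from [make_ring()] plus noise waters) into a single frame.
#'
#' @param ... `twn_frame` objects.
#' @param box,index,time frame metadata for the result.
#' @return A `twn_frame`.
#' @export
bind_waters <- function(..., box = NULL, index = 1L, time = NULL) {
  frs <- list(...)
  if (length(frs) == 1 && is.list(frs[[1]]) && !inherits(frs[[1]], "twn_frame")) {
    frs <- frs[[1]]
  }
  stopifnot(all(vapply(frs, inherits, logical(1), "twn_frame")))
  new_frame(
    o = do.call(rbind, lapply(frs, `[[`, "o")),
    h1 = do.call(rbind, lapply(frs, `[[`, "h1")),
    h2 = do.call(rbind, lapply(frs, `[[`, "h2")),
    resid = seq_len(sum(vapply(frs, n_waters, integer(1)))),
    box = box, index = index, time = time
  )
}

#' @export
print.twn_frame <- function(x, ...) {
  cat(sprintf("<twn_frame #%d: %d waters%s%s>\n", x$index, n_waters(x),
              if (.is_box(x$box)) sprintf(", box %.2f x %.2f x %.2f A",
                                          x$box[1], x$box[2], x$box[3])
              else ", no box",
              if (!is.null(x$time)) sprintf(", t = %g ps", x$time) else ""))
  invisible(x)
}

# Rigidly transform every water (and retained non-water atoms) of a frame:
# x -> R x + t. Used by invariance tests and scene builders.
#' Apply a rigid transform to a frame
#' @param frame a `twn_frame`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (angstrom).
#' @return The transformed `twn_frame` (box dropped: a rotated orthorhombic
#'   box is generally not orthorhombic).
#' @export
transform_frame <- function(frame, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(frame, "twn_frame"))
  tr <- function(m) sweep(m %*% t(rotation), 2, translation, `+`)
  other <- frame$other
  if (!is.null(other) && nrow(other)) {
    xyz <- tr(as.matrix(other[, c("x", "y", "z")]))
    other[, c("x", "y", "z")] <- xyz
  }
  new_frame(tr(frame$o), tr(frame$h1), tr(frame$h2), resid = frame$resid,
            box = NULL, index = frame$index, time = frame$time, other = other,
            validate = FALSE)
}
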