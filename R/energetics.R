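#' Water--water pair potential parameters
#'
#' Parameters of the pairwise interaction potential used to classify
#' hydrogen bonds between two rigid 3-site waters `a` and `b`:
#'
#' \deqn{v(a,b) = \sum_{i \in a}\sum_{j \in b} k\,q_i q_j / r_{ij}
#'   + A/r_{OO}^{12} - C/r_{OO}^{6}}
#'
#' The Coulomb sum runs over all nine site pairs; the Lennard-Jones term acts
#' on the oxygen--oxygen distance only. Two waters are hydrogen-bonded when
#' \eqn{v(a,b) \le} `hbond_threshold`.
#'
#' @param A Lennard-Jones repulsion, kcal A^12 / mol (default 582000).
#' @param C Lennard-Jones attraction, kcal A^6 / mol (default 595).
#' @param q_O,q_H site partial charges in units of e (defaults -0.834 and
#'   +0.417; the water must be neutral: `q_O + 2 q_H = 0`).
#' @param coulomb_constant conversion factor for `q_i q_j e^2 / r` in
#'   kcal A / (mol e^2); default 332.0636, the standard electrostatic
#'   conversion in these units.
#' @param hbond_threshold hydrogen-bond energy criterion, kcal/mol
#'   (default -2.25; must be negative).
#' @param distance_prefilter O--O candidate cutoff in angstrom used by
#'   [hbond_graph()]'s spatial index (default 3.5, must be >= 3.2).
#' @return An object of class `twn_params`.
#' @export
potential_params <- function(A = 582000, C = 595, q_O = -0.834, q_H = 0.417,
                             coulomb_constant = 332.0636,
                             hbond_threshold = -2.25,
                             distance_prefilter = 3.5) {
  if (!all(is.finite(c(A, C, q_O, q_H, coulomb_constant, hbond_threshold,
                       distance_prefilter)))) {
    stop("all potential parameters must be finite")
  }
  if (A <= 0 || C <= 0 || coulomb_constant <= 0) {
    stop("A, C and coulomb_constant must be positive")
  }
  if (hbond_threshold >= 0) stop("hbond_threshold must be negative (kcal/mol)")
  if (abs(q_O + 2 * q_H) > 1e-9) {
    stop("water must be neutral: q_O + 2*q_H = 0")
  }
  if (distance_prefilter < 3.2) {
    stop("distance_prefilter must be >= 3.2 angstrom")
  }
  structure(
    list(A = A, C = C, q_O = q_O, q_H = q_H,
         coulomb_constant = coulomb_constant,
         hbond_threshold = hbond_threshold,
         distance_prefilter = distance_prefilter),
    class = "twn_params"
  )
}

#' @export
print.twn_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<twn_params: A = %g kcal A^12/mol, C = %g kcal A^6/mol, q_O = %g e, ",
    "q_H = %g e,\n  k = %g kcal A/(mol e^2), H-bond if v <= %g kcal/mol, ",
    "prefilter %g A>\n"),
    x$A, x$C, x$q_O, x$q_H, x$coulomb_constant, x$hbond_threshold,
    x$distance_prefilter))
  invisible(x)
}

# Vectorised pair-potential core. All arguments are m x 3 coordinate
# matrices (molecule a sites and molecule b sites, row-aligned pairs).
# Minimum image, when a box is given, uses the O-O displacement's lattice
# shift for all nine site pairs of that molecule pair, keeping each molecule
# rigid. Returns a length-m vector of energies in kcal/mol.
.pair_energy_vec <- function(oa, h1a, h2a, ob, h1b, h2b, params, box = NULL) {
  .check_box(box)
  if (!is.null(box)) {
    shift <- .image_shift(oa, ob, box)
    ob <- ob + shift
    h1b <- h1b + shift
    h2b <- h2b + shift
  }
  roo2 <- rowSums((oa - ob)^2)
  if (any(roo2 < 0.01)) {
    stop("overlapping water molecules: O-O distance below 0.1 angstrom")
  }
  qO <- params$q_O
  qH <- params$q_H
  k <- params$coulomb_constant
  d <- function(p, q) sqrt(rowSums((p - q)^2))
  coul <- qO * qO / sqrt(roo2) +
    qO * qH * (1 / d(oa, h1b) + 1 / d(oa, h2b) + 1 / d(h1a, ob) + 1 / d(h2a, ob)) +
    qH * qH * (1 / d(h1a, h1b) + 1 / d(h1a, h2b) + 1 / d(h2a, h1b) + 1 / d(h2a, h2b))
  r6 <- roo2^3
  k * coul + params$A / (r6 * r6) - params$C / r6
}

#' Interaction energy between two water molecules
#'
#' Computes the pair potential (Coulomb over all nine site pairs plus
#' Lennard-Jones on the O--O distance) between two rigid 3-site waters, in
#' kcal/mol. With a periodic box, the minimum-image lattice shift of the
#' O--O displacement is applied to all sites of `b` so both molecules stay
#' rigid.
#'
#' @param a,b `twn_water` objects (see [water()]) or lists with `o`, `h1`,
#'   `h2` coordinate vectors in angstrom.
#' @param params a [potential_params()] object.
#' @param box orthorhombic box lengths (angstrom) or `NULL`.
#' @return Energy in kcal/mol.
#' @examples
#' fr <- make_ring(3)
#' pair_energy(water(fr, 1), water(fr, 2))
#' @export
pair_energy <- function(a, b, params = potential_params(), box = NULL) {
  .check_water_sites(a)
  .check_water_sites(b)
  .pair_energy_vec(
    matrix(a$o, 1, 3), matrix(a$h1, 1, 3), matrix(a$h2, 1, 3),
    matrix(b$o, 1, 3), matrix(b$h1, 1, 3), matrix(b$h2, 1, 3),
    params, box
  )[1]
}

.check_water_sites <- function(w) {
  for (s in c("o", "h1", "h2")) {
    v <- w[[s]]
    if (is.null(v) || length(v) != 3 || any(!is.finite(v))) {
      stop("water molecule is missing a finite '", s, "' site")
    }
  }
  invisible(w)
}

#' Hydrogen-bond classification of a water pair
#'
#' Two waters are hydrogen-bonded when their pair energy is at or below the
#' threshold (`<=` at exact equality).
#'
#' @inheritParams pair_energy
#' @return Logical.
#' @export
is_hbonded <- function(a, b, params = potential_params(), box = NULL) {
  pair_energy(a, b, params, box) <= params$hbond_threshold
}

#' Per-frame hydrogen-bond graph
#'
#' Builds the undirected simple graph whose nodes are the frame's water
#' indices and whose edges connect hydrogen-bonded pairs. Candidate pairs are
#' restricted to O--O distances at or below `params$distance_prefilter` by a
#' cell-list spatial index (`method = "cell"`); `method = "exhaustive"`
#' evaluates all pairs and is provided as a reference path.
#'
#' @param frame a `twn_frame`.
#' @param params a [potential_params()] object.
#' @param method candidate-pair generation: `"cell"` (spatial index) or
#'   `"exhaustive"` (all O(n^2) pairs).
#' @return A `twn_hbond_graph`: list with `n` (node count), `edges`
#'   (m x 2 integer matrix, each row `i < j`, rows sorted) and `frame_index`.
#' @export
hbond_graph <- function(frame, params = potential_params(),
                        method = c("cell", "exhaustive")) {
  stopifnot(inherits(frame, "twn_frame"))
  method <- match.arg(method)
  n <- n_waters(frame)
  empty <- matrix(integer(0), 0, 2)
  if (n < 2) {
    return(structure(list(n = n, edges = empty, frame_index = frame$index),
                     class = "twn_hbond_graph"))
  }
  cutoff <- params$distance_prefilter
  cand <- if (method == "cell") {
    .candidate_pairs_cell(frame$o, frame$box, cutoff)
  } else {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  }
  edges <- empty
  if (nrow(cand) > 0) {
    i <- cand[, 1]
    j <- cand[, 2]
    doo <- sqrt(rowSums(.min_image(frame$o[j, , drop = FALSE] -
                                     frame$o[i, , drop = FALSE],
                                   frame$box)^2))
    keep <- doo <= cutoff
    i <- i[keep]
    j <- j[keep]
    if (length(i)) {
      e <- .pair_energy_vec(
        frame$o[i, , drop = FALSE], frame$h1[i, , drop = FALSE],
        frame$h2[i, , drop = FALSE],
        frame$o[j, , drop = FALSE], frame$h1[j, , drop = FALSE],
        frame$h2[j, , drop = FALSE],
        params, frame$box
      )
      b <- e <= params$hbond_threshold
      if (any(b)) {
        lo <- pmin(i[b], j[b])
        hi <- pmax(i[b], j[b])
        ord <- order(lo, hi)
        edges <- cbind(lo[ord], hi[ord])
        storage.mode(edges) <- "integer"
      }
    }
  }
  structure(list(n = n, edges = edges, frame_index = frame$index),
            class = "twn_hbond_graph")
}

#' @export
print.twn_hbond_graph <- function(x, ...) {
  cat(sprintf("<twn_hbond_graph frame %d: %d waters, %d H-bonds>\n",
              x$frame_index, x$n, nrow(x$edges)))
  invisible(x)
}

# Cell-list candidate pairs within `cutoff` of each other (O positions).
# Periodic when box is given (positions wrapped; neighbour cells wrap), with
# an all-pairs fallback when the box is too small for a 3-cell decomposition.
.candidate_pairs_cell <- function(o, box, cutoff) {
  n <- nrow(o)
  all_pairs <- function() which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (n < 32) return(all_pairs())
  periodic <- .is_box(box)
  if (periodic) {
    ncell <- pmax(1L, as.integer(floor(box / cutoff)))
    if (any(ncell < 3L)) return(all_pairs())
    pos <- o - floor(sweep(o, 2, box, `/`)) %*% diag(box)
    cw <- box / ncell
  } else {
    lo <- apply(o, 2, min)
    pos <- sweep(o, 2, lo)
    ext <- pmax(apply(pos, 2, max), cutoff) + 1e-9
    ncell <- pmax(1L, as.integer(floor(ext / cutoff)))
    cw <- ext / ncell
  }
  ci <- pmin(floor(sweep(pos, 2, cw, `/`)), matrix(ncell - 1L, n, 3, byrow = TRUE))
  storage.mode(ci) <- "integer"
  key <- ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3])
  members <- split(seq_len(n), key)
  coords_of <- function(k) {
    x <- k %% ncell[1]
    k <- k %/% ncell[1]
    c(x, k %% ncell[2], k %/% ncell[2])
  }
  # half-space neighbour offsets (lexicographically positive) + self cell
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  pos_off <- offs[offs[, 1] > 0 |
                    (offs[, 1] == 0 & offs[, 2] > 0) |
                    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
                  drop = FALSE]
  out_i <- vector("list", length(members) * (nrow(pos_off) + 1))
  out_j <- out_i
  slot <- 0L
  keys <- as.numeric(names(members))
  for (ck in seq_along(members)) {
    m0 <- members[[ck]]
    cc <- coords_of(keys[ck])
    if (length(m0) > 1) {
      pr <- utils::combn(m0, 2)
      slot <- slot + 1L
      out_i[[slot]] <- pr[1, ]
      out_j[[slot]] <- pr[2, ]
    }
    for (r in seq_len(nrow(pos_off))) {
      nb <- cc + pos_off[r, ]
      if (periodic) {
        nb <- nb %% ncell
      } else if (any(nb < 0) || any(nb >= ncell)) {
        next
      }
      k2 <- as.character(nb[1] + ncell[1] * (nb[2] + ncell[2] * nb[3]))
      m1 <- members[[k2]]
      if (is.null(m1)) next
      slot <- slot + 1L
      out_i[[slot]] <- rep(m0, times = length(m1))
      out_j[[slot]] <- rep(m1, each = length(m0))
    }
  }
  i <- unlist(out_i[seq_len(slot)], use.names = FALSE)
  j <- unlist(out_j[seq_len(slot)], use.names = FALSE)
  if (is.null(i)) return(matrix(integer(0), 0, 2))
  cbind(i, j)
}
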