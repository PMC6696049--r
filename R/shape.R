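#' Bondi van der Waals radius of an element
#'
#' @param element character vector of element symbols.
#' @return Radii in angstrom (1.7, the carbon radius, for unlisted elements).
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, CL = 1.75, BR = 1.85, I = 1.98)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Voxel grid specification
#'
#' A regular grid of cubic voxels. The voxel with 1-based integer index
#' `(i, j, k)` has its center at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param origin grid corner (angstrom).
#' @param spacing voxel edge length (angstrom, default 0.5).
#' @param dims three positive integers.
#' @return A `twn_grid_spec`.
#' @export
grid_spec <- function(origin, spacing = 0.5, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("grid origin must be three finite coordinates")
  }
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("grid spacing must be a positive number")
  }
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 1)) {
    stop("grid dims must be three positive integers")
  }
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "twn_grid_spec")
}

#' Grid specification covering a set of atoms
#'
#' @param coords n x 3 coordinate matrix.
#' @param padding margin added on every side (angstrom; default 3, enough for
#'   the largest vdW radius plus the water probe).
#' @param spacing voxel edge length (angstrom).
#' @return A [grid_spec()].
#' @export
grid_from_atoms <- function(coords, padding = 3, spacing = 0.5) {
  coords <- .as_coord_matrix(coords, "coords")
  if (!nrow(coords)) stop("cannot build a grid around zero atoms")
  lo <- apply(coords, 2, min) - padding
  hi <- apply(coords, 2, max) + padding
  origin <- floor(lo / spacing) * spacing
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / spacing)))
  grid_spec(origin, spacing, dims)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    all(a$dims == b$dims)
}

# Mark all voxels whose center lies within radius r of any sphere center.
.mark_spheres <- function(occupied, spec, centers, radii) {
  centers <- .as_coord_matrix(centers, "centers")
  if (length(radii) == 1) radii <- rep(radii, nrow(centers))
  sp <- spec$spacing
  dims <- spec$dims
  org <- spec$origin
  for (s in seq_len(nrow(centers))) {
    p <- centers[s, ]
    r <- radii[s]
    i0 <- pmax(1L, as.integer(floor((p - r - org) / sp + 0.5)))
    i1 <- pmin(dims, as.integer(ceiling((p + r - org) / sp + 0.5)))
    if (any(i0 > i1)) next
    ix <- i0[1]:i1[1]
    iy <- i0[2]:i1[2]
    iz <- i0[3]:i1[3]
    dx2 <- (org[1] + (ix - 0.5) * sp - p[1])^2
    dy2 <- (org[2] + (iy - 0.5) * sp - p[2])^2
    dz2 <- (org[3] + (iz - 0.5) * sp - p[3])^2
    within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    occupied[ix, iy, iz] <- occupied[ix, iy, iz] | within
  }
  occupied
}

.new_grid <- function(spec, occupied, scope = "whole", n_sources = 0L) {
  structure(list(spec = spec, occupied = occupied, scope = scope,
                 n_sources = as.integer(n_sources)),
            class = "twn_grid")
}

#' @export
print.twn_grid <- function(x, ...) {
  cat(sprintf("<twn_grid [%s]: %d x %d x %d @ %.2f A, %d occupied voxel(s)>\n",
              x$scope, x$spec$dims[1], x$spec$dims[2], x$spec$dims[3],
              x$spec$spacing, sum(x$occupied)))
  invisible(x)
}

#' Voxelize a ligand (or one region) by van der Waals volume
#'
#' A voxel is occupied when its center lies within the element's van der
#' Waals radius of any in-scope atom.
#'
#' @param ligand a `twn_ligand`.
#' @param scope `"whole"`, `"head"`, `"linker"`, `"tail"` or `"Lprime"`.
#' @param grid a [grid_spec()]; default: [grid_from_atoms()] over the whole
#'   ligand, so that region grids are congruent with the whole-ligand grid.
#' @param spacing used when `grid` is `NULL`.
#' @param radii optional explicit per-atom radii (angstrom) overriding Bondi.
#' @return A `twn_grid`.
#' @export
voxelize_ligand <- function(ligand, scope = "whole", grid = NULL,
                            spacing = 0.5, radii = NULL) {
  stopifnot(inherits(ligand, "twn_ligand"))
  if (is.null(grid)) {
    grid <- grid_from_atoms(ligand_coords(ligand), spacing = spacing)
  }
  stopifnot(inherits(grid, "twn_grid_spec"))
  coords <- ligand_coords(ligand, scope = scope)  # errors on empty scope
  at <- ligand$atoms
  keep <- if (scope == "whole") rep(TRUE, nrow(at))
          else if (scope == "Lprime") at$lprime
          else at$region == .canon_label(scope)
  r <- if (is.null(radii)) vdw_radius(at$element[keep]) else radii
  occ <- array(FALSE, grid$dims)
  occ <- .mark_spheres(occ, grid, coords, r)
  .new_grid(grid, occ, scope = scope, n_sources = nrow(coords))
}

#' Voxelize TWN water density
#'
#' A voxel is occupied when its center lies within `water_radius` of any
#' member-water oxygen of any ring, aggregated (union) over frames; repeated
#' occurrences are idempotent.
#'
#' @param rings a per-ring data frame as produced by [occupancy_report()]
#'   (columns `frame` and `members` with original water indices), or a
#'   `twn_rings` object (then `frames` must be the single matching frame).
#' @param frames the `twn_frame` list the ring members index into (or a
#'   single frame).
#' @param grid a [grid_spec()] congruent with the ligand grid.
#' @param water_radius probe radius around each oxygen (angstrom,
#'   default 1.4).
#' @return A `twn_grid` with `n_sources` = number of ring instances used.
#' @export
voxelize_twn <- function(rings, frames, grid, water_radius = 1.4) {
  stopifnot(inherits(grid, "twn_grid_spec"))
  if (inherits(frames, "twn_frame")) frames <- list(frames)
  fr_index <- vapply(frames, `[[`, integer(1), "index")
  if (inherits(rings, "twn_rings")) {
    rings <- rings_table(rings, frames[[match(attr(rings, "frame_index"),
                                              fr_index)]])
  }
  stopifnot(is.data.frame(rings))
  oxy <- matrix(numeric(0), 0, 3)
  if (nrow(rings)) {
    pts <- vector("list", nrow(rings))
    for (r in seq_len(nrow(rings))) {
      fi <- match(rings$frame[r], fr_index)
      if (is.na(fi)) stop("ring references frame ", rings$frame[r],
                          " absent from the frame list")
      fr <- frames[[fi]]
      m <- rings$members[[r]]
      if (any(m < 1) || any(m > n_waters(fr))) {
        stop("ring member index out of range in frame ", rings$frame[r])
      }
      pts[[r]] <- fr$o[m, , drop = FALSE]
    }
    oxy <- unique(do.call(rbind, pts))
  }
  occ <- array(FALSE, grid$dims)
  if (nrow(oxy)) occ <- .mark_spheres(occ, grid, oxy, water_radius)
  .new_grid(grid, occ, scope = "twn", n_sources = nrow(rings))
}

#' Keep rings close to the ligand
#'
#' Retains rings whose center lies within `com_cutoff` (inclusive) of any
#' ligand *heavy* atom -- the extraction step before shape scoring.
#'
#' @param rings per-ring data frame (from [occupancy_report()]) with center
#'   columns `cx`, `cy`, `cz`.
#' @param ligand a `twn_ligand`.
#' @param com_cutoff center-of-mass cutoff in angstrom (default 2.0).
#' @return The filtered data frame.
#' @export
proximal_rings <- function(rings, ligand, com_cutoff = 2.0) {
  stopifnot(is.data.frame(rings), inherits(ligand, "twn_ligand"))
  if (!nrow(rings)) return(rings)
  heavy <- ligand_coords(ligand, heavy_only = TRUE)
  ctr <- as.matrix(rings[, c("cx", "cy", "cz")])
  dmin <- apply(ctr, 1, function(p) min(.dist_to(p, heavy)))
  rings[dmin <= com_cutoff, , drop = FALSE]
}

#' Ligand--TWN shape similarity
#'
#' Default convention (`"coverage"`): the percentage of ligand-occupied
#' voxels also occupied by TWN water density,
#' `100 * |lig & twn| / |lig|`. `"tanimoto"` scores the symmetric
#' `100 * |lig & twn| / |lig | twn|`.
#'
#' @param lig ligand `twn_grid` (from [voxelize_ligand()]).
#' @param twn TWN `twn_grid` (from [voxelize_twn()]), on a congruent grid.
#' @param mode `"coverage"` (default) or `"tanimoto"`.
#' @return A `twn_similarity`: list with `percent`, `scope`, `mode`,
#'   `n_rings_used`.
#' @export
shape_similarity <- function(lig, twn, mode = c("coverage", "tanimoto")) {
  stopifnot(inherits(lig, "twn_grid"), inherits(twn, "twn_grid"))
  mode <- match.arg(mode)
  if (!.same_grid(lig$spec, twn$spec)) {
    stop("ligand and TWN grids are not congruent (origin/spacing/dims differ)")
  }
  nlig <- sum(lig$occupied)
  if (nlig == 0) stop("ligand grid has no occupied voxels")
  inter <- sum(lig$occupied & twn$occupied)
  pct <- if (mode == "coverage") {
    100 * inter / nlig
  } else {
    uni <- sum(lig$occupied | twn$occupied)
    100 * inter / uni
  }
  structure(list(percent = pct, scope = lig$scope, mode = mode,
                 n_rings_used = twn$n_sources),
            class = "twn_similarity")
}

#' @export
print.twn_similarity <- function(x, ...) {
  cat(sprintf("shape similarity [%s, %s]: %.1f%% (%d ring(s) used)\n",
              x$scope, x$mode, x$percent, x$n_rings_used))
  invisible(x)
}

#' Export a grid as OpenDX volumetric text
#'
#' Writes occupancy as 0/1 values in OpenDX scalar format for visualization
#' (PyMOL, VMD, Chimera).
#'
#' @param grid a `twn_grid`.
#' @param path output `.dx` file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "twn_grid"))
  sp <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            sp$dims[1], sp$dims[2], sp$dims[3]),
    sprintf("origin %.4f %.4f %.4f",
            sp$origin[1] + sp$spacing / 2, sp$origin[2] + sp$spacing / 2,
            sp$origin[3] + sp$spacing / 2),
    sprintf("delta %.4f 0 0", sp$spacing),
    sprintf("delta 0 %.4f 0", sp$spacing),
    sprintf("delta 0 0 %.4f", sp$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            sp$dims[1], sp$dims[2], sp$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(sp$dims))
  ), con)
  # OpenDX expects z fastest
  vals <- as.numeric(aperm(grid$occupied, c(3, 2, 1)))
  full <- length(vals) %/% 3 * 3
  if (full > 0) {
    m <- matrix(vals[seq_len(full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%g %g %g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (full < length(vals)) {
    writeLines(paste(vals[(full + 1):length(vals)], collapse = " "), con)
  }
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"regular positions regular connections\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}
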