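# Rigid water geometry used by all generators (O-H 0.9572 A, H-O-H 104.52
# degrees -- the standard rigid 3-site geometry the potential's charges
# assume).
.WATER_OH <- 0.9572
.WATER_HOH <- 104.52 * pi / 180

# Run `expr` under a locally seeded RNG, restoring global RNG state after.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Build an ideal hydrogen-bonded water ring
#'
#' Places `size` oxygens at the vertices of a regular polygon with the given
#' O--O edge length. Each water donates one hydrogen along the edge to its
#' clockwise neighbour (a near-linear hydrogen bond); the free hydrogen lies
#' in the ring plane pointing radially outward, which keeps it away from both
#' neighbours. By construction every cyclically adjacent pair satisfies the
#' energy criterion under default parameters while non-adjacent pairs (sizes
#' >= 4) do not; this is re-checked at generation time against `params`
#' rather than assumed.
#'
#' @param size ring size, 3 to 6.
#' @param center ring center (angstrom).
#' @param normal ring plane normal.
#' @param o_o_distance O--O edge length (angstrom, default 2.8).
#' @param params a [potential_params()] used for the generation self-check.
#' @param check verify the H-bond postcondition (default `TRUE`).
#' @return A `twn_frame` fragment holding the ring's waters in cyclic order.
#' @examples
#' fr <- make_ring(5)
#' enumerate_rings(hbond_graph(fr))
#' @export
make_ring <- function(size, center = c(0, 0, 0), normal = c(0, 0, 1),
                      o_o_distance = 2.8, params = potential_params(),
                      check = TRUE) {
  size <- as.integer(size)
  if (is.na(size) || size < 3L || size > 6L) {
    stop("ring size must be between 3 and 6")
  }
  center <- as.numeric(center)
  nrm <- .unit(as.numeric(normal))
  e1 <- .perp(nrm)
  e2 <- .cross(nrm, e1)
  rc <- o_o_distance / (2 * sin(pi / size))
  th <- 2 * pi * (seq_len(size) - 1) / size
  o <- matrix(rep(center, each = size), size, 3) +
    rc * (cos(th) %o% e1 + sin(th) %o% e2)
  h1 <- h2 <- matrix(0, size, 3)
  for (i in seq_len(size)) {
    nxt <- if (i == size) 1L else i + 1L
    u <- .unit(o[nxt, ] - o[i, ])          # donor direction: along the edge
    w <- .cross(u, nrm)                     # in-plane, radially outward
    d2 <- cos(.WATER_HOH) * u + sin(.WATER_HOH) * w
    h1[i, ] <- o[i, ] + .WATER_OH * u
    h2[i, ] <- o[i, ] + .WATER_OH * d2
  }
  fr <- new_frame(o, h1, h2, resid = seq_len(size))
  if (check) .check_ring_energetics(fr, params)
  fr
}

.check_ring_energetics <- function(fr, params) {
  size <- n_waters(fr)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      if (j <= i) next
      adjacent <- (j == i + 1L) || (i == 1L && j == size)
      e <- pair_energy(water(fr, i), water(fr, j), params)
      if (adjacent && e > params$hbond_threshold) {
        stop("ring generation self-check failed: adjacent pair (", i, ",", j,
             ") has energy ", signif(e, 4), " kcal/mol above the threshold")
      }
      if (!adjacent && e <= params$hbond_threshold) {
        stop("ring generation self-check failed: non-adjacent pair (", i, ",",
             j, ") is hydrogen-bonded (", signif(e, 4), " kcal/mol)")
      }
    }
  }
  invisible(fr)
}

# One ideally shaped water at position p with a random orientation.
.random_water <- function(p) {
  repeat {
    v <- stats::rnorm(3)
    if (sum(v^2) > 1e-12) break
  }
  d1 <- .unit(v)
  a1 <- .perp(d1)
  a2 <- .cross(d1, a1)
  phi <- stats::runif(1, 0, 2 * pi)
  d2 <- cos(.WATER_HOH) * d1 +
    sin(.WATER_HOH) * (cos(phi) * a1 + sin(phi) * a2)
  list(o = p, h1 = p + .WATER_OH * d1, h2 = p + .WATER_OH * d2)
}

#' Random water box
#'
#' Places `n` randomly oriented waters uniformly in an orthorhombic box by
#' rejection sampling, enforcing a minimum O--O separation (minimum-image
#' when `periodic`). Reproducible for a fixed seed.
#'
#' @param n number of waters.
#' @param box three box edge lengths (angstrom); a scalar is recycled.
#' @param min_oo minimum O--O distance (angstrom, default 2.6).
#' @param seed integer seed (applied locally; global RNG state is restored).
#' @param periodic attach the box to the frame and use minimum-image
#'   separations (default `TRUE`).
#' @param max_tries placement attempts per water before giving up.
#' @return A `twn_frame`.
#' @export
make_box <- function(n, box = 30, min_oo = 2.6, seed = NULL, periodic = TRUE,
                     max_tries = 2000L) {
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("n must be a non-negative integer")
  if (length(box) == 1) box <- rep(box, 3)
  .check_box(box)
  .with_seed(seed, {
    o <- matrix(NA_real_, n, 3)
    h1 <- h2 <- o
    placed <- 0L
    while (placed < n) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        p <- stats::runif(3) * box
        if (placed == 0L ||
            min(.dist_to(p, o[seq_len(placed), , drop = FALSE],
                         if (periodic) box else NULL)) >= min_oo) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place ", n, " waters at min O-O ", min_oo,
             " angstrom in a ", paste(box, collapse = " x "),
             " box after ", max_tries, " tries")
      }
      placed <- placed + 1L
      w <- .random_water(p)
      o[placed, ] <- w$o
      h1[placed, ] <- w$h1
      h2[placed, ] <- w$h2
    }
    new_frame(o, h1, h2, resid = seq_len(n),
              box = if (periodic) box else NULL)
  })
}

#' Toy multi-region ligand
#'
#' A collinear rod of atoms along x with contiguous head, linker and tail
#' segments; one mid-linker atom (a carbonyl-like oxygen) is flagged L'.
#' Emulates the head/linker/tail partition of a reference inhibitor for
#' pipeline tests.
#'
#' @param n_head,n_linker,n_tail atoms per region (defaults 4/4/4).
#' @param spacing atom spacing along x (angstrom, default 1.5).
#' @param origin position of the first (head) atom.
#' @return List with `ligand` (a `twn_ligand`) and `annotation` (data frame
#'   with columns `atom`, `label`, round-trippable through
#'   [write_region_annotation()] / [read_ligand()]).
#' @export
make_toy_ligand <- function(n_head = 4L, n_linker = 4L, n_tail = 4L,
                            spacing = 1.5, origin = c(0, 0, 0)) {
  stopifnot(n_head >= 1, n_linker >= 1, n_tail >= 1, spacing > 0)
  n <- n_head + n_linker + n_tail
  x <- origin[1] + (seq_len(n) - 1) * spacing
  region <- c(rep("head", n_head), rep("linker", n_linker),
              rep("tail", n_tail))
  lp_idx <- n_head + ceiling(n_linker / 2)  # mid-linker carbonyl position
  element <- rep("C", n)
  element[lp_idx] <- "O"
  atoms <- data.frame(
    element = element, x = x, y = origin[2], z = origin[3],
    region = region, lprime = seq_len(n) == lp_idx,
    atom_name = paste0(element, seq_len(n)),
    stringsAsFactors = FALSE
  )
  lig <- new_ligand(atoms, name = "toy-rod")
  ann <- data.frame(atom = seq_len(n),
                    label = ifelse(atoms$lprime, "Lprime", region),
                    stringsAsFactors = FALSE)
  list(ligand = lig, annotation = ann)
}

#' Planted-scene specification
#'
#' Describes a synthetic multi-frame scene with known ground truth: water
#' rings planted next to chosen ligand regions plus noise waters kept far
#' enough from everything (pairwise and to all ring oxygens beyond the
#' H-bond prefilter) that they can neither form nor join rings.
#'
#' @param rings data frame with columns `size` (3--6) and `region`
#'   (head/linker/tail), optional `lprime` (logical: anchor the ring at the
#'   L' atom), `frame` (explicit frame number; default round-robin) and
#'   `offset` (per-ring anchor distance overriding the spec default, e.g. to
#'   plant rings within the proximal-extraction cutoff for shape scoring).
#' @param n_frames number of frames (default: enough for 2 rings per frame).
#' @param noise_waters noise waters per frame (default 0).
#' @param box sampling region edge length for noise placement (angstrom,
#'   default 60; frames themselves are aperiodic).
#' @param seed integer seed for noise placement.
#' @param offset distance from anchor atom to ring center (angstrom,
#'   default 4; must stay within the assignment cutoff).
#' @return A `twn_plant_spec`.
#' @export
plant_spec <- function(rings, n_frames = NULL, noise_waters = 0, box = 60,
                       seed = 1L, offset = 4) {
  stopifnot(is.data.frame(rings), all(c("size", "region") %in% names(rings)))
  if (any(rings$size < 3 | rings$size > 6)) {
    stop("planted ring sizes must be in [3, 6]")
  }
  if (!all(rings$region %in% c("head", "linker", "tail"))) {
    stop("planted ring regions must be head, linker or tail")
  }
  if (is.null(rings$lprime)) rings$lprime <- FALSE
  if (any(rings$lprime & rings$region != "linker")) {
    stop("L'-anchored rings must be linker rings")
  }
  if (is.null(rings$offset)) rings$offset <- NA_real_
  if (any(!is.na(rings$offset) & rings$offset <= 0)) {
    stop("per-ring offsets must be positive")
  }
  if (is.null(rings$frame)) {
    if (is.null(n_frames)) n_frames <- ceiling(nrow(rings) / 2)
    rings$frame <- ((seq_len(nrow(rings)) - 1L) %% n_frames) + 1L
  } else {
    n_frames <- max(n_frames, max(rings$frame), 1)
  }
  if (max(table(rings$frame)) > 2) {
    stop("at most 2 rings per frame can be planted with guaranteed isolation")
  }
  if (offset <= 0) stop("offset must be positive")
  structure(list(rings = rings, n_frames = as.integer(n_frames),
                 noise_waters = as.integer(noise_waters), box = box,
                 seed = as.integer(seed), offset = offset),
            class = "twn_plant_spec")
}

#' Generate a planted scene with known ground truth
#'
#' Builds `spec$n_frames` frames. Each planted ring is centered at
#' `spec$offset` angstrom from its anchor atom (a cycling atom of its target
#' region, or the L' atom when `lprime`), perpendicular to the ligand rod;
#' the two per-frame slots use opposite offset directions (+y / -y) so rings
#' stay isolated. Noise waters are rejected until they are farther than the
#' H-bond prefilter from every ring oxygen and from each other, so they
#' contribute no rings. Generation validates isolation and errors rather
#' than emitting a scene whose ground truth could be wrong.
#'
#' @param spec a [plant_spec()].
#' @param ligand a labelled `twn_ligand` (default [make_toy_ligand()]).
#' @param params a [potential_params()] (used for ring self-checks and the
#'   isolation margin).
#' @param assign_cutoff,lprime_cutoff the assignment cutoffs the scene is
#'   designed for (defaults match [occupancy_report()]); every planted ring's
#'   realised assignment is verified against the plan under these cutoffs.
#' @return List with `frames`, `ligand`, `truth` (list: `counts`, `percent`,
#'   `lprime_fraction`, `n_rings`) and `spec`.
#' @export
plant_scene <- function(spec, ligand = make_toy_ligand()$ligand,
                        params = potential_params(),
                        assign_cutoff = 5, lprime_cutoff = assign_cutoff) {
  stopifnot(inherits(spec, "twn_plant_spec"), inherits(ligand, "twn_ligand"))
  at <- ligand$atoms
  lig_xyz <- as.matrix(at[, c("x", "y", "z")])
  dirs <- list(c(0, 1, 0), c(0, -1, 0))
  margin <- params$distance_prefilter + 0.1
  # a linker ring NOT meant to carry the L' flag must keep its center beyond
  # lprime_cutoff of every L' atom, so it gets a larger perpendicular offset
  lp_xyz <- lig_xyz[at$lprime, , drop = FALSE]
  offset_for <- function(r) {
    if (!is.na(r$offset)) return(r$offset)
    if (r$region == "linker" && !r$lprime && nrow(lp_xyz) > 0) {
      min(assign_cutoff - 0.05, max(spec$offset, lprime_cutoff - 0.1))
    } else {
      spec$offset
    }
  }
  region_counter <- new.env(parent = emptyenv())
  frames <- vector("list", spec$n_frames)
  ring_rows <- split(seq_len(nrow(spec$rings)), spec$rings$frame)
  .with_seed(spec$seed, {
    for (f in seq_len(spec$n_frames)) {
      fragments <- list()
      oxy <- matrix(numeric(0), 0, 3)
      rows <- ring_rows[[as.character(f)]]
      for (slot in seq_along(rows)) {
        r <- spec$rings[rows[slot], ]
        anchor_pool <- if (r$lprime) {
          which(at$lprime)
        } else if (r$region == "linker") {
          which(at$region == "linker" & !at$lprime)
        } else {
          which(at$region == r$region)
        }
        if (!length(anchor_pool)) {
          stop("no anchor atoms available for a ", r$region,
               if (r$lprime) " (L')" else "", " ring")
        }
        cnt_key <- paste0(r$region, r$lprime)
        k <- (get0(cnt_key, region_counter, ifnotfound = 0L)) %%
          length(anchor_pool) + 1L
        assign(cnt_key, k, region_counter)
        anchor <- lig_xyz[anchor_pool[k], ]
        ctr <- anchor + offset_for(r) * dirs[[slot]]
        frag <- make_ring(r$size, center = ctr, normal = dirs[[slot]],
                          params = params)
        asg <- assign_ring(seq_len(n_waters(frag)), frag, ligand,
                           cutoff = assign_cutoff,
                           lprime_cutoff = lprime_cutoff)
        if (asg$region != r$region || asg$lprime != r$lprime) {
          stop("planted ring in frame ", f, " would be assigned ",
               asg$region, if (asg$lprime) "/L'" else "",
               " instead of the planned ", r$region,
               if (r$lprime) "/L'" else "",
               "; adjust the ligand layout or offsets")
        }
        fragments[[length(fragments) + 1L]] <- frag
        oxy <- rbind(oxy, frag$o)
      }
      # isolation check between planted rings of this frame
      if (length(fragments) == 2) {
        d <- as.matrix(stats::dist(oxy))
        n1 <- n_waters(fragments[[1]])
        cross <- d[seq_len(n1), (n1 + 1):nrow(oxy), drop = FALSE]
        if (min(cross) <= margin) {
          stop("planted rings in frame ", f, " are closer than the H-bond ",
               "prefilter (", signif(min(cross), 3), " angstrom); reduce ",
               "rings per frame or enlarge the ligand")
        }
      }
      # noise waters: isolated from each other and from all ring oxygens
      if (spec$noise_waters > 0) {
        lo <- colMeans(lig_xyz) - spec$box / 2
        placed <- matrix(NA_real_, spec$noise_waters, 3)
        np <- 0L
        tries <- 0L
        while (np < spec$noise_waters) {
          tries <- tries + 1L
          if (tries > 20000L) stop("noise-water placement failed; enlarge box")
          p <- lo + stats::runif(3) * spec$box
          prev <- placed[seq_len(np), , drop = FALSE]
          if ((nrow(oxy) == 0 || min(.dist_to(p, oxy)) > margin) &&
              (np == 0L || min(.dist_to(p, prev)) > margin)) {
            np <- np + 1L
            placed[np, ] <- p
          }
        }
        nw <- lapply(seq_len(spec$noise_waters),
                     function(i) .random_water(placed[i, ]))
        fragments[[length(fragments) + 1L]] <- new_frame(
          o = do.call(rbind, lapply(nw, `[[`, "o")),
          h1 = do.call(rbind, lapply(nw, `[[`, "h1")),
          h2 = do.call(rbind, lapply(nw, `[[`, "h2"))
        )
      }
      frames[[f]] <- if (length(fragments)) {
        bind_waters(fragments, index = f)
      } else {
        new_frame(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3),
                  matrix(numeric(0), 0, 3), index = f)
      }
    }
  })
  counts <- vapply(c("head", "linker", "tail"),
                   function(r) sum(spec$rings$region == r), integer(1))
  n_assigned <- sum(counts)
  truth <- list(
    counts = counts,
    percent = if (n_assigned) 100 * counts / n_assigned else counts * 0,
    lprime_fraction = if (counts[["linker"]] > 0) {
      100 * sum(spec$rings$lprime) / counts[["linker"]]
    } else 0,
    n_rings = nrow(spec$rings)
  )
  list(frames = frames, ligand = ligand, truth = truth, spec = spec)
}
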