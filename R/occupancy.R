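#' Binding-site specification
#'
#' A sphere around the binding site; waters whose oxygen lies within
#' `radius` of `center` are retained for ring analysis. When `center` is
#' `NULL`, [occupancy_report()] uses the reference-ligand centroid.
#'
#' @param center length-3 coordinates (angstrom) or `NULL`.
#' @param radius sphere radius in angstrom (default 25).
#' @return A `twn_site` object.
#' @export
site_spec <- function(center = NULL, radius = 25) {
  if (!is.null(center)) {
    center <- as.numeric(center)
    if (length(center) != 3 || any(!is.finite(center))) {
      stop("site center must be three finite coordinates")
    }
  }
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    stop("site radius must be a positive number (angstrom)")
  }
  structure(list(center = center, radius = radius), class = "twn_site")
}

.resolve_site <- function(site, ligand = NULL) {
  stopifnot(inherits(site, "twn_site"))
  if (is.null(site$center)) {
    if (is.null(ligand)) {
      stop("site center is undefined and no reference ligand was given")
    }
    site$center <- colMeans(ligand_coords(ligand))
  }
  site
}

#' Restrict a frame to binding-site waters
#'
#' Keeps waters whose oxygen lies within `site$radius` of the site center
#' (inclusive boundary), preserving water order. The original indices of the
#' kept waters are recorded in the result's `"index_map"` attribute.
#' Minimum-image distances are used when the frame has a box.
#'
#' @param frame a `twn_frame`.
#' @param site a [site_spec()] with a resolved center.
#' @return The subset `twn_frame` (with a warning when empty).
#' @export
select_site_waters <- function(frame, site) {
  stopifnot(inherits(frame, "twn_frame"))
  site <- .resolve_site(site)
  keep <- which(.dist_to(site$center, frame$o, frame$box) <= site$radius)
  if (!length(keep)) {
    warning("no waters within ", site$radius, " angstrom of the site center",
            " in frame ", frame$index)
  }
  sub <- new_frame(frame$o[keep, , drop = FALSE],
                   frame$h1[keep, , drop = FALSE],
                   frame$h2[keep, , drop = FALSE],
                   resid = frame$resid[keep], box = frame$box,
                   index = frame$index, time = frame$time,
                   other = frame$other, validate = FALSE)
  attr(sub, "index_map") <- keep
  sub
}

#' Assign a water ring to a ligand region
#'
#' The ring is assigned to the region of the labelled ligand atom nearest to
#' the ring center, provided that distance is at most `cutoff`; otherwise it
#' is `unassigned`. Exact ties are broken by label priority
#' L' > linker > head > tail. A linker-assigned ring is additionally flagged
#' L' when its center lies within `lprime_cutoff` of any L' atom.
#'
#' @param members integer vector of ring member indices (one element of a
#'   `twn_rings` object).
#' @param frame the `twn_frame` the ring lives in.
#' @param ligand a labelled `twn_ligand`.
#' @param cutoff assignment cutoff in angstrom (default 5).
#' @param lprime_cutoff L' sub-flag cutoff (default: same as `cutoff`).
#' @param weighting passed to [ring_center()].
#' @return List with `region` (head/linker/tail/unassigned), `lprime`
#'   (logical), `distance` (to the nearest labelled atom) and `center`.
#' @export
assign_ring <- function(members, frame, ligand, cutoff = 5,
                        lprime_cutoff = cutoff,
                        weighting = c("oxygen", "mass")) {
  stopifnot(inherits(ligand, "twn_ligand"))
  weighting <- match.arg(weighting)
  at <- ligand$atoms
  lab_idx <- which(at$region != "unlabeled")
  if (!length(lab_idx)) stop("ligand has no labelled atoms")
  ctr <- ring_center(members, frame, weighting = weighting)
  d <- .dist_to(ctr, as.matrix(at[lab_idx, c("x", "y", "z")]))
  dmin <- min(d)
  if (dmin > cutoff) {
    return(list(region = "unassigned", lprime = FALSE, distance = dmin,
                center = ctr))
  }
  tied <- lab_idx[d <= dmin + 1e-9]
  # priority: L' > linker > head > tail
  pri <- ifelse(at$lprime[tied], 4L,
                ifelse(at$region[tied] == "linker", 3L,
                       ifelse(at$region[tied] == "head", 2L, 1L)))
  best <- tied[which.max(pri)]
  region <- at$region[best]
  lp <- FALSE
  if (region == "linker" && any(at$lprime)) {
    dlp <- .dist_to(ctr, as.matrix(at[at$lprime, c("x", "y", "z"),
                                      drop = FALSE]))
    lp <- min(dlp) <= lprime_cutoff
  }
  list(region = region, lprime = lp, distance = dmin, center = ctr)
}

#' Aggregate TWN occupancy over frames
#'
#' Runs the full per-frame pipeline -- site-water selection, H-bond graph,
#' chordless ring enumeration, region assignment -- and pools ring instances
#' over all frames (a ring counts once per frame it appears in). Percentages
#' are computed over *assigned* rings only; the L' fraction is the share of
#' linker rings flagged L'.
#'
#' @param frames a `twn_frame` or list of them.
#' @param ligand a labelled `twn_ligand`.
#' @param site a [site_spec()]; a `NULL` center defaults to the ligand
#'   centroid.
#' @param params a [potential_params()].
#' @param assign_cutoff ring-to-region assignment cutoff (angstrom).
#' @param lprime_cutoff L' sub-flag cutoff (default: `assign_cutoff`).
#' @param min_size,max_size ring sizes to enumerate.
#' @param all_cycles passed to [enumerate_rings()].
#' @param method passed to [hbond_graph()].
#' @param weighting passed to [ring_center()].
#' @return A `twn_occupancy` object: list with `counts` (named vector over
#'   head/linker/tail/unassigned), `percent` (over assigned rings),
#'   `lprime_fraction` (percent of linker rings near L'), `n_frames`,
#'   `n_rings`, `no_assigned_rings` flag, and `rings` (per-ring data frame
#'   with original water indices in the `members` list column).
#' @export
occupancy_report <- function(frames, ligand, site = site_spec(),
                             params = potential_params(),
                             assign_cutoff = 5, lprime_cutoff = assign_cutoff,
                             min_size = 3L, max_size = 6L,
                             all_cycles = FALSE,
                             method = c("cell", "exhaustive"),
                             weighting = c("oxygen", "mass")) {
  if (inherits(frames, "twn_frame")) frames <- list(frames)
  if (!length(frames)) stop("at least one frame is required")
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  site <- .resolve_site(site, ligand)
  if (assign_cutoff <= 0) stop("assign_cutoff must be positive")
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    sub <- withCallingHandlers(
      select_site_waters(fr, site),
      warning = function(w) invokeRestart("muffleWarning")
    )
    imap <- attr(sub, "index_map")
    g <- hbond_graph(sub, params, method = method)
    rings <- enumerate_rings(g, min_size = min_size, max_size = max_size,
                             all_cycles = all_cycles)
    rl <- unclass(rings)
    if (!length(rl)) next
    asg <- lapply(rl, assign_ring, frame = sub, ligand = ligand,
                  cutoff = assign_cutoff, lprime_cutoff = lprime_cutoff,
                  weighting = weighting)
    ctr <- t(vapply(asg, `[[`, numeric(3), "center"))
    rows[[k]] <- data.frame(
      frame = fr$index,
      size = vapply(rl, length, integer(1)),
      region = vapply(asg, `[[`, character(1), "region"),
      lprime = vapply(asg, `[[`, logical(1), "lprime"),
      distance = vapply(asg, `[[`, numeric(1), "distance"),
      members = I(lapply(rl, function(v) as.integer(imap[v]))),
      resids = vapply(rl, function(v) paste(sub$resid[v], collapse = ","),
                      character(1)),
      cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(frame = integer(0), size = integer(0),
                      region = character(0), lprime = logical(0),
                      distance = numeric(0), members = I(list()),
                      resids = character(0), cx = numeric(0), cy = numeric(0),
                      cz = numeric(0))
  }
  regions <- c("head", "linker", "tail")
  counts <- vapply(c(regions, "unassigned"),
                   function(r) sum(tab$region == r), integer(1))
  n_assigned <- sum(counts[regions])
  pct <- if (n_assigned > 0) 100 * counts[regions] / n_assigned
         else stats::setNames(rep(0, 3), regions)
  n_linker <- counts[["linker"]]
  lpf <- if (n_linker > 0) 100 * sum(tab$lprime) / n_linker else 0
  structure(
    list(counts = counts, percent = pct, lprime_fraction = lpf,
         n_frames = length(frames), n_rings = nrow(tab),
         no_assigned_rings = n_assigned == 0, rings = tab,
         site = site, assign_cutoff = assign_cutoff,
         lprime_cutoff = lprime_cutoff),
    class = "twn_occupancy"
  )
}

#' @export
print.twn_occupancy <- function(x, ...) {
  cat(sprintf("TWN occupancy over %d frame(s): %d ring(s), %d assigned\n",
              x$n_frames, x$n_rings, sum(x$counts[c("head", "linker", "tail")])))
  if (x$no_assigned_rings) {
    cat("  [no rings assigned to any ligand region]\n")
  } else {
    for (r in c("head", "linker", "tail")) {
      cat(sprintf("  %-7s %5d  %6.1f%%\n", r, x$counts[[r]], x$percent[[r]]))
    }
    cat(sprintf("  L' fraction of linker rings: %.1f%%\n", x$lprime_fraction))
  }
  if (x$counts[["unassigned"]] > 0) {
    cat(sprintf("  unassigned: %d\n", x$counts[["unassigned"]]))
  }
  invisible(x)
}

#' Write an occupancy report
#'
#' @param report a `twn_occupancy`.
#' @param path output file; `.json` for a structured report, anything else
#'   for the per-ring TSV.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(report, path) {
  stopifnot(inherits(report, "twn_occupancy"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- list(
      n_frames = report$n_frames,
      n_rings = report$n_rings,
      counts = as.list(report$counts),
      percent = as.list(round(report$percent, 6)),
      lprime_fraction = round(report$lprime_fraction, 6),
      no_assigned_rings = report$no_assigned_rings,
      site = list(center = report$site$center, radius = report$site$radius),
      assign_cutoff = report$assign_cutoff,
      lprime_cutoff = report$lprime_cutoff
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    write_rings(report$rings[, c("frame", "size", "region", "lprime",
                                 "distance", "members", "resids",
                                 "cx", "cy", "cz")], path)
  }
  invisible(path)
}
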