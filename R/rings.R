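#' Enumerate water rings (chordless cycles) in an H-bond graph
#'
#' A topological water network (TWN) is a cyclic arrangement of 3--6 waters
#' mutually connected by hydrogen bonds. A ring here is a *chordless* simple
#' cycle: consecutive members are graph edges and no edge connects
#' non-consecutive members. This matches chemical ring perception and avoids
#' double counting (a triangle inside a square suppresses the square).
#' `all_cycles = TRUE` switches to all simple cycles for sensitivity
#' analysis.
#'
#' Each ring is reported once, in canonical form: lowest member index first,
#' followed by the lower of its two cycle neighbours; output is sorted by
#' canonical tuple, so results are independent of edge input order.
#'
#' @param graph a `twn_hbond_graph` from [hbond_graph()].
#' @param min_size,max_size ring size bounds; must satisfy
#'   `3 <= min_size <= max_size <= 6`.
#' @param all_cycles if `TRUE`, report all simple cycles in the size range,
#'   not only chordless ones.
#' @return A `twn_rings` object: list of integer member vectors with
#'   attributes `frame_index` and `n_nodes`.
#' @examples
#' g <- structure(list(n = 6L,
#'                     edges = cbind(1:6, c(2:6, 1L)),
#'                     frame_index = 1L), class = "twn_hbond_graph")
#' enumerate_rings(g)   # one 6-ring
#' @export
enumerate_rings <- function(graph, min_size = 3L, max_size = 6L,
                            all_cycles = FALSE) {
  stopifnot(inherits(graph, "twn_hbond_graph"))
  min_size <- as.integer(min_size)
  max_size <- as.integer(max_size)
  if (is.na(min_size) || is.na(max_size) || min_size < 3L || max_size > 6L ||
      max_size < min_size) {
    stop("ring size bounds must satisfy 3 <= min_size <= max_size <= 6")
  }
  n <- graph$n
  edges <- graph$edges
  rings <- list()
  if (n >= min_size && nrow(edges) >= min_size) {
    adj <- vector("list", n)
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]
      j <- edges[r, 2]
      if (i == j) stop("self-loop in H-bond graph")
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
    amat <- matrix(FALSE, n, n)
    amat[edges] <- TRUE
    amat[edges[, 2:1, drop = FALSE]] <- TRUE
    acc <- new.env(parent = emptyenv())
    acc$rings <- vector("list", 64)
    acc$k <- 0L
    for (s in seq_len(n)) {
      nb <- adj[[s]]
      nb <- nb[nb > s]
      if (length(nb) < 1) next
      for (v1 in nb) {
        .ring_dfs(c(s, v1), adj, amat, s, min_size, max_size, all_cycles, acc)
      }
    }
    rings <- acc$rings[seq_len(acc$k)]
    if (length(rings)) {
      # sort by canonical tuple (pad shorter rings; size breaks remaining ties)
      pad <- max_size
      keymat <- t(vapply(rings, function(m) c(m, rep(0L, pad - length(m))),
                         integer(pad)))
      ord <- do.call(order, c(as.data.frame(keymat),
                              list(vapply(rings, length, integer(1)))))
      rings <- rings[ord]
      rings <- rings[!duplicated(vapply(rings, paste, character(1),
                                        collapse = "-"))]
    }
  }
  structure(rings, class = "twn_rings",
            frame_index = graph$frame_index, n_nodes = n)
}

# DFS extension of a path anchored at its smallest vertex `s`. Visits only
# vertices > s so each cycle is found from its minimum member; direction is
# deduplicated by requiring path[2] < closing vertex. For chordless mode a
# new vertex may touch only its predecessor (plus `s` when closing).
.ring_dfs <- function(path, adj, amat, s, min_size, max_size, all_cycles, acc) {
  last <- path[length(path)]
  len <- length(path)
  for (w in adj[[last]]) {
    if (w <= s || w %in% path) next
    closes <- amat[w, s]
    if (!all_cycles) {
      mid <- if (len >= 3) path[2:(len - 1)] else integer(0)
      if (length(mid) && any(amat[w, mid])) next
    }
    if (closes && len + 1L >= min_size && path[2] < w) {
      acc$k <- acc$k + 1L
      if (acc$k > length(acc$rings)) {
        acc$rings <- c(acc$rings, vector("list", length(acc$rings)))
      }
      acc$rings[[acc$k]] <- as.integer(c(path, w))
    }
    # chordless mode never extends through a vertex adjacent to s: the
    # (w, s) edge would become a chord of any longer cycle
    extend <- len + 1L < max_size && (all_cycles || !closes)
    if (extend) {
      .ring_dfs(c(path, w), adj, amat, s, min_size, max_size, all_cycles, acc)
    }
  }
  invisible(NULL)
}

#' @export
print.twn_rings <- function(x, ...) {
  sz <- vapply(unclass(x), length, integer(1))
  cat(sprintf("<twn_rings frame %d: %d ring(s)%s>\n",
              attr(x, "frame_index"), length(sz),
              if (length(sz)) paste0(" [sizes ",
                                     paste(sort(unique(sz)), collapse = ","),
                                     "]") else ""))
  invisible(x)
}

#' Ring center
#'
#' Center of a water ring: the unweighted centroid of member oxygen
#' positions (oxygen carries 16/18 of the water mass; `weighting = "mass"`
#' instead averages all nine sites with masses 16/1/1). With a periodic box,
#' members are first unwrapped to the first member's image so a ring
#' straddling a boundary gets a center at the cluster, not at the box
#' center.
#'
#' @param members integer vector of member water indices (one element of a
#'   `twn_rings` object).
#' @param frame the `twn_frame` the ring was found in.
#' @param weighting `"oxygen"` (default) or `"mass"`.
#' @return Length-3 coordinate vector (angstrom).
#' @export
ring_center <- function(members, frame, weighting = c("oxygen", "mass")) {
  stopifnot(inherits(frame, "twn_frame"))
  weighting <- match.arg(weighting)
  members <- as.integer(members)
  if (any(is.na(members)) || any(members < 1) || any(members > n_waters(frame))) {
    stop("ring member index out of range for frame ", frame$index)
  }
  o <- frame$o[members, , drop = FALSE]
  ref <- o[1, ]
  shift <- .image_shift(ref, o, frame$box)
  o <- o + shift
  if (weighting == "oxygen") {
    colMeans(o)
  } else {
    h1 <- frame$h1[members, , drop = FALSE] + shift
    h2 <- frame$h2[members, , drop = FALSE] + shift
    (16 * colSums(o) + colSums(h1) + colSums(h2)) / (18 * length(members))
  }
}

#' Tabulate rings of one frame
#'
#' @param rings a `twn_rings` object.
#' @param frame the `twn_frame` it was computed from.
#' @param index_map optional integer vector mapping the frame's water indices
#'   back to an original numbering (as recorded by [select_site_waters()]).
#' @param weighting passed to [ring_center()].
#' @return Data frame with columns `frame`, `size`, `members` (list column of
#'   water indices, remapped through `index_map` when given), `resids`
#'   (comma-separated residue ids) and center `cx`, `cy`, `cz`.
#' @export
rings_table <- function(rings, frame, index_map = NULL,
                        weighting = c("oxygen", "mass")) {
  stopifnot(inherits(rings, "twn_rings"), inherits(frame, "twn_frame"))
  weighting <- match.arg(weighting)
  rl <- unclass(rings)
  m <- length(rl)
  ctr <- if (m) t(vapply(rl, ring_center, numeric(3), frame = frame,
                         weighting = weighting)) else matrix(numeric(0), 0, 3)
  members <- lapply(rl, function(v) {
    if (is.null(index_map)) v else as.integer(index_map[v])
  })
  data.frame(
    frame = rep(attr(rings, "frame_index"), m),
    size = vapply(rl, length, integer(1)),
    members = I(members),
    resids = vapply(rl, function(v) paste(frame$resid[v], collapse = ","),
                    character(1)),
    cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
    stringsAsFactors = FALSE
  )
}

#' Write a ring table to TSV or JSON
#'
#' @param tab data frame from [rings_table()] (or the `rings` component of an
#'   occupancy report).
#' @param path output file; format chosen by extension (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_rings <- function(tab, path) {
  flat <- tab
  flat$members <- vapply(tab$members, paste, character(1), collapse = ",")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
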