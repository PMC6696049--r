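# Independent oracles, written as plain loops so they share no code path
# with the package internals they check.

# Term-by-term 9-pair summation of the water pair potential: Coulomb over
# all site pairs plus Lennard-Jones on O-O.
oracle_pair_energy <- function(a, b, params = potential_params(),
                               box = NULL) {
  bshift <- c(0, 0, 0)
  if (!is.null(box)) {
    d <- b$o - a$o
    bshift <- -round(d / box) * box
  }
  sites_a <- list(a$o, a$h1, a$h2)
  sites_b <- list(b$o + bshift, b$h1 + bshift, b$h2 + bshift)
  q <- c(params$q_O, params$q_H, params$q_H)
  coul <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      r <- sqrt(sum((sites_a[[i]] - sites_b[[j]])^2))
      coul <- coul + params$coulomb_constant * q[i] * q[j] / r
    }
  }
  roo <- sqrt(sum((a$o - sites_b[[1]])^2))
  coul + params$A / roo^12 - params$C / roo^6
}

# All chordless cycles of size [min_size, max_size] by exhaustive subset
# enumeration: a vertex subset whose induced subgraph is a single cycle IS a
# chordless cycle. Returns canonical integer vectors (min vertex first, then
# its smaller neighbour), sorted.
oracle_chordless <- function(n, edges, min_size = 3, max_size = 6) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  out <- list()
  for (k in min_size:max_size) {
    if (n < k) next
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      deg <- vapply(sub, function(v) sum(A[v, sub]), integer(1))
      if (!all(deg == 2L)) next
      start <- min(sub)
      nbrs <- sub[A[start, sub]]
      path <- c(start, min(nbrs))
      ok <- TRUE
      while (length(path) < k) {
        cur <- path[length(path)]
        nxt <- setdiff(sub[A[cur, sub]], path)   # never revisit a vertex
        if (length(nxt) != 1) { ok <- FALSE; break }
        path <- c(path, nxt)
      }
      if (ok && length(path) == k && A[path[k], start]) {
        out[[length(out) + 1L]] <- as.integer(path)
      }
    }
  }
  out
}

ring_signatures <- function(rings) {
  sort(vapply(rings, paste, character(1), collapse = "-"))
}

# One rigid ideal-geometry water at p with orientation angles drawn from the
# current RNG stream.
rand_water <- function(p) {
  roh <- 0.9572
  hoh <- 104.52 * pi / 180
  repeat {
    v <- stats::rnorm(3)
    if (sum(v^2) > 1e-12) break
  }
  d1 <- v / sqrt(sum(v^2))
  ref <- if (abs(d1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a1 <- c(d1[2] * ref[3] - d1[3] * ref[2],
          d1[3] * ref[1] - d1[1] * ref[3],
          d1[1] * ref[2] - d1[2] * ref[1])
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(d1[2] * a1[3] - d1[3] * a1[2],
          d1[3] * a1[1] - d1[1] * a1[3],
          d1[1] * a1[2] - d1[2] * a1[1])
  phi <- stats::runif(1, 0, 2 * pi)
  d2 <- cos(hoh) * d1 + sin(hoh) * (cos(phi) * a1 + sin(phi) * a2)
  list(o = p, h1 = p + roh * d1, h2 = p + roh * d2)
}

# A random water dimer with O-O separation in [2.5, 6] angstrom.
rand_dimer <- function() {
  a <- rand_water(c(0, 0, 0))
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  b <- rand_water(dir * stats::runif(1, 2.5, 6))
  list(a = a, b = b)
}

# Canonical linear hydrogen-bond dimer: donor O-H along +x toward the
# acceptor oxygen at (roo, 0, 0); acceptor bisector points along +x.
canonical_dimer <- function(roo = 2.8) {
  roh <- 0.9572
  hoh <- 104.52 * pi / 180
  half <- hoh / 2
  a <- list(o = c(0, 0, 0),
            h1 = c(roh, 0, 0),
            h2 = roh * c(cos(hoh), sin(hoh), 0))
  o_b <- c(roo, 0, 0)
  b <- list(o = o_b,
            h1 = o_b + roh * c(cos(half), 0, sin(half)),
            h2 = o_b + roh * c(cos(half), 0, -sin(half)))
  list(a = a, b = b)
}

rand_rotation <- function() {
  th <- stats::runif(1, 0, 2 * pi)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotate_water <- function(w, R, t = c(0, 0, 0)) {
  list(o = as.numeric(R %*% w$o + t),
       h1 = as.numeric(R %*% w$h1 + t),
       h2 = as.numeric(R %*% w$h2 + t))
}

# Erdos-Renyi graph as a twn_hbond_graph-shaped object.
rand_graph <- function(n, p) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  storage.mode(edges) <- "integer"
  structure(list(n = as.integer(n), edges = edges, frame_index = 1L),
            class = "twn_hbond_graph")
}

make_graph <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  structure(list(n = as.integer(n),
                 edges = cbind(pmin(edges[, 1], edges[, 2]),
                               pmax(edges[, 1], edges[, 2])),
                 frame_index = 1L),
            class = "twn_hbond_graph")
}

# Frozen golden number: canonical_dimer(2.8) evaluated by an independent
# term-by-term summation script (9 Coulomb pairs + O-O Lennard-Jones).
GOLDEN_DIMER_ENERGY <- -6.1749390609
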