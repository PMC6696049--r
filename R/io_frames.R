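#' Default water residue names
#'
#' Residue names recognised as 3-site waters when assembling frames.
#' @return Character vector.
#' @export
default_water_resnames <- function() c("SOL", "HOH", "WAT", "TIP3", "SPC")

#' Read multi-frame water coordinates
#'
#' Reads a multi-model PDB (MODEL/ENDMDL delimits frames; a PDB without MODEL
#' records is one frame) or a (possibly concatenated multi-frame) GRO file,
#' assembles each water residue into an O/H1/H2 triple, and returns one
#' [new_frame()] per snapshot. GRO coordinates (nm) are converted to angstrom
#' on read. Boxes come from the PDB `CRYST1` record or the GRO box line; only
#' orthorhombic boxes are supported (all-90-degree cell angles, no GRO
#' off-diagonal components). Frames without box information are returned with
#' `box = NULL` and a warning.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param water_resnames residue names treated as water
#'   (default [default_water_resnames()]).
#' @return List of `twn_frame` objects, in file order. Non-water atoms are
#'   retained in each frame's `other` data frame for optional site centering.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "gro"),
                        water_resnames = default_water_resnames()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  frames <- switch(format,
                   pdb = .read_frames_pdb(path, water_resnames),
                   gro = .read_frames_gro(path, water_resnames))
  if (any(vapply(frames, function(f) is.null(f$box), logical(1)))) {
    warning("no box information found in ", basename(path),
            "; frames returned without periodic box")
  }
  frames
}

# ---- PDB ---------------------------------------------------------------

.read_frames_pdb <- function(path, water_resnames) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (ln in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (any(is.na(xyz))) {
      stop("malformed PDB coordinate record at line ", ln, " of ", path)
    }
  }
  box <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl)) {
    f <- suppressWarnings(as.numeric(c(
      substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33),
      substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54))))
    if (any(is.na(f))) stop("malformed CRYST1 record in ", path)
    if (any(abs(f[4:6] - 90) > 1e-3)) {
      stop("triclinic box not supported (CRYST1 angles ",
           paste(f[4:6], collapse = ", "), ")")
    }
    # PDB files for non-periodic systems often carry a placeholder unit cell
    if (!all(abs(f[1:3] - 1) < 1e-6)) box <- f[1:3]
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  elem <- .atom_element(at$elesy, at$elety)
  # residue key: resno + chain + insert identifies one molecule
  key <- paste(at$resno, ifelse(is.na(at$chain), "", at$chain),
               ifelse(is.na(at$insert), "", at$insert), sep = "|")
  is_wat <- at$resid %in% water_resnames
  lapply(seq_len(n_frames), function(fi) {
    co <- matrix(xyz[fi, ], ncol = 3, byrow = TRUE)
    .assemble_frame(co, elem, at$resid, key, is_wat, box = box,
                    index = fi, time = NULL, src = path)
  })
}

.atom_element <- function(elesy, elety) {
  e <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  fallback <- toupper(substr(gsub("[^A-Za-z].*$", "", elety), 1, 1))
  ifelse(is.na(e), fallback, e)
}

# ---- GRO ---------------------------------------------------------------

.read_frames_gro <- function(path, water_resnames) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  pos <- 1L
  fi <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    title <- lines[pos]
    if (pos + 1L > length(lines)) stop("truncated GRO file at line ", pos)
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat) || nat < 0) {
      stop("malformed GRO atom-count record at line ", pos + 1L, " of ", path)
    }
    if (pos + 1L + nat + 1L > length(lines)) {
      stop("truncated GRO frame starting at line ", pos, " of ", path)
    }
    al <- lines[(pos + 2L):(pos + 1L + nat)]
    resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
    resname <- trimws(substr(al, 6, 10))
    atname <- trimws(substr(al, 11, 15))
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad)) {
      stop("malformed GRO atom record at line ", pos + 1L + bad[1], " of ", path)
    }
    bl <- suppressWarnings(as.numeric(strsplit(trimws(lines[pos + 1L + nat + 1L]),
                                               "\\s+")[[1]]))
    if (!length(bl) || any(is.na(bl))) {
      stop("malformed GRO box record at line ", pos + 2L + nat, " of ", path)
    }
    if (length(bl) > 3 && any(abs(bl[-(1:3)]) > 1e-9)) {
      stop("triclinic GRO box not supported (line ", pos + 2L + nat, ")")
    }
    box <- if (all(bl[1:3] > 0)) bl[1:3] * 10 else NULL
    tm <- NULL
    tmatch <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tmatch)) tm <- as.numeric(sub("t=\\s*", "", tmatch))
    co <- cbind(x, y, z) * 10  # nm -> angstrom
    elem <- toupper(substr(atname, 1, 1))
    key <- as.character(resno)
    fi <- fi + 1L
    frames[[fi]] <- .assemble_frame(co, elem, resname, key,
                                    resname %in% water_resnames,
                                    box = box, index = fi, time = tm,
                                    src = path)
    pos <- pos + nat + 3L
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

# Group water atoms by residue key into O/H1/H2 triples, preserving file
# order of residues; non-water atoms are kept in `other`.
.assemble_frame <- function(co, elem, resname, key, is_wat, box, index, time,
                            src) {
  wkey <- key[is_wat]
  uk <- unique(wkey)
  widx <- split(which(is_wat), factor(wkey, levels = uk))
  n <- length(uk)
  o <- h1 <- h2 <- matrix(NA_real_, n, 3)
  for (w in seq_len(n)) {
    ai <- widx[[w]]
    if (length(ai) != 3) {
      stop("water residue ", uk[w], " in ", basename(src), " has ",
           length(ai), " atoms (expected 3)")
    }
    el <- elem[ai]
    oi <- ai[el == "O"]
    hi <- ai[el == "H"]
    if (length(oi) != 1 || length(hi) != 2) {
      stop("water residue ", uk[w], " in ", basename(src),
           " does not have 1 oxygen + 2 hydrogens")
    }
    o[w, ] <- co[oi, ]
    h1[w, ] <- co[hi[1], ]
    h2[w, ] <- co[hi[2], ]
  }
  other <- NULL
  if (any(!is_wat)) {
    oi <- which(!is_wat)
    other <- data.frame(element = elem[oi], x = co[oi, 1], y = co[oi, 2],
                        z = co[oi, 3], resname = resname[oi],
                        stringsAsFactors = FALSE)
  }
  new_frame(o, h1, h2, resid = uk, box = box, index = index, time = time,
            other = other)
}

# ---- writers -----------------------------------------------------------

#' Write frames to GRO or PDB
#'
#' Serialises water frames (fixture output, subset frames) back to a standard
#' coordinate format. GRO is written in nm at the format's 0.001 nm
#' precision; PDB as multi-model with a `CRYST1` record when a box is
#' present.
#'
#' @param frames a `twn_frame` or list of them.
#' @param path output file.
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (inherits(frames, "twn_frame")) frames <- list(frames)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gro") {
    for (fr in frames) {
      n <- n_waters(fr)
      writeLines(sprintf("twnr frame %d%s", fr$index,
                         if (!is.null(fr$time)) sprintf(" t= %g", fr$time)
                         else ""), con)
      writeLines(sprintf("%5d", 3L * n), con)
      for (i in seq_len(n)) {
        resno <- i %% 100000L
        for (s in list(c("OW", 1L), c("HW1", 2L), c("HW2", 3L))) {
          xyz <- switch(s[1], OW = fr$o[i, ], HW1 = fr$h1[i, ],
                        HW2 = fr$h2[i, ]) / 10
          writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                             resno, "SOL", s[1],
                             ((i - 1L) * 3L + as.integer(s[2])) %% 100000L,
                             xyz[1], xyz[2], xyz[3]), con)
        }
      }
      bx <- if (.is_box(fr$box)) fr$box / 10 else c(0, 0, 0)
      writeLines(sprintf("%10.5f%10.5f%10.5f", bx[1], bx[2], bx[3]), con)
    }
  } else {
    first <- frames[[1]]
    if (.is_box(first$box)) {
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        first$box[1], first$box[2], first$box[3], 90, 90, 90), con)
    }
    multi <- length(frames) > 1
    for (fr in frames) {
      if (multi) writeLines(sprintf("MODEL     %4d", fr$index), con)
      serial <- 0L
      for (i in seq_len(n_waters(fr))) {
        for (s in list(list("OW", fr$o[i, ], "O"), list("HW1", fr$h1[i, ], "H"),
                       list("HW2", fr$h2[i, ], "H"))) {
          serial <- serial + 1L
          writeLines(.pdb_atom_line("ATOM", serial, s[[1]], "SOL",
                                    i %% 10000L, s[[2]], s[[3]]), con)
        }
      }
      if (multi) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

# Fixed-width PDB coordinate record: name cols 13-16, altLoc 17, resname
# 18-20, chain 22, resno 23-26, xyz 31-54, element 77-78.
.pdb_atom_line <- function(rec, serial, name, resname, resno, xyz, element) {
  sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          rec, serial %% 100000L,
          if (nchar(name) < 4) paste0(" ", name) else substr(name, 1, 4),
          substr(resname, 1, 3), resno %% 10000L,
          xyz[1], xyz[2], xyz[3], element)
}

#' Write a ring overlay PDB
#'
#' Writes one `HETATM` record per ring-member oxygen, with the ring id in the
#' residue number, for visual inspection of detected water rings.
#'
#' @param rings a `twn_rings` object (or list of integer member vectors).
#' @param frame the `twn_frame` the rings belong to.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_ring_overlay <- function(rings, frame, path) {
  stopifnot(inherits(frame, "twn_frame"))
  if (inherits(rings, "twn_rings")) {
    fi <- attr(rings, "frame_index")
    if (!is.null(fi) && fi != frame$index) {
      stop("rings were enumerated in frame ", fi, ", not frame ", frame$index)
    }
  }
  rl <- unclass(rings)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 twnr ring overlay: %d ring(s), frame %d",
                     length(rl), frame$index), con)
  serial <- 0L
  for (r in seq_along(rl)) {
    members <- as.integer(rl[[r]])
    if (any(members < 1) || any(members > n_waters(frame))) {
      stop("ring ", r, " references a water index absent from frame ",
           frame$index)
    }
    for (m in members) {
      serial <- serial + 1L
      writeLines(.pdb_atom_line("HETATM", serial, "O", "RNG", r,
                                frame$o[m, ], "O"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
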