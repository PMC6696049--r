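#' Region labels recognised in annotation files
#'
#' The reference ligand is partitioned into head, linker and tail regions;
#' L' marks linker atoms at the carbonyl position where the linker joins the
#' head (an L' atom is always also part of the linker region).
#' @return Character vector of canonical labels.
#' @export
region_labels <- function() c("head", "linker", "tail", "Lprime")

.canon_label <- function(x) {
  lx <- tolower(trimws(x))
  lx[lx %in% c("l'", "lprime", "l_prime", "l-prime", "lp")] <- "Lprime"
  ok <- lx %in% c("head", "linker", "tail", "Lprime", "unlabeled")
  if (any(!ok)) {
    stop("unknown region label(s): ", paste(unique(x[!ok]), collapse = ", "),
         " (expected head/linker/tail/Lprime)")
  }
  lx
}

#' Construct a ligand model
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `region` (head/linker/tail/unlabeled) and `lprime` (logical;
#'   implies region "linker").
#' @param name ligand name.
#' @return A `twn_ligand` object.
#' @export
new_ligand <- function(atoms, name = "ligand") {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("ligand atoms need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(atoms) < 1) stop("empty ligand: no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("ligand has non-finite coordinates")
  }
  if (is.null(atoms$region)) atoms$region <- "unlabeled"
  if (is.null(atoms$lprime)) atoms$lprime <- FALSE
  atoms$element <- toupper(atoms$element)
  if (any(atoms$lprime & atoms$region != "linker")) {
    stop("every L' atom must belong to the linker region")
  }
  structure(list(name = name, atoms = atoms), class = "twn_ligand")
}

#' @export
print.twn_ligand <- function(x, ...) {
  tb <- table(x$atoms$region)
  cat(sprintf("<twn_ligand '%s': %d atoms (%s)%s>\n", x$name,
              nrow(x$atoms),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
              if (any(x$atoms$lprime))
                sprintf("; %d L'", sum(x$atoms$lprime)) else ""))
  invisible(x)
}

#' Ligand coordinates as a matrix
#' @param ligand a `twn_ligand`.
#' @param scope `"whole"`, a region label, or `"Lprime"` for L'-flagged atoms.
#' @param heavy_only drop hydrogens.
#' @return n x 3 coordinate matrix (angstrom).
#' @export
ligand_coords <- function(ligand, scope = "whole", heavy_only = FALSE) {
  stopifnot(inherits(ligand, "twn_ligand"))
  at <- ligand$atoms
  keep <- if (scope == "whole") {
    rep(TRUE, nrow(at))
  } else if (scope == "Lprime") {
    at$lprime
  } else {
    at$region == .canon_label(scope)
  }
  if (heavy_only) keep <- keep & at$element != "H"
  if (!any(keep)) stop("ligand scope '", scope, "' selects no atoms")
  as.matrix(at[keep, c("x", "y", "z")])
}

#' Read a reference ligand with region annotation
#'
#' Reads 3D ligand coordinates from PDB or SDF (V2000) and attaches region
#' labels from a two-column annotation file (atom selector, label). Selectors
#' are 1-based atom indices or atom names; labels are head / linker / tail /
#' Lprime (an `Lprime` row marks the atom as the linker carbonyl position and
#' assigns it to the linker region). Atoms not listed remain `unlabeled`.
#'
#' @param path ligand structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"sdf"`.
#' @param regions annotation file path, or a data frame with columns
#'   `atom` and `label`, or `NULL` for an unlabeled ligand.
#' @param name ligand name (default: file base name).
#' @return A `twn_ligand`.
#' @export
read_ligand <- function(path, format = c("auto", "pdb", "sdf"),
                        regions = NULL, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("ligand file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf?$", path, ignore.case = TRUE)) "sdf" else "pdb"
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  atoms <- switch(format, pdb = .read_ligand_pdb(path),
                  sdf = .read_ligand_sdf(path))
  if (nrow(atoms) < 1) stop("empty ligand: ", path)
  lig <- new_ligand(atoms, name = name)
  if (!is.null(regions)) lig <- apply_regions(lig, regions)
  lig
}

.read_ligand_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  data.frame(
    element = .atom_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    atom_name = at$elety,
    stringsAsFactors = FALSE
  )
}

.read_ligand_sdf <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  ab <- ChemmineR::atomblock(sdfs[[1]])
  elem <- sub("_[0-9]+$", "", rownames(ab))
  data.frame(
    element = toupper(elem),
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    atom_name = rownames(ab),
    stringsAsFactors = FALSE
  )
}

#' Apply a region annotation to a ligand
#'
#' @param ligand a `twn_ligand`.
#' @param regions annotation file path or data frame with columns `atom`
#'   (1-based index or atom name) and `label`.
#' @return The relabelled `twn_ligand`.
#' @export
apply_regions <- function(ligand, regions) {
  stopifnot(inherits(ligand, "twn_ligand"))
  if (is.character(regions) && length(regions) == 1) {
    if (!file.exists(regions)) stop("region annotation not found: ", regions)
    regions <- utils::read.table(regions, header = FALSE,
                                 col.names = c("atom", "label"),
                                 colClasses = "character",
                                 comment.char = "#")
  }
  stopifnot(is.data.frame(regions), all(c("atom", "label") %in% names(regions)))
  at <- ligand$atoms
  at$region <- "unlabeled"
  at$lprime <- FALSE
  n <- nrow(at)
  for (r in seq_len(nrow(regions))) {
    sel <- as.character(regions$atom[r])
    idx <- suppressWarnings(as.integer(sel))
    if (!is.na(idx)) {
      if (idx < 1 || idx > n) {
        stop("region annotation references atom ", idx,
             " of a ", n, "-atom ligand")
      }
      hit <- idx
    } else {
      hit <- which(!is.na(at$atom_name) & at$atom_name == sel)
      if (!length(hit)) {
        stop("region annotation references unknown atom name '", sel, "'")
      }
    }
    lab <- .canon_label(regions$label[r])
    if (lab == "Lprime") {
      at$region[hit] <- "linker"
      at$lprime[hit] <- TRUE
    } else if (lab != "unlabeled") {
      at$region[hit] <- lab
    }
  }
  new_ligand(at, name = ligand$name)
}

#' Write a region annotation file
#'
#' Two-column text format (atom index, label); L' atoms are written as
#' `Lprime` rows (which imply linker membership on read).
#'
#' @param ligand a `twn_ligand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_annotation <- function(ligand, path) {
  stopifnot(inherits(ligand, "twn_ligand"))
  at <- ligand$atoms
  lab <- ifelse(at$lprime, "Lprime", at$region)
  keep <- lab != "unlabeled"
  utils::write.table(
    data.frame(atom = which(keep), label = lab[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a ligand to PDB
#' @param ligand a `twn_ligand`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_ligand_pdb <- function(ligand, path) {
  stopifnot(inherits(ligand, "twn_ligand"))
  at <- ligand$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(at))) {
    nm <- if (!is.null(at$atom_name) && !is.na(at$atom_name[i])) {
      at$atom_name[i]
    } else {
      paste0(at$element[i], i)
    }
    writeLines(.pdb_atom_line("HETATM", i, substr(nm, 1, 4), "LIG", 1L,
                              c(at$x[i], at$y[i], at$z[i]), at$element[i]),
               con)
  }
  writeLines("END", con)
  invisible(path)
}
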