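#' Run the full TWN analysis pipeline
#'
#' Reads the configured inputs, computes the occupancy report (site
#' selection, H-bond graphs, ring enumeration, region assignment), extracts
#' ligand-proximal rings, scores shape similarity for the whole ligand and
#' every non-empty region scope, and writes a report directory:
#' `report.json`, `rings.tsv`, `similarity.tsv`, a ring overlay PDB for the
#' first frame containing rings (optional), and `run.log` echoing every
#' effective parameter. The run is deterministic given inputs and config;
#' on error, partially written outputs are removed and the failing stage is
#' named.
#'
#' @param config a path to a YAML config, a nested list, or a validated
#'   `twn_config`; see [validate_config()] and [default_config()].
#' @param frames optional pre-loaded frame list (overrides
#'   `config$inputs$frames`).
#' @param ligand optional pre-loaded `twn_ligand` (overrides
#'   `config$inputs$ligand`).
#' @return Invisibly, a list with `occupancy` (a `twn_occupancy`),
#'   `similarity` (data frame of per-scope results), `proximal` (the
#'   proximal-ring table) and `files` (paths written).
#' @export
run_analysis <- function(config = NULL, frames = NULL, ligand = NULL) {
  cfg <- if (inherits(config, "twn_config")) config else validate_config(config)
  written <- character(0)
  cleanup <- function() {
    for (f in written) if (file.exists(f)) unlink(f)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  lig <- stage("read_ligand", {
    if (is.null(ligand)) {
      if (is.null(cfg$inputs$ligand)) {
        stop("no ligand given (config inputs.ligand or `ligand` argument)")
      }
      read_ligand(cfg$inputs$ligand, format = cfg$inputs$ligand_format,
                  regions = cfg$inputs$regions)
    } else {
      ligand
    }
  })
  frs <- stage("read_frames", {
    if (is.null(frames)) {
      if (is.null(cfg$inputs$frames)) {
        stop("no frames given (config inputs.frames or `frames` argument)")
      }
      read_frames(cfg$inputs$frames, format = cfg$inputs$frames_format,
                  water_resnames = cfg$inputs$water_resnames)
    } else {
      if (inherits(frames, "twn_frame")) list(frames) else frames
    }
  })

  params <- stage("parameters", .params_from_config(cfg))
  site <- stage("site", site_spec(center = cfg$site$center,
                                  radius = cfg$site$radius_A))
  lpc <- cfg$assign$lprime_cutoff_A
  if (is.null(lpc)) lpc <- cfg$assign$cutoff_A

  occ <- stage("occupancy", occupancy_report(
    frs, lig, site = site, params = params,
    assign_cutoff = cfg$assign$cutoff_A, lprime_cutoff = lpc,
    min_size = cfg$rings$min_size, max_size = cfg$rings$max_size,
    all_cycles = cfg$rings$all_cycles
  ))

  prox <- stage("proximal_rings",
                proximal_rings(occ$rings, lig,
                               com_cutoff = cfg$shape$com_cutoff_A))

  sim <- stage("shape_similarity", {
    gspec <- grid_from_atoms(ligand_coords(lig),
                             padding = cfg$grid$padding_A,
                             spacing = cfg$grid$spacing_A)
    twn_grid <- voxelize_twn(prox, frs, gspec,
                             water_radius = cfg$grid$water_radius_A)
    scopes <- "whole"
    for (sc in c("head", "linker", "tail")) {
      if (any(lig$atoms$region == sc)) scopes <- c(scopes, sc)
    }
    if (any(lig$atoms$lprime)) scopes <- c(scopes, "Lprime")
    rows <- lapply(scopes, function(sc) {
      lg <- voxelize_ligand(lig, scope = sc, grid = gspec)
      s <- shape_similarity(lg, twn_grid, mode = cfg$shape$mode)
      data.frame(scope = sc, percent = s$percent, mode = s$mode,
                 n_rings_used = s$n_rings_used,
                 lig_voxels = sum(lg$occupied), stringsAsFactors = FALSE)
    })
    list(table = do.call(rbind, rows), grid = twn_grid, spec = gspec)
  })

  files <- stage("write_outputs", {
    dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(cfg$output$dir, x)
    out <- character(0)

    written <<- c(written, fp("report.json"))
    report <- list(
      n_frames = occ$n_frames, n_rings = occ$n_rings,
      counts = as.list(occ$counts),
      percent = as.list(occ$percent),
      lprime_fraction = occ$lprime_fraction,
      no_assigned_rings = occ$no_assigned_rings,
      n_proximal_rings = nrow(prox),
      similarity = lapply(seq_len(nrow(sim$table)), function(i) {
        as.list(sim$table[i, ])
      }),
      site = list(center = occ$site$center, radius = occ$site$radius),
      config = unclass(cfg)
    )
    jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    out <- c(out, fp("report.json"))

    written <<- c(written, fp("rings.tsv"))
    write_occupancy(occ, fp("rings.tsv"))
    out <- c(out, fp("rings.tsv"))

    written <<- c(written, fp("similarity.tsv"))
    utils::write.table(sim$table, fp("similarity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out <- c(out, fp("similarity.tsv"))

    if (isTRUE(cfg$output$overlay) && nrow(occ$rings) > 0) {
      fi <- occ$rings$frame[1]
      fr <- frs[[match(fi, vapply(frs, `[[`, integer(1), "index"))]]
      sel <- occ$rings[occ$rings$frame == fi, ]
      written <<- c(written, fp("overlay.pdb"))
      write_ring_overlay(sel$members, fr, fp("overlay.pdb"))
      out <- c(out, fp("overlay.pdb"))
    }
    if (isTRUE(cfg$output$dx)) {
      written <<- c(written, fp("twn.dx"))
      write_dx(sim$grid, fp("twn.dx"))
      out <- c(out, fp("twn.dx"))
    }

    written <<- c(written, fp("run.log"))
    writeLines(c(
      sprintf("twnr %s", as.character(utils::packageVersion("twnr"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("frames: %d, ligand: %s (%d atoms)",
              length(frs), lig$name, nrow(lig$atoms)),
      "parameters:",
      paste0("  ", .config_lines(unclass(cfg)))
    ), fp("run.log"))
    out <- c(out, fp("run.log"))
    out
  })

  invisible(list(occupancy = occ, similarity = sim$table, proximal = prox,
                 files = files))
}
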