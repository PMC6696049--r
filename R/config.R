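#' Default analysis configuration
#'
#' Nested list of every tunable pipeline parameter with its default. Units:
#' angstrom and kcal/mol throughout.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    potential = list(A = 582000, C = 595, q_O = -0.834, q_H = 0.417,
                     coulomb_constant = 332.0636),
    hbond = list(threshold_kcal = -2.25, prefilter_A = 3.5),
    rings = list(min_size = 3L, max_size = 6L, all_cycles = FALSE),
    site = list(center = NULL, radius_A = 25),
    assign = list(cutoff_A = 5, lprime_cutoff_A = NULL),
    grid = list(spacing_A = 0.5, water_radius_A = 1.4, padding_A = 3),
    shape = list(com_cutoff_A = 2.0, mode = "coverage"),
    inputs = list(frames = NULL, frames_format = "auto", ligand = NULL,
                  ligand_format = "auto", regions = NULL,
                  water_resnames = default_water_resnames()),
    output = list(dir = "twn-output", overlay = TRUE, dx = FALSE),
    seed = 1L
  )
}

.config_checks <- list(
  "potential.A" = function(v) is.numeric(v) && v > 0,
  "potential.C" = function(v) is.numeric(v) && v > 0,
  "potential.q_O" = function(v) is.numeric(v) && v < 0,
  "potential.q_H" = function(v) is.numeric(v) && v > 0,
  "potential.coulomb_constant" = function(v) is.numeric(v) && v > 0,
  "hbond.threshold_kcal" = function(v) is.numeric(v) && v < 0,
  "hbond.prefilter_A" = function(v) is.numeric(v) && v >= 3.2,
  "rings.min_size" = function(v) is.numeric(v) && v >= 3 && v <= 6,
  "rings.max_size" = function(v) is.numeric(v) && v >= 3 && v <= 6,
  "rings.all_cycles" = function(v) is.logical(v),
  "site.center" = function(v) is.null(v) ||
    (is.numeric(v) && length(v) == 3 && all(is.finite(v))),
  "site.radius_A" = function(v) is.numeric(v) && v > 0,
  "assign.cutoff_A" = function(v) is.numeric(v) && v > 0,
  "assign.lprime_cutoff_A" = function(v) is.null(v) ||
    (is.numeric(v) && v > 0),
  "grid.spacing_A" = function(v) is.numeric(v) && v > 0,
  "grid.water_radius_A" = function(v) is.numeric(v) && v > 0,
  "grid.padding_A" = function(v) is.numeric(v) && v >= 0,
  "shape.com_cutoff_A" = function(v) is.numeric(v) && v > 0,
  "shape.mode" = function(v) is.character(v) &&
    v %in% c("coverage", "tanimoto"),
  "inputs.frames" = function(v) is.null(v) || is.character(v),
  "inputs.frames_format" = function(v) v %in% c("auto", "pdb", "gro"),
  "inputs.ligand" = function(v) is.null(v) || is.character(v),
  "inputs.ligand_format" = function(v) v %in% c("auto", "pdb", "sdf"),
  "inputs.regions" = function(v) is.null(v) || is.character(v),
  "inputs.water_resnames" = function(v) is.character(v) && length(v) >= 1,
  "output.dir" = function(v) is.character(v) && length(v) == 1,
  "output.overlay" = function(v) is.logical(v),
  "output.dx" = function(v) is.logical(v),
  "seed" = function(v) is.numeric(v) && v == round(v)
)

#' Validate an analysis configuration
#'
#' Reads a YAML config file (or takes a nested list), fills defaults from
#' [default_config()], rejects unknown keys, and checks types and ranges.
#' All problems are reported together in one error.
#'
#' @param config path to a YAML file, a nested list, or `NULL` (pure
#'   defaults).
#' @return A validated `twn_config` (nested list).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a YAML mapping or a list")
  defaults <- default_config()
  problems <- character(0)
  merged <- defaults
  flat_keys <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(x[[nm]]) && !is.null(names(x[[nm]])) && key != "site.center") {
        out <- c(out, flat_keys(x[[nm]], key))
      } else {
        out <- c(out, key)
      }
    }
    out
  }
  known <- names(.config_checks)
  for (key in flat_keys(config)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (!(key %in% known)) {
      problems <- c(problems, paste0("unknown config key: ", key))
      next
    }
    val <- config
    for (p in parts) val <- val[[p]]
    if (key == "site.center" && !is.null(val)) val <- unlist(val)
    if (key == "inputs.water_resnames") val <- unlist(val)
    if (!.config_checks[[key]](val)) {
      problems <- c(problems,
                    paste0("invalid value for ", key, ": ",
                           paste(deparse(val), collapse = " ")))
      next
    }
    if (length(parts) == 1) merged[[parts]] <- val
    else merged[[parts[1]]][[parts[2]]] <- val
  }
  if (!is.null(merged$rings$min_size) &&
      merged$rings$max_size < merged$rings$min_size) {
    problems <- c(problems, "rings.max_size must be >= rings.min_size")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  merged$rings$min_size <- as.integer(merged$rings$min_size)
  merged$rings$max_size <- as.integer(merged$rings$max_size)
  merged$seed <- as.integer(merged$seed)
  class(merged) <- "twn_config"
  merged
}

# Build potential_params from a validated config.
.params_from_config <- function(cfg) {
  potential_params(
    A = cfg$potential$A, C = cfg$potential$C,
    q_O = cfg$potential$q_O, q_H = cfg$potential$q_H,
    coulomb_constant = cfg$potential$coulomb_constant,
    hbond_threshold = cfg$hbond$threshold_kcal,
    distance_prefilter = cfg$hbond$prefilter_A
  )
}

# Flatten a config for the audit log.
.config_lines <- function(cfg, prefix = "") {
  out <- character(0)
  for (nm in names(cfg)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- cfg[[nm]]
    if (is.list(v)) {
      out <- c(out, .config_lines(v, key))
    } else {
      out <- c(out, sprintf("%s = %s",
                            key, if (is.null(v)) "NULL"
                            else paste(v, collapse = ", ")))
    }
  }
  out
}
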