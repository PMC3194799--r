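#' Load and validate a run configuration
#'
#' Reads a YAML run configuration with exactly one model-parameter block
#' (\code{dimensionless:} or \code{dimensional:}), an optional
#' \code{protocol:} block, an \code{analysis:} selection (\code{steady},
#' \code{sweep}, \code{phase}, \code{simulate}, \code{ensemble},
#' \code{sweep_ensemble}), numeric settings and seeds.  Unknown keys are
#' rejected by name; defaults are filled in and echoed into output
#' metadata, and a loaded configuration round-trips unchanged through
#' \code{\link{save_config}}.
#'
#' @param path YAML file path.
#' @return A \code{"run_config"} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  build_config(raw)
}

build_config <- function(raw) {
  top_known <- c("dimensionless", "dimensional", "protocol", "analysis",
                 "numerics", "seed", "output_dir")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  has_dl <- !is.null(raw$dimensionless)
  has_dim <- !is.null(raw$dimensional)
  if (has_dl == has_dim)
    stop("exactly one of the 'dimensionless' and 'dimensional' parameter ",
         "blocks must be present", call. = FALSE)
  params <- if (has_dl) {
    known <- c("alpha", "beta", "kappa", "gamma", "epsilon", "alpha_range")
    unk <- setdiff(names(raw$dimensionless), known)
    if (length(unk)) stop("unknown key(s) in 'dimensionless': ",
                          paste(unk, collapse = ", "), call. = FALSE)
    do.call(dimensionless_params, raw$dimensionless)
  } else {
    known <- c("basal_protein_rate", "autocatalysis_const",
               "saturation_consts", "mirna_inhibition_const",
               "basal_mirna_rate", "protein_driven_mirna_rate",
               "protein_degradation_rate", "mirna_degradation_rate")
    unk <- setdiff(names(raw$dimensional), known)
    if (length(unk)) stop("unknown key(s) in 'dimensional': ",
                          paste(unk, collapse = ", "), call. = FALSE)
    do.call(dimensional_params, raw$dimensional)
  }
  analysis <- if (is.null(raw$analysis)) "steady" else raw$analysis
  analyses <- c("steady", "sweep", "phase", "simulate", "ensemble",
                "sweep_ensemble")
  if (!analysis %in% analyses)
    stop("'analysis' must be one of: ", paste(analyses, collapse = ", "),
         call. = FALSE)
  numerics_default <- list(dt = 0.01, sde_dt = 0.002, t_end = 100,
                           n_grid = 201, n_cells = 200)
  numerics <- numerics_default
  if (!is.null(raw$numerics)) {
    unk <- setdiff(names(raw$numerics), names(numerics_default))
    if (length(unk)) stop("unknown key(s) in 'numerics': ",
                          paste(unk, collapse = ", "), call. = FALSE)
    numerics <- modifyList(numerics_default, raw$numerics)
  }
  if (any(unlist(numerics[c("dt", "sde_dt", "t_end")]) <= 0))
    stop("'numerics' time settings must be positive", call. = FALSE)
  protocol <- if (!is.null(raw$protocol)) protocol_from_list(raw$protocol)
  structure(list(params = params, protocol = protocol, analysis = analysis,
                 numerics = numerics,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 output_dir = if (is.null(raw$output_dir)) "." else
                   raw$output_dir),
            class = "run_config")
}

#' Serialise a run configuration back to YAML
#'
#' @param config a \code{"run_config"}.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  block <- if (inherits(config$params, "dimensionless_params"))
    list(dimensionless = unclass(config$params))
  else list(dimensional = unclass(config$params))
  out <- c(block,
           if (!is.null(config$protocol))
             list(protocol = protocol_to_list(config$protocol)),
           list(analysis = config$analysis, numerics = config$numerics,
                seed = config$seed, output_dir = config$output_dir))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: analysis '%s', seed %d, output '%s'\n",
              x$analysis, x$seed, x$output_dir))
  print(x$params)
  if (!is.null(x$protocol)) print(x$protocol)
  invisible(x)
}

#' Write an analysis result to disk
#'
#' Writes CSV data plus a JSON metadata sidecar (parameters, seeds,
#' thresholds, package version, timestamp) for the result types produced by
#' the package, and a manifest listing every written file with its MD5
#' checksum.  Deterministic analyses re-run from the same configuration
#' reproduce byte-identical CSVs.
#'
#' @param result a \code{"branch_diagram"}, \code{"phase_diagram2d"},
#'   \code{"trajectory"}, \code{"ensemble_result"},
#'   \code{"steady_state_set"} or sweep-table data frame.
#' @param out_dir output directory (created if needed).
#' @param stem file-name stem.
#' @return Data frame manifest (file, md5), invisibly.
#' @export
write_results <- function(result, out_dir, stem = "result") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  meta <- list(package = "mirswitch",
               version = as.character(utils::packageVersion("mirswitch")),
               timestamp = format(Sys.time(), tz = "UTC",
                                  "%Y-%m-%dT%H:%M:%SZ"),
               class = class(result)[1])
  path <- function(suffix) file.path(out_dir, paste0(stem, suffix))
  if (inherits(result, "branch_diagram")) {
    write.csv(result$table, path("_branches.csv"), row.names = FALSE)
    bif <- do.call(rbind, lapply(c(result$saddle_nodes, result$hopf_points),
                                 function(b) data.frame(kind = b$kind,
                                                        alpha_at = b$alpha_at,
                                                        phi_at = b$phi_at,
                                                        bracket_width =
                                                          b$bracket_width)))
    if (is.null(bif)) bif <- data.frame(kind = character(0),
                                        alpha_at = numeric(0),
                                        phi_at = numeric(0),
                                        bracket_width = numeric(0))
    write.csv(bif, path("_bifurcations.csv"), row.names = FALSE)
    files <- c(path("_branches.csv"), path("_bifurcations.csv"))
    meta$params <- unclass(result$params)
    meta$switch_character <- result$switch_character
  } else if (inherits(result, "phase_diagram2d")) {
    lab <- as.data.frame(result$labels)
    names(lab) <- format(result$x_grid, digits = 8)
    lab <- cbind(setNames(data.frame(result$y_grid), result$y_param), lab)
    write.csv(lab, path("_labels.csv"), row.names = FALSE)
    files <- path("_labels.csv")
    if (!is.null(result$boundary_points)) {
      write.csv(result$boundary_points, path("_boundaries.csv"),
                row.names = FALSE)
      files <- c(files, path("_boundaries.csv"))
    }
    meta$params <- unclass(result$fixed)
    meta$axes <- list(x = result$x_param, y = result$y_param)
    meta$classifier <- result$classifier
  } else if (inherits(result, "trajectory")) {
    write.csv(as.data.frame(result), path("_trajectory.csv"),
              row.names = FALSE)
    files <- path("_trajectory.csv")
    meta$params <- unclass(result$params)
    meta$protocol <- protocol_to_list(result$protocol)
    meta$integrator <- result$meta
  } else if (inherits(result, "ensemble_result")) {
    write.csv(fraction_curve(result), path("_fraction.csv"),
              row.names = FALSE)
    files <- path("_fraction.csv")
    meta$params <- unclass(result$params)
    meta$protocol <- protocol_to_list(result$protocol)
    meta$N <- result$N
    meta$base_seed <- result$base_seed
    meta$seed_scheme <- "base_seed + cell_index"
    meta$threshold <- result$threshold
    meta$rule <- result$rule
    meta$F_s <- result$F_s
    meta$T_R <- result$T_R
  } else if (inherits(result, "steady_state_set")) {
    write_steady_states_csv(result, path("_steady_states.csv"))
    files <- path("_steady_states.csv")
    meta$params <- unclass(result$params)
  } else if (is.data.frame(result)) {
    write.csv(result, path(".csv"), row.names = FALSE)
    files <- path(".csv")
  } else stop("unsupported result type: ", class(result)[1], call. = FALSE)
  meta_path <- path("_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, meta_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, path("_manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
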