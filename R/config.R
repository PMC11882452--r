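#' Load and validate a YAML run configuration
#'
#' The configuration has sections `model` (see [model_params()]),
#' `schedule` (see [move_schedule()]), `sweep`, `synth`, `image` and
#' `analysis`, plus the top-level keys `n_sweeps`, `record_every`, `seed`,
#' `out_dir` and `log_level`. Unknown keys are rejected with the offending
#' name; missing values fall back to the documented defaults. Every run
#' driven by a configuration writes a resolved copy of it next to its
#' outputs.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config` with resolved `model` and
#'   `schedule` objects and validated section lists.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_known <- c("model", "schedule", "sweep", "synth", "image", "analysis",
                 "n_sweeps", "record_every", "seed", "out_dir", "log_level")
  bad <- setdiff(names(raw), top_known)
  if (length(bad))
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))

  check_section <- function(sec, known, where) {
    if (is.null(sec)) return(list())
    bad <- setdiff(names(sec), known)
    if (length(bad))
      stop(sprintf("unknown key(s) in %s section: %s", where,
                   paste(bad, collapse = ", ")))
    sec
  }

  model <- do.call(model_params,
                   check_section(raw$model, names(formals(model_params)),
                                 "model"))
  schedule <- do.call(move_schedule,
                      check_section(raw$schedule,
                                    names(formals(move_schedule)),
                                    "schedule"))
  sweep <- check_section(raw$sweep,
                         c("axis1", "axis2", "replicates", "nd_cut",
                           "window"), "sweep")
  synth <- check_section(raw$synth,
                         c("preset", "field_nm", "lattice_nm", "n_compact",
                           "n_elongated", "n_gas", "pixels", "noise_sd",
                           "line_offset_sd", "defect_pentagon",
                           "defect_heptagon"), "synth")
  image <- check_section(raw$image,
                         c("lattice_nm", "flatten_order", "threshold_nm",
                           "cutoff_nm", "pixel_nm"), "image")
  analysis <- check_section(raw$analysis,
                            c("threshold", "nd_cut", "window"), "analysis")

  structure(list(
    model = model, schedule = schedule, sweep = sweep, synth = synth,
    image = image, analysis = analysis,
    n_sweeps = if (is.null(raw$n_sweeps)) 5e5 else raw$n_sweeps,
    record_every = if (is.null(raw$record_every)) 2500 else raw$record_every,
    seed = raw$seed, out_dir = raw$out_dir,
    log_level = if (is.null(raw$log_level)) "info" else raw$log_level
  ), class = "run_config")
}

#' Save a resolved run configuration as YAML
#'
#' Writes the fully resolved configuration (defaults filled in), so
#' [load_config()] on the result reproduces the object: the save/load
#' round trip is the identity.
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @param provenance Optional named list appended as a comment header.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, provenance = NULL) {
  stopifnot(inherits(config, "run_config"))
  model <- unclass(config$model)
  model <- model[c("sigma", "delta", "theta_pw", "epsilon", "p_open",
                   "n_particles", "box_side")]
  out <- list(model = model, schedule = unclass(config$schedule),
              sweep = config$sweep, synth = config$synth,
              image = config$image, analysis = config$analysis,
              n_sweeps = config$n_sweeps, record_every = config$record_every,
              seed = config$seed, out_dir = config$out_dir,
              log_level = config$log_level)
  out <- Filter(function(v) !is.null(v) && (!is.list(v) || length(v) > 0), out)
  txt <- yaml::as.yaml(out)
  if (!is.null(provenance)) {
    hdr <- paste0("# ", names(provenance), ": ",
                  vapply(provenance, as.character, character(1)))
    txt <- paste(c(hdr, txt), collapse = "\n")
  }
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run config\n")
  print(x$model)
  print(x$schedule)
  cat(sprintf("  n_sweeps %g, record_every %g, seed %s\n",
              x$n_sweeps, x$record_every,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

config_hash <- function(path) {
  unname(tools::md5sum(path))
}
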