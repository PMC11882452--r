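#' Write a trajectory as JSON-lines
#'
#' One metadata record followed by one record per frame:
#' `{"step": s, "box_side": L, "particles": [[x, y, orientation, s1, s2, s3], ...]}`.
#' Serialization is deterministic: identical trajectories give byte-identical
#' files.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  meta <- list(
    type = "metadata",
    params = unclass(traj$params),
    schedule = unclass(traj$schedule),
    seed = traj$seed, n_sweeps = traj$n_sweeps,
    record_every = traj$record_every, version = traj$version,
    n_frames = length(traj$frames))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  for (f in traj$frames) {
    parts <- cbind(f$x, f$y, f$orientation, f$patch_states)
    rec <- list(step = f$step_index, box_side = f$box_side,
                particles = parts)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines trajectory
#'
#' @param path File written by [write_trajectory()].
#' @return A `trajectory` object.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty trajectory file: ", path)
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$type, "metadata"))
    stop("first record is not trajectory metadata")
  pm <- meta$params
  params <- model_params(sigma = pm$sigma, delta = pm$delta,
                         theta_pw = pm$theta_pw, epsilon = pm$epsilon,
                         p_open = pm$p_open, n_particles = pm$n_particles,
                         box_side = pm$box_side)
  sc <- meta$schedule
  schedule <- move_schedule(sc$translate, sc$rotate, sc$state_flip,
                            sc$cluster, sc$max_translate, sc$max_rotate,
                            sc$deposition_rate)
  frames <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    m <- rec$particles
    if (length(m) == 0) m <- matrix(numeric(0), 0, 6)
    if (is.null(dim(m))) m <- matrix(m, 1)
    configuration(m[, 1], m[, 2], m[, 3],
                  matrix(as.integer(m[, 4:6]), nrow(m), 3),
                  rec$box_side, step_index = rec$step)
  })
  structure(list(params = params, schedule = schedule, seed = meta$seed,
                 n_sweeps = meta$n_sweeps, record_every = meta$record_every,
                 frames = frames, observables = NULL,
                 version = meta$version),
            class = "trajectory")
}

#' Write the per-frame observables of a trajectory as CSV
#'
#' Columns: step, energy, energy_recomputed, acceptance rate per move type,
#' accepted bond-breaking rate, particle count.
#'
#' @param traj A `trajectory` with observables.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"), !is.null(traj$observables))
  write.csv(traj$observables, path, row.names = FALSE)
  invisible(path)
}
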