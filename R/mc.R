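#' Move schedule for the Monte Carlo sampler
#'
#' Per-attempt probabilities of the four move classes plus step-size limits
#' and an optional deposition rate. Fractions must be non-negative and sum
#' to 1 (deposition is a rate per sweep, not a fraction).
#'
#' @param translate,rotate,state_flip,cluster Attempt fractions (sum to 1).
#' @param max_translate Maximum translation step (length units).
#' @param max_rotate Maximum rotation step (radians).
#' @param deposition_rate Expected particles deposited per sweep
#'   (Poisson; default 0 = off). Used for kinetics experiments only.
#' @return An object of class `move_schedule`.
#' @export
move_schedule <- function(translate = 0.4, rotate = 0.2, state_flip = 0.3,
                          cluster = 0.1, max_translate = 0.3,
                          max_rotate = 0.4, deposition_rate = 0) {
  f <- c(translate, rotate, state_flip, cluster)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("move fractions must be non-negative and sum to 1")
  if (max_translate <= 0 || max_rotate <= 0)
    stop("step sizes must be > 0")
  if (deposition_rate < 0) stop("deposition_rate must be >= 0")
  structure(list(translate = translate, rotate = rotate,
                 state_flip = state_flip, cluster = cluster,
                 max_translate = max_translate, max_rotate = max_rotate,
                 deposition_rate = deposition_rate),
            class = "move_schedule")
}

#' @export
print.move_schedule <- function(x, ...) {
  cat(sprintf(
    "move schedule: translate %.2f (step %.3g), rotate %.2f (step %.3g rad), flip %.2f, cluster %.2f, deposition %.3g/sweep\n",
    x$translate, x$max_translate, x$rotate, x$max_rotate,
    x$state_flip, x$cluster, x$deposition_rate))
  invisible(x)
}

#' Acceptance probability of a patch-state flip
#'
#' The flip move targets the stationary distribution in which an isolated
#' (non-interacting) patch is open with probability exactly `p_open`:
#' `min(1, w(new)/w(old) * exp(-delta_E))` with intrinsic weights
#' `w(open) = p_open` and `w(closed) = 1 - p_open`. `delta_E` is the change
#' in bonded energy the flip would cause (breaking a bond costs `+epsilon`).
#' Flips toward a zero-weight state have acceptance 0.
#'
#' @param current_state 0 (open) or 1 (closed).
#' @param delta_E Energy change of the proposed flip, in kT.
#' @param params A `model_params` supplying `p_open`.
#' @return Acceptance probability in `[0, 1]`.
#' @examples
#' p <- model_params(p_open = 0.8, epsilon = 8)
#' state_flip_acceptance(1, 0, p)      # isolated closed -> open: 1
#' state_flip_acceptance(1, 8, p)      # bonded closed -> open: 4 * exp(-8)
#' @export
state_flip_acceptance <- function(current_state, delta_E, params) {
  stopifnot(current_state %in% c(0, 1), inherits(params, "model_params"))
  p <- params$p_open
  w_new <- if (current_state == 1) p else 1 - p
  w_old <- if (current_state == 1) 1 - p else p
  if (w_new <= 0) return(0)
  if (w_old <= 0) return(1) # leaving a zero-weight state is always accepted
  min(1, (w_new / w_old) * exp(-delta_E))
}

#' Run the Metropolis Monte Carlo sampler
#'
#' Single-particle translations and rotations, patch-state flips, and rigid
#' cluster moves (bonded components selected with probability inversely
#' proportional to their size; proposals that would create a new bond or an
#' overlap are rejected, preserving detailed balance within this move
#' class). An optional deposition step inserts new particles at a Poisson
#' rate per sweep for kinetics experiments.
#'
#' All randomness flows through R's RNG: identical seeds give bit-identical
#' trajectories.
#'
#' @param params A `model_params`.
#' @param schedule A `move_schedule`.
#' @param init A starting `configuration`, or `"random"` for rejection-
#'   sampled non-overlapping placement.
#' @param n_sweeps Number of sweeps (one sweep = N attempted moves).
#' @param record_every Recording interval in sweeps.
#' @param seed Optional integer seed.
#' @return An object of class `trajectory`: recorded frames, an observables
#'   data frame (running and recomputed energy, per-move acceptance rates,
#'   accepted bond-breaking rate, particle count) and run metadata.
#' @export
run_mc <- function(params, schedule = move_schedule(), init = "random",
                   n_sweeps = 5e5, record_every = 2500, seed = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(schedule, "move_schedule"))
  if (n_sweeps < 1 || record_every < 1 || n_sweeps %% record_every != 0)
    stop("n_sweeps must be a positive multiple of record_every")
  if (!is.null(seed)) set.seed(seed)
  if (identical(init, "random")) init <- random_configuration(params)
  stopifnot(inherits(init, "configuration"))
  if (abs(init$box_side - params$box_side) > 1e-9)
    stop("init box_side does not match params")

  res <- mc_run_cpp(init$x, init$y, init$orientation, init$patch_states,
                    params$box_side, params$sigma, params$delta,
                    params$theta_pw, params$epsilon, params$p_open,
                    c(schedule$translate, schedule$rotate,
                      schedule$state_flip, schedule$cluster),
                    schedule$max_translate, schedule$max_rotate,
                    schedule$deposition_rate,
                    as.integer(n_sweeps), as.integer(record_every))

  frames <- lapply(res$frames, function(f)
    configuration(f$x, f$y, f$orientation, f$patch_states,
                  params$box_side, step_index = f$step))
  obs <- as.data.frame(res$observables)

  drift <- max(abs(obs$energy - obs$energy_recomputed))
  if (drift > 1e-8 * max(1, length(init$x)))
    warning(sprintf("incremental energy drift %.3g exceeds tolerance", drift))
  if (res$deposition_skipped > 0)
    warning(sprintf("%d deposition insertions skipped (box saturated)",
                    res$deposition_skipped))

  structure(list(params = params, schedule = schedule, seed = seed,
                 n_sweeps = n_sweeps, record_every = record_every,
                 frames = frames, observables = obs,
                 version = as.character(packageVersion("patchnet"))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames over %g sweeps (every %g), N = %d -> %d\n",
              length(x$frames), x$n_sweeps, x$record_every,
              length(x$frames[[1]]$x),
              length(x$frames[[length(x$frames)]]$x)))
  print(x$params)
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  obs <- object$observables
  cat(sprintf("final energy %.3f kT; acceptance translate %.2f rotate %.2f flip %.2f cluster %.2f\n",
              obs$energy[nrow(obs)],
              mean(obs$acc_translate, na.rm = TRUE),
              mean(obs$acc_rotate, na.rm = TRUE),
              mean(obs$acc_flip, na.rm = TRUE),
              mean(obs$acc_cluster, na.rm = TRUE)))
  invisible(obs)
}

#' Tune step sizes toward a target acceptance window
#'
#' Runs short pilot simulations and rescales `max_translate` and
#' `max_rotate` until translation and rotation acceptance fall inside the
#' target window (or the iteration cap is hit). The returned schedule is
#' then frozen: production runs never adapt.
#'
#' @param params A `model_params`.
#' @param schedule Starting `move_schedule`.
#' @param n_sweeps Pilot run length per iteration.
#' @param target Acceptance window, default `c(0.3, 0.5)`.
#' @param max_iter Maximum pilot iterations.
#' @param seed Optional seed for the pilots.
#' @return The calibrated `move_schedule`.
#' @export
calibrate_schedule <- function(params, schedule = move_schedule(),
                               n_sweeps = 1000, target = c(0.3, 0.5),
                               max_iter = 8, seed = NULL) {
  mid <- mean(target)
  for (it in seq_len(max_iter)) {
    tr <- run_mc(params, schedule, n_sweeps = n_sweeps,
                 record_every = n_sweeps, seed = seed)
    obs <- tr$observables
    at <- obs$acc_translate[nrow(obs)]
    ar <- obs$acc_rotate[nrow(obs)]
    ok_t <- is.na(at) || (at >= target[1] && at <= target[2])
    ok_r <- is.na(ar) || (ar >= target[1] && ar <= target[2])
    if (ok_t && ok_r) break
    if (!ok_t)
      schedule$max_translate <- min(params$sigma,
                                    max(1e-3, schedule$max_translate * at / mid))
    if (!ok_r)
      schedule$max_rotate <- min(pi, max(1e-3, schedule$max_rotate * ar / mid))
  }
  schedule
}
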