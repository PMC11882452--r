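#' Minimum-image displacement in a periodic square box
#'
#' Wraps each component of a displacement vector into
#' `[-box_side/2, box_side/2)`.
#'
#' @param dx Displacement: a length-2 vector, or a 2-column matrix of
#'   displacements.
#' @param box_side Box edge length (> 0).
#' @return Wrapped displacement(s), same shape as the input.
#' @examples
#' minimum_image(c(0.6, 0), box_side = 1)   # -> c(-0.4, 0)
#' @export
minimum_image <- function(dx, box_side) {
  stopifnot(is.numeric(box_side), length(box_side) == 1, box_side > 0)
  if (is.matrix(dx)) {
    stopifnot(ncol(dx) == 2)
    w <- minimum_image_cpp(dx[, 1], dx[, 2], box_side)
    n <- nrow(dx)
    return(cbind(w[seq_len(n)], w[n + seq_len(n)]))
  }
  stopifnot(length(dx) == 2)
  w <- minimum_image_cpp(dx[1], dx[2], box_side)
  c(w[1], w[2])
}

#' Construct a particle
#'
#' A particle is a disc centre with an orientation (the outward direction of
#' patch 1; patches k sit at `orientation + (k-1)*2*pi/3`) and three binary
#' patch states (1 = closed/bindable, 0 = open/inert).
#'
#' @param x,y Centre coordinates.
#' @param orientation Angle of patch 1 in radians (wrapped mod 2 pi).
#' @param patch_states Integer vector of three values in `{0, 1}`.
#' @return A list of class `particle`.
#' @export
particle <- function(x, y, orientation = 0, patch_states = c(1L, 1L, 1L)) {
  stopifnot(is.finite(x), is.finite(y), is.finite(orientation),
            length(patch_states) == 3, all(patch_states %in% c(0L, 1L)))
  structure(list(x = x, y = y,
                 orientation = orientation %% (2 * pi),
                 patch_states = as.integer(patch_states)),
            class = "particle")
}

#' Construct a configuration of particles in a periodic box
#'
#' @param x,y Numeric vectors of centre coordinates (wrapped into
#'   `[0, box_side)`).
#' @param orientation Numeric vector of orientations (radians).
#' @param patch_states Integer matrix, one row per particle, three columns.
#' @param box_side Periodic box edge.
#' @param step_index Sweep count of the configuration (default 0).
#' @param validate Check the hard-core constraint (min-image distance >=
#'   sigma for all pairs); requires `params`.
#' @param params Optional `model_params` used for validation.
#' @return An object of class `configuration`.
#' @export
configuration <- function(x, y, orientation, patch_states, box_side,
                          step_index = 0L, validate = FALSE, params = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(orientation) == n)
  if (n > 0) {
    stopifnot(is.matrix(patch_states), nrow(patch_states) == n,
              ncol(patch_states) == 3)
  } else {
    patch_states <- matrix(integer(0), 0, 3)
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(orientation)))
    stop("non-finite coordinates")
  x <- x %% box_side
  y <- y %% box_side
  cfg <- structure(list(
    x = as.numeric(x), y = as.numeric(y),
    orientation = as.numeric(orientation) %% (2 * pi),
    patch_states = matrix(as.integer(patch_states), n, 3),
    box_side = box_side, step_index = as.integer(step_index)
  ), class = "configuration")
  if (validate) {
    if (is.null(params)) stop("validation requires params")
    total_energy(cfg, params) # errors on overlap, naming the pair
  }
  cfg
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d particles, box %.3f, step %d\n",
              length(x$x), x$box_side, x$step_index))
  invisible(x)
}

#' Place particles at random without overlap
#'
#' Rejection sampling of non-overlapping positions, uniform orientations,
#' and patch states drawn independently with closed probability
#' `1 - p_open`.
#'
#' @param params A `model_params` object.
#' @param seed Optional RNG seed.
#' @param max_attempts Placement attempts per particle before giving up.
#' @return A `configuration`.
#' @export
random_configuration <- function(params, seed = NULL, max_attempts = 5000) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_particles
  L <- params$box_side
  s2 <- params$sigma^2
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_attempts)) {
      px <- runif(1, 0, L); py <- runif(1, 0, L)
      if (i == 1) { ok <- TRUE } else {
        dx <- minimum_image_cpp(px - x[seq_len(i - 1)],
                                py - y[seq_len(i - 1)], L)
        m <- i - 1
        ok <- all(dx[seq_len(m)]^2 + dx[m + seq_len(m)]^2 >= s2)
      }
      if (ok) { x[i] <- px; y[i] <- py; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("could not place particle %d of %d: area fraction %.3f too high",
                   i, n, params$area_fraction))
  }
  st <- matrix(as.integer(runif(3 * n) < (1 - params$p_open)), n, 3)
  configuration(x, y, runif(n, 0, 2 * pi), st, L)
}

#' Pair energy of the state-augmented Kern-Frenkel potential
#'
#' Returns `Inf` (hard-core rejection sentinel) when the centre distance is
#' below `sigma`; `-epsilon` together with the bonding patch pair when the
#' pair is within range `[sigma, sigma + delta)` and a closed patch on each
#' particle points at the partner within `theta_pw`; 0 otherwise. When
#' several patch pairs satisfy the criterion simultaneously the pair with
#' the smallest summed angular deviation is the bond (a single bond per
#' pair).
#'
#' @param pi_,pj_ `particle` objects (or lists with fields `x`, `y`,
#'   `orientation`, `patch_states`).
#' @param params A `model_params` object; its `box_side` defines the
#'   periodic wrap.
#' @return A list with `energy`, `bond` (integer pair of patch indices or
#'   `NULL`) and `overlap` (logical).
#' @export
pair_energy <- function(pi_, pj_, params) {
  stopifnot(inherits(params, "model_params"))
  crd <- c(pi_$x, pi_$y, pi_$orientation, pj_$x, pj_$y, pj_$orientation)
  if (any(!is.finite(crd))) stop("non-finite coordinates")
  r <- pair_energy_cpp(pi_$x, pi_$y, pi_$orientation, as.integer(pi_$patch_states),
                       pj_$x, pj_$y, pj_$orientation, as.integer(pj_$patch_states),
                       params$box_side, params$sigma, params$delta,
                       params$theta_pw, params$epsilon)
  if (r$code < 0)
    return(list(energy = Inf, bond = NULL, overlap = TRUE))
  list(energy = r$energy,
       bond = if (r$code > 0) c(r$patch_i, r$patch_j) else NULL,
       overlap = FALSE)
}

#' Total energy of a configuration
#'
#' Cell-list accelerated sum of `pair_energy` over all unordered pairs;
#' identical to the brute-force O(N^2) sum. A hard-core overlap raises an
#' error naming the offending pair.
#'
#' @param config A `configuration`.
#' @param params A `model_params`.
#' @return Total energy in kT units.
#' @export
total_energy <- function(config, params) {
  stopifnot(inherits(config, "configuration"), inherits(params, "model_params"))
  total_energy_cpp(config$x, config$y, config$orientation,
                   config$patch_states, config$box_side,
                   params$sigma, params$delta, params$theta_pw, params$epsilon)
}

#' Bond list of a configuration
#'
#' All bonded pairs under the current patch states, with the contributing
#' patch indices.
#'
#' @inheritParams total_energy
#' @return A data frame with columns `i`, `j`, `patch_i`, `patch_j`.
#' @export
bond_pairs <- function(config, params) {
  stopifnot(inherits(config, "configuration"), inherits(params, "model_params"))
  m <- bond_list_cpp(config$x, config$y, config$orientation,
                     config$patch_states, config$box_side,
                     params$sigma, params$delta, params$theta_pw)
  as.data.frame(m)
}

#' @export
plot.configuration <- function(x, params = NULL, bonds = TRUE, ...) {
  plot(NA, xlim = c(0, x$box_side), ylim = c(0, x$box_side), asp = 1,
       xlab = "x", ylab = "y",
       main = sprintf("step %d, N = %d", x$step_index, length(x$x)), ...)
  if (bonds && !is.null(params) && length(x$x) > 1) {
    b <- bond_pairs(x, params)
    if (nrow(b) > 0) {
      for (k in seq_len(nrow(b))) {
        d <- minimum_image(c(x$x[b$j[k]] - x$x[b$i[k]],
                             x$y[b$j[k]] - x$y[b$i[k]]), x$box_side)
        lines(x$x[b$i[k]] + c(0, d[1]), x$y[b$i[k]] + c(0, d[2]), col = "grey40")
      }
    }
  }
  r <- if (is.null(params)) 0.5 else params$sigma / 2
  symbols(x$x, x$y, circles = rep(r, length(x$x)), inches = FALSE,
          add = TRUE, fg = "steelblue", bg = "#B0C4DE80")
  invisible(x)
}
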