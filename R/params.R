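#' Model parameters for the state-augmented patchy-disc model
#'
#' Collects the physical and algorithmic parameters of the two-dimensional
#' patchy-disc model: a hard core of diameter `sigma`, three attractive
#' patches equally spaced at 120 degrees with square-well depth `epsilon`
#' (in units of kT), attraction range `delta` beyond contact, and patch
#' half-opening angle `theta_pw` in the classical Kern-Frenkel convention
#' (a bond requires the angular deviation on each side to be below
#' `theta_pw`). Each patch additionally carries a binary state: closed
#' (bindable) or open (inert); `p_open` is the stationary probability that
#' a patch of an isolated particle is open, the model's interface-flexibility
#' knob.
#'
#' The geometry is validated so that a single patch can never satisfy the
#' angular bonding criterion with two partners at once: two non-overlapping
#' neighbours within range subtend an angle of at least
#' `2*asin(sigma / (2*(sigma + delta)))` at the central particle, so
#' `theta_pw` below `asin(sigma / (2*(sigma + delta)))` guarantees a single
#' bond per patch. Patches must also not overlap on the perimeter
#' (`theta_pw < pi/3`).
#'
#' @param sigma Hard-core diameter (sets the length unit; default 1).
#' @param delta Attraction range beyond contact, same unit (default 0.038).
#' @param theta_pw Patch half-opening angle in radians (default 0.44).
#' @param epsilon Well depth in units of kT (default 6).
#' @param p_open Stationary open probability of an isolated patch, in `[0, 1]`.
#' @param n_particles Number of particles (default 200).
#' @param box_side Periodic square box edge. If `NULL`, derived from
#'   `area_fraction`.
#' @param area_fraction Packing fraction `N*pi*(sigma/2)^2 / box_side^2`
#'   (default 0.1 when `box_side` is `NULL`).
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(epsilon = 8, p_open = 0.8, n_particles = 150)
#' p$box_side
#' @export
model_params <- function(sigma = 1, delta = 0.038, theta_pw = 0.44,
                         epsilon = 6, p_open = 0.5, n_particles = 200,
                         box_side = NULL, area_fraction = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, is.finite(sigma),
            is.numeric(delta), length(delta) == 1, is.finite(delta),
            is.numeric(theta_pw), length(theta_pw) == 1, is.finite(theta_pw),
            is.numeric(epsilon), length(epsilon) == 1, is.finite(epsilon),
            is.numeric(p_open), length(p_open) == 1, is.finite(p_open))
  if (sigma <= 0) stop("sigma must be > 0")
  if (delta < 0 || delta >= sigma) stop("delta must satisfy 0 <= delta < sigma")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (p_open < 0 || p_open > 1) stop("p_open must lie in [0, 1]")
  if (n_particles < 0 || n_particles != round(n_particles))
    stop("n_particles must be a non-negative integer")
  single_bond_limit <- asin(sigma / (2 * (sigma + delta)))
  max_theta <- min(pi / 3, single_bond_limit)
  if (theta_pw <= 0 || theta_pw >= max_theta)
    stop(sprintf(
      "theta_pw must lie in (0, %.4f): below pi/3 so patches do not overlap, and below asin(sigma/(2*(sigma+delta))) = %.4f so one patch can never bond two partners",
      max_theta, single_bond_limit))

  if (is.null(box_side)) {
    if (is.null(area_fraction)) area_fraction <- 0.1
    if (area_fraction <= 0 || area_fraction > 0.6)
      stop("area_fraction must lie in (0, 0.6]")
    box_side <- sqrt(n_particles * pi * (sigma / 2)^2 / area_fraction)
    if (n_particles == 0) box_side <- 10 * sigma
  }
  if (box_side <= 2 * (sigma + delta))
    stop("box_side must exceed twice the interaction range")
  area_fraction <- n_particles * pi * (sigma / 2)^2 / box_side^2

  structure(list(
    sigma = sigma, delta = delta, theta_pw = theta_pw, epsilon = epsilon,
    p_open = p_open, n_patches = 3L, n_particles = as.integer(n_particles),
    box_side = box_side, area_fraction = area_fraction
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Patchy-disc model parameters\n")
  cat(sprintf("  sigma = %g, delta = %g, theta_pw = %g rad\n",
              x$sigma, x$delta, x$theta_pw))
  cat(sprintf("  epsilon = %g kT, p_open = %g\n", x$epsilon, x$p_open))
  cat(sprintf("  N = %d, box = %.3f, area fraction = %.4f\n",
              x$n_particles, x$box_side, x$area_fraction))
  invisible(x)
}

#' Serialize model parameters to a YAML `model:` block
#'
#' @param params A `model_params` object.
#' @param path Optional file to write; when `NULL` the YAML string is
#'   returned.
#' @return The YAML string, invisibly when written to file.
#' @export
params_to_yaml <- function(params, path = NULL) {
  stopifnot(inherits(params, "model_params"))
  txt <- yaml::as.yaml(list(model = params[c(
    "sigma", "delta", "theta_pw", "epsilon", "p_open",
    "n_particles", "box_side")]))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read model parameters from a YAML `model:` block
#'
#' Unknown keys in the `model:` section are rejected; missing keys fall back
#' to the documented defaults.
#'
#' @param x A path to a YAML file or a YAML string.
#' @return A `model_params` object.
#' @export
params_from_yaml <- function(x) {
  obj <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  if (is.null(obj$model)) stop("no 'model:' section found")
  known <- names(formals(model_params))
  bad <- setdiff(names(obj$model), known)
  if (length(bad) > 0)
    stop("unknown key(s) in model section: ", paste(bad, collapse = ", "))
  do.call(model_params, obj$model)
}
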