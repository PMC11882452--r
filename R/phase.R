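#' Classify the assembly state of a finished run
#'
#' The label is derived from the last `window` recorded frames only, with
#' the weighted mean network density as the principal metric and island
#' size as the secondary determinant:
#' \itemize{
#'   \item `gas` - the largest island anywhere in the window is below the
#'     24-particle statistics threshold (mostly single particles and small
#'     aggregates);
#'   \item `short_like` - assembled, with mean eligible-island ND at or
#'     above `nd_cut` (compact isotropic clusters);
#'   \item `long_like` - assembled, mean ND below `nd_cut` (anisotropic
#'     elongated clusters);
#'   \item `dla` - overrides the assembled labels when the dynamics are
#'     kinetically trapped (accepted bond-breaking rate over the window
#'     below `bb_cut`) and the largest island is large and ramified
#'     (border ratio above `border_cut` at size >= `dla_size`), the
#'     signature of the diffusion-limited-aggregation limit of very strong
#'     attraction.
#' }
#' Classification is a pure function of the trajectory window: re-running
#' it on the same trajectory gives an identical label.
#'
#' @param traj A `trajectory` with at least `window` recorded frames.
#' @param nd_cut ND threshold separating short-like from long-like
#'   (default 0.75).
#' @param window Number of trailing frames to evaluate (default 20).
#' @param threshold Island eligibility threshold (default 24).
#' @param bb_cut Accepted bond-breaking rate below which the run counts as
#'   kinetically trapped (default 1e-3).
#' @param border_cut,dla_size Ramification test for the dla override.
#' @return A character label in `{gas, short_like, long_like, dla}` with
#'   attributes `mean_nd`, `largest_island` and `bond_break_acc`.
#' @export
classify_state <- function(traj, nd_cut = 0.75, window = 20, threshold = 24,
                           bb_cut = 1e-3, border_cut = 0.9, dla_size = 100) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < window)
    stop(sprintf("classification needs at least %d recorded frames", window))
  frames <- tail(traj$frames, window)

  largest <- 0L
  nd_vals <- numeric(0)
  nd_wts <- numeric(0)
  last_isl <- NULL
  for (f in frames) {
    g <- build_bond_graph(f, params = traj$params)
    isl <- islands(g, threshold = threshold)
    if (length(isl) > 0) {
      largest <- max(largest, isl[[1]]$size)
      el <- Filter(function(i) i$eligible, isl)
      if (length(el) > 0) {
        nd_vals <- c(nd_vals, vapply(el, network_density, numeric(1)))
        nd_wts <- c(nd_wts, vapply(el, function(i) i$size, numeric(1)))
      }
    }
    last_isl <- isl
  }

  bb <- NA_real_
  if (!is.null(traj$observables))
    bb <- mean(tail(traj$observables$bond_break_acc, window), na.rm = TRUE)

  mean_nd <- if (length(nd_vals)) weighted.mean(nd_vals, nd_wts) else NA_real_

  label <- if (largest < threshold) {
    "gas"
  } else {
    lab <- if (!is.na(mean_nd) && mean_nd >= nd_cut) "short_like" else "long_like"
    if (!is.na(bb) && bb < bb_cut && length(last_isl) > 0) {
      big <- last_isl[[1]]
      if (big$size >= dla_size && border_ratio(big) > border_cut) lab <- "dla"
    }
    lab
  }
  structure(label, mean_nd = mean_nd, largest_island = largest,
            bond_break_acc = bb)
}

#' Sweep a two-parameter grid and classify every point
#'
#' Runs `run_mc` + `classify_state` for each grid point and replicate. The
#' per-point label is the majority over replicates; ties go to the label of
#' the replicate with the median mean-ND. Per-run seeds are derived from
#' the master seed by a stable integer hash of (point, replicate), so
#' sweeps are reproducible point-by-point.
#'
#' @param axis1,axis2 Lists `list(name =, values =)`; names must be
#'   `model_params` fields (e.g. `"p_open"`, `"epsilon"`, `"theta_pw"`).
#' @param base A `model_params` providing all non-swept parameters.
#' @param schedule A `move_schedule`.
#' @param replicates Replicate runs per point (default 3).
#' @param n_sweeps,record_every Run length and recording interval.
#' @param seed Master seed.
#' @param nd_cut,window,threshold Passed to [classify_state()].
#' @param verbose Print progress.
#' @return An object of class `phase_diagram`: `points` (one row per
#'   replicate: axis values, replicate, seed, label, mean_nd, max_island,
#'   failed flag) and `grid` (one row per point with the majority label).
#' @export
sweep_phase_diagram <- function(axis1, axis2, base, schedule = move_schedule(),
                                replicates = 3, n_sweeps = 5e5,
                                record_every = 2500, seed = 1,
                                nd_cut = 0.75, window = 20, threshold = 24,
                                verbose = FALSE) {
  stopifnot(is.list(axis1), is.list(axis2),
            length(axis1$values) > 0, length(axis2$values) > 0,
            inherits(base, "model_params"))
  pts <- expand.grid(a1 = axis1$values, a2 = axis2$values,
                     rep = seq_len(replicates))
  rows <- vector("list", nrow(pts))
  for (r in seq_len(nrow(pts))) {
    v1 <- pts$a1[r]; v2 <- pts$a2[r]; rp <- pts$rep[r]
    point_index <- (match(v2, axis2$values) - 1) * length(axis1$values) +
      match(v1, axis1$values)
    run_seed <- derive_seed(seed, point_index, rp)
    pl <- unclass(base)
    pl[[axis1$name]] <- v1
    pl[[axis2$name]] <- v2
    prm <- model_params(sigma = pl$sigma, delta = pl$delta,
                        theta_pw = pl$theta_pw, epsilon = pl$epsilon,
                        p_open = pl$p_open, n_particles = pl$n_particles,
                        box_side = if (axis1$name == "n_particles" ||
                                       axis2$name == "n_particles") NULL
                                   else pl$box_side)
    res <- tryCatch({
      tr <- run_mc(prm, schedule, n_sweeps = n_sweeps,
                   record_every = record_every, seed = run_seed)
      lab <- classify_state(tr, nd_cut = nd_cut, window = window,
                            threshold = threshold)
      list(label = as.character(lab), mean_nd = attr(lab, "mean_nd"),
           max_island = attr(lab, "largest_island"), failed = FALSE)
    }, error = function(e) {
      warning(sprintf("sweep point (%g, %g) replicate %d failed: %s",
                      v1, v2, rp, conditionMessage(e)))
      list(label = NA_character_, mean_nd = NA_real_,
           max_island = NA_integer_, failed = TRUE)
    })
    rows[[r]] <- data.frame(axis1 = v1, axis2 = v2, replicate = rp,
                            seed = run_seed, label = res$label,
                            mean_nd = res$mean_nd,
                            max_island = res$max_island,
                            failed = res$failed)
    if (verbose)
      message(sprintf("[%d/%d] %s=%g %s=%g rep %d -> %s", r, nrow(pts),
                      axis1$name, v1, axis2$name, v2, rp, res$label))
  }
  points_df <- do.call(rbind, rows)
  grid_df <- majority_labels(points_df)
  structure(list(points = points_df, grid = grid_df,
                 axes = list(axis1 = axis1, axis2 = axis2),
                 nd_cut = nd_cut, seed = seed, n_sweeps = n_sweeps),
            class = "phase_diagram")
}

derive_seed <- function(master, point_index, replicate) {
  # stable integer hash, kept below 2^31
  h <- (as.double(master) %% 65521) * 31013 +
    point_index * 7919 + replicate * 104729
  as.integer(h %% 2147483647) + 1L
}

majority_labels <- function(points_df) {
  keys <- unique(points_df[, c("axis1", "axis2")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- points_df$axis1 == keys$axis1[k] & points_df$axis2 == keys$axis2[k]
    d <- points_df[sel & !points_df$failed, , drop = FALSE]
    if (nrow(d) == 0)
      return(data.frame(axis1 = keys$axis1[k], axis2 = keys$axis2[k],
                        label = NA_character_, mean_nd = NA_real_,
                        max_island = NA_integer_, n_ok = 0L))
    tab <- table(d$label)
    top <- names(tab)[tab == max(tab)]
    lab <- if (length(top) == 1) top else {
      # tie: the replicate with the median mean-ND decides
      ord <- d[order(d$mean_nd), , drop = FALSE]
      ord$label[ceiling(nrow(ord) / 2)]
    }
    data.frame(axis1 = keys$axis1[k], axis2 = keys$axis2[k], label = lab,
               mean_nd = mean(d$mean_nd, na.rm = TRUE),
               max_island = max(d$max_island), n_ok = nrow(d))
  })
  do.call(rbind, out)
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase diagram: %s x %s, %d points, %d runs\n",
              x$axes$axis1$name, x$axes$axis2$name, nrow(x$grid),
              nrow(x$points)))
  print(table(x$grid$label, useNA = "ifany"))
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  cols <- c(gas = "grey85", short_like = "#8c6bb1", long_like = "#fd8d3c",
            dla = "grey30")
  g <- x$grid
  plot(g$axis1, g$axis2, pch = 22, cex = 3, bg = cols[g$label],
       xlab = x$axes$axis1$name, ylab = x$axes$axis2$name, ...)
  legend("topright", legend = names(cols), pt.bg = cols, pch = 22, bty = "n")
  invisible(x)
}

#' Locate a phase boundary along one axis of a swept diagram
#'
#' Scans a grid line and reports the interval between the last point
#' carrying the first label and the first point carrying the second label,
#' together with its midpoint. Never extrapolates beyond the grid. When
#' several transitions occur along the line, all bracketing intervals are
#' returned.
#'
#' @param diagram A `phase_diagram`.
#' @param between Character vector of two labels, in scan order.
#' @param along `"axis1"` or `"axis2"`: the axis scanned.
#' @param at Value of the other axis selecting the line.
#' @return A data frame of transition intervals (`lower`, `upper`,
#'   `midpoint`), one row per transition.
#' @export
locate_boundary <- function(diagram, between, along = "axis1", at) {
  stopifnot(inherits(diagram, "phase_diagram"), length(between) == 2)
  g <- diagram$grid
  other <- if (along == "axis1") "axis2" else "axis1"
  line <- g[abs(g[[other]] - at) < 1e-12, , drop = FALSE]
  line <- line[order(line[[along]]), , drop = FALSE]
  if (nrow(line) < 2) stop("scan line has fewer than 2 points")
  labs <- line$label
  vals <- line[[along]]
  if (!all(between %in% labs))
    stop(sprintf("no transition: labels %s not both present on the line",
                 paste(between, collapse = " -> ")))
  idx <- which(labs[-length(labs)] == between[1] & labs[-1] == between[2])
  if (length(idx) == 0) {
    # labels present but not adjacent: report every change of label
    idx <- which(labs[-length(labs)] != labs[-1])
  }
  data.frame(lower = vals[idx], upper = vals[idx + 1],
             midpoint = (vals[idx] + vals[idx + 1]) / 2,
             from = labs[idx], to = labs[idx + 1])
}
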