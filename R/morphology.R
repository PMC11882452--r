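#' Full morphology report of a frame or trajectory
#'
#' Runs the quantification stack (bond graph, islands, face enumeration,
#' network density, border ratio, polygon census) on a simulation frame, a
#' point set of detected centres, a `bond_graph`, or every frame of a
#' `trajectory`.
#'
#' @param source A `configuration`, `trajectory`, `bond_graph`, or a data
#'   frame of points (columns `x`/`y` or `x_nm`/`y_nm`, optionally
#'   `frame`).
#' @param params `model_params` (needed for simulation input).
#' @param cutoff Bond cutoff for point input; `NULL` for the default.
#' @param threshold Island eligibility threshold for frame summaries
#'   (default 24 particles).
#' @return An object of class `morphology_report` with two data frames:
#'   `islands` (one row per island per frame: size, eligibility, nd,
#'   border_ratio, polygon counts p3..p9, voids) and `summary` (one row
#'   per frame: weighted mean ND over eligible islands, island density,
#'   particle density, polygon totals and hexagon fraction).
#' @export
morphology_report <- function(source, params = NULL, cutoff = NULL,
                              threshold = 24) {
  if (inherits(source, "trajectory")) {
    reps <- lapply(source$frames, function(f)
      morphology_report(f, params = source$params, threshold = threshold))
    isl <- do.call(rbind, lapply(seq_along(reps), function(i) {
      d <- reps[[i]]$islands
      if (nrow(d)) d$frame <- source$frames[[i]]$step_index
      d
    }))
    sm <- do.call(rbind, lapply(seq_along(reps), function(i) {
      d <- reps[[i]]$summary
      d$frame <- source$frames[[i]]$step_index
      d
    }))
    return(structure(list(islands = isl, summary = sm, threshold = threshold),
                     class = "morphology_report"))
  }

  if (inherits(source, "bond_graph")) {
    g <- source
    area <- NULL
  } else if (inherits(source, "configuration")) {
    g <- build_bond_graph(source, params = params)
    area <- source$box_side^2
  } else {
    pts <- as.data.frame(source)
    if ("frame" %in% names(pts) && length(unique(pts$frame)) > 1) {
      frames <- sort(unique(pts$frame))
      reps <- lapply(frames, function(fr)
        morphology_report(pts[pts$frame == fr, , drop = FALSE],
                          cutoff = cutoff, threshold = threshold))
      isl <- do.call(rbind, lapply(seq_along(reps), function(i) {
        d <- reps[[i]]$islands
        if (nrow(d)) d$frame <- frames[i]
        d
      }))
      sm <- do.call(rbind, lapply(seq_along(reps), function(i) {
        d <- reps[[i]]$summary
        d$frame <- frames[i]
        d
      }))
      return(structure(list(islands = isl, summary = sm,
                            threshold = threshold),
                       class = "morphology_report"))
    }
    g <- build_bond_graph(pts, cutoff = cutoff)
    area <- if (nrow(g$nodes) > 0)
      diff(range(g$nodes$x)) * diff(range(g$nodes$y)) else NULL
  }

  isl <- islands(g, threshold = threshold)
  rows <- lapply(seq_along(isl), function(k) {
    i <- isl[[k]]
    fs <- enumerate_faces(i)
    counts <- tabulate(fs$sizes, nbins = 9)[3:9]
    data.frame(island = k, size = i$size, eligible = i$eligible,
               nd = network_density(i), border_ratio = border_ratio(i, fs),
               p3 = counts[1], p4 = counts[2], p5 = counts[3],
               p6 = counts[4], p7 = counts[5], p8 = counts[6],
               p9 = counts[7], voids = fs$voids)
  })
  islands_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(island = integer(0), size = integer(0), eligible = logical(0),
               nd = numeric(0), border_ratio = numeric(0),
               p3 = integer(0), p4 = integer(0), p5 = integer(0),
               p6 = integer(0), p7 = integer(0), p8 = integer(0),
               p9 = integer(0), voids = integer(0))

  el <- islands_df[islands_df$eligible, , drop = FALSE]
  pk <- colSums(islands_df[, paste0("p", 3:9), drop = FALSE])
  total_poly <- sum(pk)
  if (is.null(area) || !is.finite(area) || area <= 0) area <- NA_real_
  summary_df <- data.frame(
    n_particles = nrow(g$nodes),
    n_islands = nrow(islands_df),
    n_islands_eligible = nrow(el),
    weighted_nd = if (nrow(el)) weighted.mean(el$nd, el$size) else NA_real_,
    largest_island = if (nrow(islands_df)) max(islands_df$size) else 0L,
    island_density = if (is.na(area)) NA_real_ else nrow(el) / area,
    particle_density = if (is.na(area)) NA_real_ else nrow(g$nodes) / area,
    polygons_total = total_poly,
    hexagon_fraction = if (total_poly > 0) pk[4] / total_poly else 0,
    border_ratio_largest = if (nrow(islands_df)) islands_df$border_ratio[1]
                           else 0)
  rownames(summary_df) <- NULL
  structure(list(islands = islands_df, summary = summary_df,
                 threshold = threshold),
            class = "morphology_report")
}

#' @export
print.morphology_report <- function(x, ...) {
  nfr <- if ("frame" %in% names(x$summary)) nrow(x$summary) else 1
  cat(sprintf("morphology report: %d frame(s), %d island rows\n",
              nfr, nrow(x$islands)))
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' Write a morphology report as tidy CSV
#'
#' One row per island per frame plus one summary row per frame (island
#' column `NA`), matching the column dictionary in the README.
#'
#' @param report A `morphology_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphology <- function(report, path) {
  stopifnot(inherits(report, "morphology_report"))
  isl <- report$islands
  isl$row_type <- if (nrow(isl)) "island" else character(0)
  sm <- report$summary
  sm$row_type <- "frame_summary"
  all_cols <- union(names(isl), names(sm))
  for (cc in setdiff(all_cols, names(isl))) isl[[cc]] <- NA
  for (cc in setdiff(all_cols, names(sm))) sm[[cc]] <- NA
  out <- rbind(isl[, all_cols, drop = FALSE], sm[, all_cols, drop = FALSE])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Polygon-size distribution of a frame
#'
#' Counts of retained polygons by size (3 to 9 vertices) and the hexagon
#' fraction (0 when the frame has no polygons).
#'
#' @inheritParams morphology_report
#' @return A list with `counts` (named integer vector, sizes 3-9) and
#'   `hexagon_fraction`.
#' @export
polygon_distribution <- function(source, params = NULL, cutoff = NULL) {
  rep_ <- morphology_report(source, params = params, cutoff = cutoff)
  pk <- colSums(rep_$islands[, paste0("p", 3:9), drop = FALSE])
  names(pk) <- 3:9
  tot <- sum(pk)
  list(counts = pk, hexagon_fraction = if (tot > 0) unname(pk["6"]) / tot else 0)
}

#' Morphology time series of a trajectory
#'
#' Per recorded frame: statistics-eligible island density and particle
#' density (per box area, normalized units) and the border fraction of the
#' largest island (0 when it has no polygons). An optional smoothing
#' spline can be overlaid downstream; only raw values are returned.
#'
#' @param traj A `trajectory` with at least 2 frames.
#' @param threshold Island eligibility threshold.
#' @return A data frame with columns `step`, `island_density`,
#'   `particle_density`, `border_fraction_largest`, `largest_island`,
#'   `weighted_nd`.
#' @export
time_series <- function(traj, threshold = 24) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2) stop("time series needs at least 2 frames")
  rep_ <- morphology_report(traj, threshold = threshold)
  sm <- rep_$summary
  data.frame(step = sm$frame,
             island_density = sm$island_density,
             particle_density = sm$particle_density,
             border_fraction_largest = sm$border_ratio_largest,
             largest_island = sm$largest_island,
             weighted_nd = sm$weighted_nd)
}
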