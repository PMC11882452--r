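#' Remove scan-line artefacts from an AFM image
#'
#' Fits a per-scan-line polynomial of order 0 (constant) or 1 (linear) to
#' the background pixels of each line (pixels below a robust global
#' threshold, median + 3 mad) and subtracts it, so the background median
#' sits at about 0 nm. Lines without enough background pixels fall back to
#' median subtraction.
#'
#' @param image An `afm_image`.
#' @param order 0 or 1: polynomial order of the per-line fit.
#' @return The flattened `afm_image`.
#' @export
flatten_image <- function(image, order = 0) {
  stopifnot(inherits(image, "afm_image"), order %in% c(0, 1))
  m <- image$height
  thr <- median(m) + 3 * mad(m)
  nfallback <- 0L
  for (r in seq_len(nrow(m))) {
    line <- m[r, ]
    bg <- which(line <= thr)
    if (length(bg) >= max(5, order + 2)) {
      if (order == 0) {
        m[r, ] <- line - median(line[bg])
      } else {
        cols <- seq_along(line)
        fit <- stats::lm.fit(cbind(1, cols[bg]), line[bg])
        m[r, ] <- line - (fit$coefficients[1] + fit$coefficients[2] * cols)
      }
    } else {
      nfallback <- nfallback + 1L
      m[r, ] <- line - median(line)
    }
  }
  if (nfallback > 0)
    warning(sprintf("%d line(s) had no background pixels; median fallback used",
                    nfallback))
  image$height <- m
  image
}

#' Upsample an AFM image by bilinear interpolation
#'
#' Centre detection works on the skeleton of the segmented ridges; at the
#' native 2.9 nm/px of a 750 nm, 256-pixel scan the ridges are only 2
#' pixels wide and thinning destroys the 3-way junctions. Upsampling to
#' about 1.5 nm/px before segmentation preserves them.
#'
#' @param image An `afm_image`.
#' @param factor Integer magnification factor.
#' @return The upsampled `afm_image`.
#' @export
upsample_image <- function(image, factor = 2) {
  stopifnot(inherits(image, "afm_image"), factor >= 1)
  if (factor == 1) return(image)
  nr <- nrow(image$height) * factor
  nc <- ncol(image$height) * factor
  up <- EBImage::resize(EBImage::Image(image$height), w = nr, h = nc)
  image$height <- matrix(as.numeric(up), nr, nc)
  image$pixel_nm <- image$pixel_nm / factor
  image
}

#' Segment the DNA ridges of a flattened AFM image
#'
#' Global threshold (automatic bimodal Otsu threshold by default,
#' overridable in nm) followed by a morphological opening with a disc of
#' radius `opening_radius` pixels.
#'
#' @param image A flattened `afm_image`.
#' @param threshold_nm Optional manual threshold; `NULL` for Otsu.
#' @param opening_radius Opening radius in pixels (default 1).
#' @return A logical matrix mask.
#' @export
segment_image <- function(image, threshold_nm = NULL, opening_radius = 1) {
  stopifnot(inherits(image, "afm_image"))
  m <- image$height
  rng <- range(m)
  if (diff(rng) < 1e-9) {
    warning("image has no contrast; empty mask")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  if (is.null(threshold_nm)) {
    norm <- (m - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    threshold_nm <- rng[1] + thr01 * diff(rng)
    # featureless images: Otsu lands inside the noise band; demand the
    # threshold clear the background by a robust margin
    floor_nm <- median(m) + 5 * mad(m)
    if (threshold_nm < floor_nm) {
      warning("no foreground above the background noise; empty mask")
      return(matrix(FALSE, nrow(m), ncol(m)))
    }
  }
  mask <- m > threshold_nm
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
  }
  if (!any(mask)) warning("empty mask after segmentation")
  matrix(as.logical(mask), nrow(m), ncol(m))
}

# number of 0->1 transitions around the 8-neighbourhood (crossing number):
# 1 for line ends, 2 along a line, >= 3 at junctions
crossing_number <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- skel
  shift <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  ring <- list(shift(-1, 0), shift(-1, 1), shift(0, 1), shift(1, 1),
               shift(1, 0), shift(1, -1), shift(0, -1), shift(-1, -1))
  a <- matrix(0L, nr, nc)
  for (k in 1:8) {
    nxt <- ring[[if (k == 8) 1 else k + 1]]
    a <- a + (ring[[k]] == 0L & nxt == 1L)
  }
  a
}

#' Detect monomer centres in a segmented mask
#'
#' The mask is skeletonized (Zhang-Suen thinning); monomer centres are the
#' 3-way branch points of the skeleton - the unique junction of the
#' three-armed tile - merged within 0.3 lattice constants. Mask components
#' without any junction (isolated monomers whose arms are too short to
#' branch cleanly) fall back to their blob centroid. Confidence reflects
#' junction sharpness (number of skeleton arms / 3, capped at 1); centroid
#' fallbacks carry confidence 0.5.
#'
#' @param mask Logical matrix from [segment_image()].
#' @param pixel_nm Pixel size in nm.
#' @param lattice_nm Lattice constant in nm (default 16).
#' @return An object of class `detection_result`: `centres` data frame
#'   (`x_nm`, `y_nm`, `confidence`), `mask`, `skeleton`.
#' @export
detect_centres <- function(mask, pixel_nm, lattice_nm = 16) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L)) {
    return(structure(list(
      centres = data.frame(x_nm = numeric(0), y_nm = numeric(0),
                           confidence = numeric(0)),
      mask = mask > 0, skeleton = mask > 0, pixel_nm = pixel_nm,
      lattice_nm = lattice_nm), class = "detection_result"))
  }
  skel <- skeletonize_cpp(mask)
  cn <- crossing_number(skel)
  bp <- which(skel == 1L & cn >= 3, arr.ind = TRUE)
  centres <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                        confidence = numeric(0))
  labels <- EBImage::bwlabel(EBImage::Image(mask))
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  covered <- integer(0)
  if (nrow(bp) > 0) {
    bx <- (bp[, "col"] - 0.5) * pixel_nm
    by <- (bp[, "row"] - 0.5) * pixel_nm
    arms <- cn[bp]
    merge_r <- 0.3 * lattice_nm
    pr <- neighbour_pairs(bx, by, merge_r)
    ig <- igraph::make_graph(edges = as.vector(rbind(pr$i, pr$j)),
                             n = length(bx), directed = FALSE)
    cl <- igraph::components(ig)$membership
    agg_x <- tapply(bx, cl, mean)
    agg_y <- tapply(by, cl, mean)
    agg_c <- tapply(pmin(1, arms / 3), cl, max)
    centres <- data.frame(x_nm = as.numeric(agg_x), y_nm = as.numeric(agg_y),
                          confidence = as.numeric(agg_c))
    covered <- unique(labels[bp])
  }
  # blob-centroid fallback for components without a junction
  blobs <- setdiff(sort(unique(labels[labels > 0])), covered)
  if (length(blobs) > 0) {
    for (b in blobs) {
      idx <- which(labels == b, arr.ind = TRUE)
      centres <- rbind(centres, data.frame(
        x_nm = mean((idx[, "col"] - 0.5) * pixel_nm),
        y_nm = mean((idx[, "row"] - 0.5) * pixel_nm),
        confidence = 0.5))
    }
  }
  structure(list(centres = centres, mask = mask > 0, skeleton = skel > 0,
                 pixel_nm = pixel_nm, lattice_nm = lattice_nm),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection: %d centres (%d junction, %d centroid fallback)\n",
              nrow(x$centres), sum(x$centres$confidence > 0.5),
              sum(x$centres$confidence <= 0.5)))
  invisible(x)
}

#' Full image-to-morphology pipeline
#'
#' Composes the four analysis stages - artefact removal, segmentation,
#' skeleton-based centre detection, bonded-graph morphology - into the
#' single entry point used by the command line. Errors are re-raised with
#' the name of the failing stage.
#'
#' @param image An `afm_image`.
#' @param lattice_nm Lattice constant in nm.
#' @param flatten_order Per-line fit order for [flatten_image()].
#' @param threshold_nm Optional manual segmentation threshold.
#' @param cutoff Bond cutoff passed to [build_bond_graph()]; `NULL` for
#'   the modal nearest-neighbour default.
#' @param threshold Island eligibility threshold.
#' @param upsample Integer magnification applied before segmentation, or
#'   `"auto"` to target about 1.5 nm/px (see [upsample_image()]).
#' @return A list with `report` (a `morphology_report`), `detection` (the
#'   `detection_result`) and the flattened image.
#' @export
image_to_morphology <- function(image, lattice_nm = 16, flatten_order = 0,
                                threshold_nm = NULL, cutoff = NULL,
                                threshold = 24, upsample = "auto") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  flat <- stage("flatten", flatten_image(image, order = flatten_order))
  if (identical(upsample, "auto"))
    upsample <- max(1, ceiling(flat$pixel_nm / 1.6))
  work <- stage("upsample", upsample_image(flat, factor = upsample))
  mask <- stage("segment", segment_image(work, threshold_nm = threshold_nm))
  det <- stage("detect", detect_centres(mask, pixel_nm = work$pixel_nm,
                                        lattice_nm = lattice_nm))
  rep_ <- stage("morphology",
                morphology_report(det$centres, cutoff = cutoff,
                                  threshold = threshold))
  list(report = rep_, detection = det, flattened = flat)
}
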