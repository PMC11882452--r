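#' Enumerate the polygon faces of an island
#'
#' Faces of the planar embedding are traced with the rotation system induced
#' by the island's coordinates: at every node neighbours are sorted by
#' angle, and each directed half-edge continues to the next-clockwise
#' half-edge at its head. Interior faces come out counter-clockwise
#' (positive signed area); the unique boundary walk with the most negative
#' signed area is the outer face and is discarded. Simple interior cycles
#' of 3 to 9 vertices are the retained polygons; larger or non-simple
#' interior faces are counted separately as voids.
#'
#' Crossing edges (possible in noisy point-derived graphs) are resolved
#' before tracing by deleting the longer edge of each crossing pair; if
#' more than 5 percent of the island's edges cross, the embedding is not
#' trusted and an error is raised.
#'
#' @param island An `island` from [islands()].
#' @param max_polygon Largest vertex count labelled as a polygon (default 9).
#' @param min_polygon Smallest vertex count labelled as a polygon (default 3).
#' @return An object of class `polygon_set`: `faces` (list of vertex
#'   cycles, local indices), `sizes`, `voids` (count of non-polygon
#'   interior faces), `outer` (vertex walk of the boundary),
#'   `n_faces_total` (all traced faces, outer included) and the number of
#'   crossing edges removed.
#' @export
enumerate_faces <- function(island, max_polygon = 9, min_polygon = 3) {
  stopifnot(inherits(island, "island"))
  x <- island$x; y <- island$y
  e <- island$edges
  n <- length(x)
  if (n == 0 || nrow(e) == 0) {
    return(new_polygon_set(list(), integer(0), 0L, integer(0), 1L, 0L, n,
                           nrow(e)))
  }
  drop <- resolve_crossings(x, y, e)
  if (length(drop) > 0) {
    if (length(drop) > 0.05 * nrow(e))
      stop(sprintf("embedding not trustworthy: %d of %d island edges cross",
                   length(drop), nrow(e)))
    e <- e[-drop, , drop = FALSE]
  }

  # adjacency, neighbours sorted counter-clockwise by angle
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e$from[k]]] <- c(adj[[e$from[k]]], e$to[k])
    adj[[e$to[k]]] <- c(adj[[e$to[k]]], e$from[k])
  }
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) > 1)
      adj[[v]] <- nb[order(atan2(y[nb] - y[v], x[nb] - x[v]))]
  }

  # trace each directed half-edge once; the successor of (u -> v) is
  # (v -> w) where w precedes u in the CCW neighbour order at v
  m <- nrow(e)
  he_from <- c(e$from, e$to)
  he_to <- c(e$to, e$from)
  keynum <- he_from * (n + 1) + he_to
  in_keys <- numeric(0); out_keys <- numeric(0)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k == 0) next
    prv <- nb[c(k, seq_len(k - 1))[seq_len(k)]]
    in_keys <- c(in_keys, nb * (n + 1) + v)
    out_keys <- c(out_keys, v * (n + 1) + prv)
  }
  next_of <- integer(2 * m)
  next_of[match(in_keys, keynum)] <- match(out_keys, keynum)

  used <- logical(2 * m)
  faces_walks <- list()
  for (h in seq_len(2 * m)) {
    if (used[h]) next
    walk <- integer(0)
    cur <- h
    repeat {
      used[cur] <- TRUE
      walk <- c(walk, he_from[cur])
      cur <- next_of[cur]
      if (cur == h) break
      if (used[cur]) break # safety; cannot happen for a valid rotation system
    }
    faces_walks[[length(faces_walks) + 1]] <- walk
  }

  areas <- vapply(faces_walks, function(w) signed_area(x[w], y[w]), numeric(1))
  outer_idx <- which.min(areas)
  outer_walk <- faces_walks[[outer_idx]]

  faces <- list(); sizes <- integer(0); voids <- 0L
  for (fi in seq_along(faces_walks)) {
    if (fi == outer_idx) next
    w <- faces_walks[[fi]]
    simple <- !anyDuplicated(w)
    if (simple && length(w) >= min_polygon && length(w) <= max_polygon) {
      faces[[length(faces) + 1]] <- w
      sizes <- c(sizes, length(w))
    } else {
      voids <- voids + 1L
    }
  }
  new_polygon_set(faces, sizes, voids, outer_walk,
                  length(faces_walks), nrow(e), n, length(drop))
}

new_polygon_set <- function(faces, sizes, voids, outer, n_faces_total,
                            n_edges, n_nodes, crossings_removed) {
  structure(list(faces = faces, sizes = sizes, voids = voids,
                 outer = outer, n_faces_total = n_faces_total,
                 n_edges = n_edges, n_nodes = n_nodes,
                 crossings_removed = as.integer(crossings_removed)),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("polygon set: %d polygons (sizes %s), %d voids\n",
              length(x$faces),
              if (length(x$sizes)) paste(sort(unique(x$sizes)), collapse = ",")
              else "-", x$voids))
  invisible(x)
}

signed_area <- function(px, py) {
  n <- length(px)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  0.5 * sum(px * py[j] - px[j] * py)
}

# indices of edges to drop so that no two remaining edges cross
# (longer edge of each crossing pair goes first)
resolve_crossings <- function(x, y, e) {
  m <- nrow(e)
  if (m < 2) return(integer(0))
  x1 <- x[e$from]; y1 <- y[e$from]; x2 <- x[e$to]; y2 <- y[e$to]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  drop <- logical(m)
  ord <- order(len, decreasing = TRUE)
  cross <- function(a, b) {
    # proper segment intersection, shared endpoints excluded
    if (e$from[a] %in% c(e$from[b], e$to[b]) ||
        e$to[a] %in% c(e$from[b], e$to[b])) return(FALSE)
    d1 <- sign((x2[a] - x1[a]) * (y1[b] - y1[a]) - (y2[a] - y1[a]) * (x1[b] - x1[a]))
    d2 <- sign((x2[a] - x1[a]) * (y2[b] - y1[a]) - (y2[a] - y1[a]) * (x2[b] - x1[a]))
    d3 <- sign((x2[b] - x1[b]) * (y1[a] - y1[b]) - (y2[b] - y1[b]) * (x1[a] - x1[b]))
    d4 <- sign((x2[b] - x1[b]) * (y2[a] - y1[b]) - (y2[b] - y1[b]) * (x2[a] - x1[b]))
    d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0
  }
  for (oi in seq_along(ord)) {
    a <- ord[oi]
    if (drop[a]) next
    for (b in seq_len(m)) {
      if (b == a || drop[b]) next
      # cheap bounding-box reject
      if (max(x1[a], x2[a]) < min(x1[b], x2[b]) ||
          max(x1[b], x2[b]) < min(x1[a], x2[a]) ||
          max(y1[a], y2[a]) < min(y1[b], y2[b]) ||
          max(y1[b], y2[b]) < min(y1[a], y2[a])) next
      if (cross(a, b)) { drop[a] <- TRUE; break }
    }
  }
  which(drop)
}

#' Fraction of polygons touching the island border
#'
#' A polygon is on the border when at least one of its vertices lies on the
#' outer boundary walk of the island. The ratio is the number of border
#' polygons over all polygons, and 0 when the island has no polygons.
#'
#' @param island An `island`.
#' @param faces Its `polygon_set` (computed when missing).
#' @return A number in `[0, 1]`.
#' @export
border_ratio <- function(island, faces = NULL) {
  if (is.null(faces)) faces <- enumerate_faces(island)
  if (length(faces$faces) == 0) return(0)
  bnd <- unique(faces$outer)
  on_border <- vapply(faces$faces, function(w) any(w %in% bnd), logical(1))
  sum(on_border) / length(on_border)
}

#' Euler-characteristic check of a traced island
#'
#' For a connected planar island, vertices - edges + faces (interior
#' polygons + voids + the outer face) must equal 2.
#'
#' @param island An `island`.
#' @param faces Its `polygon_set` (computed when missing).
#' @return `TRUE` when the identity holds.
#' @export
euler_ok <- function(island, faces = NULL) {
  if (is.null(faces)) faces <- enumerate_faces(island)
  V <- faces$n_nodes
  E <- faces$n_edges
  F_ <- faces$n_faces_total
  (V - E + F_) == 2
}
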