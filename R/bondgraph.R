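#' Build the geometric bond graph of a frame
#'
#' Bridges both input routes of the morphology stack. From a simulation
#' frame (`configuration` + `model_params`) the edges are exactly the
#' Kern-Frenkel bonds of the current patch states, and per-component
#' coordinates are unwrapped consistently across the periodic boundary.
#' From a point set (detected monomer centres, columns `x`/`y` or
#' `x_nm`/`y_nm`), edges connect pairs closer than `cutoff` (default 1.25
#' times the modal nearest-neighbour distance) and the degree is capped at
#' 3 by removing the longest edges at any over-connected node.
#'
#' @param source A `configuration` or a data frame / matrix of points.
#' @param params A `model_params` (required for configurations).
#' @param cutoff Distance cutoff for point sets; `NULL` for the default.
#' @return An object of class `bond_graph` with `nodes` (id, x, y),
#'   `edges` (from, to, length and, for simulation input, the patch
#'   indices), and `membership` (connected-component id per node).
#' @export
build_bond_graph <- function(source, params = NULL, cutoff = NULL) {
  if (inherits(source, "configuration")) {
    if (is.null(params)) stop("params required for configuration input")
    n <- length(source$x)
    b <- if (n > 1) bond_pairs(source, params) else
      data.frame(i = integer(0), j = integer(0),
                 patch_i = integer(0), patch_j = integer(0))
    edges <- data.frame(from = b$i, to = b$j,
                        patch_from = b$patch_i, patch_to = b$patch_j)
    g <- new_bond_graph(source$x, source$y, edges, box_side = source$box_side)
    return(unwrap_components(g))
  }
  pts <- as.data.frame(source)
  if (all(c("x_nm", "y_nm") %in% names(pts))) {
    px <- pts$x_nm; py <- pts$y_nm
  } else if (all(c("x", "y") %in% names(pts))) {
    px <- pts$x; py <- pts$y
  } else stop("point input needs columns x/y or x_nm/y_nm")
  n <- length(px)
  if (n == 0)
    return(new_bond_graph(numeric(0), numeric(0),
                          data.frame(from = integer(0), to = integer(0))))
  if (is.null(cutoff)) {
    nnd <- nearest_neighbour_dist(px, py)
    nnd <- nnd[is.finite(nnd)]
    if (length(nnd) < 2) {
      cutoff <- if (length(nnd)) 1.25 * nnd else 0
    } else {
      den <- suppressWarnings(
        tryCatch(density(nnd, bw = "SJ", n = 512),
                 error = function(e) density(nnd, n = 512)))
      cutoff <- 1.25 * den$x[which.max(den$y)]
    }
  }
  pr <- neighbour_pairs(px, py, cutoff)
  edges <- data.frame(from = pr$i, to = pr$j)
  attr(edges, "length") <- pr$d
  g <- new_bond_graph(px, py, edges)
  prune_degree(g, max_degree = 3)
}

new_bond_graph <- function(x, y, edges, box_side = NULL) {
  n <- length(x)
  memb <- if (n > 0) {
    ig <- igraph::make_graph(
      edges = as.vector(t(as.matrix(edges[, c("from", "to"), drop = FALSE]))),
      n = n, directed = FALSE)
    igraph::components(ig)$membership
  } else integer(0)
  structure(list(nodes = data.frame(id = seq_len(n), x = x, y = y),
                 edges = edges, membership = as.integer(memb),
                 box_side = box_side),
            class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf("bond graph: %d nodes, %d edges, %d components\n",
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$nodes)) max(x$membership) else 0))
  invisible(x)
}

# nearest-neighbour distance per point (grid accelerated)
nearest_neighbour_dist <- function(x, y, ...) {
  n <- length(x)
  if (n < 2) return(rep(Inf, n))
  if (n <= 2000) {
    d <- as.matrix(dist(cbind(x, y)))
    diag(d) <- Inf
    return(apply(d, 1, min))
  }
  # coarse grid: expand search ring until a neighbour is found
  out <- numeric(n)
  cw <- max(diff(range(x)), diff(range(y))) / ceiling(sqrt(n))
  for (i in seq_len(n)) {
    r <- cw
    repeat {
      cand <- which(abs(x - x[i]) < r & abs(y - y[i]) < r)
      cand <- setdiff(cand, i)
      if (length(cand) > 0) {
        out[i] <- sqrt(min((x[cand] - x[i])^2 + (y[cand] - y[i])^2))
        break
      }
      r <- 2 * r
      if (r > 1e9) { out[i] <- Inf; break }
    }
  }
  out
}

# all pairs with distance < cutoff, via cell binning
neighbour_pairs <- function(x, y, cutoff) {
  n <- length(x)
  empty <- list(i = integer(0), j = integer(0), d = numeric(0))
  if (n < 2 || cutoff <= 0) return(empty)
  cx <- floor(x / cutoff); cy <- floor(y / cutoff)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  ii <- integer(0); jj <- integer(0)
  coords <- unique(data.frame(cx = cx, cy = cy, key = key,
                              stringsAsFactors = FALSE))
  lookup <- function(u, v) cells[[paste(u, v)]]
  for (r in seq_len(nrow(coords))) {
    here <- cells[[coords$key[r]]]
    u <- coords$cx[r]; v <- coords$cy[r]
    # self cell: all unordered pairs
    if (length(here) > 1) {
      cmb <- utils::combn(here, 2)
      ii <- c(ii, cmb[1, ]); jj <- c(jj, cmb[2, ])
    }
    # half the neighbouring cells, to count each pair once
    for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      there <- lookup(u + off[1], v + off[2])
      if (!is.null(there)) {
        ii <- c(ii, rep(here, each = length(there)))
        jj <- c(jj, rep(there, times = length(here)))
      }
    }
  }
  if (length(ii) == 0) return(empty)
  d <- sqrt((x[ii] - x[jj])^2 + (y[ii] - y[jj])^2)
  keep <- d < cutoff
  a <- pmin(ii[keep], jj[keep]); b <- pmax(ii[keep], jj[keep])
  list(i = a, j = b, d = d[keep])
}

# cap node degree by removing the longest incident edges
prune_degree <- function(g, max_degree = 3) {
  e <- g$edges
  if (nrow(e) == 0) return(g)
  len <- attr(e, "length")
  if (is.null(len))
    len <- sqrt((g$nodes$x[e$from] - g$nodes$x[e$to])^2 +
                (g$nodes$y[e$from] - g$nodes$y[e$to])^2)
  keep <- rep(TRUE, nrow(e))
  repeat {
    deg <- tabulate(c(e$from[keep], e$to[keep]), nbins = nrow(g$nodes))
    over <- which(deg > max_degree)
    if (length(over) == 0) break
    v <- over[1]
    inc <- which(keep & (e$from == v | e$to == v))
    keep[inc[which.max(len[inc])]] <- FALSE
  }
  e2 <- e[keep, , drop = FALSE]
  attr(e2, "length") <- len[keep]
  rownames(e2) <- NULL
  new_bond_graph(g$nodes$x, g$nodes$y, e2, box_side = g$box_side)
}

# unwrap coordinates of each connected component across the periodic box
unwrap_components <- function(g) {
  L <- g$box_side
  if (is.null(L) || nrow(g$nodes) == 0) return(g)
  x <- g$nodes$x; y <- g$nodes$y
  n <- length(x)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges$from[k]; b <- g$edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  ux <- x; uy <- y
  for (root in seq_len(n)) {
    if (seen[root]) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (seen[w]) next
        d <- minimum_image(c(x[w] - ux[v], y[w] - uy[v]), L)
        ux[w] <- ux[v] + d[1]
        uy[w] <- uy[v] + d[2]
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  # consistency across non-tree edges: a component spanning the box cannot
  # be unwrapped and is flagged
  if (nrow(g$edges) > 0) {
    dd <- sqrt((ux[g$edges$from] - ux[g$edges$to])^2 +
               (uy[g$edges$from] - uy[g$edges$to])^2)
    if (any(dd > L / 2))
      warning("a bonded component spans the periodic box; unwrapping is inconsistent")
  }
  g$nodes$x <- ux
  g$nodes$y <- uy
  g
}

#' Extract islands (connected components) from a bond graph
#'
#' @param graph A `bond_graph`.
#' @param threshold Minimum size for the `eligible` flag used by
#'   frame-level statistics (default 24 particles).
#' @return A list of `island` objects, largest first. Each carries the
#'   global node ids, unwrapped coordinates, edges in local indexing, size
#'   and eligibility.
#' @export
islands <- function(graph, threshold = 24) {
  stopifnot(inherits(graph, "bond_graph"))
  n <- nrow(graph$nodes)
  if (n == 0) return(list())
  comp_ids <- sort(unique(graph$membership))
  out <- lapply(comp_ids, function(cid) {
    ids <- which(graph$membership == cid)
    local <- match(seq_len(n), ids)
    esel <- graph$membership[graph$edges$from] == cid
    e <- graph$edges[esel, , drop = FALSE]
    edges <- data.frame(from = local[e$from], to = local[e$to])
    structure(list(ids = ids,
                   x = graph$nodes$x[ids], y = graph$nodes$y[ids],
                   edges = edges, size = length(ids),
                   eligible = length(ids) >= threshold),
              class = "island")
  })
  out[order(vapply(out, function(i) i$size, numeric(1)), decreasing = TRUE)]
}

#' @export
print.island <- function(x, ...) {
  cat(sprintf("island: %d particles, %d bonds%s\n", x$size, nrow(x$edges),
              if (x$eligible) " (statistics-eligible)" else ""))
  invisible(x)
}
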