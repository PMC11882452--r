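#' @name synthetic
#' @title Synthetic ground-truth fields
#' @description Generators standing in for experimental AFM data: compact
#' honeycomb islands with planted pentagon/heptagon defects, elongated
#' chain assemblies, mixed fields, and AFM-like raster images. Every
#' generator is seed-deterministic and records its ground truth (bond
#' list, per-island polygon census, island class) so detection pipelines
#' can be scored against it.
NULL

# ---------------------------------------------------------------------------
# spiral face growth: builds a disc of fused 5/6/7-gons face by face.
# The boundary is kept as a CCW vertex cycle; a "bay" is a maximal run of
# degree-3 boundary vertices flanked by degree-2 vertices, and the deepest
# bay holding the oldest vertex is filled first, giving ring-by-ring
# spiral growth.
grow_polygon_disc <- function(n_faces, draw_size, a = 1) {
  k0 <- draw_size(1)
  rk <- a / (2 * sin(pi / k0))
  ang <- 2 * pi * (seq_len(k0) - 1) / k0
  x <- rk * cos(ang)
  y <- rk * sin(ang)
  edges_from <- seq_len(k0)
  edges_to <- c(seq_len(k0)[-1], 1L)
  deg <- rep(2L, k0)
  boundary <- seq_len(k0)
  faces <- list(seq_len(k0))
  infeasible <- 0L

  while (length(faces) < n_faces) {
    nb <- length(boundary)
    bdeg <- deg[boundary]
    # maximal runs of degree-3 boundary vertices (cyclic)
    runs <- list()
    if (any(bdeg >= 3)) {
      is3 <- bdeg >= 3
      start <- which(is3 & !c(is3[nb], is3[-nb]))
      for (s in start) {
        len <- 0L
        while (is3[((s - 1 + len) %% nb) + 1]) len <- len + 1L
        runs[[length(runs) + 1]] <- c(s, len)
      }
    }
    if (length(runs) > 0) {
      # deepest bay first; ties go to the bay holding the oldest vertex,
      # which makes growth close each ring before starting the next
      depth <- vapply(runs, function(r) r[2], numeric(1))
      cand <- which(depth == max(depth))
      oldest <- vapply(cand, function(ci) {
        r <- runs[[ci]]
        pp <- ((r[1] - 2 + seq_len(r[2] + 2) - 1) %% nb) + 1
        min(boundary[pp])
      }, numeric(1))
      r <- runs[[cand[which.min(oldest)]]]
      p <- r[2] + 1L
      path_pos <- ((r[1] - 2 + seq_len(p + 1) - 1) %% nb) + 1
    } else {
      # all boundary vertices degree 2 (the first petal): attach on the
      # edge at the oldest vertex
      if (any(bdeg >= 3)) stop("degenerate boundary: no attachment bay found")
      p <- 1L
      s <- which.min(boundary)
      path_pos <- c(s, (s %% nb) + 1)
    }
    path <- boundary[path_pos]
    A <- path[1]; B <- path[p + 1]

    k <- draw_size(1)
    if (k < p + 1) { infeasible <- infeasible + 1L; k <- p + 1 }
    if (k < 3) k <- 3
    m <- k - p - 1L
    rk <- a / (2 * sin(pi / k))

    # face-circle centre: with two or more shared edges the path fixes the
    # circle (circumcenter of three path points); a single shared edge
    # leaves two candidates and the exterior (right-hand) side of the
    # chord A -> B is the outside of the CCW boundary
    ax <- x[A]; ay <- y[A]; bx <- x[B]; by <- y[B]
    centre <- NULL
    if (p >= 2) {
      mid <- path[1 + p %/% 2]
      mx <- x[mid]; my <- y[mid]
      d2 <- 2 * (ax * (my - by) + mx * (by - ay) + bx * (ay - my))
      if (abs(d2) > 1e-9 * lattice_scale_sq(a)) {
        ux2 <- ((ax^2 + ay^2) * (my - by) + (mx^2 + my^2) * (by - ay) +
                (bx^2 + by^2) * (ay - my)) / d2
        uy2 <- ((ax^2 + ay^2) * (bx - mx) + (mx^2 + my^2) * (ax - bx) +
                (bx^2 + by^2) * (mx - ax)) / d2
        centre <- c(ux2, uy2)
      }
    }
    if (is.null(centre)) {
      chord <- sqrt((bx - ax)^2 + (by - ay)^2)
      h <- sqrt(max(0, rk^2 - (chord / 2)^2))
      nxv <- (by - ay) / chord; nyv <- -(bx - ax) / chord
      centre <- c((ax + bx) / 2 + h * nxv, (ay + by) / 2 + h * nyv)
    }
    cx <- centre[1]; cy <- centre[2]
    phiB <- atan2(by - cy, bx - cx)
    # step direction: continue the rotation sense of the shared path
    # (A -> ... -> B) around the face centre, so the new vertices land on
    # the far arc and never on top of the path
    step <- 2 * pi / k
    phis <- atan2(y[path] - cy, x[path] - cx)
    inc <- diff(phis)
    inc <- inc - 2 * pi * round(inc / (2 * pi))
    s <- if (sum(inc) >= 0) 1 else -1

    new_idx <- integer(0)
    if (m > 0) {
      new_idx <- length(x) + seq_len(m)
      phi <- phiB + s * seq_len(m) * step
      x <- c(x, cx + rk * cos(phi))
      y <- c(y, cy + rk * sin(phi))
      deg <- c(deg, rep(2L, m))
    }
    chain <- c(B, new_idx, A)
    for (q in seq_len(length(chain) - 1)) {
      edges_from <- c(edges_from, chain[q])
      edges_to <- c(edges_to, chain[q + 1])
    }
    deg[A] <- deg[A] + 1L
    deg[B] <- deg[B] + 1L
    # recorded CCW: the raw cycle (path, then chain) runs clockwise because
    # the new face sits on the exterior side of the CCW boundary
    faces[[length(faces) + 1]] <- rev(c(path, new_idx))

    # boundary update: path interior vertices leave; the new chain enters
    keep <- setdiff(seq_len(nb), path_pos[-c(1, p + 1)])
    posA <- match(path_pos[1], keep)
    newb <- integer(0)
    bkeep <- boundary[keep]
    nkeep <- length(bkeep)
    ordered <- c(bkeep[posA:nkeep], if (posA > 1) bkeep[1:(posA - 1)])
    # ordered starts at A; B follows immediately after A in the pruned cycle
    stopifnot(ordered[2] == B)
    newb <- c(ordered[1], rev(new_idx), ordered[-1])
    boundary <- newb
  }

  list(x = x, y = y,
       edges = data.frame(from = edges_from, to = edges_to),
       faces = faces, deg = deg, boundary = boundary,
       infeasible = infeasible)
}

lattice_scale_sq <- function(a) a * a

# Tutte embedding: boundary cycle pinned on a circle (spacing ~ a), every
# interior vertex at the mean of its neighbours. Guarantees a crossing-free
# start for the spring relaxation.
tutte_embed <- function(n, edges, boundary, a) {
  nb <- length(boundary)
  R <- nb * a / (2 * pi)
  ang <- 2 * pi * (seq_len(nb) - 1) / nb
  x <- numeric(n); y <- numeric(n)
  x[boundary] <- R * cos(ang)
  y[boundary] <- R * sin(ang)
  interior <- setdiff(seq_len(n), boundary)
  if (length(interior) > 0) {
    adj <- vector("list", n)
    for (k in seq_len(nrow(edges))) {
      i <- edges$from[k]; j <- edges$to[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    ni <- length(interior)
    idx <- match(seq_len(n), interior)
    A <- diag(ni)
    bx <- numeric(ni); by <- numeric(ni)
    for (q in seq_len(ni)) {
      v <- interior[q]
      nbrs <- adj[[v]]
      w <- 1 / length(nbrs)
      for (u in nbrs) {
        if (is.na(idx[u])) {
          bx[q] <- bx[q] + w * x[u]
          by[q] <- by[q] + w * y[u]
        } else {
          A[q, idx[u]] <- A[q, idx[u]] - w
        }
      }
    }
    x[interior] <- solve(A, bx)
    y[interior] <- solve(A, by)
  }
  list(x = x, y = y)
}

# elastic relaxation toward uniform bond length `a`: L-BFGS on
#   sum_bonds (d - a)^2
# + sum_{non-bonded pairs with d < 1.5 a} (1.5 a - d)^2
# + lambda/a^2 * sum_faces (signed_area - regular k-gon area)^2.
# The face-area term keeps every planted face positively oriented, so the
# sheet cannot fold over itself; the repulsive pair list is frozen within
# each outer round and refreshed between rounds.
relax_positions <- function(x, y, edges, a, faces = NULL, rounds = 8,
                            maxit = 400, lambda = 1) {
  n <- length(x)
  m <- nrow(edges)
  if (n < 3 || m == 0) return(list(x = x, y = y))
  ef <- edges$from; et <- edges$to
  bonded_key <- paste(pmin(ef, et), pmax(ef, et))
  r0 <- 1.5 * a
  wA <- lambda / a^2
  wD <- 0.1 # weight of the in-face diagonal (shear-stiffening) springs
  df_ <- integer(0); dt_ <- integer(0); dtar <- numeric(0)
  if (!is.null(faces)) {
    face_next <- lapply(faces, function(f) f[c(seq_along(f)[-1], 1)])
    face_prev <- lapply(faces, function(f) f[c(length(f), seq_along(f)[-length(f)])])
    face_target <- vapply(faces, function(f)
      length(f) * a^2 / (4 * tan(pi / length(f))), numeric(1))
    # second neighbours within each face, at the regular k-gon diagonal
    for (f in faces) {
      k <- length(f)
      diag_k <- a * sin(2 * pi / k) / sin(pi / k)
      nxt2 <- f[c(seq_len(k)[-(1:2)], 1, 2)]
      df_ <- c(df_, f); dt_ <- c(dt_, nxt2)
      dtar <- c(dtar, rep(diag_k, k))
    }
  }
  for (round in seq_len(rounds)) {
    pr <- neighbour_pairs(x, y, r0)
    nbp <- !(paste(pr$i, pr$j) %in% bonded_key)
    ri <- pr$i[nbp]; rj <- pr$j[nbp]
    fn <- function(p) {
      px <- p[1:n]; py <- p[(n + 1):(2 * n)]
      d <- sqrt((px[et] - px[ef])^2 + (py[et] - py[ef])^2)
      e <- sum((d - a)^2)
      if (length(ri)) {
        dr <- sqrt((px[rj] - px[ri])^2 + (py[rj] - py[ri])^2)
        e <- e + sum(pmax(r0 - dr, 0)^2)
      }
      if (length(df_)) {
        dd <- sqrt((px[dt_] - px[df_])^2 + (py[dt_] - py[df_])^2)
        e <- e + wD * sum((dd - dtar)^2)
      }
      if (!is.null(faces)) {
        for (q in seq_along(faces)) {
          f <- faces[[q]]
          A <- 0.5 * sum(px[f] * py[face_next[[q]]] - px[face_next[[q]]] * py[f])
          e <- e + wA * (A - face_target[q])^2
        }
      }
      e
    }
    gr <- function(p) {
      px <- p[1:n]; py <- p[(n + 1):(2 * n)]
      gx <- numeric(n); gy <- numeric(n)
      dx <- px[et] - px[ef]; dy <- py[et] - py[ef]
      d <- pmax(sqrt(dx^2 + dy^2), 1e-12)
      c1 <- 2 * (d - a) / d
      ids <- sort(unique(c(ef, et)))
      gx[ids] <- rowsum(c(-c1 * dx, c1 * dx), c(ef, et))
      gy[ids] <- rowsum(c(-c1 * dy, c1 * dy), c(ef, et))
      if (length(ri)) {
        dxr <- px[rj] - px[ri]; dyr <- py[rj] - py[ri]
        dr <- pmax(sqrt(dxr^2 + dyr^2), 1e-12)
        act <- dr < r0
        if (any(act)) {
          c2 <- 2 * (dr[act] - r0) / dr[act]
          ia <- ri[act]; ja <- rj[act]
          rid <- sort(unique(c(ia, ja)))
          gx[rid] <- gx[rid] + rowsum(c(-c2 * dxr[act], c2 * dxr[act]), c(ia, ja))
          gy[rid] <- gy[rid] + rowsum(c(-c2 * dyr[act], c2 * dyr[act]), c(ia, ja))
        }
      }
      if (length(df_)) {
        dxd <- px[dt_] - px[df_]; dyd <- py[dt_] - py[df_]
        dd <- pmax(sqrt(dxd^2 + dyd^2), 1e-12)
        c3 <- 2 * wD * (dd - dtar) / dd
        did <- sort(unique(c(df_, dt_)))
        gx[did] <- gx[did] + rowsum(c(-c3 * dxd, c3 * dxd), c(df_, dt_))
        gy[did] <- gy[did] + rowsum(c(-c3 * dyd, c3 * dyd), c(df_, dt_))
      }
      if (!is.null(faces)) {
        for (q in seq_along(faces)) {
          f <- faces[[q]]
          nx2 <- face_next[[q]]; pv <- face_prev[[q]]
          A <- 0.5 * sum(px[f] * py[nx2] - px[nx2] * py[f])
          cA <- 2 * wA * (A - face_target[q])
          # dA/dx_i = (y_next - y_prev)/2, dA/dy_i = (x_prev - x_next)/2
          gx[f] <- gx[f] + cA * 0.5 * (py[nx2] - py[pv])
          gy[f] <- gy[f] + cA * 0.5 * (px[pv] - px[nx2])
        }
      }
      c(gx, gy)
    }
    opt <- stats::optim(c(x, y), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    x <- opt$par[1:n]; y <- opt$par[(n + 1):(2 * n)]
    d <- sqrt((x[et] - x[ef])^2 + (y[et] - y[ef])^2)
    if (max(abs(d - a)) < 0.08 * a && opt$convergence == 0) break
  }
  list(x = x, y = y)
}

arm_angles_from_bonds <- function(n, edges, x, y) {
  ang <- matrix(NA_real_, n, 3)
  nb <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]
    nb[[i]] <- c(nb[[i]], atan2(y[j] - y[i], x[j] - x[i]))
    nb[[j]] <- c(nb[[j]], atan2(y[i] - y[j], x[i] - x[j]))
  }
  for (i in seq_len(n)) {
    b <- nb[[i]]
    d <- length(b)
    if (d >= 3) {
      ang[i, ] <- b[1:3]
    } else if (d == 2) {
      third <- atan2(-(sin(b[1]) + sin(b[2])), -(cos(b[1]) + cos(b[2])))
      ang[i, ] <- c(b, third)
    } else if (d == 1) {
      ang[i, ] <- c(b, b + 2 * pi / 3, b + 4 * pi / 3)
    } else {
      base <- runif(1, 0, 2 * pi)
      ang[i, ] <- base + c(0, 2, 4) * pi / 3
    }
  }
  ang %% (2 * pi)
}

new_synthetic_field <- function(points, bonds, arm_angles, census,
                                islands_df, lattice_nm, field_nm, seed) {
  structure(list(points = points, bonds = bonds, arm_angles = arm_angles,
                 census = census, islands = islands_df,
                 lattice_nm = lattice_nm, field_nm = field_nm, seed = seed),
            class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("synthetic field: %d particles, %d bonds, %d island(s), %.0f nm\n",
              nrow(x$points), nrow(x$bonds), nrow(x$islands), x$field_nm))
  invisible(x)
}

#' Generate a compact honeycomb island with planted defects
#'
#' Grows a disc of fused polygons ring by ring in a spiral; each growth
#' step draws the face size from `{5, 6, 7}` with the pentagon/heptagon
#' probabilities in `defect_rates` (hexagon otherwise). With non-zero
#' defect rates the positions are relaxed by a short spring iteration so
#' all bond lengths stay within 10 percent of the lattice constant. The
#' planted polygon census is recorded as ground truth.
#'
#' @param n_rings Number of hexagon rings (1 = a single face; 2 = the
#'   7-face flower of 24 particles). Ignored when `n_particles` is given.
#' @param n_particles Grow until at least this many particles instead.
#' @param defect_rates Length-2 numeric `(pentagon, heptagon)` rates in
#'   `[0, 0.3]`.
#' @param lattice_nm Bonded centre-to-centre distance in nm (default 16).
#' @param seed Optional RNG seed.
#' @return A `synthetic_field` with island class `"compact"`.
#' @export
make_compact_island <- function(n_rings = 2, n_particles = NULL,
                                defect_rates = c(0, 0), lattice_nm = 16,
                                seed = NULL) {
  stopifnot(length(defect_rates) == 2, all(defect_rates >= 0),
            all(defect_rates <= 0.3), sum(defect_rates) < 1)
  if (!is.null(seed)) set.seed(seed)
  # a growth step plants a defect with probability r5 + r7; each pentagon
  # is immediately followed by a heptagon (and vice versa) at the next
  # growth position, so defects enter as adjacent 5-7 dipoles - the
  # dislocation cores seen in real lattices - and the sheet stays flat.
  # For equal rates this realizes both nominal per-face rates without bias.
  pending <- 0L
  # each dipole event plants two defect faces, so the per-event probability
  # q solves 2q/(1+q) = r5 + r7, keeping the per-face defect fraction at
  # the nominal rates
  q_event <- sum(defect_rates) / (2 - sum(defect_rates))
  draw_size <- function(k) {
    if (pending != 0L) { out <- pending; pending <<- 0L; return(out) }
    if (sum(defect_rates) > 0 && runif(1) < q_event) {
      if (runif(1) < defect_rates[1] / sum(defect_rates)) {
        pending <<- 7L
        return(5L)
      }
      pending <<- 5L
      return(7L)
    }
    6L
  }
  grow_once <- function() {
    pending <<- 0L
    if (is.null(n_particles)) {
      stopifnot(n_rings >= 1)
      n_faces <- 1 + 3 * n_rings * (n_rings - 1)
      return(grow_polygon_disc(n_faces, draw_size, a = lattice_nm))
    }
    stopifnot(n_particles >= 3)
    n_faces <- 1
    repeat {
      disc <- grow_polygon_disc(n_faces, draw_size, a = lattice_nm)
      if (length(disc$x) >= n_particles) return(disc)
      n_faces <- n_faces + 1
    }
  }

  # Defective discs are relaxed from a guaranteed-planar Tutte embedding.
  # An embedding is accepted when all bond lengths stay within 10% of the
  # lattice constant and no non-bonded pair comes below 1.3 lattice
  # constants; otherwise the relaxation restarts from a perturbed start,
  # and if no clean embedding is found the defect placement itself is
  # redrawn (the rare topologies that cannot be embedded flat within
  # tolerance are discarded, keeping the ground truth exact).
  a <- lattice_nm
  good <- FALSE
  for (redraw in 1:6) {
    disc <- grow_once()
    x <- disc$x; y <- disc$y
    if (!any(vapply(disc$faces, length, integer(1)) != 6L)) {
      good <- TRUE
      break
    }
    n <- length(x)
    tt <- tutte_embed(n, disc$edges, disc$boundary, a)
    bonded_key <- paste(pmin(disc$edges$from, disc$edges$to),
                        pmax(disc$edges$from, disc$edges$to))
    for (try in 0:5) {
      sx <- tt$x + if (try > 0) rnorm(n, 0, 0.06 * try * a) else 0
      sy <- tt$y + if (try > 0) rnorm(n, 0, 0.06 * try * a) else 0
      rl <- relax_positions(sx, sy, disc$edges, a, faces = disc$faces)
      dd <- sqrt((rl$x[disc$edges$to] - rl$x[disc$edges$from])^2 +
                 (rl$y[disc$edges$to] - rl$y[disc$edges$from])^2)
      pr <- neighbour_pairs(rl$x, rl$y, 1.3 * a)
      clash <- sum(!(paste(pr$i, pr$j) %in% bonded_key))
      if (max(abs(dd - a)) <= 0.1 * a && clash == 0) { good <- TRUE; break }
    }
    x <- rl$x; y <- rl$y
    if (good) break
  }
  if (!good)
    warning("relaxed island geometry is strained: bond lengths deviate more than 10% from the lattice constant")
  n <- length(x)
  census <- data.frame(island = 1L,
                       size = vapply(disc$faces, length, integer(1)))
  new_synthetic_field(
    points = data.frame(x_nm = x, y_nm = y, island = 1L, class = "compact"),
    bonds = disc$edges,
    arm_angles = arm_angles_from_bonds(n, disc$edges, x, y),
    census = census,
    islands_df = data.frame(id = 1L, class = "compact", size = n),
    lattice_nm = lattice_nm,
    field_nm = 2 * max(abs(c(x, y))) + 4 * lattice_nm,
    seed = seed)
}

#' Generate an elongated chain-like island
#'
#' A neighbour-avoiding self-avoiding walk on the honeycomb lattice:
#' successive sites are lattice neighbours, and no site is ever placed
#' adjacent to a non-consecutive occupied site, so the bonded graph is a
#' tree (a chain with optional branches) carrying no polygons. Branching
#' restarts growth from a random occupied site with probability
#' `branch_prob` per step.
#'
#' @param n_particles Number of particles (>= 2).
#' @param branch_prob Branching probability per growth step, in `[0, 0.3]`.
#' @param lattice_nm Lattice constant in nm.
#' @param seed Optional RNG seed.
#' @return A `synthetic_field` with island class `"elongated"`.
#' @export
make_elongated_island <- function(n_particles, branch_prob = 0.1,
                                  lattice_nm = 16, seed = NULL) {
  stopifnot(n_particles >= 2, branch_prob >= 0, branch_prob <= 0.3)
  if (!is.null(seed)) set.seed(seed)
  # honeycomb sites keyed by (u, v, s); A(u,v,0) ~ B(u,v,1), B(u-1,v,1),
  # B(u,v-1,1); positions with unit bond length, scaled by lattice_nm
  nbrs <- function(s) {
    if (s[3] == 0) list(c(s[1], s[2], 1), c(s[1] - 1, s[2], 1), c(s[1], s[2] - 1, 1))
    else list(c(s[1], s[2], 0), c(s[1] + 1, s[2], 0), c(s[1], s[2] + 1, 0))
  }
  pos <- function(s) {
    t1 <- c(1.5, sqrt(3) / 2); t2 <- c(1.5, -sqrt(3) / 2)
    p <- s[1] * t1 + s[2] * t2
    if (s[3] == 1) p <- p + c(1, 0)
    p
  }
  key <- function(s) paste(s, collapse = ",")
  occupied <- new.env(parent = emptyenv())
  sites <- list(c(0L, 0L, 0L))
  assign(key(sites[[1]]), 1L, envir = occupied)
  parent <- c(NA_integer_)
  tip <- 1L
  guard <- 0
  while (length(sites) < n_particles && guard < 200 * n_particles) {
    guard <- guard + 1
    if (length(sites) > 1 && runif(1) < branch_prob)
      tip <- sample.int(length(sites), 1)
    cand <- nbrs(sites[[tip]])
    ok <- Filter(function(s) {
      if (!is.null(get0(key(s), envir = occupied))) return(FALSE)
      # neighbour avoidance: no occupied neighbour other than the tip
      for (t in nbrs(s)) {
        oi <- get0(key(t), envir = occupied)
        if (!is.null(oi) && oi != tip) return(FALSE)
      }
      TRUE
    }, cand)
    if (length(ok) == 0) { tip <- sample.int(length(sites), 1); next }
    s <- ok[[sample.int(length(ok), 1)]]
    sites[[length(sites) + 1]] <- s
    assign(key(s), length(sites), envir = occupied)
    parent <- c(parent, tip)
    tip <- length(sites)
  }
  if (length(sites) < n_particles)
    warning("chain growth stalled; island smaller than requested")
  n <- length(sites)
  xy <- t(vapply(sites, pos, numeric(2))) * lattice_nm
  edges <- data.frame(from = parent[-1], to = seq_len(n)[-1])
  x <- xy[, 1] - mean(xy[, 1]); y <- xy[, 2] - mean(xy[, 2])
  new_synthetic_field(
    points = data.frame(x_nm = x, y_nm = y, island = 1L, class = "elongated"),
    bonds = edges,
    arm_angles = arm_angles_from_bonds(n, edges, x, y),
    census = data.frame(island = integer(0), size = integer(0)),
    islands_df = data.frame(id = 1L, class = "elongated", size = n),
    lattice_nm = lattice_nm,
    field_nm = 2 * max(abs(c(x, y))) + 4 * lattice_nm,
    seed = seed)
}

#' Compose a synthetic field from island components
#'
#' Places compact islands, elongated islands and single-particle "gas"
#' monomers into a square field by rejection sampling: components are
#' randomly rotated and positioned so that their bounding circles stay a
#' lattice constant apart and inside the field.
#'
#' @param n_compact,n_elongated,n_gas Component counts.
#' @param field_nm Field edge length in nm (default 750).
#' @param lattice_nm Lattice constant in nm.
#' @param compact_args,elongated_args Argument lists passed to the island
#'   generators (minus `lattice_nm` and `seed`).
#' @param seed Optional RNG seed.
#' @param max_attempts Placement attempts per component.
#' @return A merged `synthetic_field`.
#' @export
make_field <- function(n_compact = 0, n_elongated = 0, n_gas = 0,
                       field_nm = 750, lattice_nm = 16,
                       compact_args = list(n_rings = 2),
                       elongated_args = list(n_particles = 24),
                       seed = NULL, max_attempts = 500) {
  if (!is.null(seed)) set.seed(seed)
  comps <- list()
  for (i in seq_len(n_compact))
    comps[[length(comps) + 1]] <- do.call(make_compact_island,
      c(compact_args, list(lattice_nm = lattice_nm)))
  for (i in seq_len(n_elongated))
    comps[[length(comps) + 1]] <- do.call(make_elongated_island,
      c(elongated_args, list(lattice_nm = lattice_nm)))
  for (i in seq_len(n_gas)) {
    g <- new_synthetic_field(
      points = data.frame(x_nm = 0, y_nm = 0, island = 1L, class = "gas"),
      bonds = data.frame(from = integer(0), to = integer(0)),
      arm_angles = matrix(runif(1, 0, 2 * pi) + c(0, 2, 4) * pi / 3, 1, 3),
      census = data.frame(island = integer(0), size = integer(0)),
      islands_df = data.frame(id = 1L, class = "gas", size = 1L),
      lattice_nm = lattice_nm, field_nm = field_nm, seed = NULL)
    comps[[length(comps) + 1]] <- g
  }
  if (length(comps) == 0)
    return(new_synthetic_field(
      points = data.frame(x_nm = numeric(0), y_nm = numeric(0),
                          island = integer(0), class = character(0)),
      bonds = data.frame(from = integer(0), to = integer(0)),
      arm_angles = matrix(numeric(0), 0, 3),
      census = data.frame(island = integer(0), size = integer(0)),
      islands_df = data.frame(id = integer(0), class = character(0),
                              size = integer(0)),
      lattice_nm = lattice_nm, field_nm = field_nm, seed = seed))

  # place the largest components first: greatly improves packing success
  radius_of <- function(cp) {
    if (nrow(cp$points) == 0) return(0)
    px <- cp$points$x_nm - mean(cp$points$x_nm)
    py <- cp$points$y_nm - mean(cp$points$y_nm)
    max(sqrt(px^2 + py^2))
  }
  ord <- order(vapply(comps, radius_of, numeric(1)), decreasing = TRUE)
  comps <- comps[ord]

  placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
  all_pts <- list(); all_bonds <- list(); all_arms <- list()
  all_census <- list(); all_isl <- list()
  offset <- 0L
  for (ci in seq_along(comps)) {
    cp <- comps[[ci]]
    px <- cp$points$x_nm - mean(cp$points$x_nm)
    py <- cp$points$y_nm - mean(cp$points$y_nm)
    rad <- if (length(px)) max(sqrt(px^2 + py^2)) else 0
    margin <- rad + lattice_nm
    if (2 * margin > field_nm)
      stop("component too large for the field; use a larger field_nm")
    ok <- FALSE
    for (t in seq_len(max_attempts)) {
      rot <- runif(1, 0, 2 * pi)
      cx <- runif(1, margin, field_nm - margin)
      cy <- runif(1, margin, field_nm - margin)
      if (length(placed_x) == 0 ||
          all(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) >
              placed_r + rad + 2 * lattice_nm)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place all components; use a larger field_nm or fewer components")
    placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
    placed_r <- c(placed_r, rad)
    co <- cos(rot); si <- sin(rot)
    qx <- cx + co * px - si * py
    qy <- cy + si * px + co * py
    n_i <- length(qx)
    all_pts[[ci]] <- data.frame(x_nm = qx, y_nm = qy, island = ci,
                                class = cp$points$class)
    b <- cp$bonds
    if (nrow(b)) b <- data.frame(from = b$from + offset, to = b$to + offset)
    all_bonds[[ci]] <- b
    all_arms[[ci]] <- (cp$arm_angles + rot) %% (2 * pi)
    cs <- cp$census
    if (nrow(cs)) cs$island <- ci
    all_census[[ci]] <- cs
    all_isl[[ci]] <- data.frame(id = ci, class = cp$islands$class[1],
                                size = n_i)
    offset <- offset + n_i
  }
  new_synthetic_field(
    points = do.call(rbind, all_pts),
    bonds = do.call(rbind, all_bonds),
    arm_angles = do.call(rbind, all_arms),
    census = do.call(rbind, all_census),
    islands_df = do.call(rbind, all_isl),
    lattice_nm = lattice_nm, field_nm = field_nm, seed = seed)
}

# ---------------------------------------------------------------------------

#' Rasterize a synthetic field into an AFM-like height image
#'
#' Each monomer is rendered as a three-armed Gaussian ridge star: arms of
#' length half a lattice constant leave the centre along the recorded arm
#' directions (bonded arms point at their partners, so bonded monomers
#' form continuous ridges). Additive Gaussian pixel noise and per-scan-line
#' constant offsets emulate the dominant AFM artefacts.
#'
#' @param field A `synthetic_field`.
#' @param pixels Image side in pixels (default 256).
#' @param field_nm Field edge in nm (default: the field's own size, 750 for
#'   composed fields).
#' @param height_nm Ridge height (default 2, the apparent DNA height).
#' @param ridge_width_nm Gaussian ridge width (sd) in nm.
#' @param noise_sd Pixel noise sd in nm.
#' @param line_offset_sd Per-scan-line offset sd in nm.
#' @param seed Optional RNG seed.
#' @return An object of class `afm_image`: `height` matrix (row = y,
#'   column = x, pixel centres at `(index - 0.5) * pixel_nm`), `pixel_nm`,
#'   `field_nm`, `height_nm` and provenance.
#' @export
rasterize <- function(field, pixels = 256, field_nm = NULL, height_nm = 2,
                      ridge_width_nm = 3, noise_sd = 0.1,
                      line_offset_sd = 0.15, seed = NULL) {
  stopifnot(inherits(field, "synthetic_field"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(field_nm)) field_nm <- field$field_nm
  px <- field_nm / pixels
  if (px > field$lattice_nm / 2)
    warning("pixel size coarser than half the lattice constant; centres unresolvable")
  img <- matrix(0, pixels, pixels)
  arm_len <- field$lattice_nm / 2
  w <- ridge_width_nm
  pad <- arm_len + 3 * w
  # centred fields get shifted into the image frame
  xs <- field$points$x_nm
  ys <- field$points$y_nm
  if (length(xs) && (min(xs) < 0 || min(ys) < 0)) {
    xs <- xs - min(xs) + (field_nm - diff(range(xs))) / 2
    ys <- ys - min(ys) + (field_nm - diff(range(ys))) / 2
  }
  for (i in seq_along(xs)) {
    x0 <- xs[i]; y0 <- ys[i]
    c_lo <- max(1L, floor((x0 - pad) / px)); c_hi <- min(pixels, ceiling((x0 + pad) / px))
    r_lo <- max(1L, floor((y0 - pad) / px)); r_hi <- min(pixels, ceiling((y0 + pad) / px))
    if (c_lo > c_hi || r_lo > r_hi) next
    cc <- c_lo:c_hi; rr <- r_lo:r_hi
    gx <- (cc - 0.5) * px
    gy <- (rr - 0.5) * px
    GX <- matrix(gx, length(rr), length(cc), byrow = TRUE)
    GY <- matrix(gy, length(rr), length(cc))
    local <- matrix(0, length(rr), length(cc))
    for (k in 1:3) {
      th <- field$arm_angles[i, k]
      ex <- cos(th) * arm_len; ey <- sin(th) * arm_len
      # distance of each pixel centre to the arm segment
      tpar <- ((GX - x0) * ex + (GY - y0) * ey) / (arm_len^2)
      tpar <- pmin(pmax(tpar, 0), 1)
      dx <- GX - (x0 + tpar * ex)
      dy <- GY - (y0 + tpar * ey)
      d2 <- dx^2 + dy^2
      local <- pmax(local, height_nm * exp(-d2 / (2 * w^2)))
    }
    img[rr, cc] <- pmax(img[rr, cc], local)
  }
  if (line_offset_sd > 0)
    img <- img + rnorm(pixels, 0, line_offset_sd) # recycled per column: one offset per row (scan line)
  if (noise_sd > 0)
    img <- img + matrix(rnorm(pixels * pixels, 0, noise_sd), pixels, pixels)
  structure(list(height = img, pixel_nm = px, field_nm = field_nm,
                 height_nm = height_nm,
                 provenance = list(pixels = pixels, ridge_width_nm = w,
                                   noise_sd = noise_sd,
                                   line_offset_sd = line_offset_sd,
                                   seed = seed)),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("AFM image: %d x %d px, %.3f nm/px, %.0f nm field, range [%.2f, %.2f] nm\n",
              nrow(x$height), ncol(x$height), x$pixel_nm, x$field_nm,
              min(x$height), max(x$height)))
  invisible(x)
}

#' @export
plot.afm_image <- function(x, ...) {
  image(t(x$height), col = gray(seq(0, 1, length.out = 128)),
        asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' Write an AFM image to TIFF (32-bit float) or PNG preview
#'
#' TIFF output stores heights scaled into the unit interval expected by
#' TIFF readers (1 unit = 10 nm); the scale, pixel size and field size are
#' recorded in a JSON sidecar (`<path>.json`) and restored by
#' [read_afm_image()]. PNG output is an 8-bit preview normalized to the
#' data range.
#'
#' @param image An `afm_image`.
#' @param path Output path; format chosen from the extension
#'   (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_afm_image <- function(image, path) {
  stopifnot(inherits(image, "afm_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # unit range maps [-5, 5] nm so noise below the baseline survives
    scale <- 10; offset <- 5
    m <- pmin(pmax((image$height + offset) / scale, 0), 1)
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
    meta <- list(pixel_nm = image$pixel_nm, field_nm = image$field_nm,
                 height_nm = image$height_nm, height_scale = scale,
                 height_offset = offset)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               paste0(path, ".json"))
  } else if (ext == "png") {
    rng <- range(image$height)
    m <- if (diff(rng) > 0) (image$height - rng[1]) / diff(rng)
         else image$height * 0
    png::writePNG(m, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read an AFM image written by [write_afm_image()] (or any TIFF/PNG)
#'
#' A `<path>.json` sidecar written by [write_afm_image()] restores the
#' height scale and pixel size; plain images need `pixel_nm`.
#'
#' @param path Image path.
#' @param pixel_nm Pixel size override for plain images without a sidecar.
#' @param height_scale Height scale override (nm per unit value) for plain
#'   images; default 1.
#' @return An `afm_image`.
#' @export
read_afm_image <- function(path, pixel_nm = NULL, height_scale = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      meta <- jsonlite::fromJSON(side)
      off <- if (is.null(meta$height_offset)) 0 else meta$height_offset
      return(structure(list(height = m * meta$height_scale - off,
                            pixel_nm = meta$pixel_nm,
                            field_nm = meta$field_nm,
                            height_nm = meta$height_nm,
                            provenance = list(path = path)),
                       class = "afm_image"))
    }
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
  } else stop("unsupported image format: ", ext)
  if (is.null(pixel_nm)) stop("pixel_nm required for images without metadata")
  structure(list(height = m * height_scale, pixel_nm = pixel_nm,
                 field_nm = pixel_nm * ncol(m), height_nm = NA_real_,
                 provenance = list(path = path)),
            class = "afm_image")
}
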