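# Independent oracles and fixture builders used across the suite.

# brute-force O(N^2) total energy, summed through the scalar pair kernel
brute_force_energy <- function(config, params) {
  n <- length(config$x)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) {
    pi_ <- list(x = config$x[i], y = config$y[i],
                orientation = config$orientation[i],
                patch_states = config$patch_states[i, ])
    for (j in (i + 1):n) {
      pj_ <- list(x = config$x[j], y = config$y[j],
                  orientation = config$orientation[j],
                  patch_states = config$patch_states[j, ])
      pe <- pair_energy(pi_, pj_, params)
      if (pe$overlap) stop("oracle: overlap")
      e <- e + pe$energy
    }
  }
  e
}

# ideal 6-ring of bonded particles: centres on a hexagon of circumradius
# r = d / (2 sin(pi/6)) = d, with every particle's patch 1 pointing at its
# clockwise neighbour so that two patches per particle are engaged
hex_ring_config <- function(params, d = NULL) {
  if (is.null(d)) d <- params$sigma * (1 + params$delta / 2)
  L <- params$box_side
  ang <- 2 * pi * (0:5) / 6
  cx <- L / 2 + d * cos(ang)
  cy <- L / 2 + d * sin(ang)
  ori <- numeric(6)
  for (i in 1:6) {
    j <- if (i == 6) 1 else i + 1
    ori[i] <- atan2(cy[j] - cy[i], cx[j] - cx[i])
  }
  configuration(cx, cy, ori, matrix(1L, 6, 3), L)
}

# random non-overlapping configuration with random states
random_test_config <- function(n, L, seed) {
  set.seed(seed)
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    px <- runif(1, 0, L); py <- runif(1, 0, L)
    if (length(x) == 0 ||
        all((pmin(abs(px - x), L - abs(px - x)))^2 +
            (pmin(abs(py - y), L - abs(py - y)))^2 >= 1.0001)) {
      x <- c(x, px); y <- c(y, py)
    }
  }
  configuration(x, y, runif(n, 0, 2 * pi),
                matrix(sample(0:1, 3 * n, replace = TRUE), n, 3), L)
}

# point-in-polygon by ray casting (strict interior)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Brute-force face oracle: enumerate every simple cycle of length 3..9 and
# keep those that are empty faces of the straight-line embedding (no vertex
# strictly inside, no edge crossing the interior via a chord).
oracle_faces <- function(island, max_len = 9) {
  n <- length(island$x)
  e <- island$edges
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e$from[k]]] <- c(adj[[e$from[k]]], e$to[k])
    adj[[e$to[k]]] <- c(adj[[e$to[k]]], e$from[k])
  }
  has_edge <- matrix(FALSE, n, n)
  has_edge[cbind(e$from, e$to)] <- TRUE
  has_edge <- has_edge | t(has_edge)
  cycles <- list()
  # cycles rooted at their minimal vertex, second vertex < last to dedup
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1] && length(path) >= 3) {
        if (path[2] < path[length(path)])
          cycles[[length(cycles) + 1]] <<- path
      } else if (w > path[1] && !(w %in% path) && length(path) < max_len) {
        dfs(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  is_face <- vapply(cycles, function(cy) {
    vx <- island$x[cy]; vy <- island$y[cy]
    others <- setdiff(seq_len(n), cy)
    for (o in others)
      if (point_in_polygon(island$x[o], island$y[o], vx, vy)) return(FALSE)
    # interior chords disqualify the cycle
    k <- length(cy)
    for (a in seq_len(k - 2)) for (b in (a + 2):k) {
      if (a == 1 && b == k) next
      if (has_edge[cy[a], cy[b]]) {
        mx <- (island$x[cy[a]] + island$x[cy[b]]) / 2
        my <- (island$y[cy[a]] + island$y[cy[b]]) / 2
        if (point_in_polygon(mx, my, vx, vy)) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  lengths <- vapply(cycles[is_face], length, integer(1))
  sort(lengths)
}

# quadrature oracle for the 2-particle bonded fraction: integrate over the
# separation (r, phi) and the partner orientation, with the patch states
# summed under their intrinsic weights
oracle_bonded_fraction <- function(params, n_r = 24, n_ang = 360) {
  L <- params$box_side
  sg <- params$sigma; dl <- params$delta
  th <- params$theta_pw; eps <- params$epsilon; p <- params$p_open
  aligned_frac <- function(nang) {
    # fraction of a uniform angle at which some patch of a particle with
    # orientation 0 points within th of the target direction; by symmetry
    # integrate the indicator over the direction
    # distance of a from the nearest patch direction {0, 120, 240 deg}
    a <- (seq_len(nang) - 0.5) * 2 * pi / nang
    dev <- pmin(a %% (2 * pi / 3), 2 * pi / 3 - a %% (2 * pi / 3))
    mean(dev < th)
  }
  # radial weight of the well
  rs <- sg + (seq_len(n_r) - 0.5) * dl / n_r
  shell <- sum(2 * pi * rs * dl / n_r)
  g1 <- aligned_frac(n_ang)  # particle 1's patch onto the axis
  g2 <- aligned_frac(n_ang)  # particle 2 (independent orientation)
  pcc <- (1 - p)^2
  bond_w <- shell * g1 * g2 * pcc * exp(eps)
  total <- (L^2 - pi * sg^2) + shell * g1 * g2 * pcc * (exp(eps) - 1)
  bond_w / total
}

# precision / recall of detected centres against ground truth
detection_score <- function(centres, truth, tol_nm) {
  if (nrow(centres) == 0) return(c(recall = 0, precision = 0))
  d2 <- outer(truth$x_nm, centres$x_nm, "-")^2 +
    outer(truth$y_nm, centres$y_nm, "-")^2
  c(recall = mean(sqrt(apply(d2, 1, min)) < tol_nm),
    precision = mean(sqrt(apply(d2, 2, min)) < tol_nm))
}

# batch-means standard error for a (possibly autocorrelated) 0/1 series
batch_se <- function(x, n_batch = 25) {
  m <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  sd(means) / sqrt(n_batch)
}
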