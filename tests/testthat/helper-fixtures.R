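# Shared fixtures and independent brute-force oracles. Oracles are written
# in plain R, independent of the package's computation paths.

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
}

rotate_outline <- function(o, theta) {
  as_outline(unclass(o) %*% t(rot_mat(theta)))
}

shift_outline <- function(o, dx, dy) {
  as_outline(sweep(unclass(o), 2L, c(dx, dy), "+"))
}

# Open semicircular arc of radius r on its diameter baseline, left to right.
semicircle <- function(n = 200L, r = 1) {
  t <- seq(pi, 0, length.out = n)
  as_outline(cbind(r * cos(t), r * sin(t)))
}

# Axis-aligned open rectangle outline: baseline from (0,0) to (w,0), crown
# going up the left side, across the top, down the right side. n chosen so
# corners fall exactly on sample points when resampled.
rect_outline <- function(w = 2, h = 1) {
  as_outline(cbind(c(0, 0, w, w), c(0, h, h, 0)))
}

# A small battery of distinct synthetic crowns.
tooth_battery <- function(k, n_points = 64L) {
  params <- list(
    tooth_params(1, 0, cusp_height = 0.6),
    tooth_params(1, 0, cusp_height = 0.4, asymmetry = 0.5),
    tooth_params(2, 0, cusp_height = 0.5),
    tooth_params(3, 0, cusp_height = 0.4),
    tooth_params(1, 5, cusp_height = 0.7, minor_cusp_height = 0.06),
    tooth_params(2, 4, cusp_height = 0.5, minor_cusp_height = 0.05,
                 asymmetry = -0.3),
    tooth_params(1, 0, cusp_height = 0.9, elongation = 1.6),
    tooth_params(4, 0, cusp_height = 0.35, smoothness = 0.02)
  )
  lapply(seq_len(k), function(i) {
    p <- params[[(i - 1L) %% length(params) + 1L]]
    p$cusp_height <- min(1, p$cusp_height + 0.02 * ((i - 1L) %/% length(params)))
    make_tooth(p, n_points)
  })
}

# --- oracles ---------------------------------------------------------------

# EMD by explicit double loops.
emd_brute <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  dmin_ab <- vapply(seq_len(nrow(a)), function(i)
    min(sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2)), 0.0)
  dmin_ba <- vapply(seq_len(nrow(b)), function(j)
    min(sqrt((b[j, 1] - a[, 1])^2 + (b[j, 2] - a[, 2])^2)), 0.0)
  mean(dmin_ab) + mean(dmin_ba)
}

# General position-matched distance (both directions) by enumeration.
hed_brute <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  ni <- nrow(a); nj <- nrow(b)
  k <- vapply(seq_len(ni), function(i)
    which.min(abs(i / ni - seq_len(nj) / nj)), 1L)
  l <- vapply(seq_len(nj), function(j)
    which.min(abs(j / nj - seq_len(ni) / ni)), 1L)
  mean(sqrt(rowSums((a - b[k, , drop = FALSE])^2))) +
    mean(sqrt(rowSums((b - a[l, , drop = FALSE])^2)))
}

# Even-odd point-in-polygon test.
point_in_poly_r <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi <= py && yj > py) || (yj <= py && yi > py)) {
      xint <- poly[i, 1] + (py - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# SAO by brute-force pixel-center classification on the same grid spec.
sao_brute <- function(a, b, grid) {
  count_cells <- function(poly) {
    hits <- matrix(FALSE, grid$ny, grid$nx)
    for (r in seq_len(grid$ny)) {
      yc <- grid$y0 + (r - 0.5) * grid$cy
      for (c in seq_len(grid$nx)) {
        xc <- grid$x0 + (c - 0.5) * grid$cx
        hits[r, c] <- point_in_poly_r(poly, xc, yc)
      }
    }
    hits
  }
  ma <- count_cells(unclass(a)); mb <- count_cells(unclass(b))
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}

# Largest inscribed circle radius by a plain R grid search.
inradius_brute <- function(poly, grid = 200L) {
  poly <- unclass(poly)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  best <- -1
  seg_dist <- function(px, py) {
    n <- nrow(poly)
    d <- Inf
    for (e in seq_len(n)) {
      f <- if (e == n) 1L else e + 1L
      v <- poly[f, ] - poly[e, ]
      L2 <- sum(v^2)
      t <- if (L2 > 0) ((px - poly[e, 1]) * v[1] + (py - poly[e, 2]) * v[2]) / L2 else 0
      t <- min(1, max(0, t))
      d <- min(d, sqrt((px - poly[e, 1] - t * v[1])^2 + (py - poly[e, 2] - t * v[2])^2))
    }
    d
  }
  for (i in seq_len(grid)) {
    px <- xr[1] + (i - 0.5) / grid * diff(xr)
    for (j in seq_len(grid)) {
      py <- yr[1] + (j - 0.5) / grid * diff(yr)
      if (point_in_poly_r(poly, px, py)) best <- max(best, seg_dist(px, py))
    }
  }
  best
}

# Orientation patch count for one fixed configuration by enumeration.
opc_brute_one <- function(p, partitions, rotation) {
  v <- diff(unclass(p))
  theta <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  w <- 2 * pi / partitions
  sec <- floor(((theta + rotation) %% (2 * pi)) / w)
  runs <- 1L
  for (i in seq_along(sec)[-1L]) if (sec[i] != sec[i - 1L]) runs <- runs + 1L
  runs
}

# Patristic distances by breadth-first path summation over the edge list.
patristic_brute <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  out <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_real_, nn); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[u]]))) {
        v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
        if (is.na(dist[v])) { dist[v] <- dist[u] + w; queue <- c(queue, v) }
      }
    }
    out[s, ] <- dist[seq_len(ntip)]
  }
  out
}

# Relative-position matching by enumeration.
match_relative_brute <- function(ni, nj) {
  vapply(seq_len(ni), function(i) {
    best <- 1L
    for (j in seq_len(nj))
      if (abs(i / ni - j / nj) < abs(i / ni - best / nj)) best <- j
    best
  }, 1L)
}

# Variance of the K2P distance estimate (delta method, Kimura 1980).
k2p_variance <- function(P, Q, L) {
  c1 <- 1 / (1 - 2 * P - Q)
  c2 <- 1 / (1 - 2 * Q)
  c3 <- (c1 + c2) / 2
  (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / L
}
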