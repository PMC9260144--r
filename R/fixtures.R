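# Analytic fixtures with known ground truth, used as estimator oracles:
#   rod          D_A = 1, R_A -> L/sqrt(6) under fine subdivision
#   star5        N_I(r < L) = 5 from the center
#   elbow        single right-angle weave joint
#   plane_carpet D_A = 2 (dense boustrophedon sheet)
#   ball_soup    D_M = 3 (confined random walk at near-uniform density)
#   koch3d       similarity dimension log 4 / log 3 ~ 1.262
#   htree3d      balanced binary fork structure
#   geodesic_ball spherical spiral shell: mean projection / hull area -> 1/4

# Chain of nodes -> arbor (node 1 is the root).
chain_arbor <- function(points, radius = 0.5, label = "chain") {
  n <- nrow(points)
  segment_arbor(points, parent = c(NA, seq_len(n - 1)),
                radius = rep(radius, n), label = label, normalize = FALSE)
}

#' Deterministic oracle fixtures
#'
#' Constructs geometric fixtures whose fractal dimensions, radii, Sholl
#' curves or projection statistics have closed-form or designed values
#' (see the source and the methods vignette for each fixture's ground
#' truth).
#'
#' @param fixture One of `"rod"`, `"star5"`, `"elbow"`, `"plane_carpet"`,
#'   `"ball_soup"`, `"koch3d"`, `"htree3d"`, `"geodesic_ball"`.
#' @param ... Fixture parameters, see the individual generators in the
#'   source (`L`, `level`, `size`, `seed`, ...).
#' @return A `segment_arbor`.
#' @export
make_fixture <- function(fixture, ...) {
  switch(fixture,
    rod = fixture_rod(...),
    star5 = fixture_star5(...),
    elbow = fixture_elbow(...),
    plane_carpet = fixture_plane_carpet(...),
    ball_soup = fixture_ball_soup(...),
    koch3d = fixture_koch3d(...),
    htree3d = fixture_htree3d(...),
    geodesic_ball = fixture_geodesic_ball(...),
    stop("unknown fixture: ", fixture))
}

# Straight rod along z, unit segments, centered at the origin.
fixture_rod <- function(L = 300, n = L, radius = 0.5) {
  z <- seq(-L / 2, L / 2, length.out = n + 1)
  chain_arbor(cbind(0, 0, z), radius, "rod")
}

# Five coplanar rays of length L from a central root, unit segments.
fixture_star5 <- function(L = 100, radius = 0.5) {
  nodes <- matrix(0, 1, 3)
  parent <- NA_integer_
  for (k in 0:4) {
    dir <- c(cos(2 * pi * k / 5), sin(2 * pi * k / 5), 0)
    prev <- 1L
    for (s in seq_len(L)) {
      nodes <- rbind(nodes, dir * s)
      parent <- c(parent, prev)
      prev <- nrow(nodes)
    }
  }
  segment_arbor(nodes, parent, rep(radius, nrow(nodes)), label = "star5")
}

# Two segments meeting at a right angle.
fixture_elbow <- function(L = 10, radius = 0.5) {
  chain_arbor(rbind(c(0, 0, 0), c(L, 0, 0), c(L, L, 0)), radius, "elbow")
}

# Boustrophedon sheet in the z = 0 plane: rows 'spacing' apart, far
# denser than the 2 um fine-scale cutoff, so the patch box-counts as a
# solid plane (D_A = 2).
fixture_plane_carpet <- function(size = 100, spacing = 1, radius = 0.4) {
  rows <- seq(0, size, by = spacing)
  pts <- matrix(0, 0, 3)
  x <- c(0, size)
  for (i in seq_along(rows)) {
    xx <- if (i %% 2 == 1) x else rev(x)
    pts <- rbind(pts, cbind(xx, rows[i], 0))
  }
  chain_arbor(pts, radius, "plane_carpet")
}

# Confined random walk inside a ball: stationary density is near-uniform,
# so the cumulative mass grows as r^3 over the fitting window. The step
# density is chosen so the walker's own linear trace through each origin
# is a small fraction of the enclosed volume term at the finest fitted
# radius.
fixture_ball_soup <- function(R = 56, step = 3, density = 0.8, seed = 42,
                              radius = 0.3) {
  n_steps <- ceiling(density * (4 / 3) * pi * R^3 / step)
  pts <- with_seed(seed, {
    out <- matrix(0, n_steps + 1, 3)
    dirs <- matrix(stats::rnorm(3 * n_steps), n_steps, 3)
    dirs <- dirs / row_norms(dirs)
    # start at a uniform point in the ball (no centered transient)
    cur <- stats::rnorm(3)
    cur <- cur / sqrt(sum(cur^2)) * R * stats::runif(1)^(1 / 3)
    out[1, ] <- cur
    for (i in seq_len(n_steps)) {
      cand <- cur + step * dirs[i, ]
      while (sum(cand^2) > R^2) {
        d <- stats::rnorm(3)
        cand <- cur + step * d / sqrt(sum(d^2))
      }
      cur <- cand
      out[i + 1, ] <- cur
    }
    out
  })
  chain_arbor(pts, radius, "ball_soup")
}

# Koch-like curve embedded in 3D: each segment is replaced by four of a
# third the length; the bump plane is twisted about the segment axis by a
# fixed angle per recursion to leave the plane. Similarity dimension
# log(4)/log(3) by construction.
fixture_koch3d <- function(level = 5, span = 300, twist = 0.3, radius = 0.3) {
  pts <- rbind(c(0, 0, 0), c(span, 0, 0))
  up <- c(0, 0, 1)
  for (lev in seq_len(level)) {
    new <- matrix(0, 0, 3)
    for (s in seq_len(nrow(pts) - 1)) {
      A <- pts[s, ]; B <- pts[s + 1, ]
      u <- B - A
      nrm <- unit3(pracma_cross(u, if (abs(sum(unit3(u) * up)) > 0.99)
        c(1, 0, 0) else up))
      nrm <- as.vector(rotation_matrix(u, twist * s) %*% nrm)
      peak <- A + u / 2 + nrm * sqrt(sum(u * u)) * sqrt(3) / 6
      new <- rbind(new, A, A + u / 3, peak, A + 2 * u / 3)
    }
    pts <- rbind(new, pts[nrow(pts), ])
  }
  chain_arbor(pts, radius, "koch3d")
}

# Balanced binary tree: each branch forks into two perpendicular
# daughters scaled by 1/sqrt(2), alternating split planes.
fixture_htree3d <- function(levels = 6, L0 = 80, radius = 0.5) {
  nodes <- matrix(0, 1, 3)
  parent <- NA_integer_
  grow <- function(at, parent_idx, dir, side, L, lev) {
    tip <- at + dir * L
    nodes <<- rbind(nodes, tip)
    parent <<- c(parent, parent_idx)
    idx <- nrow(nodes)
    if (lev >= levels) return(invisible())
    d1 <- unit3(pracma_cross(dir, side))
    grow(tip, idx, d1, dir, L / sqrt(2), lev + 1)
    grow(tip, idx, -d1, dir, L / sqrt(2), lev + 1)
  }
  grow(c(0, 0, 0), 1L, c(0, 0, 1), c(1, 0, 0), L0, 1)
  segment_arbor(nodes, parent, rep(radius, nrow(nodes)), label = "htree3d")
}

# Spherical spiral shell: a chain winding from pole to pole with constant
# turn spacing; with tube width >= turn spacing its projection from any
# direction is a solid disk, so mean projection / hull area approaches
# the convex-body value 1/4 (Cauchy's theorem).
fixture_geodesic_ball <- function(R = 50, turn_spacing = 1.6, seg_len = 2,
                                  width = 2) {
  N <- pi * R / turn_spacing      # number of turns
  pts <- matrix(0, 0, 3)
  t <- 0
  while (t < 1) {
    th <- pi * t; ph <- 2 * pi * N * t
    pts <- rbind(pts, R * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
    speed <- R * sqrt(pi^2 + (sin(th) * 2 * pi * N)^2)
    t <- t + seg_len / speed
  }
  pts <- rbind(pts, c(0, 0, -R))
  chain_arbor(pts, width / 2, "geodesic_ball")
}
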