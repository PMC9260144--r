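# Modified multi-origin 3D Sholl analysis and cumulative-mass analysis.
# Intersections are counted and lengths clipped against segment
# centerlines analytically (no rasterization): for each segment the
# squared distance to the origin is a quadratic in the arc parameter, so
# sphere crossings and in-ball sub-intervals have closed forms.

# Per-segment geometry relative to an origin: distances of both endpoints
# and the closest approach within the segment interval.
segment_origin_geometry <- function(st, origin, keep = st$dendritic) {
  A <- st$start[keep, , drop = FALSE]
  Bm <- st$end[keep, , drop = FALSE]
  u <- Bm - A
  ao <- sweep(A, 2, origin)
  c2 <- rowSums(u * u)                   # |u|^2 = segment length^2
  c1 <- 2 * rowSums(ao * u)
  c0 <- rowSums(ao * ao)
  d0 <- sqrt(c0)
  d1 <- sqrt(c0 + c1 + c2)
  tmin <- pmin(1, pmax(0, -c1 / (2 * c2)))
  dmin <- sqrt(pmax(0, c0 + c1 * tmin + c2 * tmin^2))
  list(c0 = c0, c1 = c1, c2 = c2, d0 = d0, d1 = d1, dmin = dmin,
       len = sqrt(c2))
}

#' Sholl intersection counts from one origin
#'
#' Counts crossings of segment centerlines with the spheres of the given
#' radii centered at `origin`: each segment contributes 0, 1 or 2
#' crossings per sphere, computed exactly from the line-sphere quadratic
#' restricted to the segment.
#'
#' @param arbor A `segment_arbor`.
#' @param origin 3-vector (um).
#' @param radii Positive radii grid (um).
#' @return Integer vector `N_I` per radius.
#' @export
sholl_counts <- function(arbor, origin, radii) {
  stopifnot(all(radii > 0))
  g <- segment_origin_geometry(segment_table(arbor), origin)
  lo <- pmin(g$d0, g$d1); hi <- pmax(g$d0, g$d1)
  vapply(radii, function(r)
    sum(lo < r & hi >= r) + 2L * sum(lo >= r & g$dmin < r),
    numeric(1))
}

#' Dendritic length inside concentric spheres
#'
#' Exact analytic clipping: each segment contributes the length of its
#' sub-interval inside the ball of radius r around `origin`.
#'
#' @inheritParams sholl_counts
#' @return Numeric vector `L_in` per radius (um); nondecreasing, bounded
#'   by the total dendritic length.
#' @export
mass_in_sphere <- function(arbor, origin, radii) {
  stopifnot(all(radii > 0))
  g <- segment_origin_geometry(segment_table(arbor), origin)
  vapply(radii, function(r) clipped_length(g, r), numeric(1))
}

# Total clipped length for one radius given precomputed quadratics.
clipped_length <- function(g, r) {
  disc <- g$c1^2 - 4 * g$c2 * (g$c0 - r^2)
  s <- sqrt(pmax(0, disc))
  tlo <- pmax(0, (-g$c1 - s) / (2 * g$c2))
  thi <- pmin(1, (-g$c1 + s) / (2 * g$c2))
  sum(ifelse(disc > 0, pmax(0, thi - tlo), 0) * g$len)
}

#' Sample Sholl origins on the arbor near its center of mass
#'
#' Origins are drawn uniformly by arc length along the part of the
#' dendritic centerline lying within `R_A/2` of the length-weighted center
#' of mass, so that spheres mostly stay inside the arbor.
#'
#' @param arbor A `segment_arbor`.
#' @param n Number of origins.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @return An `n x 3` matrix of origin points (um).
#' @export
sample_origins <- function(arbor, n = 25, seed = 1) {
  stopifnot(n >= 1)
  st <- segment_table(arbor)
  com <- center_of_mass(arbor)
  RA <- arbor_radius(arbor)
  g <- segment_origin_geometry(st, com)
  r <- RA / 2
  disc <- g$c1^2 - 4 * g$c2 * (g$c0 - r^2)
  s <- sqrt(pmax(0, disc))
  tlo <- pmax(0, (-g$c1 - s) / (2 * g$c2))
  thi <- pmin(1, (-g$c1 + s) / (2 * g$c2))
  inlen <- ifelse(disc > 0, pmax(0, thi - tlo), 0) * g$len
  total <- sum(inlen)
  if (total <= 0)
    stop(sprintf(paste0("no dendritic length within R_A/2 = %.2f um of the ",
                        "center of mass (%.1f, %.1f, %.1f)"),
                 r, com[1], com[2], com[3]))
  keep <- which(st$dendritic)
  cum <- cumsum(inlen)
  u <- with_seed(seed, stats::runif(n)) * total
  seg <- findInterval(u, cum, left.open = TRUE) + 1L
  frac <- (u - c(0, cum)[seg]) / inlen[seg]
  tt <- tlo[seg] + frac * (thi[seg] - tlo[seg])
  rows <- keep[seg]
  st$start[rows, , drop = FALSE] +
    tt * (st$end[rows, , drop = FALSE] - st$start[rows, , drop = FALSE])
}

#' Multi-origin Sholl and cumulative-mass profile
#'
#' Computes intersection counts N_I(r) and in-sphere lengths L_in(r) on a
#' common radius grid for each of `n_origins` origins sampled near the
#' center of mass, with mean and standard-error curves across origins.
#'
#' @param arbor A `segment_arbor`.
#' @param n_origins Number of origins (25 by default).
#' @param seed Integer seed for origin sampling.
#' @param radii Optional radius grid (um); default `seq(r_step, 2*R_A,
#'   r_step)`.
#' @param r_step Grid step when `radii` is not given (um).
#' @param origins Optional explicit `m x 3` origin matrix overriding
#'   sampling (e.g. a single soma-centered origin).
#' @return A `sholl_profile`: list with `radii`, matrices `N_I` and `L_in`
#'   (origins x radii), `mean_NI`, `se_NI`, `mean_Lin`, `se_Lin`,
#'   `origins`, `seed`, `L_T`, `R_A` and `extent`.
#' @export
sholl_profile <- function(arbor, n_origins = 25, seed = 1, radii = NULL,
                          r_step = 2, origins = NULL) {
  RA <- arbor_radius(arbor)
  if (is.null(radii)) radii <- seq(r_step, 2 * RA, by = r_step)
  if (is.null(origins)) origins <- sample_origins(arbor, n_origins, seed)
  origins <- matrix(origins, ncol = 3)
  m <- nrow(origins)
  st <- segment_table(arbor)
  NI <- matrix(0, m, length(radii))
  LIN <- matrix(0, m, length(radii))
  for (i in seq_len(m)) {
    g <- segment_origin_geometry(st, origins[i, ])
    lo <- pmin(g$d0, g$d1); hi <- pmax(g$d0, g$d1)
    for (j in seq_along(radii)) {
      r <- radii[j]
      NI[i, j] <- sum(lo < r & hi >= r) + 2 * sum(lo >= r & g$dmin < r)
      LIN[i, j] <- clipped_length(g, r)
    }
  }
  se <- function(M) if (m > 1) apply(M, 2, stats::sd) / sqrt(m) else
    rep(0, ncol(M))
  structure(list(radii = radii, N_I = NI, L_in = LIN,
                 mean_NI = colMeans(NI), se_NI = se(NI),
                 mean_Lin = colMeans(LIN), se_Lin = se(LIN),
                 origins = origins, seed = seed,
                 L_T = sum(st$length[st$dendritic]), R_A = RA,
                 extent = arbor_extent(arbor)),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf(paste0("<sholl_profile> %d origins, r in [%.1f, %.1f] um; ",
                     "peak mean N_I = %.1f at r = %.1f um\n"),
              nrow(x$origins), min(x$radii), max(x$radii),
              max(x$mean_NI), x$radii[which.max(x$mean_NI)]))
  invisible(x)
}

#' Mass fractal dimension from a cumulative-mass profile
#'
#' Fits `log10 L_in` against `log10 r` over the scaling range used by the
#' box-counting analysis: radii strictly above `fine` and at most
#' `extent/5`, over the max-R^2 contiguous window spanning at least one
#' order of magnitude. The slope is the mass dimension D_M.
#'
#' @param profile A `sholl_profile`.
#' @param extent Largest arbor extent (um); defaults to the profile's.
#' @param fine Fine-scale cutoff (um, default 2).
#' @return A `scaling_fit` whose `slope` is D_M.
#' @export
fit_mass_dimension <- function(profile, extent = profile$extent, fine = 2) {
  sel <- profile$radii > fine & profile$radii <= extent / 5 &
    profile$mean_Lin > 0
  if (sum(sel) < 3)
    stop(sprintf(paste0("no admissible fit range: need radii in (%.3g, %.3g] ",
                        "but only %d grid points qualify"),
                 fine, extent / 5, sum(sel)))
  fit_scaling_window(profile$radii[sel], profile$mean_Lin[sel])
}

#' @describeIn sholl_profile Flatten to a per-radius data.frame with
#'   columns `r`, `mean_N_I`, `se_N_I`, `mean_L_in`, `se_L_in` (ready
#'   for `write.csv`).
#' @param x A `sholl_profile`.
#' @param ... Unused.
#' @export
as.data.frame.sholl_profile <- function(x, ...) {
  data.frame(r = x$radii, mean_N_I = x$mean_NI, se_N_I = x$se_NI,
             mean_L_in = x$mean_Lin, se_L_in = x$se_Lin)
}
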