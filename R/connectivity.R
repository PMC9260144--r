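# Connectivity C and material cost M.
# C: orientation-averaged area of the arbor's dilated planar projection,
# normalized by convex-hull surface area. Views are Fibonacci-lattice
# directions on a hemisphere (projection area is antipodally symmetric).
# The projection is rasterized: a pixel is covered when its center lies
# within the locally dilated capsule radius of a centerline sample point.
# M: summed conical-frustum tube volume normalized by hull volume.

#' Orientation-averaged dilated projection area
#'
#' For each view direction, projects the dendritic centerline onto the
#' orthogonal plane, thickens it to the locally projected tube width plus
#' a dilation allowance (the spatial reach of spines), and measures the
#' covered area on a pixel raster. Returns the mean over views.
#'
#' @param arbor A `segment_arbor`.
#' @param n_views Number of view directions (Fibonacci hemisphere).
#' @param pixel Raster pixel size (um).
#' @param dilation Width dilation (um). With `dilation_mode = "width"`
#'   (default) the projected width grows by `dilation` in total (+1 um per
#'   side for the default 2 um); `"radius"` adds `dilation` per side.
#' @return Mean projected area (um^2) with attribute `per_view` (areas for
#'   each view).
#' @export
projection_area <- function(arbor, n_views = 64, pixel = 0.5, dilation = 2,
                            dilation_mode = c("width", "radius")) {
  dilation_mode <- match.arg(dilation_mode)
  stopifnot(n_views >= 1, pixel > 0, dilation >= 0)
  cl <- resample_centerline(arbor, spacing = pixel / 2)
  pts <- cl$points
  rad <- (cl$width + switch(dilation_mode, width = dilation,
                            radius = 2 * dilation)) / 2
  views <- fibonacci_hemisphere(n_views)
  areas <- vapply(seq_len(n_views), function(v) {
    B <- orthonormal_basis(views[v, ])
    raster_cover_area(pts %*% B, rad, pixel)
  }, numeric(1))
  structure(mean(areas), per_view = areas)
}

# Count pixels whose center is within rad[i] of sample point i, times
# pixel^2. Exact point-in-capsule test per candidate offset; unbiased for
# strip width on average over sub-pixel phase.
raster_cover_area <- function(xy, rad, pixel) {
  ix <- floor(xy[, 1] / pixel); iy <- floor(xy[, 2] / pixel)
  fx <- xy[, 1] / pixel - ix; fy <- xy[, 2] / pixel - iy
  rmax <- max(rad) / pixel
  span <- ceiling(rmax + 1)
  keys <- vector("list", (2 * span + 1)^2)
  k <- 0L
  Mx <- diff(range(iy)) + 2 * span + 10   # > any (iy + oy) spread: unique keys
  r2 <- (rad / pixel)^2
  for (ox in -span:span) {
    dx2 <- (ox + 0.5 - fx)^2
    for (oy in -span:span) {
      # quick reject: offset cell cannot be reached by any radius
      if ((max(abs(ox) - 1, 0))^2 + (max(abs(oy) - 1, 0))^2 > rmax^2) next
      hit <- dx2 + (oy + 0.5 - fy)^2 <= r2
      if (!any(hit)) next
      k <- k + 1L
      keys[[k]] <- (ix[hit] + ox) * Mx + (iy[hit] + oy)
    }
  }
  n_cells <- length(unique(unlist(keys[seq_len(k)], use.names = FALSE)))
  n_cells * pixel^2
}

#' Connectivity functional C
#'
#' The orientation-averaged dilated projection area divided by the
#' convex-hull surface area of the arbor: a dimensionless proxy for the
#' arbor's capacity to intercept passing axons, independent of absolute
#' size.
#'
#' @inheritParams projection_area
#' @return C (dimensionless), with attribute `per_view`.
#' @export
connectivity <- function(arbor, n_views = 64, pixel = 0.5, dilation = 2,
                         dilation_mode = "width") {
  hull <- convex_hull_metrics(arbor)
  if (attr(hull, "degenerate") || hull[["hull_area"]] <= 0)
    stop("degenerate convex hull: connectivity undefined")
  a <- projection_area(arbor, n_views, pixel, dilation, dilation_mode)
  structure(as.numeric(a) / hull[["hull_area"]], per_view = attr(a, "per_view"))
}

#' Material cost M
#'
#' Total tube volume of the dendritic segments, modeled as conical
#' frustums \eqn{V_i = (\pi/3)\,\delta l_i (r_0^2 + r_0 r_1 + r_1^2)},
#' normalized by the arbor's convex-hull volume.
#'
#' @param arbor A `segment_arbor`.
#' @return M (dimensionless).
#' @export
material_cost <- function(arbor) {
  hull <- convex_hull_metrics(arbor)
  if (attr(hull, "degenerate") || hull[["hull_volume"]] <= 0)
    stop("degenerate convex hull: material cost undefined")
  tube_volume(arbor) / hull[["hull_volume"]]
}

#' Total frustum tube volume of an arbor (um^3)
#' @param arbor A `segment_arbor`.
#' @export
tube_volume <- function(arbor) {
  st <- segment_table(arbor)
  keep <- st$dendritic
  sum((pi / 3) * st$length[keep] *
        (st$r0[keep]^2 + st$r0[keep] * st$r1[keep] + st$r1[keep]^2))
}

#' Connectivity-cost point for one arbor
#'
#' Computes the (D_A, C, M) triple used by the optimization analysis.
#'
#' @param arbor A `segment_arbor`.
#' @param alpha Angle-scaling factor of the arbor (1 for natural).
#' @param group,category Group bookkeeping labels.
#' @param n_views,pixel,dilation Passed to [connectivity()].
#' @return One-row data.frame: `label`, `group`, `category`, `alpha`,
#'   `D_A`, `C`, `M`.
#' @export
cm_point <- function(arbor, alpha = 1, group = NA_character_,
                     category = NA_character_, n_views = 64, pixel = 0.5,
                     dilation = 2) {
  bc <- fit_box_dimension(arbor)
  data.frame(label = arbor$label, group = group, category = category,
             alpha = alpha, D_A = bc$D_A,
             C = as.numeric(connectivity(arbor, n_views, pixel, dilation)),
             M = material_cost(arbor), row.names = NULL)
}
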