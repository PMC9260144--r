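# 3D convex hull via incremental insertion (quickhull-style visibility).
# Self-contained because no computational-geometry package is available;
# validated in the test suite against closed-form solids and frozen
# reference values for random clouds.

#' 3D convex hull of a point cloud
#'
#' Incremental convex hull returning triangular facets, total surface area
#' and enclosed volume. Degenerate inputs (collinear or coplanar points)
#' return zero volume with a `degenerate` flag; for planar clouds, the area
#' of the planar 2D hull polygon is reported.
#'
#' @param points An `n x 3` numeric matrix.
#' @return A list with `faces` (`m x 3` vertex indices into `points`,
#'   outward-oriented), `area` (um^2), `volume` (um^3) and `degenerate`.
#' @export
convex_hull_3d <- function(points) {
  P <- unique(as.matrix(points))
  storage.mode(P) <- "double"
  n <- nrow(P)
  if (n < 3) return(hull_degenerate(P))
  diam <- max(apply(P, 2, function(v) diff(range(v))))
  if (diam == 0) return(hull_degenerate(P))
  eps <- 1e-9 * diam

  # --- initial non-degenerate tetrahedron --------------------------------
  i1 <- which.max(P[, 1]); i2 <- which.min(P[, 1])
  if (i1 == i2) { i1 <- which.max(P[, 2]); i2 <- which.min(P[, 2]) }
  if (i1 == i2) { i1 <- which.max(P[, 3]); i2 <- which.min(P[, 3]) }
  d12 <- P[i2, ] - P[i1, ]
  # farthest from the line i1-i2
  ap <- sweep(P, 2, P[i1, ])
  t <- (ap %*% d12) / sum(d12 * d12)
  perp <- ap - t %*% t(d12)
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) < eps) return(hull_degenerate(P))
  nrm <- pracma_cross(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  h <- ap %*% nrm / sqrt(sum(nrm^2))
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < eps) return(hull_planar(P))

  verts <- c(i1, i2, i3, i4)
  interior <- colMeans(P[verts, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, P = P, interior = interior))

  # --- incremental insertion ---------------------------------------------
  fn <- face_normals(P, faces)
  for (p in setdiff(seq_len(n), verts)) {
    s <- fn$normals %*% P[p, ] - fn$offsets
    vis <- which(s > eps)
    if (!length(vis)) next
    # horizon = edges of visible faces not shared by two visible faces
    ed <- faces[vis, , drop = FALSE]
    edges <- rbind(ed[, c(1, 2)], ed[, c(2, 3)], ed[, c(1, 3)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[-vis, , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient_face, P = P, interior = interior))
    faces <- rbind(faces, newf)
    fn <- face_normals(P, faces)
  }

  a <- sum(face_areas(P, faces))
  v <- hull_volume_from_faces(P, faces, interior)
  list(faces = faces, area = a, volume = v, degenerate = FALSE)
}

hull_degenerate <- function(P) {
  list(faces = NULL, area = 0, volume = 0, degenerate = TRUE)
}

# Planar cloud: area of the 2D hull polygon in its own plane, volume 0.
hull_planar <- function(P) {
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  sv <- svd(X, nu = 0, nv = 2)
  uv <- X %*% sv$v
  ch <- grDevices::chull(uv[, 1], uv[, 2])
  poly <- uv[ch, , drop = FALSE]
  m <- nrow(poly)
  j <- c(2:m, 1)
  area <- abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
  list(faces = NULL, area = area, volume = 0, degenerate = TRUE)
}

orient_face <- function(f, P, interior) {
  nrm <- pracma_cross(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
  if (sum(nrm * (interior - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

face_normals <- function(P, faces) {
  a <- P[faces[, 1], , drop = FALSE]
  nrm <- cross_rows(P[faces[, 2], , drop = FALSE] - a,
                    P[faces[, 3], , drop = FALSE] - a)
  len <- row_norms(nrm)
  nrm <- nrm / len
  list(normals = nrm, offsets = rowSums(nrm * a))
}

cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

face_areas <- function(P, faces) {
  a <- P[faces[, 1], , drop = FALSE]
  row_norms(cross_rows(P[faces[, 2], , drop = FALSE] - a,
                       P[faces[, 3], , drop = FALSE] - a)) / 2
}

hull_volume_from_faces <- function(P, faces, interior) {
  a <- sweep(P[faces[, 1], , drop = FALSE], 2, interior)
  b <- sweep(P[faces[, 2], , drop = FALSE], 2, interior)
  c_ <- sweep(P[faces[, 3], , drop = FALSE], 2, interior)
  abs(sum(rowSums(cross_rows(a, b) * c_))) / 6
}

#' Convex-hull surface area and volume of an arbor
#'
#' The hull is built over all node coordinates (segment start and end
#' points); tube widths (~1.4 um) are negligible at hull scale (~100 um).
#'
#' @param arbor A `segment_arbor` or an `n x 3` point matrix.
#' @return Named numeric vector `c(hull_area, hull_volume)` (um^2, um^3),
#'   with attribute `degenerate` set `TRUE` for coplanar/collinear input.
#' @export
convex_hull_metrics <- function(arbor) {
  p <- if (inherits(arbor, "segment_arbor")) arbor$nodes else as.matrix(arbor)
  h <- convex_hull_3d(p)
  structure(c(hull_area = h$area, hull_volume = h$volume),
            degenerate = h$degenerate)
}
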