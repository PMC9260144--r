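# Angle-scaling distortion: multiplies every fork and weave angle in an
# arbor by a factor alpha while preserving all segment lengths and each
# joint's dihedral orientation. At each joint the downstream subtree is
# rotated rigidly about the normal of the plane spanned by the incoming
# and outgoing directions; applied in pre-order, this makes the
# re-measured angle at every joint exactly alpha times the original.

#' Distort an arbor by scaling all fork and weave angles
#'
#' @param arbor A `segment_arbor`.
#' @param alpha Positive angle-scaling factor. Values outside `[0.5, 2]`
#'   are accepted with a warning (they produce heavy branch overlap or
#'   tortuosity).
#' @return A `segment_arbor` with identical topology, radii and segment
#'   lengths, and every joint angle scaled to `alpha * theta` (clamped at
#'   pi; the number of clamped joints is in attribute `n_clamped`).
#' @export
distort_arbor <- function(arbor, alpha) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (alpha < 0.5 || alpha > 2)
    warning(sprintf("alpha = %.3g outside the physically motivated [0.5, 2]",
                    alpha))
  n <- nrow(arbor$nodes)
  if (n < 2) return(arbor)
  newpos <- arbor$nodes
  rot <- vector("list", n)          # accumulated rotation at each node
  rot[[1]] <- diag(3)
  n_clamped <- 0L
  for (i in 2:n) {                  # pre-order: parent already placed
    p <- arbor$parent[i]
    u <- arbor$nodes[i, ] - arbor$nodes[p, ]
    gp <- arbor$parent[p]
    if (is.na(gp)) {                # segment emanating from the root:
      rot[[i]] <- rot[[p]]          # no incoming direction, keep heading
      newpos[i, ] <- newpos[p, ] + rot[[i]] %*% u
      next
    }
    v <- arbor$nodes[p, ] - arbor$nodes[gp, ]     # incoming (original)
    Rp <- rot[[p]]
    vv <- as.vector(Rp %*% v)
    uu <- as.vector(Rp %*% u)
    theta <- vec_angle(vv, uu)
    axis <- pracma_cross(vv, uu)
    if (theta < 1e-12 || sqrt(sum(axis^2)) < 1e-12 * sqrt(sum(vv^2) * sum(uu^2))) {
      Q <- diag(3)                  # collinear: axis undefined, angle stays 0
    } else {
      target <- alpha * theta
      if (target > pi) { target <- pi; n_clamped <- n_clamped + 1L }
      Q <- rotation_matrix(axis, target - theta)
    }
    rot[[i]] <- Q %*% Rp
    newpos[i, ] <- newpos[p, ] + rot[[i]] %*% u
  }
  out <- arbor
  out$nodes <- newpos
  out$label <- sprintf("%s_alpha%.3g", arbor$label, alpha)
  structure(out, n_clamped = n_clamped)
}

#' Default angle-scaling sweep grid
#'
#' alpha from 0.5 to 2 in steps of 0.25, excluding the identity alpha = 1.
#' @export
default_alpha_grid <- function() setdiff(seq(0.5, 2, by = 0.25), 1)

#' Distort a set of arbors over an alpha grid
#'
#' Produces one distorted arbor per (arbor, alpha) pair with `alpha != 1`,
#' plus a manifest of the sweep.
#'
#' @param arbors List of `segment_arbor` objects.
#' @param grid Numeric alpha grid; the identity value 1 is dropped.
#' @return A list with `arbors` (the distorted arbors) and `manifest`
#'   (data.frame: `arbor`, `alpha`, `label`, `n_clamped`).
#' @export
distortion_sweep <- function(arbors, grid = default_alpha_grid()) {
  if (!length(arbors)) stop("no input arbors")
  grid <- grid[grid != 1]
  out <- vector("list", length(arbors) * length(grid))
  rows <- vector("list", length(out))
  k <- 0L
  for (a in seq_along(arbors)) {
    for (al in grid) {
      k <- k + 1L
      d <- distort_arbor(arbors[[a]], al)
      out[[k]] <- d
      rows[[k]] <- data.frame(arbor = a, alpha = al, label = d$label,
                              n_clamped = attr(d, "n_clamped"))
    }
  }
  manifest <- if (k) do.call(rbind, rows)
              else data.frame(arbor = integer(0), alpha = numeric(0),
                              label = character(0), n_clamped = integer(0))
  list(arbors = out, manifest = manifest)
}

#' Count self-overlapping segment pairs
#'
#' Counts pairs of non-adjacent segments (sharing no node) whose
#' centerline distance is smaller than the sum of their local radii, i.e.
#' whose tubes interpenetrate. Used to diagnose non-physical geometry
#' produced by extreme angle scaling.
#'
#' @param arbor A `segment_arbor`.
#' @return Integer overlap count, with attribute `pairs` (matrix of
#'   offending segment index pairs).
#' @export
self_overlap_check <- function(arbor) {
  st <- segment_table(arbor)
  K <- length(st$length)
  if (K < 2) return(structure(0L, pairs = NULL))
  rad <- pmax(st$r0, st$r1)
  # coarse prune on midpoint distance
  limit <- outer(st$length / 2 + rad, st$length / 2 + rad, `+`)
  md2 <- as.matrix(stats::dist(st$mid))^2
  cand <- which(upper.tri(md2) & md2 < limit^2, arr.ind = TRUE)
  if (!nrow(cand)) return(structure(0L, pairs = NULL))
  # drop adjacent pairs (sharing a node)
  shares <- st$node[cand[, 1]] == st$node[cand[, 2]] |
    st$node[cand[, 1]] == st$parent_node[cand[, 2]] |
    st$parent_node[cand[, 1]] == st$node[cand[, 2]] |
    st$parent_node[cand[, 1]] == st$parent_node[cand[, 2]]
  cand <- cand[!shares, , drop = FALSE]
  if (!nrow(cand)) return(structure(0L, pairs = NULL))
  d <- segseg_distance(st$start[cand[, 1], , drop = FALSE],
                       st$end[cand[, 1], , drop = FALSE],
                       st$start[cand[, 2], , drop = FALSE],
                       st$end[cand[, 2], , drop = FALSE])
  hit <- d < rad[cand[, 1]] + rad[cand[, 2]]
  structure(sum(hit), pairs = cand[hit, , drop = FALSE])
}

# Vectorized minimum distance between segment pairs (P1->Q1 vs P2->Q2).
segseg_distance <- function(P1, Q1, P2, Q2) {
  d1 <- Q1 - P1; d2 <- Q2 - P2; r <- P1 - P2
  a <- rowSums(d1 * d1); e <- rowSums(d2 * d2); f <- rowSums(d2 * r)
  cc <- rowSums(d1 * r); b <- rowSums(d1 * d2)
  den <- a * e - b * b
  s <- ifelse(den > 1e-12 * a * e, (b * f - cc * e) / den, 0)
  s <- pmin(1, pmax(0, s))
  t <- ifelse(e > 0, (b * s + f) / e, 0)
  # clamp t then recompute s for the clamped t
  tcl <- pmin(1, pmax(0, t))
  s2 <- ifelse(a > 0, (b * tcl - cc) / a, 0)
  s2 <- pmin(1, pmax(0, s2))
  w <- P1 + s2 * d1 - (P2 + tcl * d2)
  sqrt(rowSums(w * w))
}
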