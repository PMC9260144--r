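#' Segment-based arbor model
#'
#' A `segment_arbor` is a rooted tree of 3D conical-frustum segments: the
#' universal substrate of all analyses in this package. Nodes carry a 3D
#' position (micrometres) and a radius; every non-root node defines one
#' segment from its parent. Node 1 is always the root and node order is
#' pre-order, so a parent always precedes its children.
#'
#' @param nodes Numeric `n x 3` matrix of positions (um).
#' @param parent Integer vector of parent node indices; `NA` for the root.
#' @param radius Numeric vector of node radii (um, >= 0).
#' @param type Optional integer vector of SWC structure types (1 = soma).
#'   Segments whose two endpoints are both soma-typed are excluded from all
#'   dendritic metrics.
#' @param label Free-text identifier (e.g. neuron/group id).
#' @param normalize If `TRUE` (default) reorder nodes to pre-order and merge
#'   duplicate (zero-length) points with a warning.
#' @return An object of class `segment_arbor`.
#' @export
segment_arbor <- function(nodes, parent, radius, type = NULL, label = "",
                          normalize = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3) stop("nodes must be an n x 3 matrix")
  n <- nrow(nodes)
  parent <- as.integer(parent)
  parent[!is.na(parent) & parent < 1] <- NA_integer_
  radius <- as.double(radius)
  if (length(parent) != n || length(radius) != n)
    stop("nodes, parent and radius lengths disagree")
  if (is.null(type)) type <- rep(3L, n) else type <- as.integer(type)
  if (!all(is.finite(nodes))) stop("non-finite node coordinates")
  if (!all(is.finite(radius)) || any(radius < 0))
    stop("radii must be finite and >= 0")

  roots <- which(is.na(parent))
  if (length(roots) != 1)
    stop("arbor must have exactly one root; found roots at nodes: ",
         paste(roots, collapse = ", "))
  bad <- which(!is.na(parent) & (parent > n))
  if (length(bad)) stop("parent index out of range at nodes: ",
                        paste(bad, collapse = ", "))

  a <- structure(list(nodes = nodes, parent = parent, radius = radius,
                      type = type, label = as.character(label)[1]),
                 class = "segment_arbor")
  if (normalize) a <- normalize_arbor(a) else validate_arbor(a)
  a
}

# Checks tree property (single root, no cycles, all reachable).
validate_arbor <- function(a) {
  n <- nrow(a$nodes)
  root <- which(is.na(a$parent))
  # walk to root from every node, bounded by n steps -> cycle detection
  depth <- rep.int(NA_integer_, n)
  depth[root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    path <- i
    j <- i
    repeat {
      j <- a$parent[j]
      if (is.na(j)) break
      if (!is.na(depth[j])) { path_depth <- depth[j]; break }
      if (length(path) > n) stop("cycle detected in parent links")
      path <- c(path, j)
    }
    if (is.na(j)) path_depth <- 0L
    depth[rev(path)] <- path_depth + seq_along(path)
  }
  if (anyNA(depth)) stop("orphan nodes unreachable from root")
  invisible(a)
}

# Reorder to pre-order (root first), merging duplicated points.
normalize_arbor <- function(a) {
  validate_arbor(a)
  n <- nrow(a$nodes)
  root <- which(is.na(a$parent))

  # merge zero-length segments: child coincides with its parent
  merged <- 0L
  repeat {
    if (nrow(a$nodes) == 1) break
    d <- a$nodes - a$nodes[ifelse(is.na(a$parent), 1L, a$parent), , drop = FALSE]
    len <- row_norms(d)
    dup <- which(!is.na(a$parent) & len < 1e-9)
    if (!length(dup)) break
    merged <- merged + 1L
    drop <- dup[1]
    keep <- setdiff(seq_len(nrow(a$nodes)), drop)
    remap <- integer(nrow(a$nodes)); remap[keep] <- seq_along(keep)
    newpar <- a$parent
    newpar[newpar == drop & !is.na(newpar)] <- a$parent[drop]
    newpar <- newpar[keep]
    newpar[!is.na(newpar)] <- remap[newpar[!is.na(newpar)]]
    a$nodes <- a$nodes[keep, , drop = FALSE]
    a$radius <- a$radius[keep]
    a$type <- a$type[keep]
    a$parent <- newpar
  }
  if (merged)
    warning(sprintf("merged %d zero-length segment(s) (duplicated points)",
                    merged))

  n <- nrow(a$nodes)
  root <- which(is.na(a$parent))
  kids <- split(seq_len(n)[-root], a$parent[-root])
  order_out <- integer(n)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order_out[k] <- v
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, rev(sort(ch))) # visit in ascending order
  }
  remap <- integer(n); remap[order_out] <- seq_len(n)
  a$nodes <- a$nodes[order_out, , drop = FALSE]
  a$radius <- a$radius[order_out]
  a$type <- a$type[order_out]
  p <- a$parent[order_out]
  p[!is.na(p)] <- remap[p[!is.na(p)]]
  a$parent <- p
  a
}

#' @export
print.segment_arbor <- function(x, ...) {
  if (nrow(x$nodes) < 2) {
    cat(sprintf("<segment_arbor> '%s': single node, no segments\n", x$label))
    return(invisible(x))
  }
  st <- segment_table(x)
  cat(sprintf("<segment_arbor> '%s': %d nodes, %d segments (%d dendritic)\n",
              x$label, nrow(x$nodes), nrow(x$nodes) - 1L, sum(st$dendritic)))
  cat(sprintf("  total dendritic length %.1f um, extent %.1f um\n",
              sum(st$length[st$dendritic]), arbor_extent(x)))
  invisible(x)
}

#' Per-segment geometry table
#'
#' Expands an arbor into its segments. Row `i` describes the segment ending
#' at node `i + 1` (nodes are pre-order, node 1 is the root).
#'
#' @param arbor A `segment_arbor`.
#' @return A list with matrices `start`, `end`, `mid` (`K x 3`), vectors
#'   `r0`, `r1` (endpoint radii), `length`, `node` (child node index),
#'   `parent_node`, and logical `dendritic` (FALSE only for soma-soma
#'   segments).
#' @export
segment_table <- function(arbor) {
  n <- nrow(arbor$nodes)
  if (n < 2) stop("arbor has no segments")
  child <- 2:n
  par <- arbor$parent[child]
  start <- arbor$nodes[par, , drop = FALSE]
  end <- arbor$nodes[child, , drop = FALSE]
  len <- row_norms(end - start)
  list(start = start, end = end, mid = (start + end) / 2,
       r0 = arbor$radius[par], r1 = arbor$radius[child],
       length = len, node = child, parent_node = par,
       dendritic = !(arbor$type[par] == 1L & arbor$type[child] == 1L))
}

# Number of children of each node.
n_children <- function(arbor) {
  tabulate(arbor$parent[!is.na(arbor$parent)], nbins = nrow(arbor$nodes))
}

#' Largest axis-aligned extent of an arbor (um)
#'
#' The largest of the x, y and z spans of the node coordinates; used as the
#' coarse-scale reference for scaling-range limits.
#'
#' @param arbor A `segment_arbor` or an `n x 3` point matrix.
#' @return Extent in um.
#' @export
arbor_extent <- function(arbor) {
  p <- if (inherits(arbor, "segment_arbor")) arbor$nodes else as.matrix(arbor)
  max(apply(p, 2, function(v) diff(range(v))))
}

#' Read an SWC reconstruction
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent). Any integer ids, forward parent references and `#` comments are
#' accepted; node ids are normalized to contiguous pre-order indices.
#' Duplicate points (zero-length segments) are merged with a warning.
#'
#' @param path Path to an SWC file.
#' @return A `segment_arbor` (coordinates taken as um).
#' @export
read_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no SWC records in ", path)
  tab <- utils::read.table(text = lines, col.names =
    c("id", "type", "x", "y", "z", "radius", "parent"))
  if (anyDuplicated(tab$id)) stop("duplicate SWC node ids in ", path)
  idx <- match(tab$parent, tab$id)          # NA for roots (-1) and orphans
  is_root <- tab$parent < 0
  if (sum(is_root) != 1)
    stop("SWC file must have exactly one root; roots at ids: ",
         paste(tab$id[is_root], collapse = ", "))
  orphan <- which(!is_root & is.na(idx))
  if (length(orphan))
    stop("orphan nodes with missing parents at ids: ",
         paste(tab$id[orphan], collapse = ", "))
  idx[is_root] <- NA_integer_
  segment_arbor(nodes = cbind(tab$x, tab$y, tab$z), parent = idx,
                radius = tab$radius, type = tab$type,
                label = sub("\\.swc$", "", basename(path)))
}

#' Write an arbor to SWC
#'
#' @param arbor A `segment_arbor`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(arbor, path) {
  n <- nrow(arbor$nodes)
  par <- arbor$parent
  par[is.na(par)] <- -1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC written by arborfractal; label: %s", arbor$label),
             con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     seq_len(n), arbor$type, arbor$nodes[, 1], arbor$nodes[, 2],
                     arbor$nodes[, 3], arbor$radius, par), con)
  invisible(path)
}

#' Export an arbor as a Wavefront OBJ frustum mesh
#'
#' Each segment becomes an open tube (conical frustum) with `sides` facets:
#' `sides` vertices on a ring at each end, no caps. One OBJ group per
#' segment. Vertices are in um.
#'
#' @param arbor A `segment_arbor`.
#' @param path Output file path.
#' @param sides Facets per tube (>= 3).
#' @return Invisibly, `path`.
#' @export
write_obj <- function(arbor, path, sides = 8) {
  stopifnot(sides >= 3)
  st <- segment_table(arbor)
  K <- length(st$length)
  ang <- 2 * pi * (seq_len(sides) - 1) / sides
  cs <- cos(ang); sn <- sin(ang)
  out <- character(0)
  vert <- vector("list", K)
  face <- vector("list", K)
  for (k in seq_len(K)) {
    B <- orthonormal_basis(st$end[k, ] - st$start[k, ])
    ring <- cbind(cs, sn) %*% t(B)                       # sides x 3
    v0 <- sweep(ring * st$r0[k], 2, st$start[k, ], `+`)
    v1 <- sweep(ring * st$r1[k], 2, st$end[k, ], `+`)
    vert[[k]] <- rbind(v0, v1)
    off <- (k - 1L) * 2L * sides
    i <- seq_len(sides)
    j <- c(seq_len(sides - 1) + 1L, 1L)                  # next index on ring
    face[[k]] <- cbind(
      rbind(cbind(i, j, j + sides), cbind(i, j + sides, i + sides)) + off,
      k)
  }
  V <- do.call(rbind, vert)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# arborfractal frustum export", con)
  writeLines(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  for (k in seq_len(K)) {
    writeLines(sprintf("g segment_%d", k), con)
    f <- face[[k]]
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read the vertices of a Wavefront OBJ file as a point cloud
#'
#' Only `v` records are used; faces, normals and texture coordinates are
#' ignored. Intended for box-counting deposited mesh models for which no
#' centerline reconstruction is available.
#'
#' @param path Path to an OBJ file.
#' @return An `n x 3` matrix of vertex positions (um).
#' @export
read_obj_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices ('v' records) found in ", path)
  m <- utils::read.table(text = vl)[, 2:4]
  as.matrix(m)
}

#' Resample an arbor centerline at fixed spacing
#'
#' Returns points along every (dendritic) segment centerline with
#' inter-point spacing at most `spacing`, including segment endpoints, plus
#' the locally interpolated tube width at each point.
#'
#' @param arbor A `segment_arbor`.
#' @param spacing Maximum spacing between consecutive sample points (um).
#' @param dendritic_only Drop soma-soma segments (default `TRUE`).
#' @return A list with `points` (`m x 3`) and `width` (um, = 2 x radius).
#' @export
resample_centerline <- function(arbor, spacing, dendritic_only = TRUE) {
  stopifnot(spacing > 0)
  st <- segment_table(arbor)
  keep <- if (dendritic_only) which(st$dendritic) else seq_along(st$length)
  if (!length(keep)) stop("no dendritic segments to sample")
  len <- st$length[keep]
  nseg <- pmax(1L, ceiling(len / spacing))
  counts <- nseg + 1L
  idx <- rep.int(keep, counts)
  tt <- (sequence(counts) - 1) / rep.int(nseg, counts)
  pts <- st$start[idx, , drop = FALSE] +
    tt * (st$end[idx, , drop = FALSE] - st$start[idx, , drop = FALSE])
  w <- 2 * (st$r0[idx] + tt * (st$r1[idx] - st$r0[idx]))
  list(points = pts, width = w)
}
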