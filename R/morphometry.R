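# Scalar and structural descriptors of an arbor: total length, radius of
# gyration, hull metrics, branch decomposition, fork/weave angles and
# segment-length histograms. Only dendritic segments (at least one
# non-soma endpoint) enter any metric.

#' Total dendritic length (um)
#' @param arbor A `segment_arbor`.
#' @export
total_length <- function(arbor) {
  st <- segment_table(arbor)
  sum(st$length[st$dendritic])
}

#' Length-weighted center of mass of an arbor
#'
#' Segment midpoints weighted by segment length.
#'
#' @param arbor A `segment_arbor`.
#' @return A 3-vector (um).
#' @export
center_of_mass <- function(arbor) {
  st <- segment_table(arbor)
  w <- st$length * st$dendritic
  colSums(st$mid * w) / sum(w)
}

#' Arbor radius (radius of gyration, um)
#'
#' The length-weighted root-mean-square distance between pairs of segment
#' midpoints:
#' \deqn{R_A^2 = \frac{1}{L_T^2} \sum_i \sum_j \delta l_i \delta l_j (r_i - r_j)^2}
#' The default one-pass moment form is algebraically identical to the
#' double sum, \eqn{R_A^2 = 2(\langle r^2\rangle_w - |\langle r\rangle_w|^2)}
#' with weights \eqn{w_i = \delta l_i / L_T}; `method = "double_sum"` keeps
#' the O(K^2) reference implementation for cross-checking.
#'
#' @param arbor A `segment_arbor`.
#' @param method `"moment"` (one-pass, default) or `"double_sum"`.
#' @return R_A in um.
#' @export
arbor_radius <- function(arbor, method = c("moment", "double_sum")) {
  method <- match.arg(method)
  st <- segment_table(arbor)
  keep <- st$dendritic
  if (!any(keep)) stop("empty arbor: no dendritic segments")
  mid <- st$mid[keep, , drop = FALSE]
  dl <- st$length[keep]
  LT <- sum(dl)
  if (method == "moment") {
    w <- dl / LT
    mu <- colSums(mid * w)
    msq <- sum(rowSums(mid^2) * w)
    return(sqrt(max(0, 2 * (msq - sum(mu^2)))))
  }
  K <- length(dl)
  acc <- 0
  for (i in seq_len(K)) {
    d2 <- rowSums((mid - matrix(mid[i, ], K, 3, byrow = TRUE))^2)
    acc <- acc + sum(dl[i] * dl * d2)
  }
  sqrt(acc / LT^2)
}

#' One-row morphometric summary of an arbor
#'
#' @param arbor A `segment_arbor`.
#' @param label Optional label override.
#' @return A data.frame with columns `label`, `L_T`, `K`, `R_A`,
#'   `hull_area`, `hull_volume`, `extent` and the center-of-mass
#'   coordinates.
#' @export
arbor_summary <- function(arbor, label = arbor$label) {
  st <- segment_table(arbor)
  hull <- convex_hull_metrics(arbor)
  com <- center_of_mass(arbor)
  data.frame(label = label,
             L_T = sum(st$length[st$dendritic]),
             K = sum(st$dendritic),
             R_A = arbor_radius(arbor),
             hull_area = hull[["hull_area"]],
             hull_volume = hull[["hull_volume"]],
             extent = arbor_extent(arbor),
             com_x = com[1], com_y = com[2], com_z = com[3],
             row.names = NULL)
}

#' Decompose an arbor into branches
#'
#' A branch is the maximal chain of connected segments between two forking
#' points, between a forking point and a terminal, or between the root
#' (soma attachment) and the first fork or terminal. Every segment belongs
#' to exactly one branch; interior nodes of a branch have exactly one
#' child.
#'
#' @param arbor A `segment_arbor`.
#' @return A list of branches, each a list with `segments` (segment row
#'   indices into [segment_table()], in root-to-tip order) and `kind`
#'   (one of `"soma-to-fork"`, `"soma-to-terminal"`, `"fork-to-fork"`,
#'   `"fork-to-terminal"`).
#' @export
decompose_branches <- function(arbor) {
  n <- nrow(arbor$nodes)
  if (n < 2) return(list())
  nch <- n_children(arbor)
  root <- 1L
  kids <- split(2:n, arbor$parent[2:n])
  starts <- integer(0)           # first node of each branch (child side)
  for (v in unique(c(root, which(nch >= 2))))
    starts <- c(starts, kids[[as.character(v)]])
  branches <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    node <- starts[b]
    segs <- integer(0)
    repeat {
      segs <- c(segs, node - 1L)          # segment row = child node - 1
      if (nch[node] != 1L) break
      node <- kids[[as.character(node)]]
    }
    from <- if (arbor$parent[starts[b]] == root) "soma" else "fork"
    to <- if (nch[node] == 0L) "terminal" else "fork"
    branches[[b]] <- list(segments = segs, kind = paste0(from, "-to-", to))
  }
  branches
}

#' Fork and weave angles of an arbor
#'
#' The weave angles of a branch are the angles between its consecutive
#' segments' direction vectors; the fork angle of a branch is its first
#' weave angle, i.e. the angle between the last segment of the parent
#' branch and the branch's first segment. Branches emanating directly from
#' the root have no parent direction and hence no fork angle; their count
#' is reported in the `n_root_branches` attribute.
#'
#' @param arbor A `segment_arbor`.
#' @return A data.frame with one row per measured joint: `segment`
#'   (segment row index of the outgoing segment), `branch`, `kind`
#'   (`"fork"` or `"weave"`) and `angle` (radians in `[0, pi]`).
#' @export
measure_angles <- function(arbor) {
  st <- segment_table(arbor)
  branches <- decompose_branches(arbor)
  dirs <- (st$end - st$start) / st$length
  if (any(!is.finite(dirs))) stop("zero-length segment: angles undefined")
  rows <- list()
  for (b in seq_along(branches)) {
    segs <- branches[[b]]$segments
    first <- segs[1]
    pnode <- st$parent_node[first]
    if (pnode != 1L) {                     # has an incoming parent segment
      inseg <- pnode - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        segment = first, branch = b, kind = "fork",
        angle = vec_angle(dirs[inseg, ], dirs[first, ]))
    }
    if (length(segs) > 1) {
      for (i in 2:length(segs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          segment = segs[i], branch = b, kind = "weave",
          angle = vec_angle(dirs[segs[i - 1], ], dirs[segs[i], ]))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(segment = integer(0), branch = integer(0),
                         kind = character(0), angle = numeric(0))
  n_root <- sum(vapply(branches, function(br)
    st$parent_node[br$segments[1]] == 1L, logical(1)))
  structure(out, n_root_branches = n_root)
}

#' Histogram of dendritic segment lengths
#'
#' Counts of segment lengths L_S per bin. When `bin_edges` span the data,
#' the counts sum to the dendritic segment count K.
#'
#' @param arbor A `segment_arbor`.
#' @param bin_edges Monotone increasing bin edges (um); bins are
#'   left-closed, `[e_i, e_{i+1})`.
#' @return Integer counts per bin with attribute `outside` (number of
#'   segments outside the binned range).
#' @export
segment_length_histogram <- function(arbor, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  st <- segment_table(arbor)
  L <- st$length[st$dendritic]
  bin <- findInterval(L, bin_edges)
  inside <- bin >= 1 & bin < length(bin_edges)
  counts <- tabulate(bin[inside], nbins = length(bin_edges) - 1)
  structure(counts, outside = sum(!inside))
}
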