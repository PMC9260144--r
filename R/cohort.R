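# Synthetic CA1-like basal arbor generator with group structure: the
# stand-in for deposited reconstructions. Arbors grow from a point soma
# as a breadth-first cascade of branches: chains of lognormal-length
# segments deflected by wrapped-normal weave angles, forking with
# order-dependent probability at wrapped-normal fork angles, stopping at
# a target total length. Arbors are rejection-sampled on the arbor radius
# window; per-group tortuosity multipliers scale the angle distributions
# (the planted morphological effect).

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate CA1 basal arbors: segment length/width medians of
#' 2.6/1.4 um, arbor radii inside 68-134 um with cohort mean near 97 um,
#' and box-counting dimensions spanning roughly 1.3-1.7. Group labels and
#' sizes follow the six lesion x housing x training groups; the
#' `tortuosity` multipliers plant a group effect through the same angle
#' lever the distortion module manipulates (by default the triple-positive
#' SH-ENR-TR group is 15% more tortuous).
#'
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param n_per_group Named integer vector of arbors per group.
#' @param tortuosity Named per-group angle multipliers.
#' @param n_primary_range Range of primary dendrites from the soma.
#' @param seg_len_meanlog,seg_len_sdlog Lognormal segment lengths (um).
#' @param width_meanlog,width_sdlog Lognormal tube widths (um).
#' @param width_taper Multiplicative width taper per branch order.
#' @param weave_mean,weave_sd Weave angle distribution (degrees).
#' @param fork_mean,fork_sd Fork angle distribution (degrees).
#' @param branch_segments_mean Mean number of segments per branch.
#' @param radial_bias Outward-tropism weight in `[0, 1)`: after each weave
#'   deflection the growth direction is blended with the radial outward
#'   unit vector, so arbors stay locally tortuous (which sets the
#'   fine-scale box dimension) while still reaching realistic radii.
#' @param fork_base,fork_decay Forking probability `fork_base -
#'   fork_decay * order`, floored at 0.
#' @param target_LT_meanlog,target_LT_sdlog Lognormal target total length.
#' @param arbor_tort_sd Lognormal sd of the per-arbor tortuosity jitter.
#' @param RA_window Acceptance window for the arbor radius (um).
#' @param DA_window Acceptance window for the box-counting dimension
#'   (`NULL` disables the D_A rejection step).
#' @param max_reject Rejection-sampling cap per arbor.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1,
                          n_per_group = c("ATN-ENR-PS" = 41, "ATN-ENR-TR" = 41,
                                          "ATN-STD-TR" = 47, "SH-ENR-PS" = 31,
                                          "SH-ENR-TR" = 42, "SH-STD-TR" = 32),
                          tortuosity = c("ATN-ENR-PS" = 1, "ATN-ENR-TR" = 1,
                                         "ATN-STD-TR" = 1, "SH-ENR-PS" = 1,
                                         "SH-ENR-TR" = 1.15, "SH-STD-TR" = 1),
                          n_primary_range = c(3, 5),
                          seg_len_meanlog = log(2.6), seg_len_sdlog = 0.5,
                          width_meanlog = log(1.4), width_sdlog = 0.25,
                          width_taper = 0.93,
                          weave_mean = 30, weave_sd = 13,
                          fork_mean = 40, fork_sd = 15,
                          branch_segments_mean = 6,
                          radial_bias = 0.08,
                          fork_base = 1.0, fork_decay = 0.05,
                          target_LT_meanlog = log(8000),
                          target_LT_sdlog = 0.20,
                          arbor_tort_sd = 0.06,
                          RA_window = c(68, 134),
                          DA_window = c(1.2, 1.9),
                          max_reject = 1000) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# Rotate `dir` away from itself by `angle` at a uniformly random azimuth.
deflect <- function(dir, angle) {
  B <- orthonormal_basis(dir)
  psi <- stats::runif(1, 0, 2 * pi)
  axis <- B[, 1] * cos(psi) + B[, 2] * sin(psi)
  as.vector(rotation_matrix(axis, angle) %*% dir)
}

# Grow one arbor (uses the current RNG stream).
grow_arbor <- function(cfg, tort = 1, label = "synthetic") {
  deg <- pi / 180
  total <- 0
  target <- stats::rlnorm(1, cfg$target_LT_meanlog, cfg$target_LT_sdlog)
  n_primary <- sample(cfg$n_primary_range[1]:cfg$n_primary_range[2], 1)

  cap <- ceiling(target / exp(cfg$seg_len_meanlog) * 3) + 50
  nodes <- matrix(0, cap, 3)
  radius <- numeric(cap); radius[1] <- 6   # soma marker radius
  type <- integer(cap); type[1] <- 1L
  parent <- rep(NA_integer_, cap)
  used <- 1L

  add_node <- function(pos, par, w) {
    used <<- used + 1L
    if (used > nrow(nodes)) {               # rare overflow: double capacity
      nodes <<- rbind(nodes, matrix(0, nrow(nodes), 3))
      radius <<- c(radius, numeric(length(radius)))
      type <<- c(type, integer(length(type)))
      parent <<- c(parent, rep(NA_integer_, length(parent)))
    }
    nodes[used, ] <<- pos
    radius[used] <<- w / 2
    type[used] <<- 3L
    parent[used] <<- par
    used
  }
  sample_angle <- function(mean_deg, sd_deg) {
    th <- abs(stats::rnorm(1, mean_deg, sd_deg)) * tort * deg
    min(th, pi * 0.9)
  }

  # queue of growing tips: list(node, dir, order)
  queue <- lapply(seq_len(n_primary), function(i) {
    d <- stats::rnorm(3)
    list(node = 1L, dir = d / sqrt(sum(d^2)), order = 0L)
  })
  while (length(queue) && total < target) {
    tip <- queue[[1]]; queue <- queue[-1]
    n_seg <- 1 + stats::rpois(1, cfg$branch_segments_mean - 1)
    node <- tip$node; dir <- tip$dir
    w <- stats::rlnorm(1, cfg$width_meanlog, cfg$width_sdlog) *
      cfg$width_taper^tip$order
    w <- max(w, 0.4)
    for (s in seq_len(n_seg)) {
      # the first segment of a branch keeps its heading: its deflection is
      # the fork angle already applied when the tip was queued
      if (s > 1) {
        dir <- deflect(dir, sample_angle(cfg$weave_mean, cfg$weave_sd))
        # outward tropism: local weave stays strong but growth keeps a
        # radial drift, as real dendrites do
        radial <- nodes[node, ]
        rn <- sqrt(sum(radial^2))
        if (rn > 1e-9)
          dir <- unit3((1 - cfg$radial_bias) * dir +
                         cfg$radial_bias * radial / rn)
      }
      len <- stats::rlnorm(1, cfg$seg_len_meanlog, cfg$seg_len_sdlog)
      node <- add_node(nodes[node, ] + dir * len, node, w)
      total <- total + len
      if (total >= target) break
    }
    p_fork <- max(0, cfg$fork_base - cfg$fork_decay * (tip$order + 1))
    if (total < target && stats::runif(1) < p_fork) {
      psi <- stats::runif(1, 0, 2 * pi)
      B <- orthonormal_basis(dir)
      for (sgn in c(0, pi)) {
        ax <- B[, 1] * cos(psi + sgn) + B[, 2] * sin(psi + sgn)
        th <- sample_angle(cfg$fork_mean, cfg$fork_sd)
        queue[[length(queue) + 1]] <- list(
          node = node,
          dir = as.vector(rotation_matrix(ax, th) %*% dir),
          order = tip$order + 1L)
      }
    }
  }
  segment_arbor(nodes[seq_len(used), , drop = FALSE],
                parent[seq_len(used)], radius[seq_len(used)],
                type[seq_len(used)], label = label, normalize = TRUE)
}

#' Generate a synthetic cohort of CA1-like basal arbors
#'
#' Grows `n_per_group` arbors per group under the configured
#' distributions (a per-arbor lognormal jitter scales the sampled angles
#' during growth). A group's tortuosity multiplier, when not 1, is then
#' applied to the grown geometry via [distort_arbor()] -- the same lever
#' the distortion module manipulates, so planted group effects are
#' exactly angle-scaling effects. Arbors are rejection-sampled until the
#' arbor
#' radius falls in `RA_window` (and, if set, the box dimension in
#' `DA_window`). Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with `arbors` (list of `segment_arbor`) and `table`
#'   (data.frame: `id`, `label`, `group`, `category`, `L_T`, `K`, `R_A`,
#'   `D_A`, `tort`, `tries`).
#' @export
make_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$n_per_group)
  with_seed(config$seed, {
    arbors <- list()
    rows <- list()
    id <- 0L
    for (g in groups) {
      tort_g <- config$tortuosity[[g]]
      for (i in seq_len(config$n_per_group[[g]])) {
        id <- id + 1L
        lab <- sprintf("%s_%03d", g, i)
        tries <- 0
        repeat {
          tries <- tries + 1
          if (tries > config$max_reject)
            stop(sprintf(paste0("acceptance windows unreachable for ",
                                "group %s after %d rejections"),
                         g, config$max_reject))
          jitter <- stats::rlnorm(1, 0, config$arbor_tort_sd)
          a <- grow_arbor(config, jitter, lab)
          if (abs(tort_g - 1) > 1e-12) {
            a <- distort_arbor(a, tort_g)
            a$label <- lab
          }
          RA <- arbor_radius(a)
          if (RA < config$RA_window[1] || RA > config$RA_window[2]) next
          DA <- NA_real_
          if (!is.null(config$DA_window)) {
            DA <- tryCatch(fit_box_dimension(a)$D_A,
                           error = function(e) NA_real_)
            if (!is.finite(DA) || DA < config$DA_window[1] ||
                DA > config$DA_window[2]) next
          }
          break
        }
        st <- segment_table(a)
        arbors[[id]] <- a
        rows[[id]] <- data.frame(
          id = id, label = lab, group = g,
          category = sub("-.*$", "", g),
          L_T = sum(st$length[st$dendritic]),
          K = sum(st$dendritic), R_A = RA, D_A = DA,
          tort = tort_g, jitter = jitter, tries = tries)
      }
    }
    list(arbors = arbors, table = do.call(rbind, rows))
  })
}

#' Write a cohort to SWC files with a manifest
#'
#' @param cohort Result of [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$arbors))
    write_swc(cohort$arbors[[i]],
              file.path(dir, paste0(cohort$table$label[i], ".swc")))
  mp <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(cohort$table, mp, row.names = FALSE)
  invisible(mp)
}
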