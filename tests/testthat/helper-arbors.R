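# Shared test helpers: small deterministic arbors and geometry utilities.

# Random small tree arbor: branching chain with K segments.
random_small_arbor <- function(K = 30, seed = 1, step = 3, fork_p = 0.25) {
  withr_seed(seed)
  nodes <- matrix(0, 1, 3)
  parent <- NA_integer_
  tips <- list(list(node = 1L, dir = c(0, 0, 1)))
  while (nrow(nodes) - 1 < K && length(tips)) {
    t_i <- sample(length(tips), 1)
    tip <- tips[[t_i]]
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, 0.9)
    dir <- as.vector(rot_axis(ax, th) %*% tip$dir)
    nodes <- rbind(nodes, nodes[tip$node, ] + dir * runif(1, 0.5, 1) * step)
    parent <- c(parent, tip$node)
    new_tip <- list(node = nrow(nodes), dir = dir)
    if (runif(1) < fork_p) tips <- c(tips, list(new_tip))
    tips[[t_i]] <- new_tip
  }
  segment_arbor(nodes, parent, radius = runif(nrow(nodes), 0.3, 1))
}

# Rodrigues rotation (duplicated here so tests stay independent of
# package internals).
rot_axis <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  cos(angle) * diag(3) + sin(angle) * ux + (1 - cos(angle)) * tcrossprod(u)
}

withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# Small cohort configuration for fast pipeline-level tests.
mini_cohort_config <- function(seed = 1, n = 3) {
  cohort_config(seed = seed,
                n_per_group = c("ATN-STD-TR" = n, "SH-ENR-TR" = n),
                tortuosity = c("ATN-STD-TR" = 1, "SH-ENR-TR" = 1.15),
                target_LT_meanlog = log(3500),
                RA_window = c(40, 170), DA_window = NULL)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
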