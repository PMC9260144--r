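# Arbor radius, branch decomposition, angles and length histograms.

test_that("two far-apart equal segments give R_A = d/sqrt(2)", {
  # two unit dendritic segments whose midpoints sit d apart, joined by a
  # soma-typed connector that carries no dendritic mass
  nodes <- rbind(c(0, 0, 0), c(-1, 0, 0), c(100, 0, 0), c(101, 0, 0))
  a <- segment_arbor(nodes, c(NA, 1, 1, 3), rep(0.5, 4),
                     type = c(1, 3, 1, 3))
  d <- 100.5 - (-0.5)                    # midpoint separation
  expect_rel_equal(arbor_radius(a), d / sqrt(2), 1e-9)
})

test_that("finely subdivided rod approaches L/sqrt(6)", {
  rod <- make_fixture("rod", L = 300, n = 200)
  expect_rel_equal(arbor_radius(rod), 300 / sqrt(6), 0.005)
})

test_that("one-pass moment form equals the O(K^2) double sum", {
  for (seed in 1:10) {
    a <- random_small_arbor(sample(5:50, 1), seed = seed)
    expect_rel_equal(arbor_radius(a, "moment"),
                     arbor_radius(a, "double_sum"), 1e-9)
  }
})

test_that("R_A is invariant under rigid motion and scales linearly", {
  a <- random_small_arbor(35, seed = 8)
  R <- rot_axis(c(1, 2, 3), 1.1)
  b <- a; b$nodes <- a$nodes %*% t(R) + matrix(c(5, -3, 9), nrow(a$nodes), 3,
                                               byrow = TRUE)
  expect_rel_equal(arbor_radius(b), arbor_radius(a), 1e-9)
  cc <- a; cc$nodes <- a$nodes * 3.7
  expect_rel_equal(arbor_radius(cc), 3.7 * arbor_radius(a), 1e-9)
})

test_that("R_A lies strictly inside (0, extent) for realistic arbors", {
  for (seed in 1:4) {
    a <- random_small_arbor(60, seed = seed)
    RA <- arbor_radius(a)
    expect_gt(RA, 0)
    expect_lt(RA, arbor_extent(a))
  }
})

test_that("branch decomposition counts follow the fork structure", {
  # Y-shape: stem + two daughters
  y <- segment_arbor(rbind(c(0, 0, 0), c(0, 0, 5), c(2, 0, 8), c(-2, 0, 8)),
                     c(NA, 1, 2, 2), rep(0.5, 4))
  expect_equal(length(decompose_branches(y)), 3)
  chain <- make_fixture("elbow")
  expect_equal(length(decompose_branches(chain)), 1)
})

test_that("a binary tree with F forks has 2F + 1 branches", {
  for (seed in c(2, 4, 6)) {
    a <- random_small_arbor(45, seed = seed)
    nch <- tabulate(a$parent[!is.na(a$parent)], nbins = nrow(a$nodes))
    forks <- sum(nch >= 2)
    br <- decompose_branches(a)
    # brute-force count only exact for strictly binary forks
    if (all(nch <= 2)) expect_equal(length(br), 2 * forks + 1)
    # regardless, every segment appears in exactly one branch
    segs <- sort(unlist(lapply(br, `[[`, "segments")))
    expect_equal(segs, seq_len(nrow(a$nodes) - 1))
  }
})

test_that("weave angles measure straight chains and right angles", {
  rod <- make_fixture("rod", L = 20, n = 5)
  ang <- measure_angles(rod)
  expect_true(all(abs(ang$angle) < 1e-9))
  elbow <- make_fixture("elbow")
  ang2 <- measure_angles(elbow)
  expect_equal(nrow(ang2), 1)
  expect_equal(ang2$angle, pi / 2, tolerance = 1e-12)
  expect_equal(ang2$kind, "weave")
})

test_that("angles are rigid-motion invariant and branch-consistent", {
  a <- random_small_arbor(40, seed = 12)
  ang <- measure_angles(a)
  R <- rot_axis(c(0, 1, 1), 0.8)
  b <- a; b$nodes <- a$nodes %*% t(R)
  ang2 <- measure_angles(b)
  expect_lt(max(abs(ang$angle - ang2$angle)), 1e-9)
  # per-branch bookkeeping: non-root branches carry one fork angle and
  # (#segments - 1) weave angles
  br <- decompose_branches(a)
  n_root <- attr(ang, "n_root_branches")
  expect_equal(sum(ang$kind == "fork"), length(br) - n_root)
})

test_that("segment length histogram is conservative", {
  a <- segment_arbor(rbind(c(0, 0, 0), c(2.6, 0, 0), c(5.2, 0, 0)),
                     c(NA, 1, 2), rep(0.5, 3))
  h <- segment_length_histogram(a, c(0, 2, 4))
  expect_equal(as.integer(h), c(0L, 2L))
  b <- random_small_arbor(50, seed = 2)
  st <- segment_table(b)
  h2 <- segment_length_histogram(b, seq(0, 10, by = 0.5))
  expect_equal(sum(h2) + attr(h2, "outside"), length(st$length))
  expect_error(segment_length_histogram(b, c(3, 2, 1)), "increasing")
})
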