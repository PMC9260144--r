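# Angle-scaling distortion: the operational definition of correctness is
# measure_angles(distort(A, alpha)) == alpha * measure_angles(A).

test_that("alpha = 1 is the identity", {
  a <- random_small_arbor(50, seed = 4)
  d <- distort_arbor(a, 1)
  expect_lt(max(abs(d$nodes - a$nodes)), 1e-9)
})

test_that("a planar zig-zag doubles its weave angles", {
  th <- 30 * pi / 180
  pts <- matrix(0, 7, 3)
  bent <- as.vector(rot_axis(c(0, 0, 1), th) %*% c(1, 0, 0))
  for (i in 2:7) {
    dir <- if (i %% 2 == 0) c(1, 0, 0) else bent   # alternate: weave = th
    pts[i, ] <- pts[i - 1, ] + 5 * dir
  }
  a <- segment_arbor(pts, c(NA, 1:6), rep(0.5, 7))
  d <- distort_arbor(a, 2)
  ang <- measure_angles(d)
  expect_equal(ang$angle, rep(2 * th, 5), tolerance = 1e-9)
  expect_rel_equal(total_length(d), total_length(a), 1e-12)
})

test_that("all angles scale by alpha and lengths are conserved", {
  a <- random_small_arbor(60, seed = 16)
  base <- measure_angles(a)
  for (al in c(0.5, 1.3)) {
    d <- distort_arbor(a, al)
    ang <- measure_angles(d)
    expect_lt(max(abs(ang$angle - al * base$angle)), 1e-6)
    expect_rel_equal(total_length(d), total_length(a), 1e-9)
    lens0 <- segment_table(a)$length
    lens1 <- segment_table(d)$length
    expect_lt(max(abs(lens1 - lens0) / lens0), 1e-9)
  }
})

test_that("distorting by alpha then 1/alpha restores the arbor", {
  a <- random_small_arbor(45, seed = 23)
  b <- distort_arbor(distort_arbor(a, 1.5), 1 / 1.5)
  expect_lt(max(abs(measure_angles(b)$angle - measure_angles(a)$angle)), 1e-6)
  expect_lt(max(abs(b$nodes - a$nodes)), 1e-6)
})

test_that("angles scaling past pi are clamped and counted", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(10 + 10 * cos(2.8), 10 * sin(2.8), 0))
  a <- segment_arbor(pts, c(NA, 1, 2), rep(0.3, 3))   # joint at 160.4 deg
  expect_warning(d <- distort_arbor(a, 2.0), NA)      # 2.0 is in range
  expect_equal(attr(d, "n_clamped"), 1L)
  expect_equal(measure_angles(d)$angle, pi, tolerance = 1e-9)
  expect_error(distort_arbor(a, -1), "alpha")
  expect_warning(distort_arbor(a, 2.5), "outside")
})

test_that("sweep bookkeeping is exact", {
  arbors <- lapply(1:3, function(i) random_small_arbor(20, seed = i))
  sw <- distortion_sweep(arbors)
  expect_equal(nrow(sw$manifest), 3 * 6)
  expect_equal(length(sw$arbors), 18)
  expect_setequal(unique(sw$manifest$alpha), c(0.5, 0.75, 1.25, 1.5, 1.75, 2))
  sw0 <- distortion_sweep(arbors, grid = numeric(0))
  expect_equal(nrow(sw0$manifest), 0)
  expect_equal(length(sw0$arbors), 0)
  sw1 <- distortion_sweep(arbors, grid = c(1, 1.5))    # identity dropped
  expect_equal(nrow(sw1$manifest), 3)
})

test_that("overlap detection flags interpenetrating tubes only", {
  rod <- make_fixture("rod", L = 50, n = 50)
  expect_equal(as.integer(self_overlap_check(rod)), 0L)
  # two crossing segments 0.5 um apart with radii 0.7 um
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0),        # segment A along x
                 c(5, -5, 0.5), c(5, 5, 0.5))    # crosses above it
  a <- segment_arbor(rbind(nodes[1:2, ], nodes[3:4, ]),
                     c(NA, 1, 2, 3), rep(0.7, 4))
  ov <- self_overlap_check(a)
  expect_gte(as.integer(ov), 1L)
  pairs <- attr(ov, "pairs")
  expect_true(any(pairs[, 1] == 1 & pairs[, 2] == 3))
})

test_that("overlap grows with extreme angle scaling", {
  cfg <- mini_cohort_config(seed = 6, n = 4)
  co <- make_cohort(cfg)
  o20 <- o25 <- numeric(length(co$arbors))
  for (i in seq_along(co$arbors)) {
    o20[i] <- suppressWarnings(
      as.integer(self_overlap_check(distort_arbor(co$arbors[[i]], 2.0))))
    o25[i] <- suppressWarnings(
      as.integer(self_overlap_check(distort_arbor(co$arbors[[i]], 2.5))))
  }
  expect_gte(median(o25), median(o20))
})
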