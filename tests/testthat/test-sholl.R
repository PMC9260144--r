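# Sphere-crossing counts, in-sphere mass, origin sampling and the
# mass-dimension fit.

test_that("a star of rays crosses each sphere once per ray", {
  st <- make_fixture("star5", L = 100)
  ni <- sholl_counts(st, c(0, 0, 0), c(10, 55.5, 99.5, 101, 150))
  expect_equal(ni, c(5, 5, 5, 0, 0))
})

test_that("single segments cross spheres 0, 1 or 2 times exactly", {
  # endpoint distances 3 and 7: one crossing for 3 < r <= 7
  a <- segment_arbor(rbind(c(3, 0, 0), c(7, 0, 0)), c(NA, 1), c(0.5, 0.5))
  expect_equal(sholl_counts(a, c(0, 0, 0), c(2, 5, 7, 8)), c(0, 1, 1, 0))
  # chord at closest distance 6 with both endpoints at radius 10:
  # two crossings for 6 < r < 10
  ch <- segment_arbor(rbind(c(-8, 6, 0), c(8, 6, 0)), c(NA, 1), c(0.5, 0.5))
  expect_equal(sholl_counts(ch, c(0, 0, 0), c(5, 8, 12)), c(0, 2, 0))
})

test_that("crossing parity matches the endpoint sidedness", {
  set.seed(31)
  for (i in 1:50) {
    A <- runif(3, -10, 10); B <- runif(3, -10, 10)
    a <- segment_arbor(rbind(A, B), c(NA, 1), c(0.1, 0.1))
    r <- runif(1, 1, 12)
    n <- sholl_counts(a, c(0, 0, 0), r)
    same_side <- (sqrt(sum(A^2)) < r) == (sqrt(sum(B^2)) < r)
    expect_equal(n %% 2 == 0, same_side)
  }
})

test_that("in-sphere mass clips analytically", {
  rod <- make_fixture("rod", L = 200, n = 200)   # centered at origin
  expect_equal(mass_in_sphere(rod, c(0, 0, 0), 50), 100, tolerance = 1e-9)
  expect_equal(mass_in_sphere(rod, c(0, 0, 0), 500), 200, tolerance = 1e-9)
  expect_true(all(diff(mass_in_sphere(rod, c(1, 2, 3), 1:120)) >= 0))
})

test_that("analytic in-sphere mass matches a Monte Carlo oracle", {
  set.seed(17)
  for (i in 1:5) {
    a <- random_small_arbor(20, seed = i)
    st <- segment_table(a)
    org <- colMeans(a$nodes)
    r <- 0.6 * max(sqrt(rowSums(sweep(a$nodes, 2, org)^2)))
    exact <- mass_in_sphere(a, org, r)
    # stochastic integration: uniform points along each segment
    mc <- 0
    for (k in seq_along(st$length)) {
      tt <- runif(2000)
      pts <- st$start[rep(k, 2000), ] + tt * (st$end[rep(k, 2000), ] -
                                                st$start[rep(k, 2000), ])
      mc <- mc + st$length[k] * mean(rowSums(sweep(pts, 2, org)^2) <= r^2)
    }
    expect_rel_equal(exact, mc, 0.015)
  }
})

test_that("origins sample the centerline near the center of mass", {
  rod <- make_fixture("rod", L = 300, n = 300)
  o1 <- sample_origins(rod, 40, seed = 5)
  RA <- arbor_radius(rod); com <- center_of_mass(rod)
  d <- sqrt(rowSums(sweep(o1, 2, com)^2))
  expect_true(all(d <= RA / 2 + 1e-9))
  expect_true(all(abs(o1[, 1]) < 1e-9))          # on the rod line
  expect_identical(o1, sample_origins(rod, 40, seed = 5))
  expect_false(isTRUE(all.equal(o1, sample_origins(rod, 40, seed = 6))))
})

test_that("origin density is proportional to arc length", {
  # a gently kinked two-segment wire whose central ball straddles the
  # kink: origins must split between the segments in proportion to their
  # arc length inside the R_A/2 ball
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(22, 0.5, 0))
  a <- segment_arbor(nodes, c(NA, 1, 2), rep(0.3, 3))
  com <- center_of_mass(a); RA <- arbor_radius(a)
  org <- sample_origins(a, 4000, seed = 11)
  d <- sqrt(rowSums(sweep(org, 2, com)^2))
  expect_true(all(d <= RA / 2 + 1e-9))
  on_first <- org[, 2] < 1e-7
  on_second <- org[, 2] >= 1e-7
  expect_equal(sum(on_first) + sum(on_second), 4000)
  # numerically clipped in-ball arc lengths as the independent oracle
  clip_len <- function(A, B) {
    u <- B - A; tt <- seq(0, 1, length.out = 20001)
    pts <- matrix(A, 20001, 3, byrow = TRUE) + tt %o% u
    mean(rowSums(sweep(pts, 2, com)^2) <= (RA / 2)^2) * sqrt(sum(u^2))
  }
  l1 <- clip_len(nodes[1, ], nodes[2, ]); l2 <- clip_len(nodes[2, ], nodes[3, ])
  expect_gt(l1, 0); expect_gt(l2, 0)
  ct <- suppressWarnings(chisq.test(c(sum(on_first), sum(on_second)),
                                    p = c(l1, l2) / (l1 + l2)))
  expect_gt(ct$p.value, 0.001)
})

test_that("profiles aggregate origins with standard errors", {
  st5 <- make_fixture("star5", L = 60)
  pr1 <- sholl_profile(st5, n_origins = 1, seed = 2)
  expect_true(all(pr1$se_NI == 0))
  expect_equal(pr1$mean_NI, as.numeric(pr1$N_I[1, ]))
  pr <- sholl_profile(st5, n_origins = 10, seed = 2)
  expect_true(all(pr$mean_Lin <= pr$L_T + 1e-9))
  expect_true(all(apply(pr$L_in, 1, function(x) all(diff(x) >= -1e-9))))
})

test_that("mass dimension recovers 1D and 2D scaling", {
  st5 <- make_fixture("star5", L = 160)
  pr <- sholl_profile(st5, n_origins = 1, origins = matrix(0, 1, 3),
                      radii = seq(2.2, 40, 0.4))
  fit <- fit_mass_dimension(pr, extent = arbor_extent(st5))
  expect_lt(abs(fit$slope - 1), 0.05)
  carpet <- make_fixture("plane_carpet", size = 160)
  prc <- sholl_profile(carpet, n_origins = 8, seed = 4,
                       radii = seq(2.2, 36, 0.4))
  fitc <- fit_mass_dimension(prc, extent = 160)
  expect_lt(abs(fitc$slope - 2), 0.1)
})

test_that("mass dimension is stable under rigid motion", {
  carpet <- make_fixture("plane_carpet", size = 150)
  pr <- sholl_profile(carpet, n_origins = 6, seed = 3,
                      radii = seq(2.2, 32, 0.4))
  f1 <- fit_mass_dimension(pr, extent = 150)
  R <- rot_axis(c(1, 0, 2), 2.2)
  b <- carpet; b$nodes <- carpet$nodes %*% t(R) +
    matrix(c(3, -7, 11), nrow(carpet$nodes), 3, byrow = TRUE)
  prb <- sholl_profile(b, n_origins = 6, seed = 3, radii = seq(2.2, 32, 0.4))
  f2 <- fit_mass_dimension(prb, extent = 150)
  expect_lt(abs(f1$slope - f2$slope), 0.05)
})
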