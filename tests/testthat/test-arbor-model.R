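# SWC/OBJ input-output and the segment-arbor data model.

swc_text <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

test_that("read_swc parses a minimal chain and computes its geometry", {
  f <- swc_text(c("# a comment",
                  "1 1 0 0 0 1.0 -1",
                  "2 3 0 0 10 1.0 1",
                  "3 3 0 0 20 1.0 2"))
  a <- read_swc(f)
  st <- segment_table(a)
  expect_equal(nrow(a$nodes), 3)
  expect_equal(length(st$length), 2)
  expect_equal(sum(st$length), 20)
})

test_that("read_swc accepts forward parent references and odd ids", {
  f <- swc_text(c("10 3 0 0 20 0.5 77",   # parent appears later in file
                  "77 3 0 0 10 0.5 5",
                  "5 1 0 0 0 1.0 -1"))
  a <- read_swc(f)
  expect_equal(nrow(a$nodes), 3)
  expect_true(is.na(a$parent[1]))          # root normalized to index 1
  expect_equal(total_length(a), 20)
})

test_that("read_swc rejects structural errors with informative messages", {
  f2 <- swc_text(c("1 1 0 0 0 1 -1", "2 3 0 0 5 1 -1"))
  expect_error(read_swc(f2), "exactly one root")
  f3 <- swc_text(c("1 1 0 0 0 1 -1", "2 3 0 0 5 1 99"))
  expect_error(read_swc(f3), "orphan")
  # cycle via mutual parents (no root at all)
  f4 <- swc_text(c("1 1 0 0 0 1 2", "2 3 0 0 5 1 1"))
  expect_error(read_swc(f4))
})

test_that("duplicate points are merged with a warning", {
  f <- swc_text(c("1 1 0 0 0 1 -1",
                  "2 3 0 0 5 1 1",
                  "3 3 0 0 5 1 2",    # zero-length segment
                  "4 3 0 0 9 1 3"))
  expect_warning(a <- read_swc(f), "zero-length")
  expect_equal(nrow(a$nodes), 3)
  expect_equal(total_length(a), 9)
})

test_that("SWC round trip preserves geometry and is idempotent", {
  a <- random_small_arbor(40, seed = 3)
  f1 <- tempfile(fileext = ".swc"); f2 <- tempfile(fileext = ".swc")
  write_swc(a, f1)
  b <- read_swc(f1)
  expect_lt(max(abs(a$nodes - b$nodes)), 1e-6)
  expect_lt(max(abs(a$radius - b$radius)), 1e-6)
  expect_equal(a$parent, b$parent)
  write_swc(b, f2)
  c2 <- read_swc(f2)
  expect_identical(b$nodes, c2$nodes)
})

test_that("tree property holds: segments = nodes - 1", {
  for (seed in 1:5) {
    a <- random_small_arbor(25, seed = seed)
    expect_equal(length(segment_table(a)$length), nrow(a$nodes) - 1)
  }
})

test_that("write_obj emits an open tube per segment", {
  a <- segment_arbor(rbind(c(0, 0, 0), c(0, 0, 10)), c(NA, 1), c(1, 1))
  f <- tempfile(fileext = ".obj")
  write_obj(a, f, sides = 6)
  lines <- readLines(f)
  expect_equal(sum(grepl("^v ", lines)), 12)    # 2 rings x 6 vertices
  expect_equal(sum(grepl("^f ", lines)), 12)    # 2 triangles x 6 facets
  expect_equal(sum(grepl("^g ", lines)), 1)
})

test_that("OBJ vertex counts scale as 2 * sides * K and round-trip", {
  a <- random_small_arbor(15, seed = 9)
  K <- nrow(a$nodes) - 1
  f <- tempfile(fileext = ".obj")
  write_obj(a, f, sides = 8)
  v <- read_obj_vertices(f)
  expect_equal(nrow(v), 2 * 8 * K)
  # vertices lie within tube radius of the centerline bounding box
  expect_true(all(v[, 3] <= max(a$nodes[, 3]) + max(a$radius) + 1e-9))
})

test_that("read_obj_vertices skips comments and normals, errors when empty", {
  f <- tempfile(fileext = ".obj")
  writeLines(c("# comment", "vn 0 0 1", "v 1 2 3", "v 4 5 6", "f 1 2 1"), f)
  v <- read_obj_vertices(f)
  expect_equal(dim(v), c(2, 3))
  expect_equal(v[2, ], c(4, 5, 6), ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".obj")
  writeLines(c("# nothing", "vn 0 0 1"), f2)
  expect_error(read_obj_vertices(f2), "no vertices")
})

test_that("degenerate zero tip radius still emits a mesh", {
  a <- segment_arbor(rbind(c(0, 0, 0), c(0, 0, 5)), c(NA, 1), c(1, 0))
  f <- tempfile(fileext = ".obj")
  write_obj(a, f, sides = 5)
  v <- read_obj_vertices(f)
  expect_equal(nrow(v), 10)
  # apex ring collapses onto the tip point
  expect_lt(max(abs(sweep(v[6:10, ], 2, c(0, 0, 5)))), 1e-9)
})

test_that("packaged example reconstruction loads cleanly", {
  f <- system.file("extdata", "example_basal.swc", package = "arborfractal")
  a <- read_swc(f)
  expect_s3_class(a, "segment_arbor")
  expect_gt(total_length(a), 100)
  expect_equal(a$type[1], 1L)   # soma root
})
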