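test_that("single atom on the lattice matches the analytic classification", {
  g <- build_labeled_grid(matrix(0, 1, 3))
  # integer points with |p| <= 2: 33; interior: origin plus the six unit-axis
  # points; the remaining 26 protein points are surface
  expect_equal(g$n_surface + g$n_interior, 33)
  expect_equal(count_interior(g), 7)
  expect_equal(g$n_surface, 26)
  ann <- annotate_surface_atoms(matrix(0, 1, 3), g)
  expect_true(ann$is_surface_atom) # nearest surface point (1,1,0) at sqrt(2)
})

test_that("distant atoms form independent identical blobs", {
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0))
  g <- build_labeled_grid(xyz)
  expect_equal(g$n_surface + g$n_interior, 66)
  expect_equal(count_interior(g), 14)
  ann <- annotate_surface_atoms(xyz, g)
  expect_true(all(ann$is_surface_atom))
})

test_that("empty structures are rejected", {
  expect_error(build_labeled_grid(matrix(numeric(0), 0, 3)),
               class = "sitematch_error_no_atoms")
})

test_that("labels agree with exhaustive classification on random structures", {
  set.seed(3)
  for (rep in 1:30) {
    n <- sample(1:10, 1)
    xyz <- matrix(runif(3 * n, 0, 4), n, 3)
    g <- build_labeled_grid(xyz)
    oracle <- grid_oracle_labels(xyz, g$origin, g$dims, g$step, 2)
    expect_identical(as.integer(g$labels), oracle)
  }
})

test_that("integer lattice shifts leave counts and surface flags unchanged", {
  set.seed(9)
  xyz <- matrix(runif(15, 0, 5), 5, 3)
  g0 <- build_labeled_grid(xyz)
  a0 <- annotate_surface_atoms(xyz, g0)
  shift <- c(3, -2, 7)
  xyz1 <- sweep(xyz, 2, shift, "+")
  g1 <- build_labeled_grid(xyz1)
  expect_equal(count_interior(g1), count_interior(g0))
  expect_equal(g1$n_surface, g0$n_surface)
  expect_identical(annotate_surface_atoms(xyz1, g1)$is_surface_atom,
                   a0$is_surface_atom)
})

test_that("the protein-point set grows monotonically with atoms", {
  set.seed(21)
  xyz <- matrix(runif(24, 0, 6), 8, 3)
  origin <- floor(apply(xyz, 2, min)) - 4
  hi <- ceiling(apply(xyz, 2, max)) + 4
  dims <- as.integer(hi - origin) + 1L
  g_all <- build_labeled_grid(xyz, origin = origin, dims = dims)
  g_sub <- build_labeled_grid(xyz[1:5, ], origin = origin, dims = dims)
  expect_true(all(which(g_sub$labels != 0L) %in% which(g_all$labels != 0L)))
})

test_that("an atom inside a dense cluster is not a surface atom", {
  pts <- as.matrix(expand.grid(seq(-4, 4, 2), seq(-4, 4, 2), seq(-4, 4, 2)))
  g <- build_labeled_grid(pts)
  ann <- annotate_surface_atoms(pts, g)
  centre <- which(rowSums(pts^2) == 0)
  expect_false(ann$is_surface_atom[centre])
  corner <- which(rowSums(pts == 4) == 3)
  expect_true(ann$is_surface_atom[corner])
})

test_that("atoms outside the grid extent are reported as a mismatch", {
  g <- build_labeled_grid(matrix(0, 1, 3))
  expect_error(annotate_surface_atoms(matrix(c(50, 0, 0), 1, 3), g),
               class = "sitematch_error_grid_mismatch")
})
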