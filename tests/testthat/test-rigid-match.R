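test_that("Kabsch recovers exact congruences", {
  set.seed(1)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  tr <- kabsch_superpose(A, A)
  expect_equal(tr$R, diag(3), tolerance = 1e-9)
  expect_equal(tr$t, c(0, 0, 0), tolerance = 1e-9)

  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), 0 + cos(th), 0, 0, 0, 1), 3, 3)
  B <- sweep(A %*% t(Rz), 2, c(5, 0, 0), "+") # B = Rz A + (5,0,0)
  tr <- kabsch_superpose(A, B)
  expect_lt(bottleneck_under_transform(tr, A, B), 1e-9)
})

test_that("Kabsch RMSD agrees with an independent least-squares solver", {
  set.seed(2)
  A <- matrix(rnorm(24, sd = 3), 8, 3)
  B <- A + matrix(rnorm(24, sd = 0.3), 8, 3)
  B <- sweep(B %*% t(rand_rotation_matrix()), 2, c(3, -1, 2), "+")
  tr <- kabsch_superpose(A, B)
  rmsd_mine <- sqrt(mean(rowSums((A - apply_transform(tr, B))^2)))
  fit <- suppressWarnings( # bio3d notes it is fitting on all positions
    bio3d::fit.xyz(fixed = as.vector(t(A)), mobile = as.vector(t(B))))
  rmsd_bio3d <- sqrt(mean(rowSums((A - matrix(fit, ncol = 3, byrow = TRUE))^2)))
  expect_equal(rmsd_mine, rmsd_bio3d, tolerance = 1e-6)
})

test_that("rotations are proper and optimal against random transforms", {
  set.seed(3)
  for (rep in 1:20) {
    A <- matrix(rnorm(18, sd = 5), 6, 3)
    B <- A + matrix(rnorm(18, sd = 0.5), 6, 3)
    tr <- kabsch_superpose(A, B)
    expect_lt(max(abs(crossprod(tr$R) - diag(3))), 1e-9)
    expect_equal(det(tr$R), 1, tolerance = 1e-9)
  }
  A <- matrix(rnorm(15, sd = 5), 5, 3)
  B <- A + matrix(rnorm(15, sd = 1), 5, 3)
  best <- kabsch_superpose(A, B)
  rmsd <- function(tr) sqrt(mean(rowSums((A - apply_transform(tr, B))^2)))
  r0 <- rmsd(best)
  for (rep in 1:1000) {
    rnd <- rigid_transform(rand_rotation_matrix(), rnorm(3, sd = 3),
                           check = FALSE)
    expect_gte(rmsd(rnd), r0 - 1e-12)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line),
               class = "sitematch_error_degenerate_points")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "sitematch_error_degenerate_points")
})

test_that("bottleneck distance is the exact pairwise maximum", {
  A <- matrix(rnorm(15), 5, 3)
  expect_equal(bottleneck_under_transform(rigid_transform(), A, A), 0)
  B <- A
  B[3, ] <- B[3, ] + c(2, 0, 0)
  expect_equal(bottleneck_under_transform(rigid_transform(), A, B), 2)
  set.seed(4)
  B2 <- A + matrix(rnorm(15, sd = 0.7), 5, 3)
  expect_equal(bottleneck_under_transform(rigid_transform(), A, B2),
               max(sqrt(rowSums((A - B2)^2))))
  expect_error(bottleneck_under_transform(rigid_transform(), A, B2[1:3, ]),
               class = "sitematch_error_length_mismatch")
})

test_that("transform algebra: inverse and symmetry of superposition", {
  set.seed(5)
  A <- matrix(rnorm(21, sd = 4), 7, 3)
  B <- A + matrix(rnorm(21, sd = 0.3), 7, 3)
  fwd <- kabsch_superpose(A, B)
  rev <- kabsch_superpose(B, A)
  expect_equal(rev$R, t(fwd$R), tolerance = 1e-6)
  expect_equal(bottleneck_under_transform(fwd, A, B),
               bottleneck_under_transform(rev, B, A), tolerance = 1e-6)
  inv <- invert_transform(fwd)
  comp <- compose_transforms(inv, fwd)
  expect_equal(comp$R, diag(3), tolerance = 1e-9)
  expect_equal(comp$t, c(0, 0, 0), tolerance = 1e-9)
})

test_that("refinement never worsens the seed and honours pure translations", {
  set.seed(6)
  A <- matrix(rnorm(18, sd = 4), 6, 3)
  seed <- rigid_transform() # identity on identical points: bottleneck exactly 0
  expect_identical(refine_transform(seed, A, A), seed)

  B2 <- A + matrix(rnorm(18, sd = 0.8), 6, 3)
  seed2 <- kabsch_superpose(A, B2)
  ref2 <- refine_transform(seed2, A, B2)
  expect_lte(bottleneck_under_transform(ref2, A, B2),
             bottleneck_under_transform(seed2, A, B2) + 1e-12)

  # 2-pair instance: the optimal translation centres the residual pair
  A3 <- rbind(c(0, 0, 0), c(10, 0, 0))
  B3 <- rbind(c(0.8, 0, 0), c(10, 0, 0)) # residuals (-0.8,0,0), (0,0,0)
  seed3 <- rigid_transform() # identity: bottleneck 0.8
  ref3 <- refine_transform(seed3, A3, B3, match_parameters(d = 1.5))
  # dense translation sampling says the best pure translation achieves 0.4
  expect_lte(bottleneck_under_transform(ref3, A3, B3), 0.4 + 0.1 * 1.5)
})

test_that("congruent windows are matched in full and breaks are trimmed", {
  set.seed(8)
  A <- matrix(runif(60, 0, 15), 20, 3)
  R <- rand_rotation_matrix()
  tt <- c(30, -5, 12)
  B <- sweep(A, 2, tt) %*% R # exact rigid copy
  params <- match_parameters(d = 1.5, min_pairs = 15)
  res <- find_matching_subsegments(mk_candidate(A, B), A, B, params)
  expect_length(res, 1)
  expect_equal(res[[1]]$range, c(1, 20))
  expect_lt(res[[1]]$bottleneck, 1e-6)
  expect_lt(max(abs(crossprod(res[[1]]$transform$R) - diag(3))), 1e-9)

  B_broken <- B
  B_broken[16:20, ] <- B_broken[16:20, ] + 10 # displace the tail
  res2 <- find_matching_subsegments(mk_candidate(A, B_broken), A, B_broken, params)
  expect_length(res2, 1)
  expect_equal(res2[[1]]$range, c(1, 15))

  B_jit <- B + matrix(rnorm(60, sd = 0.2), 20, 3)
  res3 <- find_matching_subsegments(mk_candidate(A, B_jit), A, B_jit, params)
  expect_length(res3, 1)
  expect_equal(res3[[1]]$range, c(1, 20))
  expect_lte(res3[[1]]$bottleneck, 1.1 * 1.5)
})

test_that("planted transforms within d are always certified within (1+eps)d", {
  set.seed(10)
  d <- 1.5
  params <- match_parameters(d = d, min_pairs = 3)
  for (rep in 1:30) {
    k <- sample(4:8, 1)
    inst <- planted_pair_instance(k, d = d)
    expect_lte(inst$bottleneck, d)
    res <- find_matching_subsegments(mk_candidate(inst$A, inst$B),
                                     inst$A, inst$B,
                                     match_parameters(d = d, min_pairs = k))
    expect_length(res, 1)
    expect_lte(res[[1]]$bottleneck, (1 + 0.1) * d)
  }
})
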