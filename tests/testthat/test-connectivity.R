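test_that("fisher z is atanh with saturation and odd symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  set.seed(71)
  r <- runif(50, -0.99, 0.99)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "domain")
})

test_that("seed mean series is the unweighted voxel mean", {
  set.seed(73)
  shape <- c(3, 3, 3); T <- 30
  dat <- matrix(rnorm(prod(shape) * T), T, prod(shape))
  bold <- volume4d(array(t(dat), c(shape, T)))
  one <- volume3d(array(c(1, rep(0, 26)), shape), role = "binary")
  expect_equal(seed_mean_timeseries(bold, one), dat[, 1])
  # two voxels with opposite series cancel
  dat2 <- dat; dat2[, 2] <- -dat2[, 1]
  b2 <- volume4d(array(t(dat2), c(shape, T)))
  two <- volume3d(array(c(1, 1, rep(0, 25)), shape), role = "binary")
  expect_equal(seed_mean_timeseries(b2, two), rep(0, T), tolerance = 1e-12)
  # arbitrary 10-voxel seed equals the brute-force mean
  vox <- sample(27, 10)
  m <- numeric(27); m[vox] <- 1
  expect_equal(seed_mean_timeseries(bold, volume3d(array(m, shape), role = "binary")),
               rowMeans(dat[, vox]))
  empty <- volume3d(array(0, shape), role = "binary")
  expect_error(seed_mean_timeseries(bold, empty), "empty seed")
})

test_that("seed-to-voxel maps saturate perfect correlation and mark degenerate voxels", {
  set.seed(75)
  shape <- c(3, 3, 3); T <- 40
  s <- rnorm(T)
  dat <- matrix(rnorm(prod(shape) * T), T, prod(shape))
  dat[, 1] <- s            # the seed voxel itself: r = 1
  dat[, 2] <- 7            # constant voxel: missing
  bold <- volume4d(array(t(dat), c(shape, T)))
  seed <- volume3d(array(c(1, rep(0, 26)), shape), role = "binary")
  fc <- seed_to_voxel_fc(bold, seed)
  expect_equal(fc$values[1], atanh(1 - 1e-7))
  expect_true(is.na(fc$values[2]))
  expect_true(all(is.finite(fc$values[-2])))
  cst <- volume4d(array(1, c(shape, T)))
  expect_error(seed_to_voxel_fc(cst, seed), "degenerate seed")
})

test_that("planted coupling is recovered at the Fisher-z closed form", {
  set.seed(77)
  T <- 200
  rho <- 0.6
  beta <- rho / sqrt(1 - rho^2)
  shape <- c(6, 6, 3)      # 108 voxels: 1 seed + 100 targets + spares
  dat <- matrix(rnorm(prod(shape) * T), T, prod(shape))
  s <- rnorm(T)
  dat[, 1] <- s
  for (j in 2:101) dat[, j] <- beta * s + rnorm(T)
  bold <- volume4d(array(t(dat), c(shape, T)))
  seed <- volume3d(array(c(1, rep(0, prod(shape) - 1)), shape), role = "binary")
  z <- seed_to_voxel_fc(bold, seed)$values[2:101]
  expect_lt(abs(mean(z) - atanh(0.6)), 0.05)
  # seed's own region outranks any disjoint region in mean z
  expect_gt(mean(z), mean(seed_to_voxel_fc(bold, seed)$values[102:107]))
})

test_that("paired contrasts are antisymmetric and match the looped t oracle", {
  set.seed(79)
  shape <- c(4, 4, 2); n <- 8
  mk_maps <- function() lapply(1:n, function(i)
    volume3d(array(rnorm(prod(shape)), shape), role = "fisherz"))
  A <- mk_maps(); B <- mk_maps()
  names(A) <- names(B) <- paste0("p", 1:n)
  ab <- paired_contrast_map(A, B)
  ba <- paired_contrast_map(B, A)
  expect_equal(ab$tmap$values, -ba$tmap$values)
  aa <- paired_contrast_map(A, A)
  expect_true(all(aa$tmap$values == 0))
  # voxelwise agreement with scalar paired_t
  for (v in sample(prod(shape), 12)) {
    xa <- vapply(A, function(m) m$values[v], numeric(1))
    xb <- vapply(B, function(m) m$values[v], numeric(1))
    expect_equal(ab$tmap$values[v], paired_t(xa, xb)$t, tolerance = 1e-10)
  }
  names(B)[1] <- "q1"
  expect_error(paired_contrast_map(A, B), "pairing mismatch")
})

test_that("6-connectivity cluster labelling finds face-connected components only", {
  supra <- array(FALSE, c(5, 5, 5))
  supra[1:2, 1, 1] <- TRUE           # size-2 cluster
  supra[4, 4, 4] <- TRUE             # singleton
  supra[5, 5, 5] <- TRUE             # diagonal neighbour of nothing: singleton
  lab <- label_clusters_6(supra)
  sizes <- sort(tabulate(lab[lab > 0]))
  expect_equal(sizes, c(1, 1, 2))
  # diagonal contact does not merge
  d <- array(FALSE, c(3, 3, 3)); d[1, 1, 1] <- TRUE; d[2, 2, 1] <- TRUE
  expect_equal(max(label_clusters_6(d)), 2)
  # a solid block is one cluster
  blk <- array(FALSE, c(4, 4, 4)); blk[2:3, 2:3, 2:3] <- TRUE
  expect_equal(max(label_clusters_6(blk)), 1)
})

test_that("permutation inference is seeded, order-invariant, and bounded below", {
  set.seed(81)
  shape <- c(8, 8, 4); n <- 10
  D <- matrix(rnorm(n * prod(shape)), n, prod(shape))
  D[, 1:30] <- D[, 1:30] + 1.6
  cfg <- inference_config(n_permutations = 500, rng_seed = 5)
  r1 <- permutation_cluster_fwe(D, shape, cfg)
  r2 <- permutation_cluster_fwe(D, shape, cfg)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p_fwe >= 1 / 501))
  # participant order leaves observed clusters unchanged; p-values agree up to
  # Monte-Carlo noise in the sign-flip null
  perm <- sample(n)
  r3 <- permutation_cluster_fwe(D[perm, ], shape, cfg)
  expect_equal(r3$clusters$size, r1$clusters$size)
  expect_equal(r3$clusters$p_fwe, r1$clusters$p_fwe, tolerance = 0.12)
  # permutations capped at 2^n distinct sign patterns
  small <- D[1:5, ]
  expect_warning(rs <- permutation_cluster_fwe(small, shape,
                   inference_config(n_permutations = 100, rng_seed = 1)),
                 "capping")
  expect_length(rs$null_max, 32)
})
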