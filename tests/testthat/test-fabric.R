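test_that("orientation sampling is unit-norm, uniform and deterministic", {
  o <- sample_orientations(2049, seed = 1)
  expect_equal(nrow(o), 2049)
  expect_true(all(abs(sqrt(rowSums(o^2)) - 1) < 1e-12))
  # second-moment uniformity: mean outer product ~ I/3
  M <- crossprod(o) / nrow(o)
  expect_lt(norm(M - diag(3) / 3, "F"), 1e-3)
  expect_identical(o, sample_orientations(2049, seed = 1))
  expect_false(identical(o, sample_orientations(2049, seed = 2)))
  expect_error(sample_orientations(5), "at least 9")
})

test_that("MIL on alternating slabs equals the slab spacing", {
  s <- 0.25
  vox <- array(FALSE, c(24, 24, 24))
  vox[, , seq(1, 24, by = 2)] <- TRUE
  v <- image_volume(vox, s)
  roi <- list(lo = c(3, 3, 3), hi = c(22, 22, 22))
  mil <- mean_intercept_length(v, roi, c(0, 0, 1), n_points = 200, seed = 2)
  expect_lt(abs(mil - s), s / 2)
})

test_that("phase-pure ROI raises an error", {
  v <- image_volume(array(TRUE, c(16, 16, 16)), 0.2)
  expect_error(mean_intercept_length(v, list(lo = c(2, 2, 2),
                                             hi = c(15, 15, 15)),
                                     c(0, 0, 1), 50, 1), "phase-pure")
})

test_that("MIL is stable under doubling the point count", {
  tv <- generate_trabecular_volume(bvf = 0.4, shape = c(64, 64, 64), seed = 7)
  roi <- list(lo = c(5, 5, 5), hi = c(60, 60, 60))
  dir <- c(0.36, -0.48, 0.8)
  m1 <- mean_intercept_length(tv, roi, dir, n_points = 400, seed = 3)
  m2 <- mean_intercept_length(tv, roi, dir, n_points = 800, seed = 3)
  expect_lt(abs(m2 - m1) / m1, 0.02)
})

test_that("optimized crossing counts match the brute-force oracle exactly", {
  set.seed(42)
  vol <- image_volume(array(stats::runif(16^3) > 0.6, c(16, 16, 16)),
                      c(0.2, 0.25, 0.3))
  roi <- list(lo = c(2, 2, 2), hi = c(15, 15, 15))
  dirs <- sample_orientations(13, seed = 5)
  pts <- paleofract:::.roi_points(vol, roi, 40, seed = 6)
  fast <- count_phase_crossings(vol, roi, dirs, pts)
  slow <- mil_crossings_oracle(vol, roi, dirs, pts)
  expect_identical(fast$crossings, as.integer(slow[, 2]))
  expect_equal(fast$total_length_mm, slow[, 1], tolerance = 1e-10)
})

test_that("fabric tensor fit inverts a known ellipsoid", {
  # forward-generate MIL from ellipsoid with axes 3 >= 2 >= 1 along a
  # rotated frame, then invert
  axes <- c(3, 2, 1)
  set.seed(8)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  H_true <- R %*% diag(1 / axes^2) %*% t(R)
  dirs <- sample_orientations(2049, seed = 3)
  mils <- 1 / sqrt(rowSums((dirs %*% H_true) * dirs))
  fab <- fit_fabric_tensor(dirs, mils)
  expect_lt(max(abs(fab$axes - axes) / axes), 0.01)
  for (k in 1:3) {
    ang <- acos(min(1, abs(sum(fab$eigenvectors[, k] * R[, k])))) * 180 / pi
    expect_lt(ang, 1)
  }
  expect_equal(degree_of_anisotropy(fab), 3, tolerance = 0.01)
})

test_that("constant MIL gives an isotropic tensor with DA 1", {
  dirs <- sample_orientations(256, seed = 2)
  fab <- fit_fabric_tensor(dirs, rep(0.7, 256))
  expect_equal(fab$axes, rep(0.7, 3), tolerance = 1e-8)
  expect_equal(fab$DA, 1, tolerance = 1e-8)
})

test_that("under-determined or degenerate direction sets are rejected", {
  dirs8 <- sample_orientations(16, seed = 1)[1:8, ]
  expect_error(fit_fabric_tensor(dirs8, rep(1, 8)), "rank error")
  # coplanar directions
  th <- seq(0, pi, length.out = 12)
  cop <- cbind(cos(th), sin(th), 0)
  expect_error(fit_fabric_tensor(cop, rep(1, 12)), "rank error")
})

test_that("alignment angle behaves at the extremes", {
  dirs <- sample_orientations(128, seed = 4)
  mils <- sqrt(1 / rowSums((dirs %*% diag(c(1 / 9, 1, 1))) * dirs))
  fab <- fit_fabric_tensor(dirs, mils)   # primary axis = x
  expect_lt(alignment_angle(fab, c(1, 0, 0)), 1)
  expect_gt(alignment_angle(fab, c(0, 0, 1)), 89)
  expect_lt(alignment_angle(fab, c(-1, 0, 0)), 1)  # antipodal-invariant
  expect_error(alignment_angle(fab, c(0, 0, 0)), "zero")
})

test_that("isotropic phantoms give DA near 1; aligned phantoms are recovered", {
  das <- vapply(1:5, function(sd) {
    tv <- generate_trabecular_volume(anisotropy_ratio = 1, bvf = 0.3,
                                     shape = c(64, 64, 64), seed = sd)
    fabric_analysis(tv, n_orientations = 128, n_points = 150, seed = sd)$DA
  }, 1)
  expect_true(all(das >= 1 & das <= 1.15))
  ax <- c(0, 0, 1)
  tv3 <- generate_trabecular_volume(axis = ax, anisotropy_ratio = 3,
                                    bvf = 0.3, shape = c(64, 64, 64), seed = 21)
  fab3 <- fabric_analysis(tv3, n_orientations = 128, n_points = 150, seed = 2)
  expect_gt(fab3$DA, 1.2)
  expect_lt(alignment_angle(fab3, ax), 10)
})

test_that("a grid-exact 90-degree rotation rotates the primary axis", {
  tv <- generate_trabecular_volume(axis = c(0, 0, 1), anisotropy_ratio = 3,
                                   bvf = 0.3, shape = c(64, 64, 64), seed = 13)
  fab_z <- fabric_analysis(tv, n_orientations = 256, n_points = 300, seed = 5)
  # rotate the volume 90 degrees about x: z -> y, y -> -z
  rot <- aperm(tv$voxels, c(1, 3, 2))
  rot <- rot[, , dim(rot)[3]:1]
  tvr <- image_volume(rot, tv$spacing)
  fab_y <- fabric_analysis(tvr, n_orientations = 256, n_points = 300, seed = 5)
  R90 <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  v_expect <- R90 %*% fab_z$eigenvectors[, 1]
  ang <- acos(min(1, abs(sum(v_expect * fab_y$eigenvectors[, 1])))) * 180 / pi
  expect_lt(ang, 2)
})
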