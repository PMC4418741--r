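test_that("iterative intermeans threshold reaches its fixed point", {
  expect_equal(iso_threshold(c(0, 0, 0, 10, 10, 10)), 5)
  # hand iteration for {0, 0, 10}: t0 = 10/3 -> (mean 0 + mean 10)/2 = 5,
  # and 5 is the fixed point
  expect_equal(iso_threshold(c(0, 0, 10)), 5)
  expect_error(iso_threshold(rep(3, 10)), "degenerate histogram")
  # any threshold splits into two non-empty classes
  x <- c(rnorm(50, 0), rnorm(50, 8))
  t <- iso_threshold(x)
  expect_gt(sum(x < t), 0)
  expect_gt(sum(x >= t), 0)
})

test_that("segmentation recovers planted classes", {
  sp <- phantom_spec(seed = 2)
  ph <- generate_phantom(sp)
  seg <- segment_materials(ph$volume, n_cancellous = 4,
                           thresholds = ph$truth$thresholds)
  truth <- ph$truth$material_labels
  # evaluate outside the noise-blurred class boundaries: exclude voxels
  # whose noiseless greyscale lies within 2.6 noise SDs of a classification
  # cut (there the Bayes error of any binning already exceeds 1%), and
  # exclude the planted dark features (they are not material classes)
  d <- dim(truth)
  clean_grey <- array(0, d)
  inb <- truth > 0
  clean_grey[inb] <- 100 * ph$truth$class_densities[truth[inb]]
  sigma <- sp$noise_sd_frac * max(ph$truth$class_densities) * 100
  margin <- apply(abs(outer(as.vector(clean_grey),
                            ph$truth$thresholds, "-")), 1, min)
  separable <- array(margin >= 2.6 * sigma, d)
  feat <- array(FALSE, d)
  feat[ph$truth$fracture_voxels] <- TRUE
  for (cv in ph$truth$crack_voxels) feat[cv] <- TRUE
  feat <- paleofract:::.binary_dilate(feat, 1L)
  eval_set <- inb & separable & !feat
  expect_gt(sum(eval_set), 1e4)
  acc <- mean(seg$labels[eval_set] == truth[eval_set])
  expect_gte(acc, 0.99)
})

test_that("noiseless phantom segments perfectly away from features", {
  sp <- phantom_spec(seed = 2, noise_sd_frac = 0, taphonomic_cracks = 0,
                     fracture_plane = NULL)
  ph <- generate_phantom(sp)
  seg <- segment_materials(ph$volume, 4, thresholds = ph$truth$thresholds,
                           background_cut = 50)
  truth <- ph$truth$material_labels
  inb <- truth > 0
  expect_equal(mean(seg$labels[inb] == truth[inb]), 1)
})

test_that("two-class segmentation and class-volume bookkeeping", {
  sp <- phantom_spec(seed = 5)
  ph <- generate_phantom(sp)
  seg <- segment_materials(ph$volume, n_cancellous = 1)
  expect_setequal(unique(seg$labels[seg$mask]), c(1L, 2L))
  # class volumes sum exactly to the mask volume
  expect_equal(sum(seg$class_volumes_mm3),
               sum(seg$mask) * prod(ph$volume$spacing))
  expect_error(segment_materials(ph$volume, n_cancellous = 0), "n_cancellous")
})

test_that("segmentation thresholds are monotone in the label ordering", {
  sp <- phantom_spec(seed = 6)
  ph <- generate_phantom(sp)
  seg <- segment_materials(ph$volume, 4, thresholds = ph$truth$thresholds)
  g <- ph$volume$voxels
  lab <- seg$labels
  # raising a threshold never moves a voxel to a denser (lower-id) class
  th2 <- seg$thresholds
  th2[2] <- th2[2] + 10
  seg2 <- segment_materials(ph$volume, 4, thresholds = th2)
  moved <- seg2$labels[seg$mask] - seg$labels[seg$mask]
  expect_true(all(moved >= 0))
})

test_that("crack detection and the published classification rule agree with ground truth", {
  for (sd in c(1, 4, 8)) {
    sp <- phantom_spec(seed = sd)
    ph <- generate_phantom(sp)
    seg <- segment_materials(ph$volume, 4, thresholds = ph$truth$thresholds)
    cr <- classify_cracks(detect_cracks(ph$volume, seg))
    expect_length(cr, length(ph$truth$crack_voxels))
    got <- rep(NA_character_, length(ph$truth$crack_voxels))
    widths <- rep(NA_real_, length(cr))
    for (i in seq_along(cr)) {
      ov <- vapply(ph$truth$crack_voxels,
                   function(s) length(intersect(cr[[i]]$voxels, s)), 1L)
      expect_gt(max(ov), 0)
      got[which.max(ov)] <- cr[[i]]$classification
      widths[which.max(ov)] <- cr[[i]]$median_width
    }
    expect_identical(got, ph$truth$crack_class)
    # planted 2-voxel fracture measures close to 2 voxels wide
    expect_gte(widths[1], 1.5)
    expect_lte(widths[1], 2.5)
  }
})

test_that("unbroken phantom yields no crack components", {
  sp <- phantom_spec(seed = 3, taphonomic_cracks = 0, fracture_plane = NULL)
  ph <- generate_phantom(sp)
  seg <- segment_materials(ph$volume, 4, thresholds = ph$truth$thresholds)
  expect_length(detect_cracks(ph$volume, seg), 0)
})

test_that("crack detection is invariant under affine greyscale rescaling", {
  sp <- phantom_spec(seed = 9)
  ph <- generate_phantom(sp)
  v2 <- ph$volume
  v2$voxels <- 3.7 * v2$voxels + 55
  seg1 <- segment_materials(ph$volume, 4, thresholds = ph$truth$thresholds)
  seg2 <- segment_materials(v2, 4, thresholds = 3.7 * ph$truth$thresholds + 55)
  cr1 <- classify_cracks(detect_cracks(ph$volume, seg1))
  cr2 <- classify_cracks(detect_cracks(v2, seg2))
  expect_equal(length(cr1), length(cr2))
  for (i in seq_along(cr1)) {
    expect_identical(sort(cr1[[i]]$voxels), sort(cr2[[i]]$voxels))
    expect_identical(cr1[[i]]$classification, cr2[[i]]$classification)
  }
})

test_that("the width/surface rule itself follows the published wording", {
  mk <- function(w, surf) structure(list(voxels = 1:100, median_width = w,
                                         touches_surface = surf > 0,
                                         surface_fraction = surf,
                                         classification = NA_character_),
                                    class = "crack_component")
  out <- classify_cracks(list(mk(2, 0), mk(5, 0.3), mk(2, 0.3), mk(4, 0)))
  expect_identical(vapply(out, `[[`, "", "classification"),
                   c("pathologic", "preservational", "preservational",
                     "preservational"))
})
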