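#' Quasi-uniform orientations on the hemisphere
#'
#' Generates `n` unit vectors from a Fibonacci (golden-angle) lattice on the
#' upper hemisphere (antipodal directions are equivalent for intercept
#' counting), rigidly rotated by a seeded uniform random rotation so that no
#' lattice direction is axis-locked.
#'
#' @param n number of orientations (>= 9).
#' @param seed integer seed for the random rotation.
#' @return n x 3 matrix of unit vectors.
#' @examples
#' o <- sample_orientations(64, seed = 1)
#' range(sqrt(rowSums(o^2)))
#' @export
sample_orientations <- function(n, seed = 1L) {
  if (n < 9) stop("need at least 9 orientations")
  i <- seq_len(n) - 1
  z <- (i + 0.5) / n
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r <- sqrt(1 - z^2)
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  set.seed(seed)
  R <- .random_rotation()
  pts %*% t(R)
}

.random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Default central analysis region of interest
#'
#' A box of the given physical dimensions centred at a chosen fraction along
#' each axis of the volume. The default box (5.92 x 6.50 x 4.23 mm) mirrors
#' the standard proximal-end cancellous analysis window.
#'
#' @param volume an [image_volume()].
#' @param size_mm physical box dimensions (mm).
#' @param centre_frac centre as a fraction of each axis extent.
#' @return list with `lo` and `hi`, 1-based inclusive voxel index bounds.
#' @export
default_roi <- function(volume, size_mm = c(5.92, 6.50, 4.23),
                        centre_frac = c(0.5, 0.5, 0.5)) {
  d <- dim(volume$voxels)
  half <- size_mm / volume$spacing / 2
  ctr <- centre_frac * (d - 1) + 1
  lo <- pmax(1L, as.integer(round(ctr - half)))
  hi <- pmin(d, as.integer(round(ctr + half)))
  if (any(hi <= lo)) stop("ROI is empty for this volume")
  list(lo = lo, hi = hi)
}

# seeded uniform points strictly inside the ROI box (world mm)
.roi_points <- function(volume, roi, n_points, seed) {
  set.seed(seed)
  sp <- volume$spacing
  lo <- (roi$lo - 1 - 0.49) * sp
  hi <- (roi$hi - 1 + 0.49) * sp
  cbind(stats::runif(n_points, lo[1], hi[1]),
        stats::runif(n_points, lo[2], hi[2]),
        stats::runif(n_points, lo[3], hi[3]))
}

#' Phase-crossing counts along test lines
#'
#' For each direction, full test lines are cast through the seed points
#' across the ROI and bone/void transitions between consecutive visited
#' voxels are counted by an incremental voxel-traversal walk.
#'
#' @param volume a binary [image_volume()] (TRUE/nonzero = bone).
#' @param roi list with `lo`/`hi` 1-based inclusive index bounds
#'   (see [default_roi()]).
#' @param directions m x 3 matrix of unit vectors.
#' @param points n x 3 matrix of world coordinates (mm) inside the ROI.
#' @return data.frame with per-direction `total_length_mm` and `crossings`.
#' @export
count_phase_crossings <- function(volume, roi, directions, points) {
  vox <- volume$voxels
  if (!is.logical(vox)) vox <- vox != 0
  directions <- matrix(directions, ncol = 3)
  res <- mil_crossings_cpp(as.logical(vox), dim(volume$voxels),
                           as.numeric(volume$spacing),
                           as.matrix(points), directions,
                           as.integer(roi$lo - 1L), as.integer(roi$hi - 1L))
  data.frame(total_length_mm = res$total_length_mm, crossings = res$crossings)
}

#' Mean intercept length along one direction
#'
#' MIL(direction) = total test-line length within the ROI divided by the
#' number of bone/void phase crossings, with lines cast through `n_points`
#' seeded interior points along both senses of the direction. Lengths are in
#' mm via the voxel spacing.
#'
#' @param volume binary [image_volume()].
#' @param roi ROI index bounds (see [default_roi()]).
#' @param direction unit vector.
#' @param n_points number of seed points.
#' @param seed integer seed for point placement.
#' @return MIL in mm.
#' @export
mean_intercept_length <- function(volume, roi, direction, n_points = 2000L,
                                  seed = 1L) {
  direction <- direction / sqrt(sum(direction^2))
  pts <- .roi_points(volume, roi, n_points, seed)
  res <- count_phase_crossings(volume, roi, rbind(direction), pts)
  if (res$crossings[1] == 0)
    stop("phase-pure ROI along direction: no bone/void crossings")
  res$total_length_mm[1] / res$crossings[1]
}

#' Fit the MIL fabric tensor
#'
#' Least-squares fit of the MIL ellipsoid `n' H n = 1 / MIL(n)^2` over the
#' sampled directions. Fabric semi-axis magnitudes are `1/sqrt(eigenvalues
#' of H)` sorted in decreasing order, with the corresponding orthonormal
#' eigenvectors; the degree of anisotropy is the primary/tertiary ratio.
#'
#' @param directions m x 3 matrix of unit vectors (m >= 9, non-coplanar).
#' @param mils MIL values (mm), one per direction.
#' @param n_points number of seed points used (recorded only).
#' @return object of class `fabric_tensor`: fields `tensor` (H), `axes`
#'   (t1 >= t2 >= t3), `eigenvectors` (columns, matching `axes`), `DA`,
#'   `n_orientations`, `n_points`.
#' @export
fit_fabric_tensor <- function(directions, mils, n_points = NA_integer_) {
  directions <- matrix(directions, ncol = 3)
  if (nrow(directions) < 9) stop("rank error: need >= 9 directions")
  if (length(mils) != nrow(directions)) stop("one MIL per direction required")
  ok <- is.finite(mils) & mils > 0
  directions <- directions[ok, , drop = FALSE]
  mils <- mils[ok]
  A <- cbind(directions[, 1]^2, directions[, 2]^2, directions[, 3]^2,
             2 * directions[, 1] * directions[, 2],
             2 * directions[, 1] * directions[, 3],
             2 * directions[, 2] * directions[, 3])
  if (qr(A)$rank < 6) stop("rank error: directions are degenerate (coplanar)")
  b <- 1 / mils^2
  h <- qr.solve(A, b)
  H <- matrix(c(h[1], h[4], h[5],
                h[4], h[2], h[6],
                h[5], h[6], h[3]), 3, 3)
  ev <- eigen(H, symmetric = TRUE)       # eigenvalues decreasing
  if (any(ev$values <= 0))
    stop("fitted fabric tensor is not positive definite")
  axes <- rev(1 / sqrt(ev$values))       # t1 >= t2 >= t3
  vecs <- ev$vectors[, 3:1, drop = FALSE]
  structure(list(tensor = H, axes = axes, eigenvectors = vecs,
                 DA = axes[1] / axes[3],
                 n_orientations = nrow(directions),
                 n_points = n_points),
            class = "fabric_tensor")
}

#' @export
print.fabric_tensor <- function(x, ...) {
  cat(sprintf("fabric_tensor: axes %s, DA = %.3f (%d orientations)\n",
              paste(signif(x$axes, 4), collapse = " >= "), x$DA,
              x$n_orientations))
  invisible(x)
}

#' Degree of anisotropy
#'
#' Ratio of the primary to tertiary fabric semi-axis; 1 for an isotropic
#' architecture.
#'
#' @param fabric a `fabric_tensor`.
#' @return dimensionless scalar >= 1.
#' @export
degree_of_anisotropy <- function(fabric) fabric$axes[1] / fabric$axes[3]

#' Angle between the primary fabric axis and a reference axis
#'
#' Antipodal-invariant angle in degrees, in [0, 90].
#'
#' @param fabric a `fabric_tensor`.
#' @param axis reference unit vector (e.g. the bone long axis).
#' @return angle in degrees.
#' @export
alignment_angle <- function(fabric, axis) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("parameter error: zero reference axis")
  axis <- axis / nrm
  v <- fabric$eigenvectors[, 1]
  acos(pmin(1, abs(sum(v * axis)))) * 180 / pi
}

#' Full fabric analysis of a binary volume
#'
#' Samples orientations, measures MIL along each, fits the fabric tensor
#' and reports the degree of anisotropy.
#'
#' @param volume binary [image_volume()].
#' @param roi ROI bounds; default [default_roi()] of the volume.
#' @param n_orientations number of test directions.
#' @param n_points seed points per analysis.
#' @param seed integer seed (orientation rotation and point placement).
#' @return a `fabric_tensor`.
#' @export
fabric_analysis <- function(volume, roi = NULL, n_orientations = 512L,
                            n_points = 500L, seed = 1L) {
  if (is.null(roi)) roi <- default_roi(volume)
  dirs <- sample_orientations(n_orientations, seed = seed)
  pts <- .roi_points(volume, roi, n_points, seed = seed + 1L)
  res <- count_phase_crossings(volume, roi, dirs, pts)
  if (all(res$crossings == 0))
    stop("phase-pure ROI along direction: no bone/void crossings")
  mil <- ifelse(res$crossings > 0, res$total_length_mm / res$crossings, NA)
  fit_fabric_tensor(dirs, mil, n_points = n_points)
}

#' Serialise a fabric report to JSON
#' @param fabric a `fabric_tensor`
#' @param path output file
#' @param extra named list of extra fields (e.g. settings, alignment angle)
#' @return `path`, invisibly
#' @export
write_fabric_report <- function(fabric, path, extra = list()) {
  rep <- c(list(tensor = fabric$tensor, axes = fabric$axes,
                eigenvectors = fabric$eigenvectors, DA = fabric$DA,
                n_orientations = fabric$n_orientations,
                n_points = fabric$n_points), extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
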