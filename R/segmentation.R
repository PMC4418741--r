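#' Iterative intermeans (ISODATA) threshold
#'
#' Adaptive iterative thresholding of a greyscale sample: the threshold is
#' the fixed point of `t <- (mean(x[x < t]) + mean(x[x >= t])) / 2`,
#' initialised at the sample mean.
#'
#' @param values numeric sample with at least two distinct values.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the threshold.
#' @return the converged threshold (numeric scalar).
#' @examples
#' iso_threshold(c(0, 0, 0, 10, 10, 10))  # 5
#' @export
iso_threshold <- function(values, max_iter = 100L, tol = 1e-10) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2) stop("degenerate histogram")
  t <- mean(values)
  for (i in seq_len(max_iter)) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (length(lo) == 0 || length(hi) == 0) return(t)
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  warning("iso_threshold: iteration cap reached")
  t
}

#' Segment a greyscale volume into cortical and cancellous density classes
#'
#' Voxels above a background cut form the bone mask (after morphological
#' closing, so dark internal cracks stay inside the mask). Within the mask,
#' voxels are binned by greyscale into 1 + `n_cancellous` classes: label 1 is
#' cortical (brightest), labels 2 .. `n_cancellous` + 1 are cancellous in
#' decreasing density order; label 0 is background. With explicit
#' `thresholds` (strictly decreasing greyscale cuts, one fewer than the class
#' count) classification is exact binning; otherwise cuts default to
#' equal-count quantiles of the within-bone histogram.
#'
#' @param volume an [image_volume()].
#' @param n_cancellous number of cancellous classes (>= 1).
#' @param thresholds optional explicit decreasing greyscale cuts.
#' @param background_cut greyscale cut separating bone from background;
#'   default is the ISODATA threshold of the full volume.
#' @param closing_radius radius (voxels) of the chessboard closing applied
#'   to the bone mask.
#' @return list of class `segmentation_result`: `labels` (array),
#'   `thresholds`, `background_cut`, `mask`, `class_volumes_mm3`.
#' @export
segment_materials <- function(volume, n_cancellous = 4, thresholds = NULL,
                              background_cut = NULL, closing_radius = 2L) {
  if (n_cancellous < 1) stop("parameter error: n_cancellous must be >= 1")
  g <- volume$voxels
  if (is.null(background_cut)) background_cut <- iso_threshold(as.numeric(g))
  mask <- g > background_cut
  if (!any(mask)) stop("bone mask is empty")
  if (closing_radius > 0) mask <- .binary_close(mask, closing_radius)
  K <- n_cancellous + 1L
  vals <- g[mask]
  if (is.null(thresholds)) {
    thresholds <- stats::quantile(vals, probs = rev(seq_len(K - 1)) / K,
                                  names = FALSE)
  }
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != K - 1 || any(diff(thresholds) >= 0))
    stop("thresholds must be strictly decreasing, one fewer than class count")
  labels <- array(0L, dim(g))
  # label 1 = brightest (cortical); increasing label = darker
  labels[mask] <- K - findInterval(vals, sort(thresholds))
  voxvol <- prod(volume$spacing)
  cv <- as.numeric(table(factor(labels[mask], levels = seq_len(K)))) * voxvol
  structure(list(labels = labels, thresholds = thresholds,
                 background_cut = background_cut, mask = mask,
                 closing_radius = as.integer(closing_radius),
                 class_volumes_mm3 = cv),
            class = "segmentation_result")
}

# chessboard (26-neighbourhood) dilation/erosion by array shifting
.shift3 <- function(a, dx, dy, dz, fill) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  kx <- sx >= 1 & sx <= d[1]; ky <- sy >= 1 & sy <= d[2]; kz <- sz >= 1 & sz <= d[3]
  out[xs[kx], ys[ky], zs[kz]] <- a[sx[kx], sy[ky], sz[kz]]
  out
}

.binary_dilate <- function(mask, r) {
  for (i in seq_len(r)) {
    acc <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      acc <- acc | .shift3(mask, dx, dy, dz, FALSE)
    }
    mask <- acc
  }
  mask
}

.binary_erode <- function(mask, r, outside = FALSE) {
  # `outside` gives the value assumed beyond the array (FALSE = background)
  for (i in seq_len(r)) {
    acc <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      acc <- acc & .shift3(mask, dx, dy, dz, outside)
    }
    mask <- acc
  }
  mask
}

.binary_close <- function(mask, r) .binary_erode(.binary_dilate(mask, r), r,
                                                 outside = TRUE)

#' Detect dark crack components inside segmented bone
#'
#' Cracks (pathologic or preservational) appear as sharply darker voxels than
#' the surrounding bone. Candidate voxels are those inside the bone mask with
#' greyscale below `mean - k * sd` of the within-bone values; candidates are
#' grouped into 26-connected components. Per component the median width is
#' measured by a chessboard distance transform (2 x median distance to the
#' component boundary), and surface contact is flagged for voxels
#' 26-adjacent to background.
#'
#' @param volume an [image_volume()].
#' @param segmentation a `segmentation_result` for the same volume.
#' @param k darkness cut in SD units (default 2).
#' @param min_voxels discard components smaller than this (noise).
#' @return list of `crack_component`s: each has `voxels` (linear indices),
#'   `median_width` (voxels), `touches_surface`, `surface_fraction`,
#'   `classification` (NA until [classify_cracks()]).
#' @export
detect_cracks <- function(volume, segmentation, k = 2, min_voxels = 30L) {
  g <- volume$voxels
  mask <- segmentation$mask
  bone_vals <- g[mask & segmentation$labels > 0L]
  cut <- mean(bone_vals) - k * stats::sd(bone_vals)
  # the outermost mask layers are dropped: morphological closing of a bumpy
  # voxelized surface adds a dark rind up to `closing_radius` deep that would
  # bridge distinct cracks into one spurious surface-spanning component
  core <- .binary_erode(mask, segmentation$closing_radius)
  cand <- core & g < cut
  idx <- which(cand)
  if (length(idx) == 0) return(list())
  comp <- .connected_components(cand, idx)
  # surface contact: candidate voxel 26-adjacent to outside-core
  near_bg <- .binary_dilate(!core, 1L) & cand
  nb_idx <- which(near_bg)
  out <- list()
  ci <- 0L
  for (cid in seq_len(max(comp$membership))) {
    vox <- idx[comp$membership == cid]
    if (length(vox) < min_voxels) next
    ci <- ci + 1L
    dt <- .chessboard_dt(cand, vox)
    sf <- mean(vox %in% nb_idx)
    out[[ci]] <- structure(list(voxels = vox,
                                median_width = 2 * stats::median(dt),
                                touches_surface = sf > 0,
                                surface_fraction = sf,
                                classification = NA_character_),
                           class = "crack_component")
  }
  out
}

# connected components (26-neighbourhood) of TRUE voxels, via igraph
.connected_components <- function(mask, idx = which(mask)) {
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * (d[1] * d[2]) + (pos[, 2] - 1) * d[1] + pos[, 1]
  lookup <- match(key, key)  # identity; use match on shifted keys below
  edges <- list(); ei <- 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  offs <- offs[1:13, ]  # half the neighbourhood suffices for undirected edges
  for (r in seq_len(nrow(offs))) {
    np <- cbind(pos[, 1] + offs$dx[r], pos[, 2] + offs$dy[r], pos[, 3] + offs$dz[r])
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    nk <- (np[ok, 3] - 1) * (d[1] * d[2]) + (np[ok, 2] - 1) * d[1] + np[ok, 1]
    mt <- match(nk, key)
    hit <- !is.na(mt)
    if (any(hit)) {
      ei <- ei + 1L
      edges[[ei]] <- cbind(which(ok)[hit], mt[hit])
    }
  }
  n <- length(idx)
  if (ei == 0)
    return(list(membership = seq_len(n)))
  el <- do.call(rbind, edges)
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
  igraph::components(gr)
}

# chessboard distance (in voxels) from each of `vox` to the complement of
# `mask`, computed by successive 26-neighbourhood erosion; cracks are thin so
# few passes are needed
.chessboard_dt <- function(mask, vox) {
  sub <- array(FALSE, dim(mask)); sub[vox] <- TRUE
  dt <- rep(0L, length(vox))
  cur <- sub
  for (dist in 1:64) {
    cur <- .binary_erode(cur, 1L)
    alive <- cur[vox]
    dt[!alive & dt == 0L] <- dist
    if (!any(alive)) return(dt)
  }
  dt[dt == 0L] <- 65L
  dt
}

#' Classify crack components as pathologic or preservational
#'
#' Applies the published field rule: preservational (taphonomic) fractures
#' extend to the bone surface and are typically several voxels across,
#' whereas the pathologic fracture is narrow (about two voxels) and
#' subsurface. A component is pathologic iff its median width is at most
#' `width_cut` voxels and its surface contact does not exceed a small
#' allowance (the pathologic plane may near the surface over a tiny patch).
#'
#' @param components output of [detect_cracks()].
#' @param width_cut width threshold in voxels (default 2.5).
#' @param surface_allowance maximum fraction of component voxels in contact
#'   with the surface for a pathologic call (default 0.01).
#' @return the components with `classification` filled in.
#' @export
classify_cracks <- function(components, width_cut = 2.5,
                            surface_allowance = 0.01) {
  lapply(components, function(cc) {
    narrow <- cc$median_width <= width_cut
    interior <- cc$surface_fraction <= surface_allowance
    cc$classification <- if (narrow && interior) "pathologic" else "preservational"
    cc
  })
}

#' Crack report table
#'
#' @param components classified crack components.
#' @return data.frame with one row per component (id, voxel count, median
#'   width, surface flag and fraction, classification).
#' @export
crack_report <- function(components) {
  if (length(components) == 0)
    return(data.frame(id = integer(0), n_voxels = integer(0),
                      median_width = numeric(0), touches_surface = logical(0),
                      surface_fraction = numeric(0),
                      classification = character(0)))
  data.frame(id = seq_along(components),
             n_voxels = vapply(components, function(x) length(x$voxels), 1L),
             median_width = vapply(components, function(x) x$median_width, 1),
             touches_surface = vapply(components, function(x) x$touches_surface, TRUE),
             surface_fraction = vapply(components, function(x) x$surface_fraction, 1),
             classification = vapply(components, function(x) x$classification, ""))
}
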