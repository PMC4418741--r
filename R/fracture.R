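#' Fracture surface from the planted paraboloid patch
#'
#' Builds the discrete fracture surface of a phantom on a given mesh: the
#' elements whose centroids lie within `band` of the paraboloid
#' `z = z0 - c r^2`, with the analytic unit normal of the paraboloid at each
#' centroid and the slip direction (distal displacement of the external
#' fragment) as the in-plane component of the distal axis direction.
#'
#' @param mesh a [tet_mesh()] of the phantom bone.
#' @param spec the [phantom_spec()] that generated it (must carry a
#'   `fracture_plane`).
#' @param band capture half-thickness (mm); default one mean element edge.
#' @return a `fracture_surface`: `element_ids`, `points` (centroids, mm),
#'   `normals` (unit rows), `slip` (unit rows, perpendicular to normals).
#' @export
fracture_surface_from_spec <- function(mesh, spec, band = NULL) {
  fp <- spec$fracture_plane
  if (is.null(fp)) stop("spec has no fracture plane")
  L <- spec$length
  r_endo <- spec$outer_radius - spec$cortical_thickness
  z0 <- fp$apex_z_frac * L
  rmax <- fp$r_max_frac * r_endo
  if (is.null(band)) band <- mean_edge_length(mesh)
  cen <- tet_centroids(mesh)
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  zsurf <- z0 - fp$curvature * r^2
  dist <- abs(cen[, 3] - zsurf) / sqrt(1 + (2 * fp$curvature * r)^2)
  inwin <- .azimuth_dist(cen[, 1], cen[, 2], fp$azimuth_deg) <=
    fp$azimuth_halfwidth_deg
  sel <- which(dist <= band & r <= rmax & r >= 0.15 * rmax & inwin)
  if (length(sel) == 0) stop("fracture surface captures no elements")
  rs <- pmax(r[sel], 1e-9)
  # gradient of F = z - z0 + c r^2 gives the (upward) surface normal
  nrm <- cbind(2 * fp$curvature * cen[sel, 1],
               2 * fp$curvature * cen[sel, 2],
               rep(1, length(sel)))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # slip: distal (-z) direction projected into the plane
  slip <- cbind(0, 0, -1) [rep(1, length(sel)), , drop = FALSE]
  slip <- slip - nrm * rowSums(slip * nrm)
  ns <- sqrt(rowSums(slip^2))
  flat <- ns < 1e-6   # at the apex the surface is horizontal; slip radial-in
  if (any(flat)) {
    slip[flat, ] <- cbind(-cen[sel[flat], 1], -cen[sel[flat], 2], 0) / rs[flat]
    ns[flat] <- sqrt(rowSums(slip[flat, , drop = FALSE]^2))
  }
  slip <- slip / ns
  structure(list(element_ids = sel, points = cen[sel, , drop = FALSE],
                 normals = nrm, slip = slip),
            class = "fracture_surface")
}

#' Mean element edge length (mm)
#' @param mesh a [tet_mesh()]
#' @return scalar mm
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh$elements
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  tot <- 0
  for (k in seq_len(nrow(pairs))) {
    d <- mesh$nodes[e[, pairs[k, 1]], , drop = FALSE] -
      mesh$nodes[e[, pairs[k, 2]], , drop = FALSE]
    tot <- tot + sum(sqrt(rowSums(d^2)))
  }
  tot / (6 * nrow(e))
}

# minimum distance of each query point to the surface point set
.min_dist_to_surface <- function(points, surface) {
  sp <- surface$points
  out <- numeric(nrow(points))
  chunk <- 2000L
  for (s in seq(1, nrow(points), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(points))
    d2 <- outer(rowSums(points[idx, , drop = FALSE]^2), rowSums(sp^2), "+") -
      2 * points[idx, , drop = FALSE] %*% t(sp)
    out[idx] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Strain-localization criterion (C1)
#'
#' The fracture-consistent loading regime concentrates high von Mises
#' strain along the fracture, spatially restricted to - but also spanning -
#' the fracture's extent. High-strain elements H are those at or above
#' `peak_frac` of the maximum von Mises strain within the proximal half of
#' the bone, matching how high-strain regions read off a contour plot; for
#' a spatially uniform field H is the whole proximal half and C1 reduces to
#' the baseline fraction of proximal elements near the surface.
#' Two fractions are combined: `precision`, the fraction of H lying within
#' distance `d` of the fracture surface (restriction), and `coverage`, the
#' fraction of fracture-surface samples with an H element within `d`
#' (alignment with the full extent; a concentrated point load lights up one
#' spot of the surface and fails this part). C1 = precision x coverage.
#'
#' @param result an `fe_result`.
#' @param surface a `fracture_surface`.
#' @param mesh the analysed [tet_mesh()].
#' @param peak_frac high-strain cut as a fraction of the proximal peak
#'   strain (default 0.5).
#' @param d capture distance (mm); default 1.5 x mean element edge.
#' @return C1 in [0, 1], with attributes `precision` and `coverage`.
#' @export
strain_localization_score <- function(result, surface, mesh,
                                      peak_frac = 0.5, d = NULL) {
  if (is.null(d)) d <- 1.5 * mean_edge_length(mesh)
  cen <- tet_centroids(mesh)
  z <- cen[, 3]
  prox <- z >= (min(z) + max(z)) / 2
  vm <- result$von_mises_strain
  H <- which(prox & vm >= peak_frac * max(vm[prox]))
  if (length(H) == 0) stop("degenerate field: no high-strain elements")
  dist <- .min_dist_to_surface(cen[H, , drop = FALSE], surface)
  precision <- mean(dist <= d)
  # coverage: distance from each surface sample to the nearest H centroid
  dist_s <- .min_dist_to_surface(surface$points,
                                 list(points = cen[H, , drop = FALSE]))
  coverage <- mean(dist_s <= d)
  c1 <- precision * coverage
  attr(c1, "precision") <- precision
  attr(c1, "coverage") <- coverage
  c1
}

#' Shear-consistency criterion (C2)
#'
#' Scores whether the principal stress field near the fracture surface is
#' consistent with shear failure along it with the observed slip sense:
#' the maximum principal stress s11 should sit at a high angle to the
#' fracture plane, the minimum principal stress s33 at a low angle, and the
#' intermediate s22 should lie in the plane and perpendicular to the slip
#' direction. C2 is the mean of the three indicator fractions over elements
#' within `d` of the surface. Elements with degenerate (near-hydrostatic)
#' principal directions are counted as non-consistent and flagged.
#'
#' @param result an `fe_result`.
#' @param surface a `fracture_surface`.
#' @param mesh the analysed [tet_mesh()].
#' @param d capture distance (mm); default 1.5 x mean element edge.
#' @param high_angle s11-to-plane threshold (degrees, default 45).
#' @param low_angle s33-to-plane threshold (degrees, default 45).
#' @param inplane_angle s22-to-plane threshold (degrees, default 30).
#' @param perp_slip_angle minimum s22-to-slip angle (degrees, default 60).
#' @param context optional precomputed [near_surface_context()] (the
#'   near-surface element set is load-independent).
#' @return C2 in [0, 1], with attributes `fractions` and `degenerate_frac`.
#' @export
shear_consistency_score <- function(result, surface, mesh, d = NULL,
                                    high_angle = 45, low_angle = 45,
                                    inplane_angle = 30, perp_slip_angle = 60,
                                    context = NULL) {
  if (is.null(context)) context <- near_surface_context(mesh, surface, d)
  near <- context$near
  pf <- principal_stress_field(result$stress[near, , drop = FALSE])
  n_loc <- context$normals
  s_loc <- context$slip
  ang_plane <- function(dirs_col) {   # angle of direction to the plane
    v <- t(dirs_col)
    asin(pmin(1, abs(rowSums(v * n_loc)))) * 180 / pi
  }
  a11 <- ang_plane(pf$directions[, 1, ])
  a33 <- ang_plane(pf$directions[, 3, ])
  a22 <- ang_plane(pf$directions[, 2, ])
  v2 <- t(pf$directions[, 2, ])
  a22_slip <- acos(pmin(1, abs(rowSums(v2 * s_loc)))) * 180 / pi
  ok <- !pf$degenerate
  f1 <- mean(ok & a11 >= high_angle)
  f2 <- mean(ok & a33 <= low_angle)
  f3 <- mean(ok & a22 <= inplane_angle & a22_slip >= perp_slip_angle)
  c2 <- mean(c(f1, f2, f3))
  attr(c2, "fractions") <- c(s11_high = f1, s33_low = f2, s22_inplane_perp = f3)
  attr(c2, "degenerate_frac") <- mean(!ok)
  c2
}

#' Near-surface element context for criterion scoring
#'
#' Elements within `d` of the fracture surface, each with the normal and
#' slip direction of its nearest surface sample. Load-independent, so it is
#' computed once per mesh/surface pair and reused across candidates.
#'
#' @param mesh a [tet_mesh()].
#' @param surface a `fracture_surface`.
#' @param d capture distance (mm); default 1.5 x mean element edge.
#' @return list with `near` (element ids), `normals`, `slip`.
#' @export
near_surface_context <- function(mesh, surface, d = NULL) {
  if (is.null(d)) d <- 1.5 * mean_edge_length(mesh)
  cen <- tet_centroids(mesh)
  dist <- .min_dist_to_surface(cen, surface)
  near <- which(dist <= d)
  if (length(near) == 0) stop("empty near-surface element set")
  sp <- surface$points
  nn <- vapply(near, function(i) {
    d2 <- (sp[, 1] - cen[i, 1])^2 + (sp[, 2] - cen[i, 2])^2 +
      (sp[, 3] - cen[i, 3])^2
    which.min(d2)
  }, 1L)
  list(near = near, normals = surface$normals[nn, , drop = FALSE],
       slip = surface$slip[nn, , drop = FALSE])
}

#' Candidate loading-regime grids for the fracture search
#'
#' Patch centres are placed on the outer surface of the proximal third of
#' the bone (rings of azimuths at several heights); directions sample a
#' cone around the distally-directed long axis in steps of `cone_step`
#' degrees.
#'
#' @param mesh a [tet_mesh()].
#' @param n_centres approximate number of patch centres (default 12).
#' @param cone_half_angle maximum tilt from the distal axis (degrees).
#' @param cone_step tilt step (degrees, default 15).
#' @return list with `centres` (k x 3 mm) and `directions` (q x 3 unit).
#' @export
candidate_grids <- function(mesh, n_centres = 12, cone_half_angle = 30,
                            cone_step = 15) {
  z <- mesh$nodes[, 3]
  zmin <- min(z); L <- diff(range(z))
  R <- max(sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2))
  n_h <- max(1L, round(n_centres / 4))
  hs <- zmin + L * (1 - seq_len(n_h) / (n_h + 1) * (1 / 3))
  az <- c(0, 90, 180, 270) * pi / 180
  centres <- do.call(rbind, lapply(hs, function(h)
    cbind(R * cos(az), R * sin(az), h)))
  tilts <- seq(0, cone_half_angle, by = cone_step) * pi / 180
  dirs <- list(c(0, 0, -1))
  for (tl in tilts[tilts > 0]) {
    n_az <- max(8, round(8 * tl / tilts[2]))
    ph <- 2 * pi * (seq_len(n_az) - 1) / n_az
    dirs <- c(dirs, lapply(ph, function(p)
      c(sin(tl) * cos(p), sin(tl) * sin(p), -cos(tl))))
  }
  list(centres = centres, directions = do.call(rbind, dirs))
}

#' Grid search for the fracture-causing loading regime
#'
#' Systematises the iterative trial-and-error search for a loading regime
#' whose strain and stress fields are consistent with an observed fracture
#' surface: every combination of patch centre and force direction is solved
#' (one factorisation, many right-hand sides; by linearity the magnitude
#' does not affect the ranking) and scored by the two field criteria. The
#' combined score is `C1 * C2`.
#'
#' @param mesh a [tet_mesh()] with `material_id`.
#' @param materials per-element `E`/`nu` list (see [material_props()]).
#' @param surface a `fracture_surface`.
#' @param grids candidate grids from [candidate_grids()].
#' @param magnitude applied force (N, default 56.1); irrelevant to ranking.
#' @param patch_radius load patch radius (mm); default a quarter of the
#'   bone radius.
#' @return data.frame of class `regime_scores`, ranked by combined score:
#'   centre coordinates, direction, C1, C2, combined, plus `failed` flags
#'   for candidates whose solve failed.
#' @export
search_loading <- function(mesh, materials, surface, grids = NULL,
                           magnitude = 56.1, patch_radius = NULL) {
  if (is.null(grids)) grids <- candidate_grids(mesh)
  if (is.null(patch_radius)) {
    R <- max(sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2))
    patch_radius <- 0.6 * R
  }
  restr <- .fix_xyz(.end_centre_nodes(mesh, "distal"))
  sys <- fe_system(mesh, materials, restr)
  si <- surface_info(mesh)
  med <- mean_edge_length(mesh)
  ctx <- near_surface_context(mesh, surface, d = 1.5 * med)
  cand <- expand.grid(ci = seq_len(nrow(grids$centres)),
                      di = seq_len(nrow(grids$directions)))
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    ci <- cand$ci[k]; di <- cand$di[k]
    ctr <- grids$centres[ci, ]; dir <- grids$directions[di, ]
    out <- data.frame(centre_id = ci, dir_id = di,
                      cx = ctr[1], cy = ctr[2], cz = ctr[3],
                      dx = dir[1], dy = dir[2], dz = dir[3],
                      C1 = NA_real_, C2 = NA_real_, combined = NA_real_,
                      failed = FALSE)
    res <- tryCatch({
      lc <- load_case(restr,
                      patch_load(mesh, ctr, dir, magnitude, patch_radius,
                                 surface_info = si),
                      sprintf("centre %d dir %d", ci, di))
      solve_linear_static(load = lc, system = sys)
    }, error = function(e) NULL)
    if (is.null(res)) { out$failed <- TRUE; return(out) }
    out$C1 <- as.numeric(strain_localization_score(res, surface, mesh,
                                                   d = 1.5 * med))
    out$C2 <- as.numeric(shear_consistency_score(res, surface, mesh,
                                                 context = ctx))
    out$combined <- out$C1 * out$C2
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-ifelse(is.na(tab$combined), -Inf, tab$combined)), ]
  rownames(tab) <- NULL
  class(tab) <- c("regime_scores", "data.frame")
  tab
}
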