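#' Specify a synthetic long-bone phantom
#'
#' Defines an idealised long bone as a capped cylinder: a dense cortical
#' shell around a cancellous interior whose density falls off inward in
#' concentric classes (the axially concentric density pattern seen in
#' fossil long-bone sections). Optionally a thin subsurface pathologic
#' fracture (a paraboloid patch concentric with the shell, apex proximal)
#' and wider taphonomic cracks that reach the outer surface are planted,
#' with ground truth recorded for every feature.
#'
#' Default dimensions give a desk-scale stand-in for a small tetrapod
#' radius: 60 mm long, 10 mm outer radius, 2 mm cortex, with the four
#' cancellous density classes at 1.6/1.4/1.2/1.1 g/cm3 used for
#' image-based bone models and a cortical density of 2.06 g/cm3.
#'
#' @param outer_radius outer radius (mm).
#' @param cortical_thickness cortical shell thickness (mm), < `outer_radius`.
#' @param length bone length (mm).
#' @param cancellous_class_densities densities (g/cm3), outer to inner,
#'   strictly decreasing.
#' @param cortical_density cortical density (g/cm3).
#' @param trabecular_axis unit vector, principal trabecular direction.
#' @param anisotropy_ratio >= 1; 1 means statistically isotropic texture.
#' @param bone_volume_fraction trabecular bone volume fraction in (0, 1).
#' @param fracture_plane `NULL` or a list from [paraboloid_patch_spec()].
#' @param taphonomic_cracks number of preservational cracks (>= 0).
#' @param spacing voxel spacing (mm), isotropic scalar or length 3.
#' @param noise_sd_frac greyscale noise SD as a fraction of dynamic range.
#' @param seed integer seed; every realisation is deterministic given it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(outer_radius = 10, cortical_thickness = 2,
                         length = 60,
                         cancellous_class_densities = c(1.6, 1.4, 1.2, 1.1),
                         cortical_density = 2.06,
                         trabecular_axis = c(0, 0, 1),
                         anisotropy_ratio = 1,
                         bone_volume_fraction = 0.3,
                         fracture_plane = paraboloid_patch_spec(),
                         taphonomic_cracks = 2,
                         spacing = 0.5,
                         noise_sd_frac = 0.02,
                         seed = 1L) {
  if (cortical_thickness >= outer_radius)
    stop("cortical_thickness must be smaller than outer_radius")
  if (any(diff(cancellous_class_densities) >= 0))
    stop("cancellous_class_densities must be strictly decreasing (outer to inner)")
  if (anisotropy_ratio < 1) stop("anisotropy_ratio must be >= 1")
  if (bone_volume_fraction <= 0 || bone_volume_fraction >= 1)
    stop("bone_volume_fraction must lie strictly in (0, 1)")
  if (length <= 0 || outer_radius <= 0) stop("dimensions must be positive")
  ax <- trabecular_axis / sqrt(sum(trabecular_axis^2))
  structure(list(outer_radius = outer_radius,
                 cortical_thickness = cortical_thickness,
                 length = length,
                 cancellous_class_densities = cancellous_class_densities,
                 cortical_density = cortical_density,
                 trabecular_axis = ax,
                 anisotropy_ratio = anisotropy_ratio,
                 bone_volume_fraction = bone_volume_fraction,
                 fracture_plane = fracture_plane,
                 taphonomic_cracks = as.integer(taphonomic_cracks),
                 spacing = if (length(spacing) == 1) rep(spacing, 3) else spacing,
                 noise_sd_frac = noise_sd_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specify the planted pathologic fracture patch
#'
#' The fracture is modelled as a patch of the paraboloid
#' `z = apex_z - curvature * r^2` (a bowl opening distally, concentric with
#' the bone axis): parabolic in any axial section and concentric with the
#' bone margins in transverse section, lying just beneath the endosteal
#' surface. `r_max` caps its radial extent so it stays strictly interior.
#'
#' The patch is confined to an azimuthal window (default centred on the
#' lateral, +x, side), matching a fracture that affects one side of the
#' bone rather than a complete ring.
#'
#' @param apex_z_frac apex position as a fraction of bone length (proximal
#'   end is z = length). Default 0.92.
#' @param curvature paraboloid curvature (1/mm).
#' @param r_max_frac radial extent as a fraction of the endosteal radius.
#' @param thickness_voxels rendered thickness (voxels), <= 2 for a
#'   pathologic plane.
#' @param azimuth_deg azimuth of the patch centre (degrees; 0 = lateral +x).
#' @param azimuth_halfwidth_deg angular half-width of the patch (degrees).
#' @return A `paraboloid_patch_spec` list.
#' @export
paraboloid_patch_spec <- function(apex_z_frac = 0.92, curvature = 0.18,
                                  r_max_frac = 0.85, thickness_voxels = 2,
                                  azimuth_deg = 0,
                                  azimuth_halfwidth_deg = 75) {
  structure(list(apex_z_frac = apex_z_frac, curvature = curvature,
                 r_max_frac = r_max_frac, thickness_voxels = thickness_voxels,
                 azimuth_deg = azimuth_deg,
                 azimuth_halfwidth_deg = azimuth_halfwidth_deg),
            class = "paraboloid_patch_spec")
}

# angular distance (deg) of points (x, y) to an azimuth, in [0, 180]
.azimuth_dist <- function(x, y, azimuth_deg) {
  a <- atan2(y, x) * 180 / pi - azimuth_deg
  abs((a + 180) %% 360 - 180)
}

# greyscale gain: grey = 100 * density (g/cm3) + noise
.grey_gain <- 100

#' Generate a voxel phantom with ground truth
#'
#' Renders the capped-cylinder bone of a [phantom_spec()] onto a voxel grid.
#' Greyscale is linear in material density (`100 * rho` plus Gaussian noise),
#' so density classes are separable by thresholding. The pathologic fracture
#' is rendered as a dark subsurface sheet at most 2 voxels thick; taphonomic
#' cracks are dark, 4 voxels wide, and intersect the outer surface. Ground
#' truth records intact material labels (cracks do not erase class labels),
#' fracture/crack voxel sets, the per-crack pathologic/preservational class,
#' the true trabecular axis and the closed-form analytic mass.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [image_volume()]) and `truth` (list:
#'   `material_labels`, `fracture_voxels`, `crack_voxels`, `crack_class`,
#'   `true_fabric_axis`, `analytic_mass_g`, `class_volumes_mm3`,
#'   `class_densities`, `thresholds`).
#' @examples
#' ph <- generate_phantom(phantom_spec(spacing = 1, taphonomic_cracks = 0,
#'                                     fracture_plane = NULL))
#' ph$truth$analytic_mass_g
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  R <- spec$outer_radius; L <- spec$length; tcort <- spec$cortical_thickness
  if (tcort < max(sp))
    stop("parameter error: cortical shell thinner than one voxel; refine spacing")
  margin <- 4 * max(sp)
  nx <- ceiling((2 * R + 2 * margin) / sp[1])
  ny <- ceiling((2 * R + 2 * margin) / sp[2])
  nz <- ceiling((L + 2 * margin) / sp[3])
  if (nx < 8 || ny < 8 || nz < 8)
    stop("parameter error: geometry cannot fit the voxel grid")
  origin <- c(-(nx - 1) / 2 * sp[1], -(ny - 1) / 2 * sp[2], -margin)
  xs <- origin[1] + (seq_len(nx) - 1) * sp[1]
  ys <- origin[2] + (seq_len(ny) - 1) * sp[2]
  zs <- origin[3] + (seq_len(nz) - 1) * sp[3]

  r2 <- outer(xs^2, ys^2, "+")                     # nx x ny
  rxy <- sqrt(r2)
  inz <- zs >= 0 & zs <= L
  # concentric class boundaries: cortical shell then equal-width cancellous rings
  nc <- length(spec$cancellous_class_densities)
  r_endo <- R - tcort
  breaks <- c(R, r_endo, r_endo * rev(seq_len(nc - 1)) / nc, 0)
  labels <- array(0L, c(nx, ny, nz))
  lab2d <- matrix(0L, nx, ny)
  for (k in seq_len(nc + 1))                       # 1 cortical, 2.. cancellous
    lab2d[rxy <= breaks[k] & rxy > breaks[k + 1]] <- k
  lab2d[rxy <= breaks[nc + 2]] <- nc + 1L          # innermost includes r = 0
  for (iz in which(inz)) labels[, , iz] <- lab2d

  dens <- c(spec$cortical_density, spec$cancellous_class_densities)
  dvol <- array(0, c(nx, ny, nz))
  dvol[labels > 0] <- dens[labels[labels > 0]]

  # analytic mass of the intact geometry (g): ring areas x length x density
  ring_area <- pi * (breaks[-length(breaks)]^2 - breaks[-1]^2)
  ring_area[length(ring_area)] <- pi * breaks[length(breaks) - 1]^2
  class_vol <- ring_area * L                       # mm^3
  analytic_mass <- sum(dens * class_vol) / 1000    # g/cm3 * mm3 -> g

  set.seed(spec$seed)
  # pathologic fracture: paraboloid bowl z = z0 - c*r^2, subsurface
  frac_idx <- integer(0)
  if (!is.null(spec$fracture_plane)) {
    fp <- spec$fracture_plane
    if (fp$thickness_voxels > 2)
      warning("pathologic fracture thicker than 2 voxels is atypical")
    z0 <- fp$apex_z_frac * L
    rmax <- fp$r_max_frac * r_endo
    half_t <- fp$thickness_voxels / 2 * max(sp)
    zg <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
    rg <- array(rep(rxy, nz), c(nx, ny, nz))
    zsurf <- z0 - fp$curvature * rg^2
    # distance to surface along z, corrected for local slope
    dist <- abs(zg - zsurf) / sqrt(1 + (2 * fp$curvature * rg)^2)
    xg <- array(rep(xs, ny * nz), c(nx, ny, nz))
    yg <- array(rep(rep(ys, each = nx), nz), c(nx, ny, nz))
    inwin <- .azimuth_dist(xg, yg, fp$azimuth_deg) <= fp$azimuth_halfwidth_deg |
      rg <= 0.2 * rmax                 # keep the apex cap regardless
    inside <- labels > 1L & rg <= rmax & dist <= half_t & inwin  # cancellous only
    frac_idx <- which(inside)
    if (length(frac_idx) == 0)
      stop("parameter error: fracture patch does not intersect the cancellous interior")
  }

  # taphonomic cracks: planar slabs through the surface, in the distal half
  crack_sets <- list()
  if (spec$taphonomic_cracks > 0) {
    zg <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
    xg <- array(rep(xs, ny * nz), c(nx, ny, nz))
    yg <- array(rep(rep(ys, each = nx), nz), c(nx, ny, nz))
    nct <- spec$taphonomic_cracks
    zslots <- if (nct == 1) 0.3 * L else L * (0.12 + 0.33 * (seq_len(nct) - 1) / (nct - 1))
    for (ci in seq_len(nct)) {
      theta <- stats::runif(1, 0, 2 * pi)
      # distal half, one slot per crack so cracks never merge with each other
      # or with the proximal fracture patch
      zc <- zslots[ci] + stats::runif(1, -0.02, 0.02) * L
      p0 <- c(R * cos(theta), R * sin(theta), zc)  # a point on the outer surface
      # crack plane roughly transverse, tilted at random
      tilt <- stats::runif(1, -0.35, 0.35)
      nrm <- c(sin(tilt) * cos(theta), sin(tilt) * sin(theta), cos(tilt))
      nrm <- nrm / sqrt(sum(nrm^2))
      half_w <- 2 * max(sp)                        # 4-voxel full width
      reach <- 0.65 * R                            # penetration from the surface point
      dplane <- abs((xg - p0[1]) * nrm[1] + (yg - p0[2]) * nrm[2] + (zg - p0[3]) * nrm[3])
      dpt <- sqrt((xg - p0[1])^2 + (yg - p0[2])^2 + (zg - p0[3])^2)
      sel <- labels > 0L & dplane <= half_w & dpt <= reach
      crack_sets[[ci]] <- which(sel)
    }
  }

  grey <- dvol * .grey_gain
  if (length(frac_idx)) grey[frac_idx] <- 0
  for (cs in crack_sets) grey[cs] <- 0
  if (spec$noise_sd_frac > 0) {
    sdn <- spec$noise_sd_frac * max(dens) * .grey_gain
    grey <- grey + array(stats::rnorm(length(grey), 0, sdn), dim(grey))
  }

  thresholds <- .grey_gain * c((spec$cortical_density +
                                  spec$cancellous_class_densities[1]) / 2,
                               utils::head(spec$cancellous_class_densities, -1) -
                                 diff(-spec$cancellous_class_densities) / 2)
  all_cracks <- c(if (length(frac_idx)) list(frac_idx) else list(), crack_sets)
  crack_class <- c(if (length(frac_idx)) "pathologic" else character(0),
                   rep("preservational", length(crack_sets)))
  list(volume = image_volume(grey, sp, origin),
       truth = list(material_labels = labels,
                    fracture_voxels = frac_idx,
                    crack_voxels = all_cracks,
                    crack_class = crack_class,
                    true_fabric_axis = spec$trabecular_axis,
                    analytic_mass_g = analytic_mass,
                    class_volumes_mm3 = class_vol,
                    class_densities = dens,
                    thresholds = thresholds))
}

#' Generate an oriented binary trabecular volume
#'
#' Emulates a cancellous-bone region for fabric analysis: a Gaussian random
#' field smoothed with an anisotropic Gaussian kernel whose along-axis
#' standard deviation is `anisotropy_ratio` times the transverse one, then
#' thresholded at the `1 - bvf` quantile, so the realised bone volume
#' fraction equals `bvf` up to ties. `anisotropy_ratio = 1` gives a
#' statistically isotropic structure.
#'
#' @param axis unit vector, preferred trabecular direction.
#' @param anisotropy_ratio >= 1.
#' @param bvf target bone volume fraction, strictly in (0, 1).
#' @param shape integer length-3 voxel dimensions.
#' @param seed integer seed.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param sigma_t transverse smoothing SD in voxels (sets trabecular scale).
#' @return A binary [image_volume()] (logical voxels; TRUE = bone).
#' @export
generate_trabecular_volume <- function(axis = c(0, 0, 1), anisotropy_ratio = 1,
                                       bvf = 0.3, shape = c(64, 64, 64),
                                       seed = 1L, spacing = 0.1,
                                       sigma_t = 1.4) {
  if (bvf <= 0 || bvf >= 1) stop("parameter error: bvf must be in (0, 1)")
  if (anisotropy_ratio < 1) stop("parameter error: anisotropy_ratio must be >= 1")
  axis <- axis / sqrt(sum(axis^2))
  shape <- as.integer(shape)
  set.seed(seed)
  noise <- array(stats::rnorm(prod(shape)), shape)
  # anisotropic Gaussian transfer function in the frequency domain:
  # exp(-((sig_ax^2 - sig_t^2) (k.axis)^2 + sig_t^2 |k|^2) / 2)
  sig_ax <- sigma_t * anisotropy_ratio
  kfreq <- function(n) 2 * pi * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
  kx <- kfreq(shape[1]); ky <- kfreq(shape[2]); kz <- kfreq(shape[3])
  KX <- array(rep(kx, times = shape[2] * shape[3]), shape)
  KY <- array(rep(rep(ky, each = shape[1]), times = shape[3]), shape)
  KZ <- array(rep(kz, each = shape[1] * shape[2]), shape)
  kax <- KX * axis[1] + KY * axis[2] + KZ * axis[3]
  k2 <- KX^2 + KY^2 + KZ^2
  transfer <- exp(-0.5 * ((sig_ax^2 - sigma_t^2) * kax^2 + sigma_t^2 * k2))
  field <- Re(stats::fft(stats::fft(noise) * transfer, inverse = TRUE)) / prod(shape)
  cut <- stats::quantile(field, 1 - bvf, names = FALSE)
  image_volume(field > cut, spacing)
}

#' Generate a tetrahedral phantom mesh with per-element density
#'
#' Structured meshing of the capped-cylinder bone: the cross-section disc is
#' triangulated (central fan plus concentric rings whose radial breaks are
#' aligned with the material class boundaries), extruded along the axis into
#' wedges, and each wedge is split into three tetrahedra with face diagonals
#' chosen through the globally smallest node index, which keeps the mesh
#' conforming and watertight. Ring node radii are inflated so each polygonal
#' annulus has exactly the area of its circular counterpart, making the
#' meshed volume match the analytic volume to discretisation rounding only.
#' Every element carries the density of the class containing its centroid.
#'
#' @param spec a [phantom_spec()].
#' @param target_elements requested element count (>= 500); achieved count is
#'   within about 25%.
#' @param min_dihedral_floor error if any element dihedral angle (degrees)
#'   falls below this.
#' @return list with `mesh` (a [tet_mesh()] with `material_id`: 1 cortical,
#'   2.. cancellous outer to inner), `density` (g/cm3 per element), and
#'   `class_densities`.
#' @export
generate_tet_phantom <- function(spec, target_elements = 5000,
                                 min_dihedral_floor = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (target_elements < 500) stop("target_elements must be >= 500")
  R <- spec$outer_radius; L <- spec$length
  nc <- length(spec$cancellous_class_densities)
  r_endo <- R - spec$cortical_thickness
  class_breaks <- c(0, r_endo * seq_len(nc - 1) / nc, r_endo, R)  # ascending

  # choose resolution (nr radial intervals, ns sectors, nl layers): meet the
  # element budget within 25% while keeping the worst cell aspect ratio low
  best <- NULL
  for (nr_c in (nc + 1):(nc + 9)) {
    dr <- R / nr_c
    for (ns_c in c(8, 10, 12, 16, 20, 26, 32, 40, 52, 64)) {
      per_layer <- 3 * ns_c * (2 * nr_c - 1)
      nl_c <- max(3, round(target_elements / per_layer))
      count_c <- nl_c * per_layer
      if (abs(count_c - target_elements) / target_elements > 0.25) next
      dz <- L / nl_c
      arc_min <- 2 * pi * dr / ns_c          # arc length at the first ring
      arc_max <- 2 * pi * R / ns_c
      aspect <- max(dz, dr, arc_max) / min(dz, dr, arc_min)
      if (is.null(best) || aspect < best$aspect)
        best <- list(nr = nr_c, ns = ns_c, nl = nl_c, count = count_c,
                     aspect = aspect)
    }
  }
  if (is.null(best))
    stop("meshing failure at sizing stage: cannot match target element count")
  nr <- best$nr; ns <- best$ns; nl <- best$nl; count <- best$count

  # radial breaks: refine class bands to nr intervals, keeping class radii
  base <- class_breaks
  while (length(base) - 1 < nr) {
    widths <- diff(base)
    k <- which.max(widths)
    base <- sort(c(base, (base[k] + base[k + 1]) / 2))
  }
  radii <- base[-1]                                 # nr ring radii (ascending)
  # area-preserving inflation for an ns-gon
  infl <- sqrt(2 * pi / ns / sin(2 * pi / ns))
  nr_rings <- length(radii)

  theta <- 2 * pi * (seq_len(ns) - 1) / ns
  layer_n <- 1 + nr_rings * ns
  nl_nodes <- nl + 1
  nodes <- matrix(0, layer_n * nl_nodes, 3)
  zs <- L * (0:nl) / nl
  for (iz in seq_len(nl_nodes)) {
    off <- (iz - 1) * layer_n
    nodes[off + 1, ] <- c(0, 0, zs[iz])
    for (j in seq_len(nr_rings)) {
      idx <- off + 1 + (j - 1) * ns + seq_len(ns)
      nodes[idx, 1] <- infl * radii[j] * cos(theta)
      nodes[idx, 2] <- infl * radii[j] * sin(theta)
      nodes[idx, 3] <- zs[iz]
    }
  }
  ring_id <- function(layer, j, k)                  # j ring >=1, k sector (1-based, wraps)
    (layer - 1) * layer_n + 1 + (j - 1) * ns + ((k - 1) %% ns) + 1
  centre_id <- function(layer) (layer - 1) * layer_n + 1

  # disc triangles (counter-clockwise seen from +z); each remembers the
  # annulus [radii[j-1], radii[j]] it tiles, which fixes its material class
  tri <- matrix(0L, ns * (2 * nr_rings - 1), 3)
  tri_ring <- integer(nrow(tri))
  t <- 0L
  for (k in seq_len(ns)) {
    t <- t + 1L
    tri[t, ] <- c(centre_id(1), ring_id(1, 1, k), ring_id(1, 1, k + 1))
    tri_ring[t] <- 1L
  }
  if (nr_rings > 1) for (j in seq_len(nr_rings - 1)) for (k in seq_len(ns)) {
    a <- ring_id(1, j, k); b <- ring_id(1, j, k + 1)
    c2 <- ring_id(1, j + 1, k + 1); d <- ring_id(1, j + 1, k)
    tri[t + 1L, ] <- c(a, d, c2); tri[t + 2L, ] <- c(a, c2, b)
    tri_ring[t + 1:2] <- j + 1L
    t <- t + 2L
  }

  elems <- matrix(0L, 3 * nl * nrow(tri), 4)
  e <- 0L
  for (iz in seq_len(nl)) {
    off_b <- (iz - 1) * layer_n; off_t <- iz * layer_n
    for (ti in seq_len(nrow(tri))) {
      w <- c(tri[ti, ] + off_b, tri[ti, ] + off_t)  # wedge b1 b2 b3 t1 t2 t3
      tets <- .split_wedge(w)
      elems[e + 1:3, ] <- tets
      e <- e + 3L
    }
  }

  mesh <- tet_mesh(nodes, elems)
  # class of each element from the annulus its wedge tiles (rings are
  # aligned with the class boundaries, so the midpoint radius of the ring
  # identifies the class containing the whole element)
  ring_mid <- (base[-1] + base[-length(base)]) / 2
  band_of_ring <- findInterval(ring_mid,
                               class_breaks[-c(1, length(class_breaks))]) + 1
  elem_ring <- rep(rep(tri_ring, each = 3), nl)   # 3 tets per wedge, per layer
  band <- band_of_ring[elem_ring]
  # band 1 = innermost cancellous ... nc = outermost cancellous, nc+1 = cortical
  material <- ifelse(band == nc + 1, 1L, nc + 2L - band)
  dens <- c(spec$cortical_density, spec$cancellous_class_densities)
  mesh$material_id <- as.integer(material)

  mq <- min(min_dihedral_angles(mesh))
  if (mq < min_dihedral_floor)
    stop(sprintf("meshing failure at quality stage: min dihedral %.2f deg", mq))
  list(mesh = mesh, density = dens[material], class_densities = dens)
}

# split a wedge (b1,b2,b3,t1,t2,t3 global ids) into 3 tets using the
# smallest-global-index diagonal rule on the quadrilateral faces, so shared
# faces of adjacent wedges always receive the same diagonal
.split_wedge <- function(w) {
  rot <- function(w) w[c(2, 3, 1, 5, 6, 4)]
  flip <- function(w) w[c(4, 6, 5, 1, 3, 2)]
  for (i in 1:4) {
    p <- which.min(w)
    if (p == 1) break
    w <- if (p <= 3) rot(w) else flip(w)
  }
  # w[1] is now the global minimum; diagonals w1-w5 and w1-w6 are forced.
  # remaining quad (b2,b3,t3,t2) = (w2,w3,w6,w5): diagonal through its min
  q <- w[c(2, 3, 6, 5)]
  if (min(q) %in% q[c(1, 3)]) {   # diagonal w2-w6
    rbind(w[c(1, 2, 3, 6)], w[c(1, 2, 6, 5)], w[c(1, 5, 6, 4)])
  } else {                        # diagonal w3-w5
    rbind(w[c(1, 2, 3, 5)], w[c(1, 5, 3, 6)], w[c(1, 5, 6, 4)])
  }
}
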