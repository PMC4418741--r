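# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the intercept counter enumerates grid-plane crossing
# parameters and reads voxels at interval midpoints (no incremental walk).

# brute-force line-intercept counter: for each direction, cast full lines
# through the points across the ROI box and count bone/void transitions
mil_crossings_oracle <- function(volume, roi, dirs, pts) {
  vox <- volume$voxels != 0
  sp <- volume$spacing
  blo <- (roi$lo - 1 - 0.5) * sp
  bhi <- (roi$hi - 1 + 0.5) * sp
  out <- matrix(0, nrow(dirs), 2)
  for (j in seq_len(nrow(dirs))) {
    dir <- dirs[j, ]
    len <- 0
    cross <- 0
    for (k in seq_len(nrow(pts))) {
      p <- pts[k, ]
      tmin <- -Inf; tmax <- Inf; miss <- FALSE
      for (a in 1:3) {
        if (abs(dir[a]) < 1e-300) {
          if (p[a] < blo[a] || p[a] > bhi[a]) { miss <- TRUE; break }
        } else {
          t1 <- (blo[a] - p[a]) / dir[a]; t2 <- (bhi[a] - p[a]) / dir[a]
          if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
          tmin <- max(tmin, t1); tmax <- min(tmax, t2)
        }
      }
      if (miss || tmax <= tmin) next
      len <- len + tmax - tmin
      ts <- numeric(0)
      for (a in 1:3) if (abs(dir[a]) > 1e-300) {
        iv <- floor((p[a] + tmin * dir[a]) / sp[a] + 0.5):
          floor((p[a] + tmax * dir[a]) / sp[a] + 0.5)
        bnds <- unique(sort(c(iv - 0.5, iv + 0.5))) * sp[a]
        tb <- (bnds - p[a]) / dir[a]
        ts <- c(ts, tb[tb > tmin + 1e-12 & tb < tmax - 1e-12])
      }
      ts <- sort(unique(ts))
      mids <- (c(tmin, ts) + c(ts, tmax)) / 2
      prev <- NA
      for (tm in mids) {
        iv <- pmin(pmax(floor((p + tm * dir) / sp + 0.5), roi$lo - 1),
                   roi$hi - 1)
        cur <- vox[iv[1] + 1, iv[2] + 1, iv[3] + 1]
        if (!is.na(prev) && cur != prev) cross <- cross + 1
        prev <- cur
      }
    }
    out[j, ] <- c(len, cross)
  }
  out
}

# closed-form mass (g) of the default capped-cylinder phantom geometry
analytic_phantom_mass <- function(spec) {
  nc <- length(spec$cancellous_class_densities)
  r_endo <- spec$outer_radius - spec$cortical_thickness
  breaks <- c(spec$outer_radius, r_endo, r_endo * rev(seq_len(nc - 1)) / nc, 0)
  areas <- pi * (breaks[-length(breaks)]^2 - breaks[-1]^2)
  dens <- c(spec$cortical_density, spec$cancellous_class_densities)
  sum(dens * areas * spec$length) / 1000
}

# a small one-material cylinder FE model with an axial end load, solved
# against the closed-form uniform-stress bar solution in the tests
make_bar_model <- function(target_elements = 3000, E = 10000, P = 500) {
  sp <- phantom_spec(taphonomic_cracks = 0, fracture_plane = NULL)
  tp <- generate_tet_phantom(sp, target_elements)
  mesh <- tp$mesh
  m <- nrow(mesh$elements)
  prox <- paleofract:::.end_face_nodes(mesh, "proximal")
  dist <- paleofract:::.end_face_nodes(mesh, "distal")
  wp <- paleofract:::.tributary_end_weights(mesh, prox)
  restr <- data.frame(node = rep(dist, each = 3), dof = rep(1:3, length(dist)),
                      value = 0)
  lc <- load_case(restr, data.frame(node = prox, fx = 0, fy = 0, fz = P * wp),
                  "uniaxial bar")
  list(mesh = mesh, mats = list(E = rep(E, m), nu = rep(0, m)), load = lc,
       P = P, A = pi * sp$outer_radius^2, E = E, length = sp$length)
}
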