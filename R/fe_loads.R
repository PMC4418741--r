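# geometry helpers for load construction on capped-cylinder bone meshes:
# the long axis is z, the proximal end is the z-max face, lateral is +x,
# anterior is +y

.end_face_nodes <- function(mesh, end = c("proximal", "distal"), tol = 1e-6) {
  end <- match.arg(end)
  z <- mesh$nodes[, 3]
  zt <- if (end == "proximal") max(z) else min(z)
  which(abs(z - zt) < tol + 1e-9 * diff(range(z)))
}

# nodes near the centre of an end face ("a small number of nodes in the
# centre"); radius defaults to 2% of bone length but always includes at
# least `min_nodes` nodes so all six rigid-body modes are removed
.end_centre_nodes <- function(mesh, end, radius_frac = 0.02, min_nodes = 7L) {
  face <- .end_face_nodes(mesh, end)
  ctr <- colMeans(mesh$nodes[face, , drop = FALSE])
  r <- sqrt((mesh$nodes[face, 1] - ctr[1])^2 + (mesh$nodes[face, 2] - ctr[2])^2)
  rcut <- max(radius_frac * diff(range(mesh$nodes[, 3])),
              sort(r)[min(min_nodes, length(r))])
  face[r <= rcut + 1e-12]
}

.fix_xyz <- function(nodes) {
  data.frame(node = rep(nodes, each = 3), dof = rep(1:3, length(nodes)),
             value = 0)
}

#' Precomputed boundary-surface summary of a mesh
#'
#' Boundary nodes and their tributary areas (each surface triangle assigns a
#' third of its area to each vertex); reused by repeated patch-load
#' construction.
#'
#' @param mesh a [tet_mesh()]
#' @return list with `faces`, `nodes` (sorted boundary node ids) and
#'   `node_area` (full-length vector, mm^2).
#' @export
surface_info <- function(mesh) {
  sf <- surface_faces(mesh)
  fg <- face_geometry(mesh, sf$faces)
  acc <- rowsum(rep(fg$area / 3, 3), group = as.vector(sf$faces))
  w <- numeric(nrow(mesh$nodes))
  w[as.integer(rownames(acc))] <- acc[, 1]
  list(faces = sf$faces, nodes = sort(unique(as.vector(sf$faces))),
       node_area = w)
}

#' Distribute a total force over the nodes of a surface patch
#'
#' Selects boundary-surface nodes within `patch_radius` of `centre` and
#' applies `total_force` split proportionally to tributary surface area
#' (area-weighted patch loading avoids the point artifacts of concentrated
#' nodal loads).
#'
#' @param mesh a [tet_mesh()].
#' @param centre patch centre (mm, length 3).
#' @param direction unit force direction.
#' @param magnitude total force (N).
#' @param patch_radius selection radius (mm).
#' @param surface_info optional precomputed [surface_info()] (avoids
#'   recomputing the boundary surface for repeated calls on one mesh).
#' @return data.frame of nodal forces (see [load_case()]); attribute
#'   `nodes` lists the patch nodes.
#' @export
patch_load <- function(mesh, centre, direction, magnitude, patch_radius,
                       surface_info = NULL) {
  si <- if (is.null(surface_info)) surface_info(mesh) else surface_info
  surf_nodes <- si$nodes
  d2 <- (mesh$nodes[surf_nodes, 1] - centre[1])^2 +
    (mesh$nodes[surf_nodes, 2] - centre[2])^2 +
    (mesh$nodes[surf_nodes, 3] - centre[3])^2
  sel <- surf_nodes[d2 <= patch_radius^2]
  if (length(sel) == 0) stop("empty load patch: no surface nodes within radius")
  w <- si$node_area[sel]
  if (sum(w) == 0) stop("selected nodes carry no surface area")
  w <- w / sum(w)
  direction <- direction / sqrt(sum(direction^2))
  f <- outer(w * magnitude, direction)
  out <- data.frame(node = sel, fx = f[, 1], fy = f[, 2], fz = f[, 3])
  attr(out, "nodes") <- sel
  out
}

#' The five canonical comparison loading regimes
#'
#' Uniaxial compression, uniaxial tension and uniaxial torsion (loads on the
#' proximal end, translation restrained at a few nodes in the distal end
#' centre) plus anteroposterior and mediolateral midshaft bending
#' (restrained at both end centres, transverse load on a small midshaft
#' surface patch). Axis conventions: long axis z (proximal at z-max),
#' lateral +x, anterior +y.
#'
#' @param mesh a [tet_mesh()] of the capped-cylinder bone.
#' @param magnitude total applied force (N); for torsion, the magnitude of
#'   the force couple.
#' @return named list of five [load_case()]s.
#' @export
canonical_load_cases <- function(mesh, magnitude = 100) {
  z <- mesh$nodes[, 3]
  L <- diff(range(z))
  R <- max(sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2))
  distal_fix <- .fix_xyz(.end_centre_nodes(mesh, "distal"))
  both_fix <- rbind(distal_fix, .fix_xyz(.end_centre_nodes(mesh, "proximal")))

  prox <- .end_face_nodes(mesh, "proximal")
  wp <- .tributary_end_weights(mesh, prox)
  axial <- function(sign_, label) {
    f <- data.frame(node = prox, fx = 0, fy = 0, fz = sign_ * magnitude * wp)
    load_case(distal_fix, f, label)
  }
  # torsion: tangential couple on the proximal face, net force exactly zero
  ctr <- colMeans(mesh$nodes[prox, , drop = FALSE])
  rx <- mesh$nodes[prox, 1] - ctr[1]; ry <- mesh$nodes[prox, 2] - ctr[2]
  tang <- cbind(-ry, rx)
  nz <- sqrt(rowSums(tang^2)) > 1e-9
  fx <- fy <- numeric(length(prox))
  fx[nz] <- wp[nz] * tang[nz, 1]; fy[nz] <- wp[nz] * tang[nz, 2]
  scale <- magnitude / sum(sqrt(fx^2 + fy^2))
  fx <- fx * scale; fy <- fy * scale
  fx <- fx - mean(fx); fy <- fy - mean(fy)   # enforce zero net force
  torsion <- load_case(distal_fix,
                       data.frame(node = prox, fx = fx, fy = fy, fz = 0),
                       "uniaxial torsion")

  mid_r <- max(0.06 * L, 2.5)
  ap <- load_case(both_fix,
                  patch_load(mesh, c(0, -R, L / 2 + min(z)), c(0, 1, 0),
                             magnitude, mid_r),
                  "anteroposterior bending")
  ml <- load_case(both_fix,
                  patch_load(mesh, c(R, 0, L / 2 + min(z)), c(-1, 0, 0),
                             magnitude, mid_r),
                  "mediolateral bending")
  list(compression = axial(-1, "uniaxial compression"),
       tension = axial(+1, "uniaxial tension"),
       torsion = torsion,
       ap_bending = ap,
       ml_bending = ml)
}

# area weights over an end face (triangles of the boundary surface whose
# three vertices lie on the face)
.tributary_end_weights <- function(mesh, face_nodes) {
  sf <- surface_faces(mesh)
  on_face <- matrix(sf$faces %in% face_nodes, ncol = 3)
  keep <- rowSums(on_face) == 3
  f <- sf$faces[keep, , drop = FALSE]
  fg <- face_geometry(mesh, f)
  acc <- rowsum(rep(fg$area / 3, 3), group = as.vector(f))
  w <- numeric(nrow(mesh$nodes))
  w[as.integer(rownames(acc))] <- acc[, 1]
  w[face_nodes] / sum(w[face_nodes])
}

#' Heterogeneous-versus-homogeneous material comparison
#'
#' Runs the five canonical regimes on the same mesh under two material
#' cards and reports, per regime, the mean von Mises element strain of each
#' model and the relative difference
#' `|mean_het - mean_hom| / mean_het * 100` (per cent), the standard check
#' that a volume-weighted homogenisation of the cancellous classes does not
#' distort whole-bone strain summaries.
#'
#' @param mesh a [tet_mesh()] with `material_id`.
#' @param het_card heterogeneous [material_card()].
#' @param hom_card homogenised card; cancellous classes may be collapsed to
#'   one (missing classes fall back to the homogenised cancellous row,
#'   class 2).
#' Because the structured phantom mesh grades element size strongly from the
#' axis outward, the volume-weighted mean is the faithful analogue of an
#' element mean on a uniform-sized voxel-derived mesh and is used for
#' `diff_pct`; the raw element-count mean difference is also reported.
#'
#' @param magnitude applied force (N).
#' @return data.frame: regime, volume-weighted and unweighted mean / SD
#'   (microstrain) for each model, percent difference of the volume-weighted
#'   means (`diff_pct`) and of the unweighted means (`diff_pct_unweighted`).
#' @export
compare_het_hom <- function(mesh, het_card, hom_card, magnitude = 100) {
  cases <- canonical_load_cases(mesh, magnitude)
  props_for <- function(card) {
    id <- mesh$material_id
    if (!all(id %in% card$class)) id <- ifelse(id == 1L, 1L, 2L)
    i <- match(id, card$class)
    list(E = card$E_mpa[i], nu = card$nu[i])
  }
  het <- props_for(het_card); hom <- props_for(hom_card)
  rows <- lapply(names(cases), function(nm) {
    lc <- cases[[nm]]
    sys_het <- fe_system(mesh, het, lc$restraints)
    sys_hom <- fe_system(mesh, hom, lc$restraints)
    r1 <- mean_vm_strain(solve_linear_static(load = lc, system = sys_het))
    r2 <- mean_vm_strain(solve_linear_static(load = lc, system = sys_hom))
    data.frame(regime = lc$label,
               mean_het_ue = r1$mean_volume_weighted,
               sd_het_ue = r1$sd_volume_weighted,
               mean_hom_ue = r2$mean_volume_weighted,
               sd_hom_ue = r2$sd_volume_weighted,
               diff_pct = abs(r1$mean_volume_weighted - r2$mean_volume_weighted) /
                 r1$mean_volume_weighted * 100,
               mean_het_unw_ue = r1$mean, mean_hom_unw_ue = r2$mean,
               diff_pct_unweighted = abs(r1$mean - r2$mean) / r1$mean * 100)
  })
  do.call(rbind, rows)
}
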