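#' Isotropic elasticity matrix (Voigt order xx, yy, zz, xy, yz, zx)
#'
#' Engineering shear strains; stress in the units of `E`.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio, 0 <= nu < 0.5.
#' @return 6 x 6 matrix.
#' @export
elastic_matrix <- function(E, nu) {
  if (nu < 0 || nu >= 0.5) stop("nu must be in [0, 0.5)")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# shape-function gradient coefficients of one tet: 3 x 4 matrix G where
# G[, i] = grad N_i; also the volume
.tet_gradients <- function(coords) {
  C <- cbind(1, coords)
  V <- det(C) / 6
  if (V <= 0) stop("degenerate tet (non-positive volume)")
  G <- solve(C)[2:4, , drop = FALSE]
  list(G = G, V = V)
}

.strain_displacement <- function(G) {
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- G[1, i]
    B[2, c0 + 2] <- G[2, i]
    B[3, c0 + 3] <- G[3, i]
    B[4, c0 + 1] <- G[2, i]; B[4, c0 + 2] <- G[1, i]
    B[5, c0 + 2] <- G[3, i]; B[5, c0 + 3] <- G[2, i]
    B[6, c0 + 1] <- G[3, i]; B[6, c0 + 3] <- G[1, i]
  }
  B
}

#' Element stiffness of a constant-strain tetrahedron
#'
#' `K = V * B' D B` for the linear tetrahedron: symmetric positive
#' semidefinite with exactly six rigid-body zero-energy modes.
#'
#' @param coords 4 x 3 node coordinates (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 12 x 12 stiffness matrix (N/mm).
#' @export
element_stiffness <- function(coords, E, nu) {
  g <- .tet_gradients(as.matrix(coords))
  B <- .strain_displacement(g$G)
  g$V * t(B) %*% elastic_matrix(E, nu) %*% B
}

#' Per-element elastic properties from a material card
#'
#' @param mesh a [tet_mesh()] with `material_id`.
#' @param card a [material_card()] (rows indexed by class id).
#' @return list with vectors `E` (MPa) and `nu`, one entry per element.
#' @export
material_props <- function(mesh, card) {
  if (is.null(mesh$material_id)) stop("mesh has no material ids")
  i <- match(mesh$material_id, card$class)
  if (anyNA(i)) stop("mesh references material classes missing from the card")
  list(E = card$E_mpa[i], nu = card$nu[i])
}

#' Define a load case
#'
#' @param restraints data.frame with columns `node`, `dof` (1 = x, 2 = y,
#'   3 = z) and `value` (prescribed displacement, mm; 0 for a fixed support).
#' @param forces data.frame with columns `node`, `fx`, `fy`, `fz` (N).
#' @param label description of the regime.
#' @return a `load_case` list.
#' @export
load_case <- function(restraints, forces = NULL, label = "") {
  if (is.null(forces))
    forces <- data.frame(node = integer(0), fx = numeric(0), fy = numeric(0),
                         fz = numeric(0))
  structure(list(restraints = restraints, forces = forces, label = label),
            class = "load_case")
}

#' Assemble and factorise the linear system for a mesh and restraint set
#'
#' The expensive part of a linear-static analysis (stiffness assembly and
#' sparse Cholesky factorisation) depends only on the mesh, the materials
#' and the restrained degrees of freedom, so it can be reused across many
#' right-hand sides (e.g. a grid search over loading regimes).
#'
#' @param mesh a [tet_mesh()].
#' @param materials list with per-element `E` (MPa) and `nu`.
#' @param restraints restraint data.frame (see [load_case()]).
#' @return an `fe_system` object.
#' @export
fe_system <- function(mesh, materials, restraints) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  E <- rep_len(materials$E, m); nu <- rep_len(materials$nu, m)
  Gx <- matrix(0, m, 4); Gy <- matrix(0, m, 4); Gz <- matrix(0, m, 4)
  V <- numeric(m)
  ii <- vector("list", m); jj <- vector("list", m); xx <- vector("list", m)
  dof_of <- function(nodes) rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes)
  for (e in seq_len(m)) {
    en <- mesh$elements[e, ]
    g <- .tet_gradients(mesh$nodes[en, , drop = FALSE])
    Gx[e, ] <- g$G[1, ]; Gy[e, ] <- g$G[2, ]; Gz[e, ] <- g$G[3, ]
    V[e] <- g$V
    B <- .strain_displacement(g$G)
    Ke <- g$V * crossprod(B, elastic_matrix(E[e], nu[e]) %*% B)
    ed <- as.vector(dof_of(en))
    ii[[e]] <- rep(ed, times = 12)
    jj[[e]] <- rep(ed, each = 12)
    xx[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * n, 3 * n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2, uplo = "U")
  fixed_dof <- 3 * (restraints$node - 1) + restraints$dof
  if (anyDuplicated(fixed_dof)) stop("duplicate restraints on a dof")
  free <- setdiff(seq_len(3 * n), fixed_dof)
  if (length(fixed_dof) == 0) stop("insufficient restraints")
  Kff <- K[free, free, drop = FALSE]
  fac <- tryCatch(suppressWarnings(Matrix::Cholesky(Kff, LDL = FALSE)),
                  error = function(e) stop("insufficient restraints: singular system"))
  structure(list(mesh = mesh, E = E, nu = nu, V = V,
                 Gx = Gx, Gy = Gy, Gz = Gz,
                 K = K, free = free, fixed_dof = fixed_dof,
                 fixed_val = restraints$value, chol = fac, n_dof = 3 * n),
            class = "fe_system")
}

#' Solve a linear-static load case
#'
#' Sparse symmetric positive-definite solve of `K u = f` with prescribed
#' displacements eliminated, followed by field post-processing: per-element
#' strain and stress tensors, von Mises stress (MPa) and strain
#' (microstrain), and the global equilibrium residual.
#'
#' The von Mises strain uses the `(1 + nu)`-consistent convention
#' `eps_vm = sqrt(((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2) / 2) / (1 + nu)`,
#' which reduces to the axial strain under uniaxial stress and equals
#' `sigma_vm / E` elementwise for isotropic elasticity.
#'
#' @param mesh a [tet_mesh()] (ignored if `system` is given).
#' @param materials list with per-element `E`, `nu` (ignored if `system`).
#' @param load a [load_case()].
#' @param system optional prebuilt [fe_system()] to reuse.
#' @return an `fe_result`: `u` (n x 3 mm), `strain`/`stress` (m x 6 Voigt),
#'   `von_mises_stress` (MPa), `von_mises_strain` (microstrain),
#'   `reactions`, `equilibrium_residual` (relative), `load`.
#' @export
solve_linear_static <- function(mesh = NULL, materials = NULL, load,
                                system = NULL) {
  if (is.null(system)) system <- fe_system(mesh, materials, load$restraints)
  f <- numeric(system$n_dof)
  if (nrow(load$forces) > 0) {
    fd <- 3 * (load$forces$node - 1)
    f[fd + 1] <- f[fd + 1] + load$forces$fx
    f[fd + 2] <- f[fd + 2] + load$forces$fy
    f[fd + 3] <- f[fd + 3] + load$forces$fz
  }
  u <- numeric(system$n_dof)
  u[system$fixed_dof] <- system$fixed_val
  rhs <- f[system$free] -
    as.numeric(system$K[system$free, system$fixed_dof, drop = FALSE] %*%
                 system$fixed_val)
  u[system$free] <- as.numeric(Matrix::solve(system$chol, rhs))
  ku <- as.numeric(system$K %*% u)
  reactions <- ku[system$fixed_dof] - f[system$fixed_dof]
  res_free <- ku[system$free] - f[system$free]
  scale <- max(sum(abs(f)), max(abs(ku)), 1e-30)
  eq_res <- max(abs(res_free)) / scale

  mesh <- system$mesh
  Ux <- matrix(u[3 * mesh$elements - 2], ncol = 4)
  Uy <- matrix(u[3 * mesh$elements - 1], ncol = 4)
  Uz <- matrix(u[3 * mesh$elements], ncol = 4)
  exx <- rowSums(system$Gx * Ux)
  eyy <- rowSums(system$Gy * Uy)
  ezz <- rowSums(system$Gz * Uz)
  gxy <- rowSums(system$Gy * Ux + system$Gx * Uy)
  gyz <- rowSums(system$Gz * Uy + system$Gy * Uz)
  gzx <- rowSums(system$Gx * Uz + system$Gz * Ux)
  strain <- cbind(xx = exx, yy = eyy, zz = ezz, xy = gxy, yz = gyz, zx = gzx)
  lam <- system$E * system$nu / ((1 + system$nu) * (1 - 2 * system$nu))
  mu <- system$E / (2 * (1 + system$nu))
  tr <- exx + eyy + ezz
  stress <- cbind(xx = lam * tr + 2 * mu * exx,
                  yy = lam * tr + 2 * mu * eyy,
                  zz = lam * tr + 2 * mu * ezz,
                  xy = mu * gxy, yz = mu * gyz, zx = mu * gzx)
  vm_stress <- von_mises(stress)
  vm_strain <- 1e6 * von_mises_strain(strain, system$nu)
  structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                 strain = strain, stress = stress,
                 von_mises_stress = vm_stress,
                 von_mises_strain = vm_strain,
                 element_volume = system$V,
                 reactions = reactions,
                 equilibrium_residual = eq_res,
                 load = load),
            class = "fe_result")
}

#' Von Mises equivalent stress
#'
#' `sqrt(((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2) / 2)` expressed directly in
#' stress components; zero for hydrostatic states, `sigma` for uniaxial
#' stress, `sqrt(3) tau` for pure shear.
#'
#' @param stress length-6 Voigt vector (xx, yy, zz, xy, yz, zx) or an
#'   m x 6 matrix of them; MPa.
#' @return equivalent stress (MPa), scalar or vector.
#' @export
von_mises <- function(stress) {
  s <- if (is.matrix(stress)) stress else matrix(stress, ncol = 6)
  v <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                     (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (is.matrix(stress)) v else v[1]
}

#' Von Mises equivalent strain
#'
#' The `(1 + nu)`-consistent convention (see [solve_linear_static()]):
#' computed from the strain deviator so that uniaxial stress at strain
#' `eps` returns `eps`.
#'
#' @param strain length-6 Voigt vector or m x 6 matrix, engineering shears.
#' @param nu Poisson's ratio (scalar or per-row).
#' @return equivalent strain (same units as input), scalar or vector.
#' @export
von_mises_strain <- function(strain, nu = 0.3) {
  e <- if (is.matrix(strain)) strain else matrix(strain, ncol = 6)
  v <- sqrt(0.5 * ((e[, 1] - e[, 2])^2 + (e[, 2] - e[, 3])^2 +
                     (e[, 3] - e[, 1])^2) +
              0.75 * (e[, 4]^2 + e[, 5]^2 + e[, 6]^2)) / (1 + nu)
  if (is.matrix(strain)) v else v[1]
}

#' Principal stresses and directions of one stress tensor
#'
#' Tension-positive eigen-decomposition, sorted `s11 >= s22 >= s33`, with
#' orthonormal direction columns.
#'
#' @param stress length-6 Voigt vector (xx, yy, zz, xy, yz, zx).
#' @return list with `values` (length 3, decreasing) and `directions`
#'   (3 x 3, columns matching `values`).
#' @export
principal_stresses <- function(stress) {
  S <- matrix(c(stress[1], stress[4], stress[6],
                stress[4], stress[2], stress[5],
                stress[6], stress[5], stress[3]), 3, 3)
  ev <- eigen(S, symmetric = TRUE)
  list(values = ev$values, directions = ev$vectors)
}

#' Principal stress fields for every element
#'
#' @param stress m x 6 Voigt stress matrix.
#' @return list with `values` (m x 3, decreasing per row) and `directions`
#'   (3 x 3 x m array, columns matching values), plus `degenerate` flags for
#'   elements with nearly equal principal values (direction ill-defined).
#' @export
principal_stress_field <- function(stress) {
  m <- nrow(stress)
  vals <- matrix(0, m, 3)
  dirs <- array(0, c(3, 3, m))
  for (e in seq_len(m)) {
    p <- principal_stresses(stress[e, ])
    vals[e, ] <- p$values
    dirs[, , e] <- p$directions
  }
  spread <- vals[, 1] - vals[, 3]
  degenerate <- spread <= 1e-8 * pmax(abs(vals[, 1]), abs(vals[, 3]), 1e-30)
  list(values = vals, directions = dirs, degenerate = degenerate)
}

#' Mean von Mises element strain of a solved case
#'
#' @param result an `fe_result`.
#' @return list with unweighted `mean` and `sd` over elements (microstrain;
#'   the primary summary) and the volume-weighted variants.
#' @export
mean_vm_strain <- function(result) {
  v <- result$von_mises_strain
  w <- result$element_volume / sum(result$element_volume)
  mw <- sum(w * v)
  list(mean = mean(v), sd = stats::sd(v),
       mean_volume_weighted = mw,
       sd_volume_weighted = sqrt(sum(w * (v - mw)^2)))
}
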