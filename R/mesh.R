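#' Construct a tetrahedral mesh
#'
#' Nodes are in millimetres; elements are 4-node (constant-strain)
#' tetrahedra stored as 1-based row indices into `nodes`. Signed volumes must
#' be positive: element ordering follows the usual convention where the
#' fourth node lies on the positive side of the oriented base triangle.
#'
#' @param nodes numeric n x 3 matrix of coordinates (mm).
#' @param elements integer m x 4 connectivity matrix.
#' @param material_id optional integer vector (length m) of material class ids.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, material_id = NULL) {
  nodes <- as.matrix(nodes)
  elements <- matrix(as.integer(elements), ncol = 4)
  if (ncol(nodes) != 3) stop("`nodes` must be n x 3")
  if (min(elements) < 1 || max(elements) > nrow(nodes))
    stop("connectivity indices out of range")
  if (!is.null(material_id) && length(material_id) != nrow(elements))
    stop("`material_id` must have one entry per element")
  m <- structure(list(nodes = nodes, elements = elements,
                      material_id = material_id), class = "tet_mesh")
  v <- tet_volumes(m)
  if (any(v <= 0))
    stop(sprintf("%d elements have non-positive signed volume (first: %d)",
                 sum(v <= 0), which(v <= 0)[1]))
  orphan <- setdiff(seq_len(nrow(nodes)), unique(as.vector(elements)))
  if (length(orphan) > 0)
    stop(sprintf("%d orphan nodes not referenced by any element", length(orphan)))
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra\n",
              nrow(x$nodes), nrow(x$elements)))
  invisible(x)
}

#' Signed element volumes (mm^3), vectorized over elements
#' @param mesh a `tet_mesh`
#' @return numeric vector of volumes
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elements
  a <- n[e[, 2], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  b <- n[e[, 3], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  d <- n[e[, 4], , drop = FALSE] - n[e[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  (cx * d[, 1] + cy * d[, 2] + cz * d[, 3]) / 6
}

#' Element centroids (mm)
#' @param mesh a `tet_mesh`
#' @return m x 3 matrix
#' @export
tet_centroids <- function(mesh) {
  e <- mesh$elements
  (mesh$nodes[e[, 1], , drop = FALSE] + mesh$nodes[e[, 2], , drop = FALSE] +
   mesh$nodes[e[, 3], , drop = FALSE] + mesh$nodes[e[, 4], , drop = FALSE]) / 4
}

# the four oriented faces of each tet (outward normals for positive volume)
.tet_face_local <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))

#' Boundary surface of a tet mesh
#'
#' Faces that belong to exactly one tetrahedron. For a watertight mesh every
#' other face is shared by exactly two.
#'
#' @param mesh a `tet_mesh`
#' @return list with `faces` (k x 3 node indices, outward-oriented),
#'   `element` (owning tet of each face), and `shared_ok` (TRUE if all
#'   interior faces are shared by exactly two tets).
#' @export
surface_faces <- function(mesh) {
  e <- mesh$elements
  m <- nrow(e)
  faces <- do.call(rbind, lapply(1:4, function(f)
    cbind(e[, .tet_face_local[f, 1]], e[, .tet_face_local[f, 2]],
          e[, .tet_face_local[f, 3]])))
  owner <- rep(seq_len(m), 4)
  srt <- cbind(pmin(faces[, 1], faces[, 2], faces[, 3]),
               pmax(faces[, 1], faces[, 2], faces[, 3]))
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - srt[, 1] - srt[, 2]
  nn <- max(faces) + 1
  key <- (srt[, 1] * nn + mid) * nn + srt[, 2]
  cnt <- table(key)
  multi <- as.numeric(names(cnt)[cnt > 2])
  if (length(multi) > 0)
    return(list(faces = NULL, element = NULL, shared_ok = FALSE))
  solo <- as.numeric(names(cnt)[cnt == 1])
  keep <- key %in% solo
  list(faces = faces[keep, , drop = FALSE], element = owner[keep],
       shared_ok = TRUE)
}

#' Areas and outward normals of a set of triangular faces
#' @param mesh a `tet_mesh`
#' @param faces k x 3 matrix of node indices (oriented)
#' @return list with `area` (mm^2) and `normal` (k x 3 unit vectors)
#' @export
face_geometry <- function(mesh, faces) {
  p1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  p2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  p3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  a2 <- sqrt(rowSums(n^2))
  list(area = a2 / 2, normal = n / a2,
       centroid = (p1 + p2 + p3) / 3)
}

#' Minimum dihedral angle of each element (degrees)
#' @param mesh a `tet_mesh`
#' @return numeric vector, one value per element
#' @export
min_dihedral_angles <- function(mesh) {
  e <- mesh$elements
  # inward unit normals of the 4 faces
  nrm <- vector("list", 4)
  for (f in 1:4) {
    fa <- .tet_face_local[f, ]
    p1 <- mesh$nodes[e[, fa[1]], , drop = FALSE]
    p2 <- mesh$nodes[e[, fa[2]], , drop = FALSE]
    p3 <- mesh$nodes[e[, fa[3]], , drop = FALSE]
    u <- p2 - p1; v <- p3 - p1
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    nrm[[f]] <- -n / sqrt(rowSums(n^2))   # inward
  }
  pairs <- utils::combn(4, 2)
  ang <- matrix(NA_real_, nrow(e), ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    d <- rowSums(nrm[[pairs[1, k]]] * nrm[[pairs[2, k]]])
    ang[, k] <- 180 - acos(pmin(1, pmax(-1, d))) * 180 / pi
  }
  apply(ang, 1, min)
}

#' Write / read a tet mesh as legacy VTK ASCII
#'
#' Unstructured-grid format (`DATASET UNSTRUCTURED_GRID`, cell type 10).
#' Optional per-cell scalar fields are written as `CELL_DATA` arrays.
#'
#' @param mesh a `tet_mesh`
#' @param path output file
#' @param cell_data named list of numeric per-element vectors
#' @return `path`, invisibly
#' @export
write_vtk_mesh <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(format(r, digits = 12), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(mesh$elements - 1L, 1, function(r) paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (!is.null(mesh$material_id)) cell_data$material_id <- mesh$material_id
  if (length(cell_data) > 0) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 12), con)
    }
  }
  invisible(path)
}

#' @rdname write_vtk_mesh
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE)
  cells <- matrix(cells, ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4)) stop("only tetrahedral cells supported")
  mat <- NULL
  is_mat <- grep("^SCALARS material_id", lines)
  if (length(is_mat) == 1)
    mat <- as.integer(scan(text = lines[(is_mat + 2):(is_mat + 1 + m)], quiet = TRUE))
  tet_mesh(nodes, cells[, 2:5] + 1L, material_id = mat)
}

#' Structured box mesh of tetrahedra
#'
#' Kuhn triangulation of a regular hexahedral grid: each cell is split into
#' six tetrahedra sharing the main diagonal, which is face-consistent across
#' neighbouring cells, so the mesh is conforming and watertight. Intended
#' for solver verification problems (patch tests, bars, beams).
#'
#' @param size box edge lengths (mm, length 3).
#' @param n cells per axis (length 3).
#' @param origin minimum corner (mm).
#' @return a [tet_mesh()].
#' @export
box_mesh <- function(size = c(1, 1, 1), n = c(4, 4, 4), origin = c(0, 0, 0)) {
  n <- as.integer(n)
  nx <- n[1] + 1L; ny <- n[2] + 1L; nz <- n[3] + 1L
  xs <- origin[1] + size[1] * (0:n[1]) / n[1]
  ys <- origin[2] + size[2] * (0:n[2]) / n[2]
  zs <- origin[3] + size[3] * (0:n[3]) / n[3]
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  even <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  cells <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  elems <- matrix(0L, 6L * nrow(cells), 4)
  e <- 0L
  for (r in seq_len(nrow(cells))) {
    base <- c(cells$i[r], cells$j[r], cells$k[r])
    for (p in 1:6) {
      vv <- matrix(base, 4, 3, byrow = TRUE)
      for (s in 1:3) vv[(s + 1):4, perms[p, s]] <- vv[(s + 1):4, perms[p, s]] + 1L
      ids <- nid(vv[, 1], vv[, 2], vv[, 3])
      if (!even[p]) ids <- ids[c(1, 2, 4, 3)]
      e <- e + 1L
      elems[e, ] <- ids
    }
  }
  tet_mesh(nodes, elems)
}
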