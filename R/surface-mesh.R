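#' Triangle mesh container
#'
#' @param vertices N x 3 numeric matrix of coordinates in mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices; faces are
#'   expected to be consistently oriented with outward normals.
#' @param hemisphere Optional "left"/"right"/"both" tag.
#' @return A \code{cortical_mesh}.
#' @export
cortical_mesh <- function(vertices, faces, hemisphere = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces,
                 hemisphere = hemisphere), class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  top <- mesh_topology(x)
  cat(sprintf("Cortical mesh: %d vertices, %d faces, %s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (top$closed) sprintf("closed (genus %d)", top$genus)
              else sprintf("open (%d boundary edges)", top$n_boundary_edges),
              if (!is.null(x$hemisphere)) paste0(", ", x$hemisphere) else ""))
  invisible(x)
}

.face_geometry <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  p1 <- V[Fc[, 1], , drop = FALSE]
  p2 <- V[Fc[, 2], , drop = FALSE]
  p3 <- V[Fc[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(nrm^2))
  list(normal = nrm, area = area)
}

#' Per-vertex areas
#'
#' Each vertex receives one third of the summed areas of its incident
#' triangles, so the vertex areas partition the total surface area exactly.
#' Degenerate zero-area faces contribute nothing.
#'
#' @param mesh A \code{cortical_mesh}.
#' @return List with \code{vertex_area} (mm^2, length N) and
#'   \code{total_area} (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fg <- .face_geometry(mesh)
  n <- nrow(mesh$vertices)
  va <- numeric(n)
  third <- fg$area / 3
  for (c_i in 1:3) {
    acc <- rowsum(third, mesh$faces[, c_i])
    va[as.integer(rownames(acc))] <- va[as.integer(rownames(acc))] + acc[, 1]
  }
  list(vertex_area = va, total_area = sum(fg$area))
}

#' Outward vertex normals (area-weighted face normal average)
#' @param mesh A \code{cortical_mesh} with outward-oriented faces.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fg <- .face_geometry(mesh)
  n <- nrow(mesh$vertices)
  acc <- matrix(0, n, 3)
  for (c_i in 1:3) {
    a <- rowsum(fg$normal, mesh$faces[, c_i])
    idx <- as.integer(rownames(a))
    acc[idx, ] <- acc[idx, ] + a
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

# Meyer mixed vertex area: Voronoi area for non-obtuse triangles, area/2 at
# the obtuse corner and area/4 elsewhere otherwise. More accurate than the
# barycentric third for curvature normalization on irregular meshes.
.mixed_vertex_area <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  n <- nrow(V)
  p <- lapply(1:3, function(c_i) V[Fc[, c_i], , drop = FALSE])
  e <- list(p[[3]] - p[[2]], p[[1]] - p[[3]], p[[2]] - p[[1]])  # opposite edges
  l2 <- vapply(e, function(x) rowSums(x^2), numeric(nrow(Fc)))
  cr <- cbind(e[[3]][, 2] * (-e[[2]])[, 3] - e[[3]][, 3] * (-e[[2]])[, 2],
              e[[3]][, 3] * (-e[[2]])[, 1] - e[[3]][, 1] * (-e[[2]])[, 3],
              e[[3]][, 1] * (-e[[2]])[, 2] - e[[3]][, 2] * (-e[[2]])[, 1])
  area2 <- sqrt(rowSums(cr^2))  # 2 * face area
  area <- area2 / 2
  # cot of the angle at corner c = dot of adjacent edges / (2 * area)
  cotc <- cbind(rowSums((-e[[2]]) * e[[3]]),
                rowSums((-e[[3]]) * e[[1]]),
                rowSums((-e[[1]]) * e[[2]])) / pmax(area2, 1e-300)
  obtuse_at <- max.col(-cotc) * (apply(cotc, 1, min) < 0)
  acc <- numeric(n)
  for (c_i in 1:3) {
    others <- setdiff(1:3, c_i)
    vor <- (l2[, others[1]] * cotc[, others[1]] +
            l2[, others[2]] * cotc[, others[2]]) / 8
    contrib <- ifelse(obtuse_at == 0L, vor,
                      ifelse(obtuse_at == c_i, area / 2, area / 4))
    a <- rowsum(contrib, Fc[, c_i])
    idx <- as.integer(rownames(a))
    acc[idx] <- acc[idx] + a[, 1]
  }
  acc
}

#' Discrete mean curvature
#'
#' Cotangent-Laplacian mean-curvature normal: for vertex i,
#' \eqn{K_i = \sum_j (\cot\alpha_{ij} + \cot\beta_{ij})(x_i - x_j)} over
#' incident edges, and \eqn{H_i = \|K_i\| / (4 A_i)} with Meyer mixed vertex
#' area \eqn{A_i}, signed positive when \eqn{K_i} points along the outward
#' normal (so a sphere of radius r has \eqn{H = +1/r}). Units 1/mm.
#'
#' Boundary vertices of an open mesh have undefined curvature and are
#' returned as NA with a warning.
#'
#' @param mesh A closed, consistently oriented \code{cortical_mesh}.
#' @param field_smoothing Number of uniform neighbor-averaging passes
#'   applied to the signed curvature field, a numerical regularization for
#'   meshes extracted from voxel data (0 = none).
#' @return N-vector of signed mean curvature (1/mm).
#' @export
mean_curvature <- function(mesh, field_smoothing = 0L) {
  V <- mesh$vertices; Fc <- mesh$faces
  n <- nrow(V)
  cot3 <- function(a, b, c) {
    # cotangent of the angle at a in triangle (a, b, c)
    u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    v <- V[c, , drop = FALSE] - V[a, , drop = FALSE]
    dt <- rowSums(u * v)
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    crn <- sqrt(rowSums(cr^2))
    crn[crn < 1e-300] <- 1e-300
    dt / crn
  }
  i1 <- Fc[, 1]; i2 <- Fc[, 2]; i3 <- Fc[, 3]
  w12 <- cot3(i3, i1, i2)  # angle opposite edge (1,2)
  w23 <- cot3(i1, i2, i3)
  w31 <- cot3(i2, i3, i1)
  ii <- c(i1, i2, i2, i3, i3, i1)
  jj <- c(i2, i1, i3, i2, i1, i3)
  ww <- c(w12, w12, w23, w23, w31, w31) / 2
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  K <- as.matrix(Matrix::Diagonal(x = Matrix::rowSums(W)) %*% V - W %*% V)
  va <- .mixed_vertex_area(mesh)
  H <- sqrt(rowSums(K^2)) / (2 * pmax(va, 1e-300))
  sgn <- sign(rowSums(K * vertex_normals(mesh)))
  sgn[sgn == 0] <- 1
  H <- H * sgn
  if (field_smoothing > 0L) {
    i_all <- c(i1, i2, i2, i3, i3, i1)
    j_all <- c(i2, i1, i3, i2, i1, i3)
    Adj <- Matrix::sparseMatrix(i = i_all, j = j_all, x = 1,
                                dims = c(n, n)) > 0
    deg <- pmax(Matrix::rowSums(Adj), 1)
    for (p_i in seq_len(field_smoothing)) H <- as.vector(Adj %*% H) / deg
  }
  top <- mesh_topology(mesh)
  if (!top$closed) {
    H[top$boundary_vertices] <- NA_real_
    warning(sprintf("open mesh: curvature undefined at %d boundary vertices",
                    length(top$boundary_vertices)), call. = FALSE)
  }
  H
}

#' Discrete Gaussian curvature (angle defect)
#'
#' \eqn{K_i = (2\pi - \sum \theta)/A_i}; by the discrete Gauss-Bonnet
#' theorem the total angle defect of a closed mesh is \eqn{2\pi\chi}.
#'
#' @param mesh A \code{cortical_mesh}.
#' @return List with \code{gaussian_curvature} (1/mm^2) and
#'   \code{total_angle_defect}.
#' @export
gaussian_curvature <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  n <- nrow(V)
  angle_at <- function(a, b, c) {
    u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    v <- V[c, , drop = FALSE] - V[a, , drop = FALSE]
    cosv <- rowSums(u * v) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)), 1e-300)
    acos(pmin(pmax(cosv, -1), 1))
  }
  ang <- numeric(n)
  for (c_i in 1:3) {
    others <- setdiff(1:3, c_i)
    a <- rowsum(angle_at(Fc[, c_i], Fc[, others[1]], Fc[, others[2]]),
                Fc[, c_i])
    idx <- as.integer(rownames(a))
    ang[idx] <- ang[idx] + a[, 1]
  }
  defect <- 2 * pi - ang
  va <- vertex_areas(mesh)$vertex_area
  list(gaussian_curvature = defect / pmax(va, 1e-300),
       total_angle_defect = sum(defect))
}

#' Mesh topology summary
#'
#' @param mesh A \code{cortical_mesh}.
#' @return List: vertex/edge/face counts, Euler characteristic, genus (for
#'   closed meshes), \code{closed}, boundary edge count and boundary
#'   vertices.
#' @export
mesh_topology <- function(mesh) {
  Fc <- mesh$faces
  e <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  n_edges <- length(tab)
  boundary <- names(tab)[tab == 1L]
  nv <- nrow(mesh$vertices); nf <- nrow(Fc)
  chi <- nv - n_edges + nf
  closed <- length(boundary) == 0L && all(tab == 2L)
  bverts <- if (length(boundary)) {
    unique(as.integer(unlist(strsplit(boundary, " "))))
  } else integer(0)
  list(n_vertices = nv, n_edges = n_edges, n_faces = nf, euler = chi,
       genus = if (closed) as.integer(round(1 - chi / 2)) else NA_integer_,
       closed = closed, n_boundary_edges = length(boundary),
       boundary_vertices = bverts)
}

#' Non-dimensionalized curvature K*
#'
#' Area-weighted mean of the mean-curvature magnitude times the
#' characteristic radius \eqn{\sqrt{SA/4\pi}}. Dimensionless, scale
#' invariant, equal to 1 for a sphere, and increasing with cortical
#' folding.
#'
#' @param mesh A closed \code{cortical_mesh}.
#' @param field_smoothing Passed to \code{\link{mean_curvature}}.
#' @return Scalar K*.
#' @export
nondimensional_curvature <- function(mesh, field_smoothing = 0L) {
  va <- vertex_areas(mesh)
  if (va$total_area <= 0) stop("zero surface area", call. = FALSE)
  H <- abs(mean_curvature(mesh, field_smoothing))
  ok <- !is.na(H)
  h_mean <- sum(H[ok] * va$vertex_area[ok]) / sum(va$vertex_area[ok])
  h_mean * sqrt(va$total_area / (4 * pi))
}

#' Morphometric cortical thickness
#'
#' Cortical plate volume divided by mid-cortical surface area, reported in
#' mm: \code{10 * volume_mL / surface_area_cm2}.
#'
#' @param cortical_plate_volume_ml Volume in mL (= cm^3).
#' @param surface_area_cm2 Mid-cortical surface area in cm^2.
#' @return Thickness in mm.
#' @export
morphometric_thickness <- function(cortical_plate_volume_ml,
                                   surface_area_cm2) {
  if (any(surface_area_cm2 <= 0)) {
    stop("surface area must be positive", call. = FALSE)
  }
  10 * cortical_plate_volume_ml / surface_area_cm2
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; faces oriented outward.
#'
#' @param radius Sphere radius (mm).
#' @param subdivisions Number of 4-to-1 triangle subdivisions.
#' @param center Sphere center.
#' @return A \code{cortical_mesh}.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    ne <- nrow(f)
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(key)
    mididx <- nrow(v) + match(key, uk)
    first <- match(uk, key)
    mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mididx[1:ne]; m23 <- mididx[ne + 1:ne]; m31 <- mididx[2 * ne + 1:ne]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  cortical_mesh(v, f)
}

#' Taubin lambda-mu mesh smoothing
#'
#' Alternating positive/negative uniform-Laplacian steps: low-pass filtering
#' of the vertex positions without the volume shrinkage of plain Laplacian
#' smoothing. Used to remove voxel-scale staircase artifacts from extracted
#' isosurfaces before curvature estimation.
#'
#' @param mesh A \code{cortical_mesh}.
#' @param iterations Number of lambda+mu passes.
#' @param lambda,mu Step sizes (defaults are the standard shrink-free pair).
#' @return The smoothed \code{cortical_mesh}.
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5,
                          mu = -0.53) {
  Fc <- mesh$faces
  n <- nrow(mesh$vertices)
  e <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  A <- A > 0
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(A %*% V) / deg - V)
    V <- V + mu * (as.matrix(A %*% V) / deg - V)
  }
  cortical_mesh(V, Fc, hemisphere = mesh$hemisphere)
}

#' Keep the largest connected component of a mesh
#'
#' @param mesh A \code{cortical_mesh}.
#' @return A \code{cortical_mesh} restricted to the largest vertex-connected
#'   component, with vertices reindexed.
#' @export
largest_component <- function(mesh) {
  Fc <- mesh$faces
  g <- igraph::graph_from_edgelist(
    rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which.max(comp$csize)
  vkeep <- comp$membership == keep
  fkeep <- vkeep[Fc[, 1]] & vkeep[Fc[, 2]] & vkeep[Fc[, 3]]
  remap <- cumsum(vkeep)
  cortical_mesh(mesh$vertices[vkeep, , drop = FALSE],
                matrix(remap[Fc[fkeep, ]], ncol = 3),
                hemisphere = mesh$hemisphere)
}

#' Write a mesh as Wavefront OBJ
#'
#' Plain-text OBJ (vertices in mm, 1-based faces), readable by any mesh
#' tool; per-vertex scalars are best written alongside as CSV.
#'
#' @param mesh A \code{cortical_mesh}.
#' @param path Output .obj path.
#' @return The path, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' @param path .obj file with v/f records (triangles).
#' @return A \code{cortical_mesh}.
#' @export
read_mesh_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  cortical_mesh(v, f)
}
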