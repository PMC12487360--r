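# Mid-cortical surface extraction from anatomical label volumes.
# Pipeline: hemisphere restriction -> removal of brainstem, cerebellum and
# extra-axial CSF -> distance-based reassignment of cortical plate voxels
# (deep half joins the interior mask) -> 5x5x5 box smoothing -> isosurface
# at 0.5 -> largest connected component.

# Separable k^3 box filter (zero padding), equivalent to convolution with a
# normalized box kernel.
.box_smooth3 <- function(arr, k = 5L) {
  stopifnot(k %% 2L == 1L)
  h <- (k - 1L) %/% 2L
  run1 <- function(x, dim_i) {
    d <- dim(x)
    perm <- c(dim_i, setdiff(1:3, dim_i))
    xp <- aperm(x, perm)
    m <- matrix(xp, nrow = d[dim_i])
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(seq_len(n) + h, n)
    lo <- pmax(seq_len(n) - h, 1L)
    out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / k
    xp <- array(out, dim = d[perm])
    aperm(xp, order(perm))
  }
  for (i in 1:3) arr <- run1(arr, i)
  arr
}

# Euclidean distance (in voxels) from every voxel to the nearest voxel of
# `target_mask`. Assumes isotropic voxels.
.distance_to_set <- function(target_mask) {
  if (!any(target_mask)) stop("empty target set", call. = FALSE)
  src <- array(1, dim = dim(target_mask))
  src[target_mask] <- 0
  as.array(EBImage::distmap(src, metric = "euclidean"))
}

#' Isosurface by marching tetrahedra
#'
#' Extracts the level surface of a 3-D scalar field sampled on a regular
#' grid. Each grid cube is split into six tetrahedra around its main
#' diagonal (a decomposition that is consistent across neighboring cubes),
#' surface vertices are placed by linear interpolation along tetrahedron
#' edges, and triangles are oriented so normals point from the
#' above-level region outward. Sample values exactly at the level are
#' nudged to the above side, matching the convention that ties belong to
#' the interior. The result is a closed 2-manifold whenever the above-level
#' region does not touch the grid boundary.
#'
#' @param field 3-D numeric array.
#' @param level Iso-level.
#' @param spacing Grid spacing per axis (mm).
#' @param origin World coordinate of the first sample.
#' @return A \code{cortical_mesh} in world coordinates (possibly with
#'   several connected components).
#' @export
marching_tetrahedra <- function(field, level = 0.5, spacing = c(1, 1, 1),
                                origin = c(0, 0, 0)) {
  d <- dim(field)
  stopifnot(length(d) == 3L, all(d >= 2L))
  s <- as.numeric(field) - level
  s[s == 0] <- 1e-12
  dim(s) <- d
  inside <- s > 0

  II <- array(0L, d); II[inside] <- 1L
  i1 <- 1:(d[1] - 1L); i2 <- 2:d[1]
  j1 <- 1:(d[2] - 1L); j2 <- 2:d[2]
  k1 <- 1:(d[3] - 1L); k2 <- 2:d[3]
  csum <- II[i1, j1, k1] + II[i2, j1, k1] + II[i1, j2, k1] + II[i2, j2, k1] +
          II[i1, j1, k2] + II[i2, j1, k2] + II[i1, j2, k2] + II[i2, j2, k2]
  cross_cubes <- which(csum > 0L & csum < 8L)
  if (!length(cross_cubes)) {
    stop("field does not cross the iso-level", call. = FALSE)
  }
  cube_ijk <- arrayInd(cross_cubes, d - 1L)

  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  corner_idx <- matrix(0, nrow(cube_ijk), 8)
  for (c_i in 1:8) {
    corner_idx[, c_i] <- (cube_ijk[, 1] + off[c_i, 1]) +
      (cube_ijk[, 2] + off[c_i, 2] - 1) * d[1] +
      (cube_ijk[, 3] + off[c_i, 3] - 1) * d[1] * d[2]
  }

  # Kuhn decomposition: six tetrahedra sharing the c0-c7 diagonal
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  # per-case triangle table: rows of (in, out) slot pairs, 3 edges/triangle
  case_tbl <- vector("list", 14L)
  for (b in 1:14) {
    bits <- c(bitwAnd(b, 1L), bitwAnd(b, 2L), bitwAnd(b, 4L), bitwAnd(b, 8L))
    ins <- which(bits > 0L); outs <- setdiff(1:4, ins)
    case_tbl[[b]] <- if (length(ins) == 1L) {
      matrix(c(ins, outs[1], ins, outs[2], ins, outs[3]), nrow = 1)
    } else if (length(ins) == 3L) {
      matrix(c(ins[1], outs, ins[2], outs, ins[3], outs), nrow = 1)
    } else {
      p1 <- ins[1]; p2 <- ins[2]; q1 <- outs[1]; q2 <- outs[2]
      rbind(c(p1, q1, p1, q2, p2, q2),
            c(p1, q1, p2, q2, p2, q1))
    }
  }

  ein <- list(); eout <- list(); nblock <- 0L
  for (t_i in 1:6) {
    tid <- corner_idx[, tets[t_i, ], drop = FALSE]
    tin <- matrix(inside[tid], ncol = 4)
    b <- tin[, 1] + 2L * tin[, 2] + 4L * tin[, 3] + 8L * tin[, 4]
    for (bb in 1:14) {
      rows <- which(b == bb)
      if (!length(rows)) next
      tdef <- case_tbl[[bb]]
      for (r in seq_len(nrow(tdef))) {
        nblock <- nblock + 1L
        ein[[nblock]] <- cbind(tid[rows, tdef[r, 1]],
                               tid[rows, tdef[r, 3]],
                               tid[rows, tdef[r, 5]])
        eout[[nblock]] <- cbind(tid[rows, tdef[r, 2]],
                                tid[rows, tdef[r, 4]],
                                tid[rows, tdef[r, 6]])
      }
    }
  }
  ein <- do.call(rbind, ein)   # ntri x 3 inside grid endpoints
  eout <- do.call(rbind, eout) # ntri x 3 outside grid endpoints

  ng <- prod(d)
  key <- pmin(ein, eout) + ng * pmax(ein, eout)  # ntri x 3 edge keys
  ukey <- unique(as.vector(key))
  vid <- matrix(match(as.vector(key), ukey), ncol = 3)
  first <- match(ukey, as.vector(key))
  ga <- as.vector(ein)[first]; gb <- as.vector(eout)[first]
  tt <- s[ga] / (s[ga] - s[gb])
  pa <- arrayInd(ga, d); pb <- arrayInd(gb, d)
  verts <- (pa - 1 + tt * (pb - pa))
  verts <- sweep(sweep(verts, 2, spacing, "*"), 2, origin, "+")

  # orient: normal away from the inside endpoints of the triangle's edges
  v1 <- verts[vid[, 1], , drop = FALSE]
  v2 <- verts[vid[, 2], , drop = FALSE]
  v3 <- verts[vid[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  to_world <- function(gi) {
    sweep(sweep(arrayInd(gi, d) - 1, 2, spacing, "*"), 2, origin, "+")
  }
  pin <- (to_world(ein[, 1]) + to_world(ein[, 2]) + to_world(ein[, 3])) / 3
  cen <- (v1 + v2 + v3) / 3
  flip <- rowSums(nrm * (cen - pin)) < 0
  faces <- vid
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]

  cortical_mesh(verts, faces)
}

#' Extract the mid-cortical surface from a label volume
#'
#' Implements the mask-editing construction of the mid-cortical surface:
#' after restricting to one hemisphere (mid-sagittal split at the volume's
#' x-midpoint unless \code{hemisphere = "both"}), the brainstem, cerebellum
#' and extra-axial CSF labels are removed; remaining non-cortical-plate
#' labels form the interior binary mask; each cortical plate voxel is added
#' to the mask when its Euclidean distance to the interior mask is no
#' greater than its distance to the outside of the brain (ties join the
#' interior), and dropped otherwise, so the mask boundary runs through the
#' middle depth of the cortical plate. The edited mask is smoothed with a
#' 5x5x5 uniform box filter and the 0.5-isosurface is extracted by
#' \code{\link{marching_tetrahedra}} in world coordinates; the largest
#' connected component is returned. Extraction is deterministic. Assumes
#' isotropic voxels for the distance comparison.
#'
#' @param vol A \code{label_volume} containing cortical plate (label 2) and
#'   at least one interior label.
#' @param hemisphere "left", "right", or "both".
#' @param smooth_iterations Taubin smoothing passes applied to the extracted
#'   mesh to remove voxel-scale staircase artifacts (see
#'   \code{\link{taubin_smooth}}).
#' @return A \code{cortical_mesh} (mm, world coordinates). A topology
#'   warning with the boundary-edge count is issued if the result is not
#'   closed.
#' @export
extract_midcortical_surface <- function(vol,
                                        hemisphere = c("left", "right",
                                                       "both"),
                                        smooth_iterations = 50L) {
  stopifnot(inherits(vol, "label_volume"))
  hemisphere <- match.arg(hemisphere)
  lab <- vol$labels
  d <- dim(lab)
  if (hemisphere != "both") {
    mid <- d[1] / 2
    xs <- seq_len(d[1])
    keep <- if (hemisphere == "left") xs <= mid else xs > mid
    lab[!keep, , ] <- 0L
  }
  lab[lab %in% c(1L, 7L, 8L)] <- 0L  # drop CSF, cerebellum, brainstem
  cp <- lab == 2L
  interior <- lab != 0L & !cp
  if (!any(cp)) stop("no cortical plate voxels", call. = FALSE)
  if (!any(interior)) stop("no interior (non-cortical-plate) labels",
                           call. = FALSE)
  background <- lab == 0L
  d_int <- .distance_to_set(interior)
  d_bg <- .distance_to_set(background)
  mask <- array(0, d)
  mask[interior] <- 1
  deep_cp <- cp & (d_int <= d_bg)
  mask[deep_cp] <- 1
  sm <- .box_smooth3(mask, 5L)
  mesh <- marching_tetrahedra(sm, level = 0.5, spacing = vol$voxel_dims)
  mesh <- largest_component(mesh)
  mesh <- taubin_smooth(mesh, iterations = smooth_iterations)
  mesh$hemisphere <- hemisphere
  top <- mesh_topology(mesh)
  if (!top$closed) {
    warning(sprintf("extracted surface is not closed (%d boundary edges)",
                    top$n_boundary_edges), call. = FALSE)
  }
  mesh
}

#' Global surface metrics for one mesh
#'
#' @param mesh A closed \code{cortical_mesh}.
#' @param cortical_plate_volume_ml Optional cortical plate volume (mL) for
#'   the thickness computation.
#' @param field_smoothing Curvature-field smoothing passes (see
#'   \code{\link{mean_curvature}}); the default suits meshes extracted
#'   from voxel data.
#' @return List: \code{surface_area_cm2}, \code{k_star},
#'   \code{characteristic_radius_mm}, and \code{thickness_mm} when the
#'   volume is supplied.
#' @export
surface_metrics <- function(mesh, cortical_plate_volume_ml = NULL,
                            field_smoothing = 10L) {
  va <- vertex_areas(mesh)
  sa_cm2 <- va$total_area / 100
  out <- list(
    surface_area_cm2 = sa_cm2,
    k_star = nondimensional_curvature(mesh, field_smoothing),
    characteristic_radius_mm = sqrt(va$total_area / (4 * pi))
  )
  if (!is.null(cortical_plate_volume_ml)) {
    out$thickness_mm <- morphometric_thickness(cortical_plate_volume_ml,
                                               sa_cm2)
  }
  out
}
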