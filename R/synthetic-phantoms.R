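# Geometric phantoms with analytic ground truth, used to validate the
# volumetric and surface operations.

# Surface area of a star-shaped surface r(theta, phi) by dense quadrature:
# dA = r * sqrt((r^2 + r_theta^2) * sin^2(theta) + r_phi^2) dtheta dphi.
.radial_surface_area <- function(rfun, n_theta = 400L, n_phi = 800L) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  dth <- pi / n_theta; dph <- 2 * pi / n_phi
  TH <- matrix(th, n_theta, n_phi)
  PH <- matrix(ph, n_theta, n_phi, byrow = TRUE)
  r <- rfun(TH, PH)
  eps <- 1e-5
  rt <- (rfun(TH + eps, PH) - rfun(TH - eps, PH)) / (2 * eps)
  rp <- (rfun(TH, PH + eps) - rfun(TH, PH - eps)) / (2 * eps)
  sum(r * sqrt((r^2 + rt^2) * sin(TH)^2 + rp^2)) * dth * dph
}

# Volume enclosed by r(theta, phi): (1/3) int r^3 sin(theta).
.radial_volume <- function(rfun, n_theta = 400L, n_phi = 800L) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  TH <- matrix(th, n_theta, n_phi)
  PH <- matrix(ph, n_theta, n_phi, byrow = TRUE)
  sum(rfun(TH, PH)^3 * sin(TH)) / 3 * (pi / n_theta) * (2 * pi / n_phi)
}

#' Phantom label volumes with analytic ground truth
#'
#' Builds a concentric-shell head phantom on an isotropic voxel grid:
#' ventricle core (label 4), subcortical gray shell (6), subplate shell
#' (3), cortical plate shell (2), and an outer extra-axial CSF shell (1),
#' with empty space beyond. The \code{folded_shell} variant displaces the
#' cortical plate shell (both boundaries, preserving its thickness) by a
#' smooth angular ripple \code{amplitude * sin(l theta) * cos(m phi)},
#' emulating gyrification; zero amplitude reproduces the concentric
#' phantom exactly. The returned truth record carries analytic compartment
#' volumes, the analytic mid-cortical surface area, and the true shell
#' thickness (computed by spherical quadrature for the folded variant).
#'
#' @param kind "concentric_shells" or "folded_shell".
#' @param radii Increasing boundary radii in mm:
#'   ventricles | subcortical | subplate | cortical plate | CSF.
#' @param voxel_mm Isotropic voxel size.
#' @param amplitude Fold amplitude in mm (folded variant).
#' @param l,m Angular frequencies of the fold pattern.
#' @param margin_mm Empty margin around the outer shell.
#' @return List with \code{volume} (a \code{label_volume}) and \code{truth}
#'   (analytic volumes in mL, mid-surface area in mm^2, thickness in mm).
#' @export
make_phantom_labelmap <- function(kind = c("concentric_shells",
                                           "folded_shell"),
                                  radii = c(5, 10, 15, 17, 20),
                                  voxel_mm = 0.5, amplitude = 1.5,
                                  l = 4, m = 3, margin_mm = 2) {
  kind <- match.arg(kind)
  stopifnot(length(radii) == 5L, all(diff(radii) > 0))
  if (kind == "concentric_shells") amplitude <- 0
  if (amplitude >= (radii[3] - radii[2]) ||
      amplitude >= (radii[5] - radii[4])) {
    stop("fold amplitude exceeds the shell margins", call. = FALSE)
  }
  extent <- radii[5] + margin_mm
  n <- as.integer(ceiling(2 * extent / voxel_mm)) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  R <- sqrt(X^2 + Y^2 + Z^2)

  ripple <- if (amplitude > 0) {
    TH <- acos(pmin(pmax(Z / pmax(R, 1e-12), -1), 1))
    PH <- atan2(Y, X)
    amplitude * sin(l * TH) * cos(m * PH)
  } else 0
  r3 <- radii[3] + ripple  # cortical plate inner boundary
  r4 <- radii[4] + ripple  # cortical plate outer boundary

  lab <- array(0L, c(n, n, n))
  lab[R < radii[1]] <- 4L
  lab[R >= radii[1] & R < radii[2]] <- 6L
  lab[R >= radii[2] & R < r3] <- 3L
  lab[R >= r3 & R < r4] <- 2L
  lab[R >= r4 & R < radii[5]] <- 1L

  rip_fun <- function(th, phi) {
    if (amplitude > 0) amplitude * sin(l * th) * cos(m * phi) else 0
  }
  sphere_vol <- function(r) 4 / 3 * pi * r^3
  mid_r <- (radii[3] + radii[4]) / 2
  if (amplitude > 0) {
    v_in <- .radial_volume(function(th, ph) radii[3] + rip_fun(th, ph))
    v_out <- .radial_volume(function(th, ph) radii[4] + rip_fun(th, ph))
    sa_mid <- .radial_surface_area(function(th, ph) mid_r + rip_fun(th, ph))
  } else {
    v_in <- sphere_vol(radii[3]); v_out <- sphere_vol(radii[4])
    sa_mid <- 4 * pi * mid_r^2
  }
  truth <- list(
    volumes_ml = c(
      ventricles = sphere_vol(radii[1]),
      subcortical_gray = sphere_vol(radii[2]) - sphere_vol(radii[1]),
      nascent_white_matter = v_in - sphere_vol(radii[2]),
      cortical_plate = v_out - v_in,
      extra_axial_csf = sphere_vol(radii[5]) - v_out,
      whole_brain = v_out,
      icv = sphere_vol(radii[5])
    ) / 1000,
    mid_surface_area_mm2 = sa_mid,
    thickness_mm = radii[4] - radii[3],
    radii = radii, amplitude = amplitude, voxel_mm = voxel_mm
  )
  list(volume = label_volume(lab, rep(voxel_mm, 3)), truth = truth)
}

#' Write a label volume to NIfTI
#'
#' @param vol A \code{label_volume}.
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- vol$voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Growing mesh sequence with exact vertex correspondence
#'
#' Generates a sequence of icosphere-based meshes whose vertices are
#' displaced radially by a smooth spatial growth field ramped in time by a
#' logistic schedule, emulating registered cortical surfaces across age
#' with known per-vertex area expansion. The radial scale applied to vertex
#' v at age t is \code{sqrt(E(v, t))} with
#' \code{E(v, t) = 1 + (A(v) - 1) * (L(t) - L(t0)) / (1 - L(t0))},
#' \code{L} the logistic ramp, so the recorded truth expansion relative to
#' the first age is exactly \code{E} for a spatially uniform field and
#' approximately \code{E} (to first order in the field gradient) otherwise.
#'
#' @param ages Strictly increasing ages (days); the first is the reference.
#' @param radius Reference icosphere radius (mm).
#' @param subdivisions Icosphere subdivision level.
#' @param amplitude_field Function of an N x 3 matrix of unit directions
#'   returning per-vertex asymptotic expansion A(v) (> 0); default a
#'   smooth occipital-high / frontal-low gradient between 4 and 9.
#' @param rg,tmid Logistic ramp parameters of the time schedule.
#' @return List: \code{ages}, \code{meshes} (list of \code{cortical_mesh}
#'   with identical topology), \code{truth_expansion} (N x n_ages matrix of
#'   generating expansion factors relative to the first age),
#'   \code{provenance = "synthetic_known"}.
#' @export
make_growing_mesh_sequence <- function(ages = c(85, 97, 110, 122, 135, 147,
                                                155, 1770),
                                       radius = 10, subdivisions = 3,
                                       amplitude_field = NULL,
                                       rg = 0.05, tmid = 125) {
  stopifnot(all(diff(ages) > 0), length(ages) >= 2L)
  base <- icosphere(radius, subdivisions)
  dirs <- base$vertices / sqrt(rowSums(base$vertices^2))
  if (is.null(amplitude_field)) {
    amplitude_field <- function(u) 6.5 + 2.5 * u[, 2]  # gradient along y
  }
  A_v <- amplitude_field(dirs)
  if (any(A_v <= 0)) stop("growth field must be positive", call. = FALSE)
  L <- function(t) 1 / (1 + exp(-rg * (t - tmid)))
  l0 <- L(ages[1])
  expansion <- outer(A_v - 1, (L(ages) - l0) / (1 - l0)) + 1
  meshes <- lapply(seq_along(ages), function(i) {
    scale_v <- sqrt(expansion[, i])
    cortical_mesh(base$vertices * scale_v, base$faces)
  })
  list(ages = ages, meshes = meshes, truth_expansion = expansion,
       provenance = "synthetic_known")
}
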