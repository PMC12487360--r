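test_that("vertex areas partition the total surface area", {
  tri <- cortical_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                       rbind(c(1, 2, 3)))
  va <- vertex_areas(tri)
  expect_equal(va$total_area, sqrt(3) / 4, tolerance = 1e-10)
  expect_equal(va$vertex_area, rep(sqrt(3) / 12, 3), tolerance = 1e-10)

  ico <- icosphere(1, 4)
  vi <- vertex_areas(ico)
  expect_lt(abs(vi$total_area / (4 * pi) - 1), 0.005)
  expect_equal(sum(vi$vertex_area), vi$total_area, tolerance = 1e-9)

  scaled <- ico; scaled$vertices <- ico$vertices * 3
  vs <- vertex_areas(scaled)
  expect_equal(vs$vertex_area, 9 * vi$vertex_area, tolerance = 1e-10)
})

test_that("mean curvature matches analytic values on spheres and planes", {
  ico <- icosphere(10, 4)
  H <- mean_curvature(ico)
  expect_lt(max(abs(H * 10 - 1)), 0.02)

  flat <- flat_grid_mesh(15)
  expect_warning(Hf <- mean_curvature(flat), "boundary")
  interior <- setdiff(seq_len(nrow(flat$vertices)),
                      mesh_topology(flat)$boundary_vertices)
  expect_lt(max(abs(Hf[interior])), 1e-8)
})

test_that("spheroid curvature agrees with the closed form away from poles", {
  el <- icosphere(1, 4)
  a <- 10; c_ax <- 20
  el$vertices <- el$vertices %*% diag(c(a, a, c_ax))
  H <- abs(mean_curvature(el))
  z <- el$vertices[, 3]
  th <- acos(pmin(pmax(z / c_ax, -1), 1))
  den <- a^2 * cos(th)^2 + c_ax^2 * sin(th)^2
  H_true <- (a * c_ax / den^1.5 + c_ax / (a * sqrt(den))) / 2
  away <- abs(cos(th)) < 0.9
  expect_lt(max(abs(H[away] / H_true[away] - 1)), 0.05)
})

test_that("K* is 1 for spheres and invariant to uniform scaling", {
  for (r in c(4, 16)) {
    expect_lt(abs(nondimensional_curvature(icosphere(r, 4)) - 1), 0.02)
  }
  m <- icosphere(5, 3)
  k1 <- nondimensional_curvature(m)
  m$vertices <- m$vertices * 3
  expect_lt(abs(nondimensional_curvature(m) / k1 - 1), 1e-6)
})

test_that("Gauss-Bonnet holds on closed meshes", {
  expect_equal(gaussian_curvature(icosphere(7, 3))$total_angle_defect,
               4 * pi, tolerance = 0.01)
  ph <- make_phantom_labelmap("concentric_shells",
                              radii = c(3, 6, 9, 10.5, 12), voxel_mm = 0.5)
  mesh <- extract_midcortical_surface(ph$volume, "both")
  top <- mesh_topology(mesh)
  expect_true(top$closed)
  expect_equal(gaussian_curvature(mesh)$total_angle_defect,
               4 * pi * (1 - top$genus), tolerance = 0.01)
})

test_that("shell phantom extraction recovers the analytic mid-surface", {
  ph <- make_phantom_labelmap("concentric_shells")
  mesh <- extract_midcortical_surface(ph$volume, "both")
  sa <- vertex_areas(mesh)$total_area
  expect_lt(abs(sa / ph$truth$mid_surface_area_mm2 - 1), 0.05)
  # between the inner and outer boundary areas of the cortical shell
  expect_gt(sa, 4 * pi * ph$truth$radii[3]^2)
  expect_lt(sa, 4 * pi * ph$truth$radii[4]^2)
  # sphere: K* of the extracted mesh close to 1 with the pipeline defaults
  expect_lt(abs(surface_metrics(mesh)$k_star - 1), 0.02)
  # thickness from volume / area
  v <- compartment_volumes(ph$volume)
  th <- morphometric_thickness(v[["cortical_plate"]], sa / 100)
  expect_lt(abs(th / ph$truth$thickness_mm - 1), 0.05)
})

test_that("extraction is deterministic and fails without interior labels", {
  ph <- make_phantom_labelmap("concentric_shells",
                              radii = c(3, 5, 7, 8.5, 10), voxel_mm = 0.5)
  m1 <- extract_midcortical_surface(ph$volume, "both")
  m2 <- extract_midcortical_surface(ph$volume, "both")
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)

  lab <- array(0L, c(20, 20, 20))
  lab[8:12, 8:12, 8:12] <- 2L  # cortical ball, no interior
  expect_error(extract_midcortical_surface(label_volume(lab, rep(1, 3))),
               "interior")
  lab2 <- array(0L, c(20, 20, 20))
  lab2[8:12, 8:12, 8:12] <- 3L  # no cortical plate at all
  expect_error(extract_midcortical_surface(label_volume(lab2, rep(1, 3))),
               "cortical plate")
})

test_that("folding increases surface area and K*", {
  smooth_ph <- make_phantom_labelmap("concentric_shells")
  m0 <- extract_midcortical_surface(smooth_ph$volume, "both")
  folded <- make_phantom_labelmap("folded_shell", amplitude = 1.5)
  m1 <- extract_midcortical_surface(folded$volume, "both")
  expect_gt(vertex_areas(m1)$total_area, vertex_areas(m0)$total_area)
  expect_gt(surface_metrics(m1)$k_star, surface_metrics(m0)$k_star)
})

test_that("hemisphere restriction halves the shell (plus the cut face)", {
  ph <- make_phantom_labelmap("concentric_shells",
                              radii = c(3, 5, 7, 8.5, 10), voxel_mm = 0.5)
  mesh <- suppressWarnings(extract_midcortical_surface(ph$volume, "left"))
  full <- extract_midcortical_surface(ph$volume, "both")
  ratio <- vertex_areas(mesh)$total_area / vertex_areas(full)$total_area
  # half of the spherical shell plus a flat mid-sagittal cap: ~0.75
  expect_gt(ratio, 0.55)
  expect_lt(ratio, 0.9)
})

test_that("thickness arithmetic is linear with the expected units", {
  expect_equal(morphometric_thickness(1, 10), 1)   # 1 mL over 10 cm^2 = 1 mm
  expect_equal(morphometric_thickness(2, 10), 2)
  expect_error(morphometric_thickness(1, 0), "positive")
})

test_that("OBJ round trip preserves geometry and topology", {
  m <- icosphere(7, 2)
  path <- tempfile(fileext = ".obj")
  write_mesh_obj(m, path)
  back <- read_mesh_obj(path)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$faces, m$faces, ignore_attr = TRUE)
})
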