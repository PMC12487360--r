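test_that("identity and uniform-scaling expansion are exact", {
  m <- icosphere(10, 3)
  expect_equal(vertex_expansion(m, m), rep(1, nrow(m$vertices)))
  for (s in c(0.5, 2, 3)) {
    big <- m; big$vertices <- m$vertices * s
    ve <- vertex_expansion(m, big)
    expect_equal(ve, rep(s^2, nrow(m$vertices)), tolerance = 1e-6)
    expect_equal(vertex_expansion(m, big, average = "geometric"), ve,
                 tolerance = 1e-6)
  }
  other <- icosphere(10, 2)
  expect_error(vertex_expansion(m, other), "correspondence")
})

test_that("a smooth radial growth field is recovered within 3%", {
  m <- icosphere(10, 4)
  dirs <- m$vertices / 10
  g <- 1.3 + 0.2 * dirs[, 3]          # gentle axial gradient
  grown <- m; grown$vertices <- m$vertices * g
  ve <- vertex_expansion(m, grown)
  expect_lt(stats::quantile(abs(ve / g^2 - 1), 0.95), 0.03)
})

test_that("expansion to a reference age behaves like a flow map", {
  cset <- make_growing_mesh_sequence(ages = c(85, 110, 135, 155, 1770),
                                     subdivisions = 3)
  em <- expansion_to_reference(cset, 85)
  expect_equal(em[, 1], rep(1, nrow(em)))      # reference column exact
  expect_error(expansion_to_reference(cset, 99), "reference")

  # two-age uniform doubling: expansion 4 everywhere
  base <- icosphere(8, 3)
  dbl <- base; dbl$vertices <- base$vertices * 2
  cs2 <- list(ages = c(85, 155), meshes = list(base, dbl))
  expect_equal(expansion_to_reference(cs2, 85)[, 2],
               rep(4, nrow(base$vertices)), tolerance = 1e-6)

  # composition consistency on the smooth synthetic flow
  e_ab <- vertex_expansion(cset$meshes[[1]], cset$meshes[[2]])
  e_bc <- vertex_expansion(cset$meshes[[2]], cset$meshes[[3]])
  e_ac <- vertex_expansion(cset$meshes[[1]], cset$meshes[[3]])
  expect_lt(stats::quantile(abs(e_ab * e_bc / e_ac - 1), 0.95), 0.05)
})

test_that("total area ratio equals the area-weighted mean expansion", {
  cset <- make_growing_mesh_sequence(ages = c(85, 122, 155),
                                     subdivisions = 3)
  young <- cset$meshes[[1]]; old <- cset$meshes[[3]]
  ve <- vertex_expansion(young, old)
  va <- vertex_areas(young)
  lhs <- vertex_areas(old)$total_area / va$total_area
  rhs <- sum(ve * va$vertex_area) / va$total_area
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("vertex-wise logistic fits recover the generating fields", {
  ages <- c(85, 97, 110, 122, 135, 147, 155, 1770)
  set.seed(10)
  n <- 300
  A_v <- runif(n, 6, 11)
  Rg_v <- runif(n, 0.03, 0.08)
  tm_v <- runif(n, 110, 140)
  maps <- t(vapply(seq_len(n), function(i) {
    y <- eval_growth_model("logistic3", c(A_v[i], Rg_v[i], tm_v[i]), ages)
    y * (1 + rnorm(length(ages), 0, 0.02))
  }, numeric(length(ages))))
  traj <- fit_expansion_trajectories(maps, ages)
  expect_gt(mean(traj$converged), 0.95)
  ok <- traj$converged
  expect_lt(median(abs(traj$tmid_map[ok] - tm_v[ok])), 3)
  expect_lt(median(abs(traj$A_map[ok] / A_v[ok] - 1)), 0.05)

  # spatially constant growth gives spatially constant maps
  const_maps <- t(vapply(1:50, function(i) {
    eval_growth_model("logistic3", c(8, 0.05, 125), ages)
  }, numeric(length(ages))))
  ct <- fit_expansion_trajectories(const_maps, ages)
  expect_lt(sd(ct$A_map) / mean(ct$A_map), 0.02)
  expect_lt(sd(ct$tmid_map) / mean(ct$tmid_map), 0.02)

  # a noise-dominated flat series is masked rather than fitted
  bad <- rbind(rep(2.0001, 8) + c(0, 0, 0, 0, 0, 0, 0, 0))
  bad[1, ] <- 2  # exactly flat
  bt <- fit_expansion_trajectories(rbind(maps[1:3, ], bad), ages)
  expect_false(bt$converged[4])
  expect_error(fit_expansion_trajectories(maps[, 1:3], ages[1:3]),
               "at least 4")
})

test_that("mean expansion differences are area-weighted and exact", {
  m <- icosphere(5, 3)
  a <- rep(2, nrow(m$vertices))
  expect_equal(mean_expansion_difference(a, a, m), 0)
  expect_equal(mean_expansion_difference(a, a + 1.5, m), 1.5)
  expect_error(mean_expansion_difference(a, a[-1]), "length")

  # staged synthetic growth: difference matches the generating schedule
  cset <- make_growing_mesh_sequence(subdivisions = 3)
  em <- expansion_to_reference(cset)
  ref <- cset$meshes[[1]]
  for (j in c(3, 7)) {
    got <- mean_expansion_difference(em[, j], em[, j + 1], ref)
    va <- vertex_areas(ref)$vertex_area
    truth <- sum((cset$truth_expansion[, j + 1] -
                  cset$truth_expansion[, j]) * va) / sum(va)
    expect_lt(abs(got - truth) / max(truth, 0.1), 0.02)
  }
})
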