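test_that("HU-to-density follows the piecewise fit with a floor and near-continuous break", {
  k <- mapping_constants()
  expect_equal(hu_to_density(0, k), 0.105)
  expect_equal(hu_to_density(1000, k), 7.69e-4 * 1000 + 1.028)
  expect_equal(hu_to_density(1000, k), 1.797, tolerance = 1e-12)
  # branch mismatch at the threshold stays tiny (published piecewise fit)
  lo <- k$a1 * k$hu_threshold + k$b1
  hi <- k$a2 * k$hu_threshold + k$b2
  expect_lt(abs(lo - hi), 2e-4)
  # air maps to the density floor, not to a negative density
  expect_equal(hu_to_density(-1000, k), k$rho_floor)
  # closed-form oracle agreement and monotonicity over random intensities
  set.seed(3)
  hu <- runif(1e4, -1200, 3000)
  oracle <- pmax(ifelse(hu < 816, 1.9e-3 * hu + 0.105, 7.69e-4 * hu + 1.028),
                 k$rho_floor)
  expect_equal(hu_to_density(hu, k), oracle, tolerance = 1e-12)
  o <- order(hu)
  expect_true(all(diff(hu_to_density(hu[o], k)) >= 0))
})

test_that("density-to-modulus power law matches its closed form and rejects bad input", {
  k <- mapping_constants()
  expect_equal(density_to_modulus(1, k), 2017.3)
  expect_equal(density_to_modulus(1.6555, k), 2017.3 * 1.6555^2.46, tolerance = 1e-12)
  expect_equal(density_to_modulus(1.6555, k), 6971.87, tolerance = 1e-4)
  expect_equal(density_to_modulus(0.5, k), 366.637, tolerance = 1e-4)
  rho <- seq(0.05, 2, length.out = 500)
  expect_true(all(diff(density_to_modulus(rho, k)) > 0))
  expect_error(density_to_modulus(0, k), "> 0")
  expect_error(density_to_modulus(-1, k), "> 0")
})

test_that("material assignment composes the two maps on uniform volumes and applies overrides", {
  ph <- test_phantom()
  lo <- apply(ph$mesh$nodes, 2, min) - 2
  hi <- apply(ph$mesh$nodes, 2, max) + 2
  dims <- ceiling((hi - lo) / 2)
  ct0 <- voxel_volume(array(300, dims), spacing = c(2, 2, 2), origin = lo)
  k <- mapping_constants()
  mats <- assign_materials(ph$mesh, ct0, k)
  canc <- mats$tets[mats$tets$label == "cancellous", ]
  E_expect <- 2017.3 * (1.9e-3 * 300 + 0.105)^2.46
  expect_true(all(abs(canc$E - E_expect) < 1e-9))
  expect_true(all(canc$nu == k$cancellous_nu))
  cort <- mats$tets[mats$tets$label == "cortical", ]
  expect_true(all(cort$E == 17000))
  expect_true(all(cort$nu == 0.26))
  expect_true(all(mats$membranes$E == 17000))
  # cartilage elements are deferred to the constitutive layer
  expect_true(all(mats$tets$family[grepl("^cartilage", mats$tets$label)] ==
                    "mooney_rivlin"))
  expect_true(all(is.na(mats$tets$E[grepl("^cartilage", mats$tets$label)])))
})

test_that("elements outside the volume fall back to the density floor and are tallied", {
  mesh <- make_verification_mesh("unit_cube", 1)
  mesh$element_region <- rep("cancellous", nrow(mesh$tets))
  # volume far away from the mesh
  vol <- voxel_volume(array(300, c(4, 4, 4)), spacing = c(1, 1, 1),
                      origin = c(100, 100, 100))
  k <- mapping_constants()
  mats <- assign_materials(mesh, vol, k)
  expect_equal(mats$outside_elements, nrow(mesh$tets))
  expect_true(all(mats$tets$rho == k$rho_floor))
})

test_that("unit-mismatch heuristic rejects meshes vastly larger than the volume", {
  mesh <- make_verification_mesh("unit_cube", 1)
  mesh$nodes <- mesh$nodes * 1000
  vol <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(assign_materials(mesh, vol), "unit mismatch")
})

test_that("voxel-in-tet sampling agrees with a brute-force all-voxel containment test", {
  mesh <- make_verification_mesh("unit_cube", 1)  # 6 tets
  set.seed(5)
  vals <- array(runif(20^3, 0, 1000), c(20, 20, 20))
  vol <- voxel_volume(vals, spacing = rep(0.05, 3), origin = c(0, 0, 0))
  got <- pelvifem:::sample_hu_in_tets(mesh, vol, seq_len(nrow(mesh$tets)))
  # brute force: test every voxel centre against every tet
  centers <- as.matrix(expand.grid(x = pelvifem:::voxel_centers(vol, 1),
                                   y = pelvifem:::voxel_centers(vol, 2),
                                   z = pelvifem:::voxel_centers(vol, 3),
                                   KEEP.OUT.ATTRS = FALSE))
  vflat <- as.vector(vals)
  for (e in seq_len(nrow(mesh$tets))) {
    X <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    inside <- pelvifem:::points_in_tet(centers, X)
    expect_equal(unname(got[e]), mean(vflat[inside]), tolerance = 1e-12)
  }
})

test_that("raising every voxel intensity never lowers any element modulus", {
  mesh <- make_verification_mesh("unit_cube", 2)
  mesh$element_region <- rep("cancellous", nrow(mesh$tets))
  set.seed(9)
  vals <- array(runif(10^3, -200, 1500), c(10, 10, 10))
  vol1 <- voxel_volume(vals, spacing = rep(0.1, 3))
  vol2 <- voxel_volume(vals + 150, spacing = rep(0.1, 3))
  E1 <- assign_materials(mesh, vol1)$tets$E
  E2 <- assign_materials(mesh, vol2)$tets$E
  canc <- !is.na(E1)
  expect_true(all(E2[canc] >= E1[canc]))
})
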