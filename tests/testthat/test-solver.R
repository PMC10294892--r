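test_that("a lone spring extends by F/k", {
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0))
  mesh <- fe_mesh(nodes, tets = matrix(integer(), ncol = 4),
                  springs = data.frame(node_a = 1L, node_b = 2L,
                                       stiffness = 10, name = "s"),
                  named_sets = list(fix = 1L, tip = 2L))
  mats <- lin_mats(mesh)
  sys <- fe_assemble(mesh, mats,
                     list(boundary_condition("fix", c("x", "y", "z")),
                          boundary_condition("tip", c("y", "z"))))
  sol <- solve_linear(sys, list(load_case("tip", c(5, 0, 0))))
  expect_equal(sol$u[2, 1], 0.5, tolerance = 1e-12)
  expect_equal(sol$reactions[1], -5, tolerance = 1e-10)
})

test_that("uniform traction on a unit cube gives the homogeneous state exactly", {
  mesh <- make_verification_mesh("unit_cube", 1)
  mats <- lin_mats(mesh, E = 100, nu = 0.3)
  bcs <- list(boundary_condition("xmin", "x"), boundary_condition("ymin", "y"),
              boundary_condition("zmin", "z"))
  p <- 2.5
  sys <- fe_assemble(mesh, mats, bcs)
  sol <- solve_linear(sys, consistent_surface_load(mesh, "xmax", c(p, 0, 0)))
  sxx <- vapply(sol$tet_stress, function(s) s[1, 1], double(1))
  syy <- vapply(sol$tet_stress, function(s) s[2, 2], double(1))
  exx <- vapply(sol$tet_strain, function(e) e[1, 1], double(1))
  expect_equal(sxx, rep(p, length(sxx)), tolerance = 1e-8)
  expect_equal(syy, rep(0, length(syy)), tolerance = 1e-8)
  expect_equal(exx, rep(p / 100, length(exx)), tolerance = 1e-8)
  pp <- postprocess(sol)
  s <- pp$summaries[pp$summaries$subset == "all", ]
  expect_equal(s$max_vm, s$mean_vm, tolerance = 1e-10)
  expect_equal(s$max_vm, p, tolerance = 1e-8)
})

test_that("the patch test reproduces a constant strain state exactly", {
  mesh <- make_verification_mesh("unit_cube", 2)
  set.seed(42)
  onb <- apply(mesh$nodes, 1, function(q) any(abs(q) < 1e-12 | abs(q - 1) < 1e-12))
  mesh$nodes[!onb, ] <- mesh$nodes[!onb, ] +
    matrix(runif(sum(!onb) * 3, -0.08, 0.08), ncol = 3)
  mats <- lin_mats(mesh)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 2e-4, -5e-4, 3e-4, -1e-4, 3e-4, 4e-4), 3, 3)
  b <- c(1e-3, -2e-3, 5e-4)
  ub <- mesh$nodes %*% t(A) + matrix(b, nrow(mesh$nodes), 3, byrow = TRUE)
  bcs <- list()
  for (n in which(onb)) for (ax in 1:3)
    bcs[[length(bcs) + 1]] <- boundary_condition(n, c("x", "y", "z")[ax],
                                                 value = ub[n, ax])
  sol <- solve_linear(fe_assemble(mesh, mats, bcs), list())
  expect_lt(max(abs(sol$u - ub)), 1e-10)
  expect_lt(max(vapply(sol$tet_strain, function(e) max(abs(e - A)), double(1))),
            1e-10)
})

test_that("rigid translation produces zero strain and zero load produces zero displacement", {
  mesh <- make_verification_mesh("unit_cube", 1)
  mats <- lin_mats(mesh)
  t0 <- c(0.3, -0.2, 0.1)
  bcs <- list()
  for (n in seq_len(nrow(mesh$nodes))) for (ax in 1:3)
    bcs[[length(bcs) + 1]] <- boundary_condition(n, c("x", "y", "z")[ax],
                                                 value = t0[ax])
  sol <- solve_linear(fe_assemble(mesh, mats, bcs), list())
  expect_lt(max(vapply(sol$tet_strain, function(e) max(abs(e)), double(1))), 1e-12)

  sys <- fe_assemble(mesh, mats, list(boundary_condition("xmin", c("x", "y", "z"))))
  sol0 <- solve_linear(sys, list(load_case("xmax", c(0, 0, 0))))
  expect_equal(sol0$u, matrix(0, nrow(mesh$nodes), 3))
})

test_that("doubling the load doubles the displacement of an all-linear model", {
  mesh <- make_verification_mesh("cantilever_beam", 1)
  mats <- lin_mats(mesh, E = 1000, nu = 0.3)
  sys <- fe_assemble(mesh, mats, list(boundary_condition("fixed", c("x", "y", "z"))))
  s1 <- solve_linear(sys, list(load_case("loaded", c(0, -1, 0))))
  s2 <- solve_linear(sys, list(load_case("loaded", c(0, -2, 0))))
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-12)
})

test_that("cantilever tip deflection approaches slender-beam theory under refinement", {
  E <- 1000; P <- 1; L <- 10; I <- 1 / 12
  exact <- P * L^3 / (3 * E * I)
  errs <- c()
  for (r in c(1, 2, 4)) {
    mesh <- make_verification_mesh("cantilever_beam", r)
    mats <- lin_mats(mesh, E = E, nu = 0.3)
    sys <- fe_assemble(mesh, mats, list(boundary_condition("fixed", c("x", "y", "z"))))
    sol <- solve_linear(sys, list(load_case("loaded", c(0, -P, 0))))
    tip <- -mean(sol$u[mesh$named_sets$loaded, 2])
    errs <- c(errs, abs(tip - exact) / exact)
    # global equilibrium at every refinement
    fres <- colSums(matrix(sol$reactions + sol$f_ext, ncol = 3, byrow = TRUE))
    expect_lt(sqrt(sum(fres^2)), 1e-8 * sqrt(sum(sol$f_ext^2)))
  }
  expect_true(all(diff(errs) < 0))     # monotone convergence
  expect_lt(errs[length(errs)], 0.15)  # within 15% at resolution 4
})

test_that("assembled stiffness is consistent with the postprocessed strain energy", {
  mesh <- make_verification_mesh("two_block_contact", 1)
  mats <- lin_mats(mesh, E = 50, nu = 0.25)
  K <- pelvifem:::assemble_static_stiffness(mesh, mats)
  set.seed(8)
  u <- rnorm(3 * nrow(mesh$nodes), 0, 1e-3)
  quad <- 0.5 * sum(u * as.vector(K %*% u))
  # independent path: element-wise 1/2 sigma:eps integration + spring energy
  sol <- pelvifem:::postprocess_solution(u, mesh, mats, u * 0, u * 0)
  vols <- tet_volumes(mesh)
  e_tet <- sum(vapply(seq_len(nrow(mesh$tets)), function(e)
    0.5 * vols[e] * sum(sol$tet_strain[[e]] * sol$tet_stress[[e]]), double(1)))
  U <- matrix(u, ncol = 3, byrow = TRUE)
  e_spr <- sum(vapply(seq_len(nrow(mesh$springs)), function(i) {
    d <- pelvifem:::spring_direction(mesh, i)
    ext <- sum((U[mesh$springs$node_b[i], ] - U[mesh$springs$node_a[i], ]) * d)
    0.5 * mesh$springs$stiffness[i] * ext^2
  }, double(1)))
  expect_equal(quad, e_tet + e_spr, tolerance = 1e-10)
})

test_that("two stacked blocks in contact transmit uniform compression", {
  mesh <- make_verification_mesh("two_block_contact", 1)
  mats <- lin_mats(mesh, E = 100, nu = 0)
  # the upper block is held laterally by a guided platen; the contact springs
  # carry the normal direction only
  sys <- fe_assemble(mesh, mats,
                     list(boundary_condition("fixed", c("x", "y", "z")),
                          boundary_condition("loaded", c("x", "z")),
                          boundary_condition("interface_upper", c("x", "z"))))
  sol <- solve_linear(sys, consistent_surface_load(mesh, "loaded", c(0, -4, 0)))
  syy <- vapply(sol$tet_stress, function(s) s[2, 2], double(1))
  # uniform up to the finite contact-penalty compliance
  expect_equal(syy, rep(-4, length(syy)), tolerance = 1e-4)
})

test_that("a free-floating component is reported with one of its nodes", {
  cube <- make_verification_mesh("unit_cube", 1)
  far <- make_verification_mesh("single_tet")
  far$nodes <- far$nodes + 100
  mesh <- fe_mesh(rbind(cube$nodes, far$nodes),
                  rbind(cube$tets, far$tets + nrow(cube$nodes)),
                  named_sets = list(fixed = cube$named_sets$xmin))
  mats <- lin_mats(mesh)
  sys <- fe_assemble(mesh, mats, list(boundary_condition("fixed", c("x", "y", "z"))))
  expect_error(solve_linear(sys, list()), "floating|singular.*node")
})

test_that("the Newton path reproduces the hyperelastic uniaxial closed form", {
  mesh <- make_verification_mesh("unit_cube", 2)
  mats <- mr_mats(mesh)
  bcs <- list(boundary_condition("xmin", "x"), boundary_condition("ymin", "y"),
              boundary_condition("zmin", "z"),
              boundary_condition("xmax", "x", value = 0.1))
  sol <- solve_newton(mesh, mats, bcs, numeric(3 * nrow(mesh$nodes)), steps = 5)
  m <- mooney_rivlin3()
  lat <- function(mu) mr_cauchy_stress(diag(c(1.1, mu, mu)), m)[2, 2]
  mu <- stats::uniroot(lat, c(0.8, 1.05), tol = 1e-12)$root
  oracle <- mr_cauchy_stress(diag(c(1.1, mu, mu)), m)[1, 1]
  sxx <- vapply(sol$tet_stress, function(s) s[1, 1], double(1))
  expect_lt(max(abs(sxx - oracle)) / oracle, 0.02)
  # zero load, zero prescribed displacement: exactly zero displacement
  bcs0 <- list(boundary_condition("xmin", c("x", "y", "z")))
  sol0 <- solve_newton(mesh, mats, bcs0, numeric(3 * nrow(mesh$nodes)), steps = 1)
  expect_equal(sol0$u, matrix(0, nrow(mesh$nodes), 3))
})

test_that("cartilage-secant elements stiffen under compression and stay at the floor in tension", {
  mesh <- make_verification_mesh("unit_cube", 1)
  mats <- material_field(
    tets = tibble::tibble(element = seq_len(nrow(mesh$tets)),
                          label = "cartilage_pubic", family = "cartilage",
                          rho = NA_real_, E = NA_real_, nu = NA_real_),
    membranes = tibble::tibble(element = integer(), E = double(), nu = double()),
    cartilage_family = "cartilage")
  bcs <- function(v) list(boundary_condition("xmin", "x"),
                          boundary_condition("ymin", "y"),
                          boundary_condition("zmin", "z"),
                          boundary_condition("xmax", "x", value = v))
  f0 <- numeric(3 * nrow(mesh$nodes))
  # deep compression: volumetric strain well past the negative-fit region,
  # so the quadratic stiffening dominates the floor modulus
  comp <- solve_newton(mesh, mats, bcs(-0.3), f0, steps = 5)
  ten <- solve_newton(mesh, mats, bcs(0.3), f0, steps = 5)
  # compressive state engages the quadratic stiffening; tension stays at E_min
  expect_gt(max(vapply(comp$tet_stress, function(s) abs(s[1, 1]), double(1))),
            max(vapply(ten$tet_stress, function(s) abs(s[1, 1]), double(1))))
})

test_that("global equilibrium holds on the phantom standing-load solve", {
  ph <- test_phantom()
  mats <- all_linear_phantom_mats(ph, test_ct())
  mesh <- model_I_variant(ph$mesh)
  sys <- fe_assemble(mesh, mats, standing_bcs())
  sol <- solve_linear(sys, list(load_case("load_top", c(0, -550, 0))))
  fres <- colSums(matrix(sol$reactions + sol$f_ext, ncol = 3, byrow = TRUE))
  expect_lt(sqrt(sum(fres^2)), 1e-8 * sqrt(sum(sol$f_ext^2)))
  # vertical reactions balance the applied weight
  expect_equal(sum(sol$reactions[seq(2, length(sol$reactions), by = 3)]), 550,
               tolerance = 1e-8)
})
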