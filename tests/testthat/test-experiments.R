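test_that("an all-linear loading experiment scales exactly with load", {
  ph <- test_phantom()
  mats <- all_linear_phantom_mats(ph, test_ct())
  mesh <- model_II_variant(ph$mesh)
  rep_ <- run_loading_experiment(mesh, mats, load_schedule(c(50, 550)))
  expect_equal(length(rep_$failures), 0L)
  s <- rep_$summaries[rep_$summaries$subset == "all", ]
  expect_equal(nrow(s), 2L)
  expect_equal(s$max_vm[s$load == 550], 11 * s$max_vm[s$load == 50],
               tolerance = 1e-8)
  expect_equal(s$mean_eq_strain[s$load == 550],
               11 * s$mean_eq_strain[s$load == 50], tolerance = 1e-8)
  # probed strains are affine in load (R^2 = 1 against magnitude)
  pts <- default_measurement_points(ph)
  strains <- vapply(c("50", "550"), function(l)
    probe_strain(rep_$solutions[[l]], pts)$eq_strain[3], double(1))
  expect_equal(unname(strains[2]), unname(11 * strains[1]), tolerance = 1e-8)
})

test_that("the default schedule produces six summaries per model", {
  sched <- load_schedule()
  expect_equal(sched$magnitudes, c(50, 150, 250, 350, 450, 550))
  ph <- test_phantom()
  mats <- all_linear_phantom_mats(ph, test_ct())
  rep_ <- run_loading_experiment(model_I_variant(ph$mesh), mats, sched,
                                 keep_solutions = FALSE)
  expect_equal(sum(rep_$summaries$subset == "all"), 6L)
  # monotone max stress across increasing loads in an all-linear model
  s <- rep_$summaries[rep_$summaries$subset == "all", ]
  expect_true(all(diff(s$max_vm[order(s$load)]) > 0))
})

test_that("model comparison computes reductions, is antisymmetric, and validates schedules", {
  a <- tibble::tibble(load = 550, max_vm = 11.248, mean_vm = 0.087251)
  b <- tibble::tibble(load = 550, max_vm = 6.1664, mean_vm = 0.058051)
  cm <- compare_models(a, b)
  expect_equal(cm$reduction_pct[cm$quantity == "max_vm"], 45.18, tolerance = 1e-4)
  expect_equal(cm$ratio[cm$quantity == "max_vm"], 11.248 / 6.1664)
  # identical reports reduce by zero
  cm0 <- compare_models(a, a)
  expect_true(all(cm0$reduction_pct == 0))
  expect_true(all(cm0$ratio == 1))
  # swapping arguments turns an x% reduction into the matching inflation
  sw <- compare_models(b, a)
  expect_equal(sw$reduction_pct / 100, 1 - 1 / (1 - cm$reduction_pct / 100),
               tolerance = 1e-12)
  expect_error(compare_models(a, tibble::tibble(load = 450, max_vm = 1)),
               "mismatched")
})

test_that("strain probing averages by volume over the neighbourhood", {
  ph <- test_phantom()
  mats <- all_linear_phantom_mats(ph, test_ct())
  mesh <- model_I_variant(ph$mesh)
  sol <- solve_linear(fe_assemble(mesh, mats, standing_bcs()),
                      list(load_case("load_top", c(0, -550, 0))))
  # radius covering exactly one element returns that element's strain
  cen <- tet_centroids(mesh)
  d <- sqrt(rowSums(sweep(cen, 2, cen[1, ])^2))
  r1 <- min(d[d > 0]) * 0.5
  p1 <- measurement_point(1, cen[1, ], r1)
  expect_equal(probe_strain(sol, list(p1))$eq_strain, sol$tet_eq_strain[1])
  # two equal-volume elements average to the arithmetic mean
  two <- order(d)[1:2]
  vols <- tet_volumes(mesh)[two]
  expect_equal(vols[1], vols[2], tolerance = 1e-12)
  r2 <- sort(d)[2] + 1e-9
  p2 <- measurement_point(2, cen[1, ], r2)
  got <- probe_strain(sol, list(p2))
  expect_equal(got$n_elements, 2L)
  expect_equal(got$eq_strain, mean(sol$tet_eq_strain[two]), tolerance = 1e-12)
  # empty neighbourhood is rejected naming the point
  p3 <- measurement_point(99, c(1e4, 1e4, 1e4), 1)
  expect_error(probe_strain(sol, list(p3)), "99")
})

test_that("probing a uniform field returns that strain at every point", {
  mesh <- make_verification_mesh("unit_cube", 2)
  mats <- lin_mats(mesh, E = 100, nu = 0)
  bcs <- list(boundary_condition("xmin", "x"), boundary_condition("ymin", "y"),
              boundary_condition("zmin", "z"),
              boundary_condition("xmax", "x", value = 0.01))
  sol <- solve_linear(fe_assemble(mesh, mats, bcs), list())
  pts <- list(measurement_point(1, c(0.5, 0.5, 0.5), 0.4),
              measurement_point(2, c(0.25, 0.25, 0.5), 0.2))
  got <- probe_strain(sol, pts)
  expect_equal(got$eq_strain, rep(sol$tet_eq_strain[1], 2), tolerance = 1e-10)
})

test_that("the validation regression matches ordinary least squares", {
  r1 <- regress_validation(1:5, 1:5)
  expect_equal(r1$slope, 1); expect_equal(r1$intercept, 0)
  expect_equal(r1$r_squared, 1)
  x <- c(0.1, 0.5, 1, 2, 3)
  r2 <- regress_validation(x, 2 * x + 1)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, 1, tolerance = 1e-12)
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
  # five-point case against the normal-equations oracle
  set.seed(21)
  x <- c(1, 2, 4, 7, 11); y <- c(0.8, 2.2, 3.9, 7.5, 10.4)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r3 <- regress_validation(x, y)
  expect_equal(r3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r3$slope, beta[2], tolerance = 1e-10)
  res <- y - X %*% beta
  expect_equal(r3$r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_error(regress_validation(rep(1, 4), 1:4), "variance")
  expect_error(regress_validation(1:2, 1:2), "length")
})

test_that("the packaged reference strain table is intact and physically ordered", {
  m <- load_reference_strains()
  expect_equal(dim(m), c(7L, 6L))
  expect_equal(m[1, "50"], 3.08e-5)
  expect_equal(m[3, "550"], 1.77e-3)
  expect_equal(sum(!is.na(m)), 42L)
  # every point's strain strictly increases with load
  expect_true(all(apply(m, 1, function(r) all(diff(r) > 0))))
})
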