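test_that("muscle stiffness scales with the attachment-area ratio", {
  expect_equal(scale_spring_stiffness(100, 50, 50), 100)
  # gluteus maximus split over five equal patches
  expect_equal(scale_spring_stiffness(962, 4822 / 5, 4822), 192.4)
  k1 <- scale_spring_stiffness(200, 10, 400)
  expect_equal(scale_spring_stiffness(200, 20, 400), 2 * k1)
  expect_error(scale_spring_stiffness(100, 0, 50), "> 0")
  expect_error(scale_spring_stiffness(100, -5, 50), "> 0")
})

test_that("the default registry yields the published spring counts on the phantom", {
  ph <- test_phantom()
  mesh <- build_network(ph$mesh, load_tissue_table(), joints = list())
  expect_equal(nrow(mesh$springs), 51L)
  lig <- c("anterior_sacroiliac", "long_posterior_sacroiliac",
           "short_posterior_sacroiliac", "sacrospinous", "sacrotuberous",
           "iliolumbar", "inguinal", "supraspinous", "intertransverse")
  expect_equal(sum(mesh$springs$name %in% lig), 37L)
  expect_equal(sum(!mesh$springs$name %in% lig), 14L)
  asl <- mesh$springs[mesh$springs$name == "anterior_sacroiliac", ]
  expect_equal(nrow(asl), 10L)
  expect_true(all(asl$stiffness == 230))
  # co-modelled muscles add no standalone springs
  expect_false(any(mesh$springs$name %in%
                     c("gluteus_medius", "gluteus_minimus", "gemellus_inferior")))
  # no zero-length springs, no self-loops
  len <- sqrt(rowSums((mesh$nodes[mesh$springs$node_a, ] -
                       mesh$nodes[mesh$springs$node_b, ])^2))
  expect_true(all(len > 0))
  expect_true(all(mesh$springs$node_a != mesh$springs$node_b))
})

test_that("spring pairing is invariant under permutation of the input sets", {
  ph <- test_phantom()
  mesh2 <- ph$mesh
  set.seed(13)
  for (nm in c("gluteus_maximus_origin", "gluteus_maximus_insertion"))
    mesh2$named_sets[[nm]] <- sample(mesh2$named_sets[[nm]])
  tab <- load_tissue_table()
  tab <- tab[tab$name == "gluteus_maximus", ]
  a <- build_network(ph$mesh, tab, joints = list())$springs
  b <- build_network(mesh2, tab, joints = list())$springs
  expect_identical(a[order(a$node_a, a$node_b), c("node_a", "node_b")],
                   b[order(b$node_a, b$node_b), c("node_a", "node_b")])
})

test_that("bilateral tissues attach symmetrically to both sides", {
  ph <- test_phantom()
  S <- ph$spec$overall_scale
  tab <- load_tissue_table()
  mesh <- build_network(ph$mesh, tab[tab$name == "gluteus_maximus", ],
                        joints = list())
  x_org <- mesh$nodes[mesh$springs$node_a, 1]
  expect_equal(sum(x_org < S / 2), 3L)  # left half takes the odd spring
  expect_equal(sum(x_org > S / 2), 2L)
})

test_that("degenerate registries are rejected with the tissue named", {
  ph <- test_phantom()
  bad <- list(tissue_spec("phantom_tissue", "ligament", 100, 2,
                          origin_set = "no_such_set",
                          insertion_set = "load_top"))
  expect_error(build_network(ph$mesh, bad), "phantom_tissue")
  toomany <- list(tissue_spec("greedy", "ligament", 100, 10000,
                              origin_set = "supraspinous_origin",
                              insertion_set = "supraspinous_insertion"))
  expect_error(build_network(ph$mesh, toomany), "not enough")
  expect_error(tissue_spec("t", "ligament", k_per_spring = NA, n_springs = 2),
               "k_per_spring")
})

test_that("model variants implement the two-model ablation", {
  ph <- test_phantom()
  mI <- model_I_variant(ph$mesh)
  expect_equal(nrow(mI$springs), 0L)
  expect_equal(nrow(mI$nodes), nrow(ph$mesh$nodes))

  mII <- model_II_variant(ph$mesh)
  tissue <- mII$springs[!startsWith(mII$springs$name, "joint_"), ]
  expect_equal(nrow(tissue), 51L)
  joints <- mII$springs[startsWith(mII$springs$name, "joint_"), ]
  expect_gt(nrow(joints), 0L)
  # frictionless joints act along their normals only
  si <- joints[grepl("sacroiliac", joints$name), ]
  expect_true(all(si$dx == 1 & si$dy == 0 & si$dz == 0))
  ac <- joints[grepl("acetabular", joints$name), ]
  expect_true(all(ac$dx == 0 & ac$dy == 1 & ac$dz == 0))
  # pubic joint stays tied: no penalty springs, no duplicated sheet
  expect_false(any(grepl("pubic", joints$name)))
  # variants share the original node coordinates; duplicates are coincident
  n0 <- nrow(ph$mesh$nodes)
  expect_equal(mII$nodes[seq_len(n0), ], ph$mesh$nodes)
  dups <- seq(n0 + 1L, nrow(mII$nodes))
  expect_true(all(vapply(dups, function(i) {
    any(rowSums(abs(sweep(ph$mesh$nodes, 2, mII$nodes[i, ]))) < 1e-12)
  }, logical(1))))
})

test_that("joint penalties are tributary-area weighted with a unit mean", {
  ph <- test_phantom()
  mII <- model_II_variant(ph$mesh, joints = default_joints(1e4))
  ac <- mII$springs[mII$springs$name == "joint_acetabular_left", ]
  expect_equal(mean(ac$stiffness), 1e4, tolerance = 1e-12)
  # corner nodes of the interface carry less stiffness than interior nodes
  expect_gt(max(ac$stiffness), min(ac$stiffness))
})
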