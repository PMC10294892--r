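#' Specification of the synthetic pelvis-ring phantom
#'
#' The phantom is a stylised, fully parametric stand-in for a segmented
#' pelvis: a closed ring of structured hexahedral blocks (each split into six
#' tetrahedra) comprising a sacrum block, two innominate arcs joined to it
#' through thin sacroiliac cartilage layers and to each other through a
#' pubic-symphysis cartilage wedge, femur stubs below the acetabular regions,
#' and a lumbar column stub with a flat loading face on top.  It exists so
#' that every downstream stage — CT mapping, spring networks, solving, the
#' two-model protocol — is testable without clinical geometry.
#'
#' @param overall_scale ring width in mm (x extent; y extent equals it,
#'   z depth is a quarter of it).
#' @param block_resolution elements per block edge (integer >= 1).
#' @param cortical_shell_hu_mean mean CT intensity of the cortical shell (HU).
#' @param cancellous_hu_mean mean CT intensity of cancellous interior (HU).
#'   Defaults straddle the density-mapping branch threshold so both branches
#'   of the piecewise HU-to-density fit are exercised.
#' @param hu_noise_sd CT noise standard deviation (HU, >= 0).
#' @param cartilage_gap thickness of each cartilage layer in mm.
#' @param seed integer seed for the synthetic CT noise.
#' @param voxel_spacing CT voxel edge in mm; default half the smaller of the
#'   cartilage gap and the block row height.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(overall_scale = 180, block_resolution = 2L,
                         cortical_shell_hu_mean = 1200,
                         cancellous_hu_mean = 300,
                         hu_noise_sd = 50, cartilage_gap = 4,
                         seed = 1L, voxel_spacing = NULL) {
  stopifnot(overall_scale > 0, block_resolution >= 1,
            hu_noise_sd >= 0, cortical_shell_hu_mean > cancellous_hu_mean)
  if (cartilage_gap <= 0)
    stop("cartilage_gap must be > 0: zero-thickness cartilage layers have no elements")
  if (3 * cartilage_gap >= overall_scale)
    stop("cartilage_gap too large for overall_scale")
  if (is.null(voxel_spacing))
    voxel_spacing <- min(cartilage_gap, overall_scale / 7) / 2
  structure(list(overall_scale = overall_scale,
                 block_resolution = as.integer(block_resolution),
                 cortical_shell_hu_mean = cortical_shell_hu_mean,
                 cancellous_hu_mean = cancellous_hu_mean,
                 hu_noise_sd = hu_noise_sd, cartilage_gap = cartilage_gap,
                 seed = as.integer(seed), voxel_spacing = voxel_spacing),
            class = "phantom_spec")
}

# Cell occupancy of the ring on a 7x7 (column x row) layout, rows bottom-up.
phantom_layout <- function() {
  occ <- matrix(NA_character_, nrow = 7, ncol = 7)  # [col, row]
  occ[1, 1] <- "femur_left";       occ[7, 1] <- "femur_right"
  occ[1:3, 2] <- "innominate_left"; occ[4, 2] <- "cartilage_pubic"
  occ[5:7, 2] <- "innominate_right"
  occ[1, 3:4] <- "innominate_left"; occ[7, 3:4] <- "innominate_right"
  occ[1, 5] <- "innominate_left";  occ[2, 5] <- "cartilage_si_left"
  occ[3:5, 5] <- "sacrum";         occ[6, 5] <- "cartilage_si_right"
  occ[7, 5] <- "innominate_right"
  occ[3:5, 6:7] <- "lumbar"
  occ
}

# Six-tet split of a hex given its 8 corner ids in the order
# (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1).
# All tets share the main diagonal v1-v7, which makes face diagonals
# consistent between neighbouring hexes of a structured grid.
hex_tets <- function(v) {
  rbind(c(v[1], v[2], v[3], v[7]),
        c(v[1], v[3], v[4], v[7]),
        c(v[1], v[4], v[8], v[7]),
        c(v[1], v[8], v[5], v[7]),
        c(v[1], v[5], v[6], v[7]),
        c(v[1], v[6], v[2], v[7]))
}

fix_orientation <- function(nodes, tets) {
  for (e in seq_len(nrow(tets))) {
    X <- nodes[tets[e, ], , drop = FALSE]
    v <- det(cbind(1, X)) / 6
    if (v < 0) tets[e, c(3L, 4L)] <- tets[e, c(4L, 3L)]
  }
  tets
}

# Structured tet mesh of a box [0,Lx]x[0,Ly]x[0,Lz] with nx x ny x nz hexes.
structured_box <- function(nx, ny, nz, Lx = 1, Ly = 1, Lz = 1) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  zs <- seq(0, Lz, length.out = nz + 1)
  nid <- function(i, j, k) i + (nx + 1L) * ((j - 1L) + (ny + 1L) * (k - 1L))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  tets <- matrix(0L, 6L * nx * ny * nz, 4L)
  pos <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    v <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
           nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i + 1L, j + 1L, k + 1L),
           nid(i, j + 1L, k + 1L))
    tets[pos + 1:6, ] <- hex_tets(v)
    pos <- pos + 6L
  }
  list(nodes = nodes, tets = fix_orientation(nodes, tets))
}

pick_nodes <- function(nodes, x = NULL, y = NULL, z = NULL, tol = 1e-9) {
  inwin <- function(v, win) {
    if (is.null(win)) return(rep(TRUE, length(v)))
    if (!is.list(win)) win <- list(win)
    Reduce(`|`, lapply(win, function(r) v >= r[1] - tol & v <= r[2] + tol))
  }
  which(inwin(nodes[, 1], x) & inwin(nodes[, 2], y) & inwin(nodes[, 3], z))
}

#' Build the synthetic pelvis-ring phantom
#'
#' Constructs the conforming structured mesh of the ring described in
#' [phantom_spec], labels every element (`cortical`, `cancellous`,
#' `cartilage_si_left`, `cartilage_si_right`, `cartilage_pubic`, `femur`,
#' `lumbar`), emits cortical membrane triangles on the boundary faces of the
#' bone regions, and defines every named node set the soft-tissue registry
#' and the loading protocol refer to: one origin and one insertion patch per
#' ligament and muscle, the load/constraint sets (`load_top`,
#' `vertebra_guide`, `femur_fix`) and the joint interface sets.  The
#' construction is deterministic: identical specs give identical models.
#'
#' @param spec a [phantom_spec].
#' @param shell_thickness cortical membrane thickness in mm.
#' @return object of class `phantom_model` with fields `mesh` ([fe_mesh]),
#'   `region_labels`, `named_sets`, `joint_info` and `spec`.
#' @export
make_pelvis_phantom <- function(spec = phantom_spec(), shell_thickness = 1.41) {
  S <- spec$overall_scale; g <- spec$cartilage_gap
  r <- spec$block_resolution
  w <- (S - 3 * g) / 4
  h <- S / 7
  d <- S / 4
  col_w <- c(w, g, w, g, w, g, w)
  xe <- cumsum(c(0, col_w))              # column edges e0..e7
  ye <- seq(0, S, by = h)                # row edges Y0..Y7
  occ <- phantom_layout()

  # global sub-hex grid: 7r x 7r x r; tick coordinates per axis
  xt <- unlist(lapply(1:7, function(c_) xe[c_] + (0:(r - 1)) / r * col_w[c_]))
  xt <- c(xt, S)
  yt <- seq(0, S, length.out = 7L * r + 1L)
  zt <- seq(0, d, length.out = r + 1L)
  nx <- 7L * r; ny <- 7L * r; nz <- r

  block_at <- function(gx, gy) {
    if (gx < 1L || gx > nx || gy < 1L || gy > ny) return(NA_character_)
    occ[ceiling(gx / r), ceiling(gy / r)]
  }
  fused <- function(a, b) {
    p <- sort(c(a, b))
    identical(p, c("lumbar", "sacrum"))
  }
  bone_blocks <- c("sacrum", "innominate_left", "innominate_right")

  nid <- function(i, j, k) i + (nx + 1L) * ((j - 1L) + (ny + 1L) * (k - 1L))
  ntet_max <- 6L * nx * ny * nz
  tets <- matrix(0L, ntet_max, 4L)
  region <- character(ntet_max)
  block <- character(ntet_max)
  pos <- 0L
  for (gy in seq_len(ny)) for (gx in seq_len(nx)) {
    b <- block_at(gx, gy)
    if (is.na(b)) next
    if (b %in% bone_blocks) {
      cortical <- FALSE
      for (nb in list(c(gx - 1L, gy), c(gx + 1L, gy),
                      c(gx, gy - 1L), c(gx, gy + 1L))) {
        other <- block_at(nb[1L], nb[2L])
        if (is.na(other) || startsWith(other, "cartilage") ||
            (other != b && !fused(other, b))) { cortical <- TRUE; break }
      }
      lab <- if (cortical) "cortical" else "cancellous"
    } else if (startsWith(b, "femur")) {
      lab <- "femur"
    } else if (b == "lumbar") {
      lab <- "lumbar"
    } else {
      lab <- b                            # cartilage_* labels pass through
    }
    for (gz in seq_len(nz)) {
      v <- c(nid(gx, gy, gz), nid(gx + 1L, gy, gz), nid(gx + 1L, gy + 1L, gz),
             nid(gx, gy + 1L, gz), nid(gx, gy, gz + 1L), nid(gx + 1L, gy, gz + 1L),
             nid(gx + 1L, gy + 1L, gz + 1L), nid(gx, gy + 1L, gz + 1L))
      tets[pos + 1:6, ] <- hex_tets(v)
      region[pos + 1:6] <- lab
      block[pos + 1:6] <- b
      pos <- pos + 6L
    }
  }
  tets <- tets[seq_len(pos), , drop = FALSE]
  region <- region[seq_len(pos)]; block <- block[seq_len(pos)]

  # compress node ids to used nodes
  grid_nodes <- as.matrix(expand.grid(x = xt, y = yt, z = zt,
                                      KEEP.OUT.ATTRS = FALSE))
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(grid_nodes)); remap[used] <- seq_along(used)
  nodes <- grid_nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4L)
  tets <- fix_orientation(nodes, tets)

  cart_labels <- c("cartilage_si_left", "cartilage_si_right", "cartilage_pubic")
  for (cl in cart_labels) if (!any(region == cl))
    stop("resolution too low: cartilage layer '", cl, "' has zero elements")

  # cortical membranes on boundary faces of bone regions (incl. stubs)
  bone_tets <- which(region %in% c("cortical", "cancellous", "femur", "lumbar"))
  bf <- boundary_faces(nodes, tets[bone_tets, , drop = FALSE])
  tri_block <- block[bone_tets[attr(bf, "owner")]]
  tris <- unclass(bf); attr(tris, "owner") <- NULL

  tol <- 1e-9 * S
  win <- function(a, b) c(a, b)
  both_sides_x <- function(lo_w, hi_w) list(lo_w, hi_w)
  Y <- ye; E <- xe
  sets <- list()
  sets$load_top <- pick_nodes(nodes, y = win(S, S), tol = tol)
  sets$vertebra_guide <- sets$load_top
  sets$femur_fix <- pick_nodes(nodes, y = win(0, 0), tol = tol)
  sets$joint_acetabular_left <- pick_nodes(nodes, x = win(E[1], E[2]),
                                           y = win(Y[2], Y[2]), tol = tol)
  sets$joint_acetabular_right <- pick_nodes(nodes, x = win(E[7], E[8]),
                                            y = win(Y[2], Y[2]), tol = tol)
  sets$joint_sacroiliac_left <- pick_nodes(nodes, x = win(E[2], E[2]),
                                           y = win(Y[5], Y[6]), tol = tol)
  sets$joint_sacroiliac_right <- pick_nodes(nodes, x = win(E[7], E[7]),
                                            y = win(Y[5], Y[6]), tol = tol)
  sets$joint_pubic <- pick_nodes(nodes, x = both_sides_x(win(E[4], E[4]), win(E[5], E[5])),
                                 y = win(Y[2], Y[3]), tol = tol)

  outer_x <- both_sides_x(win(0, 0), win(S, S))
  ilium_x <- both_sides_x(win(E[1], E[2]), win(E[7], E[8]))
  ilium_inner_x <- both_sides_x(win(E[2], E[2]), win(E[7], E[7]))
  pubis_x <- both_sides_x(win(E[2], E[4]), win(E[5], E[7]))
  pubis_bot_x <- both_sides_x(win(E[3], E[4]), win(E[5], E[6]))
  femur_inner_x <- both_sides_x(win(E[2], E[2]), win(E[7], E[7]))
  femur_y <- win(0, Y[2] - 10 * tol)     # exclusive of the acetabular plane
  sacrum_x <- win(E[3], E[6])
  half <- h / 2

  patch <- function(...) pick_nodes(nodes, ..., tol = tol)
  sets$anterior_sacroiliac_origin <- patch(x = sacrum_x, y = win(Y[5], Y[6]), z = win(0, 0))
  sets$anterior_sacroiliac_insertion <- patch(x = ilium_x, y = win(Y[5], Y[6]), z = win(0, 0))
  sets$long_posterior_sacroiliac_origin <- patch(x = sacrum_x, y = win(Y[5] + half, Y[6]), z = win(d, d))
  sets$long_posterior_sacroiliac_insertion <- patch(x = ilium_x, y = win(Y[5] + half, Y[6]), z = win(d, d))
  sets$short_posterior_sacroiliac_origin <- patch(x = sacrum_x, y = win(Y[5], Y[5] + half), z = win(d, d))
  sets$short_posterior_sacroiliac_insertion <- patch(x = ilium_x, y = win(Y[5], Y[5] + half), z = win(d, d))
  # the sacrospinous and sacrotuberous ligaments run obliquely from the
  # posterior sacrum to anterior structures; disjoint z windows keep their
  # springs genuinely oblique, which also stabilises the ring against
  # anterior-posterior drift once the joints are frictionless
  sets$sacrospinous_origin <- patch(x = sacrum_x, y = win(Y[5], Y[5]),
                                    z = win(0.6 * d, d))
  sets$sacrospinous_insertion <- patch(x = ilium_inner_x, y = win(Y[3], Y[5] - 10 * tol),
                                       z = win(0, 0.4 * d))
  sets$sacrotuberous_origin <- sets$sacrospinous_origin
  sets$sacrotuberous_insertion <- patch(x = pubis_x, y = win(Y[3], Y[3]),
                                        z = win(0, 0.4 * d))
  sets$iliolumbar_origin <- patch(x = both_sides_x(win(E[3], E[3]), win(E[6], E[6])),
                                  y = win(Y[6], Y[8]))
  sets$iliolumbar_insertion <- patch(x = ilium_x, y = win(Y[6], Y[6]))
  sets$inguinal_origin <- patch(x = ilium_x, y = win(Y[4], Y[6]), z = win(0, 0))
  sets$inguinal_insertion <- patch(x = pubis_x, y = win(Y[2], Y[3]), z = win(0, 0))
  sets$supraspinous_origin <- patch(x = sacrum_x, y = win(Y[6], Y[8]), z = win(d, d))
  sets$supraspinous_insertion <- patch(x = sacrum_x, y = win(Y[5] + half, Y[6]), z = win(d, d))
  sets$intertransverse_origin <- patch(x = sacrum_x, y = win(Y[6], Y[8]), z = win(0, 0))
  sets$intertransverse_insertion <- patch(x = sacrum_x, y = win(Y[5] + half, Y[6]), z = win(0, 0))

  sets$gluteus_maximus_origin <- patch(x = outer_x, y = win(Y[3], Y[6]))
  sets$gluteus_maximus_insertion <- patch(x = outer_x, y = femur_y)
  sets$gluteus_medius_origin <- sets$gluteus_maximus_origin
  sets$gluteus_medius_insertion <- sets$gluteus_maximus_insertion
  sets$gluteus_minimus_origin <- sets$gluteus_maximus_origin
  sets$gluteus_minimus_insertion <- sets$gluteus_maximus_insertion
  sets$pectineus_origin <- patch(x = pubis_x, y = win(Y[2], Y[3]), z = win(0, 0))
  sets$pectineus_insertion <- patch(x = ilium_x, y = femur_y, z = win(0, 0))
  sets$adductor_magnus_origin <- patch(x = pubis_bot_x, y = win(Y[2], Y[2]))
  sets$adductor_magnus_insertion <- patch(x = femur_inner_x, y = femur_y)
  sets$adductor_longus_origin <- sets$pectineus_origin
  sets$adductor_longus_insertion <- sets$adductor_magnus_insertion
  sets$piriformis_origin <- patch(x = sacrum_x, y = win(Y[5], Y[5]), z = win(0, d / 2))
  sets$piriformis_insertion <- patch(x = ilium_x, y = femur_y, z = win(d, d))
  sets$gemellus_superior_origin <- patch(x = ilium_inner_x, y = win(Y[3], Y[4]))
  sets$gemellus_superior_insertion <- sets$piriformis_insertion
  sets$gemellus_inferior_origin <- sets$gemellus_superior_origin
  sets$gemellus_inferior_insertion <- sets$piriformis_insertion

  empty <- names(sets)[vapply(sets, length, integer(1)) == 0L]
  if (length(empty))
    stop("phantom named sets are empty: ", paste(empty, collapse = ", "))

  mesh <- fe_mesh(nodes = nodes, tets = tets, tris = tris,
                  tri_thickness = shell_thickness, named_sets = sets,
                  element_region = region)
  mesh$element_block <- block
  mesh$tri_block <- tri_block

  joint_info <- list(
    sacroiliac_left = list(set = "joint_sacroiliac_left",
                           side_blocks = "cartilage_si_left", normal = c(1, 0, 0)),
    sacroiliac_right = list(set = "joint_sacroiliac_right",
                            side_blocks = "cartilage_si_right", normal = c(1, 0, 0)),
    acetabular_left = list(set = "joint_acetabular_left",
                           side_blocks = "femur_left", normal = c(0, 1, 0)),
    acetabular_right = list(set = "joint_acetabular_right",
                            side_blocks = "femur_right", normal = c(0, 1, 0)),
    pubic = list(set = "joint_pubic", side_blocks = "cartilage_pubic",
                 normal = c(1, 0, 0)))
  mesh$joint_info <- joint_info

  structure(list(mesh = mesh, ct = NULL,
                 region_labels = region, named_sets = sets,
                 joint_info = joint_info, spec = spec),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("<phantom_model> scale ", x$spec$overall_scale, " mm, resolution ",
      x$spec$block_resolution, "\n", sep = "")
  print(x$mesh)
  invisible(x)
}

#' Canonical verification meshes for the solver
#'
#' @param kind one of `"single_tet"`, `"unit_cube"`, `"cantilever_beam"`,
#'   `"two_block_contact"`.
#' @param resolution elements per edge (>= 1).  The cantilever keeps a
#'   length-to-depth ratio of 10 (1 x 1 x 10 mm) so slender-beam theory
#'   applies; its cross-section has `resolution` elements per edge and the
#'   axis ten times that.
#' @return an [fe_mesh] with named face sets `fixed` and `loaded` (plus the
#'   axis-aligned face sets of the box kinds).
#' @export
make_verification_mesh <- function(kind = c("single_tet", "unit_cube",
                                            "cantilever_beam", "two_block_contact"),
                                   resolution = 1L) {
  kind <- match.arg(kind)
  resolution <- as.integer(resolution)
  stopifnot(resolution >= 1L)
  tol <- 1e-9
  face_sets <- function(nodes, Lx, Ly, Lz) {
    list(xmin = pick_nodes(nodes, x = c(0, 0), tol = tol),
         xmax = pick_nodes(nodes, x = c(Lx, Lx), tol = tol),
         ymin = pick_nodes(nodes, y = c(0, 0), tol = tol),
         ymax = pick_nodes(nodes, y = c(Ly, Ly), tol = tol),
         zmin = pick_nodes(nodes, z = c(0, 0), tol = tol),
         zmax = pick_nodes(nodes, z = c(Lz, Lz), tol = tol))
  }
  if (kind == "single_tet") {
    nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    return(fe_mesh(nodes, tets = matrix(1:4, 1L),
                   named_sets = list(fixed = 1:3, loaded = 4L)))
  }
  if (kind == "unit_cube") {
    sb <- structured_box(resolution, resolution, resolution)
    fs <- face_sets(sb$nodes, 1, 1, 1)
    fs$fixed <- fs$xmin; fs$loaded <- fs$xmax
    return(fe_mesh(sb$nodes, sb$tets, named_sets = fs))
  }
  if (kind == "cantilever_beam") {
    # cross-section 2r x 2r: linear tets need several elements through the
    # depth to represent bending, so resolution counts elements per half-depth
    sb <- structured_box(20L * resolution, 2L * resolution, 2L * resolution,
                         Lx = 10, Ly = 1, Lz = 1)
    fs <- face_sets(sb$nodes, 10, 1, 1)
    fs$fixed <- fs$xmin; fs$loaded <- fs$xmax
    return(fe_mesh(sb$nodes, sb$tets, named_sets = fs))
  }
  # two_block_contact: two unit cubes stacked in y with duplicated interface
  # nodes coupled by normal-direction penalty springs
  r <- resolution
  lower <- structured_box(r, r, r)
  upper <- structured_box(r, r, r)
  upper$nodes[, 2L] <- upper$nodes[, 2L] + 1
  off <- nrow(lower$nodes)
  nodes <- rbind(lower$nodes, upper$nodes)
  tets <- rbind(lower$tets, upper$tets + off)
  top_of_lower <- pick_nodes(lower$nodes, y = c(1, 1), tol = tol)
  bot_of_upper <- off + pick_nodes(upper$nodes, y = c(1, 1), tol = tol)
  # pair coincident nodes
  key <- function(p) paste(round(p[, 1L], 9), round(p[, 3L], 9))
  ka <- key(nodes[top_of_lower, , drop = FALSE])
  kb <- key(nodes[bot_of_upper, , drop = FALSE])
  m <- match(ka, kb)
  springs <- data.frame(node_a = top_of_lower, node_b = bot_of_upper[m],
                        stiffness = 1e6, name = "contact",
                        dx = 0, dy = 1, dz = 0)
  sets <- list(fixed = pick_nodes(nodes, y = c(0, 0), tol = tol),
               loaded = pick_nodes(nodes, y = c(2, 2), tol = tol),
               interface_lower = top_of_lower,
               interface_upper = bot_of_upper[m])
  fe_mesh(nodes, tets, springs = springs, named_sets = sets)
}

#' Rasterise the phantom into a synthetic CT volume
#'
#' Voxels whose centres fall inside cortical-labelled elements draw their
#' intensity from `Normal(cortical_shell_hu_mean, hu_noise_sd)`, cancellous
#' voxels likewise from the cancellous distribution; the femur and lumbar
#' stubs are treated as dense bone (cortical distribution) and cartilage as
#' soft tissue at 100 HU plus noise.  Background voxels are air at -1000 HU.
#' The volume adds a one-voxel air margin around the mesh bounding box.
#' Reproducible: the generator state is seeded from `spec$seed` and restored
#' afterwards.
#'
#' @param model a [phantom_model].
#' @param spec the [phantom_spec] (defaults to the one in `model`).
#' @return a [voxel_volume] in HU.
#' @export
rasterize_ct <- function(model, spec = model$spec) {
  mesh <- model$mesh
  if (!nrow(mesh$tets) || sum(tet_volumes(mesh)) <= 0)
    stop("cannot rasterise a zero-volume mesh")
  sp <- rep(spec$voxel_spacing, 3L)
  lo <- apply(mesh$nodes, 2L, min) - sp
  hi <- apply(mesh$nodes, 2L, max) + sp
  shape <- pmax(ceiling((hi - lo) / sp), 1L)
  vol <- array(-1000, dim = shape)

  cx <- lo[1L] + (seq_len(shape[1L]) - 0.5) * sp[1L]
  cy <- lo[2L] + (seq_len(shape[2L]) - 0.5) * sp[2L]
  cz <- lo[3L] + (seq_len(shape[3L]) - 0.5) * sp[3L]
  region <- mesh$element_region
  hu_mean <- c(cortical = spec$cortical_shell_hu_mean,
               cancellous = spec$cancellous_hu_mean,
               femur = spec$cortical_shell_hu_mean,
               lumbar = spec$cortical_shell_hu_mean)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  for (e in seq_len(nrow(mesh$tets))) {
    X <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    ix <- which(cx >= min(X[, 1L]) & cx <= max(X[, 1L]))
    iy <- which(cy >= min(X[, 2L]) & cy <= max(X[, 2L]))
    iz <- which(cz >= min(X[, 3L]) & cz <= max(X[, 3L]))
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz],
                                 KEEP.OUT.ATTRS = FALSE))
    inside <- points_in_tet(pts, X)
    if (!any(inside)) next
    idx <- as.matrix(expand.grid(i = ix, j = iy, k = iz,
                                 KEEP.OUT.ATTRS = FALSE))[inside, , drop = FALSE]
    mu <- if (startsWith(region[e], "cartilage")) 100 else hu_mean[[region[e]]]
    vol[idx] <- mu
  }
  if (spec$hu_noise_sd > 0) {
    body <- vol > -1000
    vol[body] <- vol[body] + stats::rnorm(sum(body), 0, spec$hu_noise_sd)
  }
  voxel_volume(vol, spacing = sp, origin = lo)
}
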