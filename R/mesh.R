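#' Finite-element mesh container
#'
#' An `fe_mesh` bundles the geometry of an integrated pelvis model: volumetric
#' 4-node tetrahedra for bone and cartilage, surface membrane triangles
#' standing in for the cortical shell, two-node axial springs for ligaments,
#' muscles and joint penalties, and named node sets used for attachments,
#' constraints and loads.  All coordinates are millimetres; node and element
#' ids are 1-based (file writers convert to each format's own convention).
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param tets integer matrix, one row per tetrahedron, 4 node ids.
#' @param tris integer matrix, one row per surface triangle, 3 node ids.
#'   May have zero rows.
#' @param tri_thickness membrane thickness in mm, recycled to `nrow(tris)`.
#' @param springs data frame with columns `node_a`, `node_b`,
#'   `stiffness` (N/mm) and `name`; optional columns `dx`, `dy`, `dz` give an
#'   explicit action line for springs between coincident nodes (joint
#'   penalties).  `NULL` means no springs.
#' @param named_sets named list of integer node-id vectors.
#' @param element_region character vector, one region label per tetrahedron
#'   (e.g. `"cortical"`, `"cancellous"`, `"cartilage_pubic"`).
#' @param tri_region optional character vector of labels per triangle.
#'
#' @return an object of class `fe_mesh`.
#' @export
fe_mesh <- function(nodes, tets, tris = NULL, tri_thickness = numeric(),
                    springs = NULL, named_sets = list(),
                    element_region = NULL, tri_region = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("`nodes` must have 3 columns (x, y, z in mm)")
  tets <- matrix(as.integer(tets), ncol = 4L)
  if (is.null(tris)) tris <- matrix(integer(), ncol = 3L)
  tris <- matrix(as.integer(tris), ncol = 3L)
  if (length(tri_thickness) == 1L) tri_thickness <- rep(tri_thickness, nrow(tris))
  if (is.null(springs)) {
    springs <- data.frame(node_a = integer(), node_b = integer(),
                          stiffness = double(), name = character(),
                          dx = double(), dy = double(), dz = double())
  } else {
    springs <- as.data.frame(springs)
    if (!all(c("node_a", "node_b", "stiffness", "name") %in% names(springs)))
      stop("`springs` needs columns node_a, node_b, stiffness, name")
    for (d in c("dx", "dy", "dz")) if (is.null(springs[[d]])) springs[[d]] <- NA_real_
  }
  if (is.null(element_region)) element_region <- rep("cancellous", nrow(tets))
  if (is.null(tri_region)) tri_region <- rep("cortical", nrow(tris))

  mesh <- structure(
    list(nodes = nodes, tets = tets, tris = tris,
         tri_thickness = as.double(tri_thickness),
         springs = springs, named_sets = named_sets,
         element_region = as.character(element_region),
         tri_region = as.character(tri_region)),
    class = "fe_mesh")
  validate_fe_mesh(mesh)
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("<fe_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets), " tets, ",
      nrow(x$tris), " membrane tris, ", nrow(x$springs), " springs, ",
      length(x$named_sets), " named sets\n", sep = "")
  invisible(x)
}

validate_fe_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  ids <- c(mesh$tets, mesh$tris, mesh$springs$node_a, mesh$springs$node_b,
           unlist(mesh$named_sets, use.names = FALSE))
  if (length(ids) && (min(ids) < 1L || max(ids) > n))
    stop("mesh refers to node ids outside 1..", n)
  if (nrow(mesh$tets)) {
    v <- tet_volumes(mesh)
    if (any(v <= 0)) {
      bad <- which(v <= 0)
      stop("inverted or degenerate tetrahedra (non-positive volume): elements ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  if (length(mesh$element_region) != nrow(mesh$tets))
    stop("element_region length must match number of tets")
  if (length(mesh$tri_thickness) != nrow(mesh$tris))
    stop("tri_thickness length must match number of tris")
  if (length(mesh$tri_thickness) && any(mesh$tri_thickness <= 0))
    stop("membrane thickness must be > 0")
  if (nrow(mesh$springs) && any(mesh$springs$stiffness <= 0))
    stop("spring stiffness must be > 0")
  invisible(mesh)
}

#' Signed tetrahedron volumes
#'
#' @param mesh an [fe_mesh].
#' @return numeric vector of signed volumes in mm^3 (positive for correctly
#'   oriented elements).
#' @export
tet_volumes <- function(mesh) {
  X <- mesh$nodes
  t1 <- mesh$tets[, 1L]; t2 <- mesh$tets[, 2L]
  t3 <- mesh$tets[, 3L]; t4 <- mesh$tets[, 4L]
  a <- X[t2, , drop = FALSE] - X[t1, , drop = FALSE]
  b <- X[t3, , drop = FALSE] - X[t1, , drop = FALSE]
  c_ <- X[t4, , drop = FALSE] - X[t1, , drop = FALSE]
  (a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
   a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
   a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Tetrahedron centroids
#' @param mesh an [fe_mesh].
#' @return matrix of centroid coordinates (mm), one row per tet.
#' @export
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
}

# Boundary triangular faces of a set of tets: faces appearing exactly once.
# Returns a matrix of 3 node ids per face, wound so the outward normal points
# away from the owning tet, plus the owning tet index as an attribute.
boundary_faces <- function(nodes, tets) {
  if (!nrow(tets)) return(structure(matrix(integer(), ncol = 3L), owner = integer()))
  faceidx <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 4L, 3L))
  nf <- nrow(tets) * 4L
  faces <- matrix(0L, nf, 3L)
  owner <- rep(seq_len(nrow(tets)), each = 4L)
  for (k in 1:4) faces[seq(k, nf, by = 4L), ] <- tets[, faceidx[k, ], drop = FALSE]
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  once <- names(which(table(key) == 1L))
  keep <- key %in% once
  structure(faces[keep, , drop = FALSE], owner = owner[keep])
}

# Union-find over nodes connected by tets/springs; returns component id per node.
mesh_components <- function(mesh) {
  n <- nrow(mesh$nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  if (nrow(mesh$tets)) for (e in seq_len(nrow(mesh$tets))) {
    t <- mesh$tets[e, ]
    unite(t[1L], t[2L]); unite(t[1L], t[3L]); unite(t[1L], t[4L])
  }
  if (nrow(mesh$tris)) for (e in seq_len(nrow(mesh$tris))) {
    t <- mesh$tris[e, ]
    unite(t[1L], t[2L]); unite(t[1L], t[3L])
  }
  if (nrow(mesh$springs)) for (e in seq_len(nrow(mesh$springs)))
    unite(mesh$springs$node_a[e], mesh$springs$node_b[e])
  vapply(seq_len(n), find, integer(1))
}
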