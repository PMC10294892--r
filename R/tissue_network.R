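#' Passive tissue specification
#'
#' One ligament or (relaxed) muscle modelled as a bundle of constant-stiffness
#' axial springs between an origin and an insertion node patch.  Entries
#' co-modelled with another tissue (anatomically merged bundles) carry no
#' springs of their own.
#'
#' @param name tissue name.
#' @param class `"ligament"` or `"muscle"`.
#' @param k_per_spring stiffness per spring in N/mm (NA when co-modelled).
#' @param n_springs number of springs (NA when co-modelled).
#' @param attachment_area muscle attachment area in mm^2 (optional).
#' @param origin_set,insertion_set names of mesh node sets.
#' @param co_modeled_with parent tissue name, or `""`.
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(name, class = c("ligament", "muscle"),
                        k_per_spring = NA_real_, n_springs = NA_integer_,
                        attachment_area = NA_real_,
                        origin_set = paste0(name, "_origin"),
                        insertion_set = paste0(name, "_insertion"),
                        co_modeled_with = "") {
  class <- match.arg(class)
  co <- !is.na(co_modeled_with) && nzchar(co_modeled_with)
  if (!co) {
    if (is.na(k_per_spring) || k_per_spring <= 0)
      stop("tissue '", name, "': k_per_spring must be > 0 unless co-modelled")
    if (is.na(n_springs) || n_springs < 1)
      stop("tissue '", name, "': n_springs must be >= 1 unless co-modelled")
  }
  structure(list(name = name, class = class, k_per_spring = k_per_spring,
                 n_springs = as.integer(n_springs),
                 attachment_area = attachment_area,
                 origin_set = origin_set, insertion_set = insertion_set,
                 co_modeled_with = if (co) co_modeled_with else ""),
            class = "tissue_spec")
}

tissue_specs_from_table <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    tissue_spec(name = tab$name[i], class = tab$class[i],
                k_per_spring = tab$k_per_spring[i],
                n_springs = tab$n_springs[i],
                attachment_area = tab$attachment_area[i],
                origin_set = tab$origin_set[i],
                insertion_set = tab$insertion_set[i],
                co_modeled_with = tab$co_modeled_with[i])
  })
}

#' Joint treatment specification
#'
#' @param name one of `"sacroiliac_left"`, `"sacroiliac_right"`,
#'   `"acetabular_left"`, `"acetabular_right"`, `"pubic"`.
#' @param mode `"tied"` (interface nodes shared/merged) or
#'   `"free_frictionless"` (interface duplicated; motion constrained only
#'   along the interface normal by penalty gap springs).
#' @param penalty normal penalty stiffness in N/mm (frictionless mode).
#' @return object of class `joint_spec`.
#' @export
joint_spec <- function(name, mode = c("free_frictionless", "tied"),
                       penalty = 1e4) {
  name <- match.arg(name, c("sacroiliac_left", "sacroiliac_right",
                            "acetabular_left", "acetabular_right", "pubic"))
  mode <- match.arg(mode)
  if (mode == "free_frictionless" && penalty <= 0)
    stop("penalty stiffness must be > 0 in frictionless mode")
  structure(list(name = name, mode = mode, penalty = penalty),
            class = "joint_spec")
}

#' Default joint set of the integrated model
#'
#' Sacroiliac and acetabular joints are mobile and frictionless; the pubic
#' symphysis stays tied to its cartilage wedge.
#'
#' @param penalty normal penalty stiffness in N/mm.
#' @return list of [joint_spec] objects.
#' @export
default_joints <- function(penalty = 1e4) {
  list(joint_spec("sacroiliac_left", "free_frictionless", penalty),
       joint_spec("sacroiliac_right", "free_frictionless", penalty),
       joint_spec("acetabular_left", "free_frictionless", penalty),
       joint_spec("acetabular_right", "free_frictionless", penalty),
       joint_spec("pubic", "tied"))
}

#' Scale an isometric muscle stiffness to a spring attachment
#'
#' `k_s = k_iso * A_s / A_ml`: the equivalent spring carries the share of the
#' isometric muscle stiffness proportional to the cortical attachment area
#' `A_s` (mm^2) its node covers, out of the muscle's total attachment area
#' `A_ml` (mm^2).
#'
#' @param k_iso isometric stiffness in N/mm.
#' @param A_S attachment area covered by the spring's node, mm^2.
#' @param A_ML total muscle attachment area, mm^2.
#' @return spring stiffness in N/mm.
#' @export
scale_spring_stiffness <- function(k_iso, A_S, A_ML) {
  if (any(c(k_iso, A_S, A_ML) <= 0) || any(!is.finite(c(k_iso, A_S, A_ML))))
    stop("stiffness and areas must be finite and > 0")
  k_iso * A_S / A_ML
}

# Deterministic closest-pair selection between two node patches: all
# origin x insertion pairs ranked by (distance, origin id, insertion id);
# zero-length pairs (shared corner nodes) are excluded.  Bilateral tissues
# (both patches straddling the model midline) are treated as a symmetric
# pair of bundles: the spring count is split between the left and right
# half-patches (the left half takes the odd spring) and the closest-pair
# rule applies within each side — otherwise the id tie-break would put every
# spring of a mirrored tissue on one side.
closest_pairs <- function(nodes, origin, insertion, n) {
  mid <- mean(range(nodes[c(origin, insertion), 1L]))
  straddles <- function(ids) any(nodes[ids, 1L] < mid - 1e-9) &&
    any(nodes[ids, 1L] > mid + 1e-9)
  if (straddles(origin) && straddles(insertion) && n > 1L) {
    left <- function(ids) ids[nodes[ids, 1L] <= mid + 1e-9]
    right <- function(ids) ids[nodes[ids, 1L] > mid + 1e-9]
    nl <- ceiling(n / 2); nr <- n - nl
    out <- rbind(closest_pairs_one(nodes, left(origin), left(insertion), nl),
                 if (nr > 0L) closest_pairs_one(nodes, right(origin),
                                                right(insertion), nr))
    return(out)
  }
  closest_pairs_one(nodes, origin, insertion, n)
}

closest_pairs_one <- function(nodes, origin, insertion, n) {
  d2 <- outer(seq_along(origin), seq_along(insertion), function(i, j) {
    rowSums((nodes[origin[i], , drop = FALSE] - nodes[insertion[j], , drop = FALSE])^2)
  })
  ord <- order(as.vector(d2), rep(origin, times = length(insertion)),
               rep(insertion, each = length(origin)))
  oi <- rep(origin, times = length(insertion))[ord]
  ii <- rep(insertion, each = length(origin))[ord]
  keep <- as.vector(d2)[ord] > 1e-20 & oi != ii
  oi <- oi[keep]; ii <- ii[keep]
  if (length(oi) < n)
    stop("not enough distinct origin/insertion pairs (", length(oi),
         ") for ", n, " springs")
  data.frame(node_a = oi[seq_len(n)], node_b = ii[seq_len(n)])
}

#' Attach the passive soft-tissue spring network to a mesh
#'
#' For every non-co-modelled tissue in `specs`, creates exactly `n_springs`
#' axial springs between the `n_springs` closest origin/insertion node pairs
#' (deterministic ordering: distance, then lowest node ids), each carrying
#' the tissue's per-spring stiffness.  Frictionless joints are realised by
#' duplicating the interface node sheet, reassigning the joint's far-side
#' elements to the duplicates, and coupling each node pair with a
#' normal-direction penalty spring; tangential directions stay unconstrained.
#' Tied joints keep the conforming (merged) interface.
#'
#' @param mesh an [fe_mesh] carrying the referenced node sets (a phantom mesh).
#' @param specs list of [tissue_spec] objects, or the tibble from
#'   [load_tissue_table].
#' @param joints list of [joint_spec] objects; joint interface geometry is
#'   looked up in the mesh's `joint_info` (phantom meshes carry it).
#' @return the mesh with springs (and, for frictionless joints, duplicated
#'   interface nodes) added.
#' @export
build_network <- function(mesh, specs = load_tissue_table(), joints = list()) {
  if (is.data.frame(specs)) specs <- tissue_specs_from_table(specs)
  springs <- mesh$springs
  for (sp in specs) {
    if (nzchar(sp$co_modeled_with)) next
    for (setname in c(sp$origin_set, sp$insertion_set)) {
      if (!setname %in% names(mesh$named_sets))
        stop("tissue '", sp$name, "': unknown node set '", setname, "'")
      if (!length(mesh$named_sets[[setname]]))
        stop("tissue '", sp$name, "': node set '", setname, "' is empty")
    }
    pr <- closest_pairs(mesh$nodes, mesh$named_sets[[sp$origin_set]],
                        mesh$named_sets[[sp$insertion_set]], sp$n_springs)
    springs <- rbind(springs,
                     data.frame(node_a = pr$node_a, node_b = pr$node_b,
                                stiffness = sp$k_per_spring, name = sp$name,
                                dx = NA_real_, dy = NA_real_, dz = NA_real_))
  }
  mesh$springs <- springs
  for (jt in joints) {
    if (jt$mode == "tied") next
    mesh <- split_joint(mesh, jt)
  }
  validate_fe_mesh(mesh)
  mesh
}

# Duplicate the interface node sheet of a frictionless joint and couple the
# pairs with penalty springs along the interface normal.  Each pair's
# stiffness is weighted by the node's tributary share of the interface area
# (normalised to a mean of one, so the joint's total normal stiffness is
# penalty x number of pairs); without the weighting, edge and corner nodes
# of the interface are over-stiff and concentrate contact force there.
split_joint <- function(mesh, jt) {
  info <- mesh$joint_info[[jt$name]]
  if (is.null(info))
    stop("mesh carries no interface geometry for joint '", jt$name, "'")
  iface <- resolve_set(mesh, info$set)
  if (!length(iface)) stop("joint '", jt$name, "' has an empty interface set")
  side <- mesh$element_block %in% info$side_blocks
  tributary <- interface_tributary_area(mesh, iface, side)
  tri_side <- if (!is.null(mesh$tri_block)) mesh$tri_block %in% info$side_blocks
              else rep(FALSE, nrow(mesh$tris))
  n0 <- nrow(mesh$nodes)
  newrows <- list(); pairs <- list()
  for (nd in iface) {
    touching <- side & (mesh$tets[, 1L] == nd | mesh$tets[, 2L] == nd |
                        mesh$tets[, 3L] == nd | mesh$tets[, 4L] == nd)
    if (!any(touching)) next
    newid <- n0 + length(newrows) + 1L
    newrows[[length(newrows) + 1L]] <- mesh$nodes[nd, ]
    mesh$tets[touching & mesh$tets[, 1L] == nd, 1L] <- newid
    mesh$tets[touching & mesh$tets[, 2L] == nd, 2L] <- newid
    mesh$tets[touching & mesh$tets[, 3L] == nd, 3L] <- newid
    mesh$tets[touching & mesh$tets[, 4L] == nd, 4L] <- newid
    if (any(tri_side)) for (cc in 1:3) {
      hit <- tri_side & mesh$tris[, cc] == nd
      mesh$tris[hit, cc] <- newid
    }
    pairs[[length(pairs) + 1L]] <- c(nd, newid)
  }
  if (!length(pairs)) return(mesh)
  mesh$nodes <- rbind(mesh$nodes, do.call(rbind, newrows))
  pm <- do.call(rbind, pairs)
  wt <- tributary[match(pm[, 1L], iface)]
  keep <- wt > 0
  pm <- pm[keep, , drop = FALSE]; wt <- wt[keep]
  wt <- wt / mean(wt)
  mesh$springs <- rbind(mesh$springs,
                        data.frame(node_a = pm[, 1L], node_b = pm[, 2L],
                                   stiffness = jt$penalty * wt,
                                   name = paste0("joint_", jt$name),
                                   dx = info$normal[1L], dy = info$normal[2L],
                                   dz = info$normal[3L]))
  mesh
}

# Tributary interface area per interface node: one third of each interface
# triangle (a face of a far-side tet with all three nodes on the interface).
interface_tributary_area <- function(mesh, iface, side) {
  area <- setNames(numeric(length(iface)), iface)
  on_iface <- matrix(mesh$tets %in% iface, ncol = 4L)
  cand <- which(side & rowSums(on_iface) >= 3L)
  faceidx <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  for (e in cand) {
    for (f in 1:4) {
      tri <- mesh$tets[e, faceidx[f, ]]
      if (all(tri %in% iface)) {
        P <- mesh$nodes[tri, , drop = FALSE]
        v1 <- P[2L, ] - P[1L, ]; v2 <- P[3L, ] - P[1L, ]
        a <- sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2],
                        v1[3] * v2[1] - v1[1] * v2[3],
                        v1[1] * v2[2] - v1[2] * v2[1])^2)) / 2
        for (nd in tri) area[as.character(nd)] <- area[as.character(nd)] + a / 3
      }
    }
  }
  unname(area)
}

#' Model variants of the two-model comparison protocol
#'
#' Model I is the bone-only ablation: no ligament or muscle springs, every
#' joint tied (the phantom's conforming interfaces are kept merged).
#' Model II is the integrated model: the full spring registry attached and
#' the sacroiliac and acetabular joints mobile and frictionless.  The two
#' variants share identical node coordinates for the original mesh nodes;
#' they differ only in elements and constraints.
#'
#' @param mesh a phantom [fe_mesh].
#' @param specs tissue registry (tibble or list of [tissue_spec]).
#' @param joints list of [joint_spec]; default [default_joints].
#' @return an [fe_mesh].
#' @export
model_I_variant <- function(mesh) {
  mesh$springs <- mesh$springs[0, , drop = FALSE]
  mesh
}

#' @rdname model_I_variant
#' @export
model_II_variant <- function(mesh, specs = load_tissue_table(),
                             joints = default_joints()) {
  build_network(model_I_variant(mesh), specs, joints)
}
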