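#' Boundary condition on a named node set
#'
#' @param node_set name of a mesh node set, or an integer vector of node ids.
#' @param axes subset of `c("x","y","z")` to constrain.
#' @param value prescribed displacement in mm (default 0).
#' @return object of class `boundary_condition`.
#' @export
boundary_condition <- function(node_set, axes, value = 0) {
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  stopifnot(length(axes) >= 1L, is.finite(value))
  structure(list(node_set = node_set, axes = axes, value = value),
            class = "boundary_condition")
}

#' Load case: a total force distributed over a node set
#'
#' @param node_set name of a mesh node set, or an integer vector of node ids.
#' @param force total force vector in N, shared equally by the set's nodes.
#' @param label optional label.
#' @return object of class `load_case`.
#' @export
load_case <- function(node_set, force, label = "load") {
  force <- as.double(force)
  stopifnot(length(force) == 3L, all(is.finite(force)))
  structure(list(node_set = node_set, force = force, label = label),
            class = "load_case")
}

resolve_set <- function(mesh, node_set) {
  if (is.character(node_set)) {
    if (!node_set %in% names(mesh$named_sets))
      stop("unknown node set '", node_set, "'")
    mesh$named_sets[[node_set]]
  } else as.integer(node_set)
}

# Shape-function gradients of a linear tet: 3x4 matrix G with
# G[j, a] = dN_a/dx_j, plus the element volume.
tet_gradients <- function(X) {
  Cmat <- cbind(1, X)
  V <- det(Cmat) / 6
  G <- solve(Cmat)[2:4, , drop = FALSE]
  list(G = G, V = V)
}

# 12x12 stiffness of a linear tet (dof order x1 y1 z1 x2 ...).
tet_stiffness <- function(X, D) {
  g <- tet_gradients(X)
  B <- tet_B(g$G)
  list(K = g$V * crossprod(B, D %*% B), V = g$V)
}

# 6x12 strain-displacement matrix from tet gradients (Voigt xx yy zz xy yz zx).
tet_B <- function(G) {
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- G[1, a]
    B[2, c0 + 2] <- G[2, a]
    B[3, c0 + 3] <- G[3, a]
    B[4, c0 + 1] <- G[2, a]; B[4, c0 + 2] <- G[1, a]
    B[5, c0 + 2] <- G[3, a]; B[5, c0 + 3] <- G[2, a]
    B[6, c0 + 1] <- G[3, a]; B[6, c0 + 3] <- G[1, a]
  }
  B
}

# Membrane (plane-stress CST) element: local basis, 2D B matrix, area and
# the 6x9 map from global dofs to in-plane local dofs.
tri_membrane <- function(P) {
  e1 <- P[2L, ] - P[1L, ]
  nrm <- c(e1[2] * (P[3, 3] - P[1, 3]) - e1[3] * (P[3, 2] - P[1, 2]),
           e1[3] * (P[3, 1] - P[1, 1]) - e1[1] * (P[3, 3] - P[1, 3]),
           e1[1] * (P[3, 2] - P[1, 2]) - e1[2] * (P[3, 1] - P[1, 1]))
  A <- sqrt(sum(nrm^2)) / 2
  if (A <= 0) stop("degenerate membrane triangle")
  e1 <- e1 / sqrt(sum(e1^2))
  n <- nrm / (2 * A)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  # local 2D coordinates
  loc <- cbind((P - rep(P[1L, ], each = 3L)) %*% e1,
               (P - rep(P[1L, ], each = 3L)) %*% e2)
  x <- loc[, 1L]; y <- loc[, 2L]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  B <- matrix(0, 3, 6)
  for (a in 1:3) {
    B[1, 2 * a - 1] <- b[a]
    B[2, 2 * a] <- c_[a]
    B[3, 2 * a - 1] <- c_[a]; B[3, 2 * a] <- b[a]
  }
  B <- B / (2 * A)
  Tm <- matrix(0, 6, 9)
  for (a in 1:3) {
    Tm[2 * a - 1, (3 * a - 2):(3 * a)] <- e1
    Tm[2 * a,     (3 * a - 2):(3 * a)] <- e2
  }
  list(B = B, T = Tm, A = A, e1 = e1, e2 = e2, n = n)
}

spring_direction <- function(mesh, i) {
  s <- mesh$springs[i, ]
  if (!is.na(s$dx)) {
    d <- c(s$dx, s$dy, s$dz)
  } else {
    d <- mesh$nodes[s$node_b, ] - mesh$nodes[s$node_a, ]
  }
  len <- sqrt(sum(d^2))
  if (len == 0) stop("spring ", i, " has coincident nodes and no explicit direction")
  d / len
}

# Assemble stiffness of a subset of tets with per-element E, nu into triplets.
tet_triplets <- function(mesh, elems, E, nu) {
  nnz <- length(elems) * 144L
  ii <- integer(nnz); jj <- integer(nnz); xx <- double(nnz)
  pos <- 0L
  for (idx in seq_along(elems)) {
    e <- elems[idx]
    X <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    Ke <- tet_stiffness(X, elastic_D(E[idx], nu[idx]))$K
    dofs <- as.vector(t(cbind(3L * mesh$tets[e, ] - 2L,
                              3L * mesh$tets[e, ] - 1L,
                              3L * mesh$tets[e, ])))
    ii[pos + 1:144] <- rep(dofs, times = 12L)
    jj[pos + 1:144] <- rep(dofs, each = 12L)
    xx[pos + 1:144] <- as.vector(Ke)
    pos <- pos + 144L
  }
  list(i = ii, j = jj, x = xx)
}

# Assemble the constant part of the stiffness: linear-family tets, all
# membranes, all springs.  Returns a sparse ndof x ndof matrix.
assemble_static_stiffness <- function(mesh, materials) {
  ndof <- 3L * nrow(mesh$nodes)
  trip <- list(i = integer(), j = integer(), x = double())
  lin <- which(materials$tets$family == "linear")
  if (length(lin)) {
    tt <- tet_triplets(mesh, materials$tets$element[lin],
                       materials$tets$E[lin], materials$tets$nu[lin])
    trip <- Map(c, trip, tt)
  }
  if (nrow(mesh$tris)) {
    nnz <- nrow(mesh$tris) * 81L
    ii <- integer(nnz); jj <- integer(nnz); xx <- double(nnz)
    pos <- 0L
    for (e in seq_len(nrow(mesh$tris))) {
      P <- mesh$nodes[mesh$tris[e, ], , drop = FALSE]
      tm <- tri_membrane(P)
      Dps <- plane_stress_D(materials$membranes$E[e], materials$membranes$nu[e])
      K6 <- tm$A * mesh$tri_thickness[e] * crossprod(tm$B, Dps %*% tm$B)
      K9 <- crossprod(tm$T, K6 %*% tm$T)
      dofs <- as.vector(t(cbind(3L * mesh$tris[e, ] - 2L,
                                3L * mesh$tris[e, ] - 1L,
                                3L * mesh$tris[e, ])))
      ii[pos + 1:81] <- rep(dofs, times = 9L)
      jj[pos + 1:81] <- rep(dofs, each = 9L)
      xx[pos + 1:81] <- as.vector(K9)
      pos <- pos + 81L
    }
    trip <- Map(c, trip, list(i = ii, j = jj, x = xx))
  }
  if (nrow(mesh$springs)) {
    for (e in seq_len(nrow(mesh$springs))) {
      d <- spring_direction(mesh, e)
      kd <- mesh$springs$stiffness[e] * tcrossprod(d)
      Ke <- rbind(cbind(kd, -kd), cbind(-kd, kd))
      na <- mesh$springs$node_a[e]; nb <- mesh$springs$node_b[e]
      dofs <- c(3L * na - 2L, 3L * na - 1L, 3L * na,
                3L * nb - 2L, 3L * nb - 1L, 3L * nb)
      trip <- Map(c, trip, list(i = rep(dofs, times = 6L),
                                j = rep(dofs, each = 6L),
                                x = as.vector(Ke)))
    }
  }
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                       dims = c(ndof, ndof), symmetric = FALSE)
}

# Cartilage secant stiffness for the current displacement (zero matrix when
# no cartilage-secant elements are active).
assemble_cartilage_stiffness <- function(mesh, materials, u) {
  elems <- materials$tets$element[materials$tets$family == "cartilage"]
  ndof <- 3L * nrow(mesh$nodes)
  if (!length(elems))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                                dims = c(ndof, ndof)))
  E <- vapply(elems, function(e) {
    X <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    g <- tet_gradients(X)
    ue <- matrix(u, ncol = 3L, byrow = TRUE)[mesh$tets[e, ], , drop = FALSE]
    H <- t(ue) %*% t(g$G)
    vol_strain <- sum(diag(H))
    max(cartilage_modulus(vol_strain, materials$cartilage), materials$cartilage$E_min)
  }, double(1))
  nu <- rep(materials$mooney_rivlin$nu, length(elems))
  tt <- tet_triplets(mesh, elems, E, nu)
  Matrix::sparseMatrix(i = tt$i, j = tt$j, x = tt$x, dims = c(ndof, ndof))
}

# Internal force and consistent (finite-difference) tangent of the
# Mooney-Rivlin tets at displacement u.
mr_force_tangent <- function(mesh, materials, u, want_tangent = TRUE) {
  elems <- materials$tets$element[materials$tets$family == "mooney_rivlin"]
  ndof <- 3L * nrow(mesh$nodes)
  f <- numeric(ndof)
  trip <- list(i = integer(), j = integer(), x = double())
  if (!length(elems))
    return(list(f = f, K = Matrix::sparseMatrix(i = integer(), j = integer(),
                                                x = double(), dims = c(ndof, ndof))))
  m <- materials$mooney_rivlin
  U <- matrix(u, ncol = 3L, byrow = TRUE)
  h <- 1e-6
  for (e in elems) {
    conn <- mesh$tets[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    g <- tet_gradients(X)
    F_ <- diag(3) + t(U[conn, , drop = FALSE]) %*% t(g$G)
    P <- mr_first_piola(F_, m)
    fe <- g$V * P %*% g$G                # 3 x 4, column a = force at node a
    dofs <- as.vector(rbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn))
    f[dofs] <- f[dofs] + as.vector(fe)
    if (want_tangent) {
      # dP/dF by central differences, then K[(a,i),(b,m)] =
      # V * sum_{j,l} A[i,j,m,l] G[l,b] G[j,a]
      A <- array(0, c(3, 3, 3, 3))
      for (k in 1:3) for (l in 1:3) {
        Fp <- F_; Fp[k, l] <- Fp[k, l] + h
        Fm <- F_; Fm[k, l] <- Fm[k, l] - h
        A[, , k, l] <- (mr_first_piola(Fp, m) - mr_first_piola(Fm, m)) / (2 * h)
      }
      Ke <- matrix(0, 12, 12)
      for (a in 1:4) for (b in 1:4) {
        gab <- outer(g$G[, a], g$G[, b])   # [j, l] = dN_a/dx_j * dN_b/dx_l
        blk <- matrix(0, 3, 3)
        for (i in 1:3) for (mm in 1:3)
          blk[i, mm] <- sum(A[i, , mm, ] * gab)
        Ke[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- g$V * blk
      }
      trip <- Map(c, trip, list(i = rep(dofs, times = 12L),
                                j = rep(dofs, each = 12L),
                                x = as.vector(Ke)))
    }
  }
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(ndof, ndof))
  list(f = f, K = K)
}

bc_dofs <- function(mesh, bcs) {
  fixed <- integer(); vals <- double()
  axmap <- c(x = 0L, y = 1L, z = 2L)
  for (bc in bcs) {
    nodes <- resolve_set(mesh, bc$node_set)
    if (!length(nodes)) stop("boundary condition refers to an empty node set")
    for (ax in bc$axes) {
      d <- 3L * (nodes - 1L) + axmap[[ax]] + 1L
      fixed <- c(fixed, d); vals <- c(vals, rep(bc$value, length(d)))
    }
  }
  dup <- !duplicated(fixed)
  list(fixed = fixed[dup], vals = vals[dup])
}

#' Assemble the constrained static FE system
#'
#' Builds the global stiffness for the mesh's linear elements (tetrahedra,
#' membranes, springs) and records the constrained degrees of freedom.  The
#' stiffness is symmetric by construction; after constraint elimination it
#' must be positive definite, which is verified at factorisation time.  A
#' singular system caused by a free-floating mesh component is reported with
#' a node id from the offending component.
#'
#' @param mesh an [fe_mesh].
#' @param materials a [material_field] covering every element.
#' @param bcs list of [boundary_condition] objects.
#' @return object of class `fe_system` (stiffness, fixed dofs, mesh handle).
#' @export
fe_assemble <- function(mesh, materials, bcs) {
  if (nrow(materials$tets) != nrow(mesh$tets))
    stop("materials must cover every tetrahedron")
  K <- assemble_static_stiffness(mesh, materials)
  # cartilage-secant elements contribute their floor stiffness in the
  # linear path so the constrained system stays well posed
  K <- K + assemble_cartilage_stiffness(mesh, materials, numeric(3L * nrow(mesh$nodes)))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  bc <- bc_dofs(mesh, bcs)
  if (!length(bc$fixed)) stop("at least one constrained dof is required")
  structure(list(K = K, fixed = bc$fixed, vals = bc$vals,
                 mesh = mesh, materials = materials, bcs = bcs),
            class = "fe_system")
}

#' Consistent nodal loads for a uniform surface traction
#'
#' Distributes a uniform traction over the boundary faces spanned by a node
#' set using the linear-element tributary rule (one third of each face's
#' area per node), the discretisation under which a uniform traction
#' reproduces a homogeneous stress state exactly.  [load_case], by contrast,
#' shares a total force equally over a set's nodes.
#'
#' @param mesh an [fe_mesh].
#' @param node_set name of a node set or integer node ids spanning the faces.
#' @param traction traction vector in MPa (N/mm^2).
#' @return load vector of nodal forces (N), length `3 * n_nodes`.
#' @export
consistent_surface_load <- function(mesh, node_set, traction) {
  nodes <- resolve_set(mesh, node_set)
  bf <- boundary_faces(mesh$nodes, mesh$tets)
  f <- numeric(3L * nrow(mesh$nodes))
  used <- FALSE
  for (i in seq_len(nrow(bf))) {
    tri <- bf[i, ]
    if (!all(tri %in% nodes)) next
    P <- mesh$nodes[tri, , drop = FALSE]
    v1 <- P[2L, ] - P[1L, ]; v2 <- P[3L, ] - P[1L, ]
    A <- sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2],
                    v1[3] * v2[1] - v1[1] * v2[3],
                    v1[1] * v2[2] - v1[2] * v2[1])^2)) / 2
    for (nd in tri) {
      ix <- (3L * nd - 2L):(3L * nd)
      f[ix] <- f[ix] + A / 3 * traction
    }
    used <- TRUE
  }
  if (!used) stop("node set spans no boundary faces")
  f
}

#' Global load vector from load cases
#'
#' @param mesh an [fe_mesh].
#' @param loads list of [load_case] objects (or a single one).
#' @return numeric vector of nodal forces in N, length `3 * n_nodes`.
#' @export
load_vector <- function(mesh, loads) {
  if (inherits(loads, "load_case")) loads <- list(loads)
  f <- numeric(3L * nrow(mesh$nodes))
  for (ld in loads) {
    nodes <- resolve_set(mesh, ld$node_set)
    if (!length(nodes)) stop("load case '", ld$label, "' has an empty node set")
    per <- ld$force / length(nodes)
    f[3L * nodes - 2L] <- f[3L * nodes - 2L] + per[1L]
    f[3L * nodes - 1L] <- f[3L * nodes - 1L] + per[2L]
    f[3L * nodes] <- f[3L * nodes] + per[3L]
  }
  f
}

factor_or_diagnose <- function(Kff, mesh, free_dofs) {
  tryCatch(
    # CHOLMOD emits a warning alongside its error on indefinite systems;
    # the diagnostic below replaces both
    suppressWarnings(
      Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, perm = TRUE)),
    error = function(e) {
      comp <- mesh_components(mesh)
      fixed_nodes <- unique((setdiff(seq_len(3L * nrow(mesh$nodes)), free_dofs) - 1L) %/% 3L + 1L)
      floating <- setdiff(unique(comp), unique(comp[fixed_nodes]))
      if (length(floating)) {
        node <- which(comp == floating[1L])[1L]
        stop("singular constrained system: mesh component containing node ",
             node, " has no constrained dof", call. = FALSE)
      }
      stop("singular constrained system: ", conditionMessage(e), call. = FALSE)
    })
}

#' Solve the linear static system
#'
#' Direct sparse Cholesky solve of the constraint-eliminated system; the
#' relative residual of the free equations is checked against 1e-8.
#'
#' @param system an `fe_system` from [fe_assemble].
#' @param loads list of [load_case] objects (or a precomputed load vector).
#' @return an `fe_solution` (see [postprocess]); displacements in mm.
#' @export
solve_linear <- function(system, loads) {
  mesh <- system$mesh
  ndof <- 3L * nrow(mesh$nodes)
  f <- if (is.numeric(loads)) loads else load_vector(mesh, loads)
  free <- setdiff(seq_len(ndof), system$fixed)
  u <- numeric(ndof)
  u[system$fixed] <- system$vals
  rhs <- f[free] - as.vector(system$K[free, system$fixed, drop = FALSE] %*% system$vals)
  ch <- factor_or_diagnose(system$K[free, free, drop = FALSE], mesh, free)
  u[free] <- as.vector(Matrix::solve(ch, rhs))
  res <- as.vector(system$K[free, free, drop = FALSE] %*% u[free]) - rhs
  ref <- max(sqrt(sum(rhs^2)), 1e-30)
  if (sqrt(sum(res^2)) / ref > 1e-8)
    warning("linear solve residual exceeds 1e-8 relative")
  reactions <- as.vector(system$K %*% u) - f
  reactions[free] <- 0
  postprocess_solution(u, mesh, system$materials, f, reactions)
}

#' Newton-Raphson solve for models with hyperelastic or secant elements
#'
#' Load-stepped Newton iteration: the external load is applied in `steps`
#' equal increments; within each increment the residual (internal minus
#' external force on the free dofs) is driven below `tol` times the applied
#' load norm.  Cartilage-secant moduli are re-evaluated from the current
#' volumetric strain each iteration; Mooney-Rivlin tets contribute an exact
#' internal force and a finite-difference consistent tangent.  Divergence
#' (residual growing over two successive iterations) and iteration overflow
#' abort with the residual history attached to the error condition.
#'
#' @param mesh an [fe_mesh].
#' @param materials a [material_field].
#' @param bcs list of [boundary_condition] objects (homogeneous).
#' @param loads list of [load_case] objects or a load vector.
#' @param steps number of equal load substeps (default 5).
#' @param tol relative residual tolerance (default 1e-6).
#' @param max_iter Newton iteration cap per substep (default 25).
#' @return an `fe_solution`.
#' @export
solve_newton <- function(mesh, materials, bcs, loads, steps = 5,
                         tol = 1e-6, max_iter = 25) {
  stopifnot(tol > 0, steps >= 1)
  ndof <- 3L * nrow(mesh$nodes)
  f_ext <- if (is.numeric(loads)) loads else load_vector(mesh, loads)
  K0 <- assemble_static_stiffness(mesh, materials)
  bc <- bc_dofs(mesh, bcs)
  free <- setdiff(seq_len(ndof), bc$fixed)
  u <- numeric(ndof)
  fnorm <- sqrt(sum(f_ext[free]^2))
  history <- numeric()
  for (s in seq_len(steps)) {
    fac <- s / steps
    target <- fac * f_ext
    u[bc$fixed] <- fac * bc$vals
    prev <- Inf; grew <- 0L
    for (it in seq_len(max_iter)) {
      Kc <- assemble_cartilage_stiffness(mesh, materials, u)
      mr <- mr_force_tangent(mesh, materials, u)
      f_int <- as.vector(K0 %*% u) + as.vector(Kc %*% u) + mr$f
      r <- target - f_int
      rnorm <- sqrt(sum(r[free]^2))
      history <- c(history, rnorm)
      # displacement-controlled steps have no external load; scale the
      # residual by the constraint reactions instead
      ref <- max(fac * fnorm, sqrt(sum(f_int[bc$fixed]^2)), 1e-12)
      if (rnorm <= tol * ref) break
      if (rnorm > prev) {
        grew <- grew + 1L
        if (grew >= 2L) {
          cond <- simpleError(paste0("Newton diverged at substep ", s,
                                     " (residual ", signif(rnorm, 4), ")"))
          cond$residual_history <- history
          stop(cond)
        }
      } else grew <- 0L
      prev <- rnorm
      Kt <- K0 + Kc + mr$K
      Kt <- Matrix::forceSymmetric((Kt + Matrix::t(Kt)) / 2)
      ch <- factor_or_diagnose(Kt[free, free, drop = FALSE], mesh, free)
      u[free] <- u[free] + as.vector(Matrix::solve(ch, r[free]))
      if (it == max_iter) {
        cond <- simpleError(paste0("Newton failed to converge in ", max_iter,
                                   " iterations at substep ", s))
        cond$residual_history <- history
        stop(cond)
      }
    }
  }
  Kc <- assemble_cartilage_stiffness(mesh, materials, u)
  mr <- mr_force_tangent(mesh, materials, u, want_tangent = FALSE)
  f_int <- as.vector(K0 %*% u) + as.vector(Kc %*% u) + mr$f
  reactions <- f_int - f_ext
  reactions[free] <- 0
  sol <- postprocess_solution(u, mesh, materials, f_ext, reactions)
  sol$residual_history <- history
  sol
}

#' Solve a static model, choosing the linear or Newton path
#'
#' Uses the direct linear path when every element family is linear (including
#' cartilage elements pinned at their floor modulus would not be, so any
#' `cartilage` or `mooney_rivlin` family triggers the Newton path).
#'
#' @inheritParams solve_newton
#' @param ... passed to [solve_newton].
#' @return an `fe_solution`.
#' @export
fe_solve <- function(mesh, materials, bcs, loads, ...) {
  nonlinear <- any(materials$tets$family %in% c("cartilage", "mooney_rivlin"))
  if (nonlinear) {
    solve_newton(mesh, materials, bcs, loads, ...)
  } else {
    solve_linear(fe_assemble(mesh, materials, bcs), loads)
  }
}

# Build the fe_solution object: per-element tensors, scalar summaries.
postprocess_solution <- function(u, mesh, materials, f_ext, reactions) {
  U <- matrix(u, ncol = 3L, byrow = TRUE)
  ntet <- nrow(mesh$tets)
  strain <- vector("list", ntet); stress <- vector("list", ntet)
  vm <- numeric(ntet); eqs <- numeric(ntet)
  fam <- materials$tets$family
  for (e in seq_len(ntet)) {
    conn <- mesh$tets[e, ]
    g <- tet_gradients(mesh$nodes[conn, , drop = FALSE])
    H <- t(U[conn, , drop = FALSE]) %*% t(g$G)
    eps <- (H + t(H)) / 2
    if (fam[e] == "mooney_rivlin") {
      F_ <- diag(3) + H
      sig <- mr_cauchy_stress(F_, materials$mooney_rivlin)
      nu_eff <- materials$mooney_rivlin$nu
    } else if (fam[e] == "cartilage") {
      Ee <- max(cartilage_modulus(sum(diag(eps)), materials$cartilage),
                materials$cartilage$E_min)
      nu_eff <- materials$mooney_rivlin$nu
      sig <- linear_stress(eps, linear_elastic(Ee, nu_eff))
    } else {
      nu_eff <- materials$tets$nu[e]
      sig <- linear_stress(eps, linear_elastic(materials$tets$E[e], nu_eff))
    }
    strain[[e]] <- eps; stress[[e]] <- sig
    vm[e] <- von_mises(sig)
    eqs[e] <- equivalent_strain(eps, nu_eff)
  }
  ntri <- nrow(mesh$tris)
  tri_vm <- numeric(ntri); tri_eqs <- numeric(ntri)
  tri_stress <- vector("list", ntri)
  if (ntri) for (e in seq_len(ntri)) {
    conn <- mesh$tris[e, ]
    tm <- tri_membrane(mesh$nodes[conn, , drop = FALSE])
    ul <- as.vector(tm$T %*% as.vector(t(U[conn, , drop = FALSE])))
    epsl <- as.vector(tm$B %*% ul)       # xx, yy, gamma_xy (local plane)
    Dps <- plane_stress_D(materials$membranes$E[e], materials$membranes$nu[e])
    sigl <- as.vector(Dps %*% epsl)
    sig3 <- matrix(0, 3, 3)
    sig3[1, 1] <- sigl[1]; sig3[2, 2] <- sigl[2]
    sig3[1, 2] <- sig3[2, 1] <- sigl[3]
    eps3 <- matrix(0, 3, 3)
    nu_m <- materials$membranes$nu[e]
    eps3[1, 1] <- epsl[1]; eps3[2, 2] <- epsl[2]
    eps3[1, 2] <- eps3[2, 1] <- epsl[3] / 2
    eps3[3, 3] <- -nu_m / (1 - nu_m) * (epsl[1] + epsl[2])  # plane-stress thickness strain
    tri_stress[[e]] <- sig3
    tri_vm[e] <- von_mises(sig3)
    tri_eqs[e] <- equivalent_strain(eps3, nu_m)
  }
  structure(list(u = U, tet_strain = strain, tet_stress = stress,
                 tet_vm = vm, tet_eq_strain = eqs,
                 tri_stress = tri_stress, tri_vm = tri_vm,
                 tri_eq_strain = tri_eqs,
                 f_ext = f_ext, reactions = reactions,
                 mesh = mesh, materials = materials),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  s <- postprocess(x)
  cat("<fe_solution> max |u| = ", signif(max(abs(x$u)), 4), " mm, max von Mises = ",
      signif(s$summaries$max_vm[s$summaries$subset == "all"], 4), " MPa\n", sep = "")
  invisible(x)
}

#' Scalar summaries of a solved field
#'
#' Maximum and mean von Mises stress and equivalent elastic strain, computed
#' over (a) all elements (tets and membranes) and (b) the bone-only subset
#' (cortical, cancellous, femur and lumbar regions plus the cortical
#' membranes), both reported because the averaging population is a genuine
#' modelling choice.
#'
#' @param solution an `fe_solution`.
#' @return a list with `summaries` (tibble: subset, max/mean von Mises and
#'   equivalent strain) and `element_table` (per-element scalars).
#' @export
postprocess <- function(solution) {
  mesh <- solution$mesh
  et <- tibble::tibble(
    elem_type = c(rep("tet", nrow(mesh$tets)), rep("tri", nrow(mesh$tris))),
    element = c(seq_len(nrow(mesh$tets)), seq_len(nrow(mesh$tris))),
    region = c(mesh$element_region, mesh$tri_region),
    von_mises = c(solution$tet_vm, solution$tri_vm),
    eq_strain = c(solution$tet_eq_strain, solution$tri_eq_strain))
  bone_regions <- c("cortical", "cancellous", "femur", "lumbar")
  subsets <- list(all = rep(TRUE, nrow(et)),
                  bone = et$region %in% bone_regions)
  summaries <- do.call(rbind, lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]]
    tibble::tibble(subset = nm,
                   max_vm = max(et$von_mises[sel]),
                   mean_vm = mean(et$von_mises[sel]),
                   max_eq_strain = max(et$eq_strain[sel]),
                   mean_eq_strain = mean(et$eq_strain[sel]))
  }))
  list(summaries = summaries, element_table = et)
}
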