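#' Constants of the CT-to-material mapping
#'
#' Collects the published calibration used to turn CT intensities into bone
#' material properties.  Density follows a piecewise-linear fit in Hounsfield
#' units with a break at `hu_threshold`:
#' `rho = a1 * Hu + b1` below the break and `rho = a2 * Hu + b2` at or above
#' it (g/cm^3).  Young's modulus of cancellous bone follows the power law
#' `E = c * rho^p` (MPa).  Cortical bone is carried separately as a thin
#' stiff shell with fixed modulus, Poisson ratio and thickness.
#'
#' `rho_floor` guards the power law against the non-physical near-zero or
#' negative densities the linear fit yields for air and fat voxels.
#'
#' @param a1,b1 slope (g/cm^3 per HU) and intercept (g/cm^3) below the break.
#' @param a2,b2 slope and intercept at or above the break.
#' @param hu_threshold break point of the piecewise density fit (HU).
#' @param c,p coefficient (MPa) and exponent of the density-modulus power law.
#' @param cortical_E cortical Young's modulus in MPa (17 GPa default).
#' @param cortical_nu cortical Poisson ratio.
#' @param cortical_thickness cortical shell thickness in mm.
#' @param cancellous_nu Poisson ratio assigned to density-mapped elements.
#' @param rho_floor lower bound on mapped density (g/cm^3), > 0.
#' @return object of class `mapping_constants`.
#' @export
mapping_constants <- function(a1 = 1.9e-3, b1 = 0.105,
                              a2 = 7.69e-4, b2 = 1.028,
                              hu_threshold = 816,
                              c = 2017.3, p = 2.46,
                              cortical_E = 17000, cortical_nu = 0.26,
                              cortical_thickness = 1.41,
                              cancellous_nu = 0.2,
                              rho_floor = 0.05) {
  stopifnot(c > 0, p > 0, cortical_thickness > 0, rho_floor > 0,
            cortical_E > 0, cancellous_nu > -1, cancellous_nu < 0.5)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 hu_threshold = hu_threshold, c = c, p = p,
                 cortical_E = cortical_E, cortical_nu = cortical_nu,
                 cortical_thickness = cortical_thickness,
                 cancellous_nu = cancellous_nu, rho_floor = rho_floor),
            class = "mapping_constants")
}

#' Map Hounsfield units to bone density
#'
#' Piecewise-linear calibration from CT intensity to apparent bone density,
#' floored at `k$rho_floor` so downstream moduli stay physical.  The mapping
#' is monotone non-decreasing in HU; the two published branches disagree by
#' about 1e-4 g/cm^3 at the break, which is kept as printed.
#'
#' @param hu numeric vector of CT intensities (HU); any real value accepted.
#' @param k a [mapping_constants] object.
#' @return densities in g/cm^3, same length as `hu`.
#' @export
hu_to_density <- function(hu, k = mapping_constants()) {
  rho <- ifelse(hu < k$hu_threshold, k$a1 * hu + k$b1, k$a2 * hu + k$b2)
  pmax(rho, k$rho_floor)
}

#' Map bone density to Young's modulus
#'
#' Power law `E = c * rho^p` giving cancellous modulus in MPa from apparent
#' density in g/cm^3; strictly increasing in density.
#'
#' @param rho densities in g/cm^3, all > 0.
#' @param k a [mapping_constants] object.
#' @return Young's moduli in MPa.
#' @export
density_to_modulus <- function(rho, k = mapping_constants()) {
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("density must be finite and > 0 (apply the density floor upstream)")
  k$c * rho^k$p
}

#' Assign per-element material properties from a CT volume
#'
#' Cancellous-labelled tetrahedra receive a Young's modulus mapped from the
#' mean HU of the voxel centres falling inside the element (falling back to
#' the HU of the voxel containing the element centroid when the element is
#' smaller than a voxel), with the cancellous Poisson ratio.  Cortical
#' elements and all membrane triangles receive the fixed cortical constants.
#' `femur`- and `lumbar`-labelled stub elements are treated as dense bone and
#' also receive the cortical constants.  Cartilage-labelled elements are left
#' to the constitutive layer: they are emitted with family `"cartilage"` and
#' no modulus, to be resolved by the run configuration (strain-dependent
#' compressive modulus or Mooney-Rivlin).
#'
#' Elements lying wholly outside the volume are mapped at the density floor
#' and counted in the `outside_elements` attribute of the result.
#'
#' @param mesh an [fe_mesh] with `element_region` labels.
#' @param vol a [voxel_volume] of HU.
#' @param k a [mapping_constants] object.
#' @param cartilage_family constitutive family for cartilage elements
#'   (see [material_field]).
#' @param cartilage parameters of the compressive secant model.
#' @param mooney_rivlin parameters of the hyperelastic model.
#' @return a [material_field] (tibble of per-element material cards).
#' @export
assign_materials <- function(mesh, vol, k = mapping_constants(),
                             cartilage_family = "mooney_rivlin",
                             cartilage = cartilage_compressive(),
                             mooney_rivlin = mooney_rivlin3()) {
  mb <- apply(mesh$nodes, 2L, range)
  vb <- rbind(vol$origin, vol$origin + vol$shape * vol$spacing)
  if (any((mb[2L, ] - mb[1L, ]) > 10 * (vb[2L, ] - vb[1L, ])))
    stop("mesh bounding box exceeds 10x the volume extent: ",
         "likely a unit mismatch between mesh (mm) and volume")

  region <- mesh$element_region
  ntet <- nrow(mesh$tets)
  E <- rep(NA_real_, ntet); nu <- rep(NA_real_, ntet)
  rho <- rep(NA_real_, ntet)
  family <- rep("linear", ntet)
  outside <- 0L

  cance <- which(region == "cancellous")
  if (length(cance)) {
    hu_mean <- sample_hu_in_tets(mesh, vol, cance)
    outside <- attr(hu_mean, "outside")
    r <- hu_to_density(hu_mean, k)
    r[is.na(hu_mean)] <- k$rho_floor
    rho[cance] <- r
    E[cance] <- density_to_modulus(r, k)
    nu[cance] <- k$cancellous_nu
  }
  cort <- which(region %in% c("cortical", "femur", "lumbar"))
  E[cort] <- k$cortical_E
  nu[cort] <- k$cortical_nu
  cart <- grepl("^cartilage", region)
  family[cart] <- "cartilage"

  material_field(
    tets = tibble::tibble(
      element = seq_len(ntet), label = region, family = family,
      rho = rho, E = E, nu = nu),
    membranes = tibble::tibble(
      element = seq_len(nrow(mesh$tris)),
      E = rep(k$cortical_E, nrow(mesh$tris)),
      nu = rep(k$cortical_nu, nrow(mesh$tris))),
    constants = k, cartilage = cartilage, mooney_rivlin = mooney_rivlin,
    cartilage_family = cartilage_family,
    outside_elements = outside)
}

#' Per-element material cards
#'
#' @param tets tibble with columns element, label, family, rho, E, nu.
#' @param membranes tibble with columns element, E, nu.
#' @param constants the [mapping_constants] used.
#' @param cartilage a [cartilage_compressive] parameter set.
#' @param mooney_rivlin a [mooney_rivlin3] parameter set.
#' @param cartilage_family `"mooney_rivlin"` (default, hyperelastic joint
#'   cartilage) or `"cartilage"` (strain-dependent compressive secant
#'   modulus) — which constitutive family cartilage-labelled elements use.
#' @param outside_elements count of elements that fell outside the CT volume.
#' @return object of class `material_field`.
#' @export
material_field <- function(tets, membranes = NULL,
                           constants = mapping_constants(),
                           cartilage = cartilage_compressive(),
                           mooney_rivlin = mooney_rivlin3(),
                           cartilage_family = "mooney_rivlin",
                           outside_elements = 0L) {
  stopifnot(cartilage_family %in% c("mooney_rivlin", "cartilage"))
  tets <- tibble::as_tibble(tets)
  fam <- tets$family
  fam[fam == "cartilage"] <- cartilage_family
  tets$family <- fam
  if (is.null(membranes))
    membranes <- tibble::tibble(element = integer(), E = double(), nu = double())
  structure(list(tets = tets, membranes = tibble::as_tibble(membranes),
                 constants = constants, cartilage = cartilage,
                 mooney_rivlin = mooney_rivlin,
                 cartilage_family = cartilage_family,
                 outside_elements = outside_elements),
            class = "material_field")
}

#' @export
print.material_field <- function(x, ...) {
  cat("<material_field> ", nrow(x$tets), " tets (",
      paste(sprintf("%s: %d", names(table(x$tets$family)),
                    as.integer(table(x$tets$family))), collapse = ", "),
      "), ", nrow(x$membranes), " membranes\n", sep = "")
  invisible(x)
}

# Mean HU of voxel centres inside each listed tet.  Barycentric containment
# with inclusive boundaries (tolerance 1e-12 on unit-scaled coordinates);
# centroid-voxel fallback for sub-voxel elements; NA (plus a tally) for
# elements wholly outside the volume.
sample_hu_in_tets <- function(mesh, vol, elems) {
  cx <- voxel_centers(vol, 1L); cy <- voxel_centers(vol, 2L)
  cz <- voxel_centers(vol, 3L)
  out <- rep(NA_real_, length(elems))
  outside <- 0L
  for (i in seq_along(elems)) {
    e <- elems[i]
    X <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    ix <- which(cx >= min(X[, 1L]) - 1e-12 & cx <= max(X[, 1L]) + 1e-12)
    iy <- which(cy >= min(X[, 2L]) - 1e-12 & cy <= max(X[, 2L]) + 1e-12)
    iz <- which(cz >= min(X[, 3L]) - 1e-12 & cz <= max(X[, 3L]) + 1e-12)
    hu <- NA_real_
    if (length(ix) && length(iy) && length(iz)) {
      pts <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz],
                                   KEEP.OUT.ATTRS = FALSE))
      inside <- points_in_tet(pts, X)
      if (any(inside)) {
        idx <- as.matrix(expand.grid(i = ix, j = iy, k = iz,
                                     KEEP.OUT.ATTRS = FALSE))[inside, , drop = FALSE]
        hu <- mean(vol$values[idx])
      }
    }
    if (is.na(hu)) {
      # centroid fallback: HU of the voxel containing the element centroid
      cen <- colMeans(X)
      v <- floor((cen - vol$origin) / vol$spacing) + 1
      if (all(v >= 1) && all(v <= vol$shape)) {
        hu <- vol$values[v[1L], v[2L], v[3L]]
      } else {
        outside <- outside + 1L
      }
    }
    out[i] <- hu
  }
  structure(out, outside = outside)
}

# Vectorised point-in-tetrahedron test via barycentric coordinates,
# inclusive on boundaries (ties broken toward inclusion).
points_in_tet <- function(pts, X, tol = 1e-12) {
  M <- t(X[2:4, , drop = FALSE]) - X[1L, ]
  rel <- sweep(pts, 2L, X[1L, ])
  lam <- t(solve(M, t(rel)))             # barycentric 2..4
  l1 <- 1 - rowSums(lam)
  lam[, 1L] >= -tol & lam[, 2L] >= -tol & lam[, 3L] >= -tol & l1 >= -tol
}
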