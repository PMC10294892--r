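#' Linear elastic material
#'
#' @param E Young's modulus in MPa.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return object of class `linear_elastic`.
#' @export
linear_elastic <- function(E, nu) {
  stopifnot(is.finite(E), E > 0, is.finite(nu), nu > -1, nu < 0.5)
  structure(list(E = E, nu = nu), class = "linear_elastic")
}

#' Strain-dependent compressive cartilage modulus parameters
#'
#' Articular cartilage carries load only in compression; its secant Young's
#' modulus follows the quadratic fit `E = a*eps + b*eps^2` for compressive
#' strain (`eps < 0`) and vanishes in tension.  Taken literally the quadratic
#' is negative for small compressive strains (between about -0.0862 and 0),
#' which would make a stiffness matrix indefinite, so the value is clamped
#' from below at `E_min`.
#'
#' @param a linear coefficient in MPa (per unit strain).
#' @param b quadratic coefficient in MPa.
#' @param E_min positive floor on the returned modulus in MPa.
#' @param rectified if `TRUE`, evaluate the fit as `a*|eps| + b*eps^2` for
#'   compressive strain (an alternative reading of the published quadratic
#'   in which both terms stiffen with compression); default `FALSE` keeps
#'   the literal signed form.
#' @return object of class `cartilage_compressive`.
#' @export
cartilage_compressive <- function(a = 20.17, b = 234, E_min = 0.5,
                                  rectified = FALSE) {
  stopifnot(E_min > 0)
  structure(list(a = a, b = b, E_min = E_min, rectified = isTRUE(rectified)),
            class = "cartilage_compressive")
}

#' Three-parameter Mooney-Rivlin hyperelastic material
#'
#' Strain-energy density
#' `W = C10*(I1b - 3) + C01*(I2b - 3) + C11*(I1b - 3)*(I2b - 3) + (J - 1)^2 / D1`
#' with `I1b`, `I2b` the isochoric invariants of the right Cauchy-Green tensor
#' and `J = det F`.  The published parameter set specifies a Poisson ratio but
#' no bulk term; the volumetric penalty `D1` is derived from `nu` and the
#' initial shear modulus `mu0 = 2*(C10 + C01)` via
#' `K0 = 2*mu0*(1 + nu) / (3*(1 - 2*nu))`, `D1 = 2/K0`.
#'
#' @param C10,C01,C11 material coefficients in MPa.
#' @param nu Poisson ratio in [0, 0.5).
#' @return object of class `mooney_rivlin3` with derived `mu0`, `K0`, `D1`.
#' @export
mooney_rivlin3 <- function(C10 = 0.1, C01 = 0.45, C11 = 1.67, nu = 0.2) {
  stopifnot(C10 + C01 > 0, nu >= 0, nu < 0.5)
  mu0 <- 2 * (C10 + C01)
  K0 <- 2 * mu0 * (1 + nu) / (3 * (1 - 2 * nu))
  structure(list(C10 = C10, C01 = C01, C11 = C11, nu = nu,
                 mu0 = mu0, K0 = K0, D1 = 2 / K0),
            class = "mooney_rivlin3")
}

#' Compressive secant modulus of cartilage
#'
#' Zero in tension (`strain >= 0`); the quadratic fit, floored at `m$E_min`,
#' in compression.
#'
#' @param strain volumetric/axial strain, dimensionless (negative = compression).
#' @param m a [cartilage_compressive] parameter set.
#' @return secant Young's modulus in MPa, same length as `strain`.
#' @export
cartilage_modulus <- function(strain, m = cartilage_compressive()) {
  lin <- if (m$rectified) m$a * abs(strain) else m$a * strain
  raw <- lin + m$b * strain^2
  ifelse(strain >= 0, 0, pmax(raw, m$E_min))
}

# Invariants helper: returns list(I1b, I2b, J, C, Cinv) for a deformation
# gradient F (3x3, det > 0).
mr_invariants <- function(F_) {
  J <- det(F_)
  if (!is.finite(J) || J <= 0) stop("deformation gradient must have det F > 0")
  C <- crossprod(F_)                     # F^T F
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  list(I1b = J^(-2 / 3) * I1, I2b = J^(-4 / 3) * I2, J = J,
       C = C, Cinv = solve(C), I1 = I1, I2 = I2)
}

#' Mooney-Rivlin strain-energy density
#'
#' @param F_ deformation gradient, 3x3 matrix with `det(F_) > 0`.
#' @param m a [mooney_rivlin3] object.
#' @return energy density in MPa.
#' @export
mr_strain_energy <- function(F_, m = mooney_rivlin3()) {
  iv <- mr_invariants(F_)
  m$C10 * (iv$I1b - 3) + m$C01 * (iv$I2b - 3) +
    m$C11 * (iv$I1b - 3) * (iv$I2b - 3) + (iv$J - 1)^2 / m$D1
}

# Second Piola-Kirchhoff stress S = 2 dW/dC for the decoupled Mooney-Rivlin
# energy; exact closed form.
mr_pk2_stress <- function(F_, m = mooney_rivlin3()) {
  iv <- mr_invariants(F_)
  W1 <- m$C10 + m$C11 * (iv$I2b - 3)     # dW/dI1b
  W2 <- m$C01 + m$C11 * (iv$I1b - 3)     # dW/dI2b
  I3 <- diag(3)
  dI1b <- iv$J^(-2 / 3) * (I3 - (iv$I1 / 3) * iv$Cinv)
  dI2b <- iv$J^(-4 / 3) * (iv$I1 * I3 - iv$C - (2 * iv$I2 / 3) * iv$Cinv)
  Svol <- (2 * iv$J * (iv$J - 1) / m$D1) * iv$Cinv
  2 * (W1 * dI1b + W2 * dI2b) + Svol
}

# First Piola-Kirchhoff stress P = F S.
mr_first_piola <- function(F_, m = mooney_rivlin3()) F_ %*% mr_pk2_stress(F_, m)

#' Mooney-Rivlin Cauchy stress
#'
#' Exact push-forward `sigma = (1/J) F S F^T` of the closed-form second
#' Piola-Kirchhoff stress of the decoupled three-parameter energy.
#'
#' @inheritParams mr_strain_energy
#' @return symmetric 3x3 Cauchy stress tensor in MPa.
#' @export
mr_cauchy_stress <- function(F_, m = mooney_rivlin3()) {
  S <- mr_pk2_stress(F_, m)
  sig <- F_ %*% S %*% t(F_) / det(F_)
  (sig + t(sig)) / 2
}

#' Isotropic linear-elastic (Hooke) stress
#'
#' @param strain symmetric 3x3 small-strain tensor.
#' @param m a [linear_elastic] material.
#' @return symmetric 3x3 stress tensor in MPa.
#' @export
linear_stress <- function(strain, m) {
  lam <- m$E * m$nu / ((1 + m$nu) * (1 - 2 * m$nu))
  mu <- m$E / (2 * (1 + m$nu))
  lam * sum(diag(strain)) * diag(3) + 2 * mu * strain
}

#' Von Mises equivalent stress
#'
#' @param stress symmetric 3x3 stress tensor (MPa).
#' @return scalar von Mises stress in MPa.
#' @export
von_mises <- function(stress) {
  s <- stress - mean(diag(stress)) * diag(3)
  sqrt(1.5 * sum(s * s))
}

#' Equivalent elastic strain
#'
#' The scalar strain summary conventional in FE postprocessing:
#' `eps_eq = sqrt(((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2) / 2) / (1 + nu_eff)`
#' over the principal strains, with the element material's effective Poisson
#' ratio.
#'
#' @param strain symmetric 3x3 strain tensor.
#' @param nu_eff effective Poisson ratio of the element's material.
#' @return scalar equivalent strain (dimensionless).
#' @export
equivalent_strain <- function(strain, nu_eff) {
  e <- eigen((strain + t(strain)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(((e[1L] - e[2L])^2 + (e[2L] - e[3L])^2 + (e[3L] - e[1L])^2) / 2) /
    (1 + nu_eff)
}

# 6x6 isotropic elasticity matrix (Voigt order xx, yy, zz, xy, yz, zx;
# engineering shear strains).
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# 3x3 plane-stress elasticity matrix (xx, yy, xy with engineering shear).
plane_stress_D <- function(E, nu) {
  E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
}
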