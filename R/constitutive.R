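#' Deformation state at a material point
#'
#' Bundles a deformation gradient \code{F} and a reference fiber direction
#' \code{N} with the derived quantities used by the isochoric (volume-split)
#' constitutive models: the volume ratio \eqn{J = \det F}, the first
#' invariant \eqn{\bar{I}_1 = \mathrm{tr}(J^{-2/3} F^T F)} of the modified
#' right Cauchy--Green tensor, and the isochoric fiber stretch
#' \eqn{\bar{\lambda}_f = J^{-1/3} |F N|}.
#'
#' @param F 3x3 deformation gradient (dimensionless), \code{det(F) > 0}.
#' @param N unit reference fiber direction (length-3 numeric).
#' @return An object of class \code{"deformation_state"}: a list with
#'   elements \code{F}, \code{N}, \code{J}, \code{Ibar1}, \code{lambdabar_f}.
#' @examples
#' st <- deformation_state(diag(3), c(1, 0, 0))
#' st$Ibar1        # 3 at the reference state
#' @export
deformation_state <- function(F, N = c(1, 0, 0)) {
  F <- as.matrix(F)
  stopifnot(is.numeric(F), identical(dim(F), c(3L, 3L)), all(is.finite(F)))
  N <- as.numeric(N)
  stopifnot(length(N) == 3, all(is.finite(N)))
  J <- det(F)
  if (J <= 0) {
    stop("invalid deformation: det(F) must be positive, got ", format(J))
  }
  nrm <- sqrt(sum(N^2))
  if (abs(nrm - 1) > 1e-8) {
    stop("fiber direction N must be a unit vector (|N| = ", format(nrm), ")")
  }
  N <- N / nrm
  C <- crossprod(F)                      # F^T F
  Ibar1 <- J^(-2 / 3) * sum(diag(C))
  lambdabar_f <- J^(-1 / 3) * sqrt(sum((F %*% N)^2))
  structure(
    list(F = F, N = N, J = J, Ibar1 = Ibar1, lambdabar_f = lambdabar_f),
    class = "deformation_state"
  )
}

#' @rdname deformation_state
#' @param x,... show method arguments.
#' @export
print.deformation_state <- function(x, ...) {
  cat("<deformation_state>  J =", format(x$J, digits = 6),
      " Ibar1 =", format(x$Ibar1, digits = 6),
      " lambdabar_f =", format(x$lambdabar_f, digits = 6), "\n")
  invisible(x)
}

#' Compute isochoric invariants from a deformation gradient
#'
#' Convenience wrapper around [deformation_state()].
#'
#' @inheritParams deformation_state
#' @return A \code{"deformation_state"} object.
#' @export
compute_invariants <- function(F, N = c(1, 0, 0)) deformation_state(F, N)

#' Constitutive parameters of the transversely isotropic muscle model
#'
#' The strain energy is \eqn{U = U_m + U_f + U_J} with an exponential
#' isotropic matrix \eqn{U_m = c\{e^{b(\bar{I}_1 - 3)} - 1\}}, a fiber part
#' \eqn{U_f = A\{e^{a(\bar{\lambda}_f-1)^2} - 1\} + \theta T_0^M
#' [(\bar{\lambda}_f-1) - \tfrac{4}{3}(\bar{\lambda}_f-1)^3]} (passive +
#' active), and a volumetric penalty \eqn{U_J = (1/D)(J-1)^2}.
#'
#' Defaults are the pelvic-floor-muscle values used throughout:
#' c = 0.0185 MPa, b = 1.1730, A = 0.0280 MPa, a = 0.6215. The activation
#' level defaults to \code{theta = 0} (passive tissue), so the active term
#' and \code{T0M} are inert unless activation is switched on. The volumetric
#' stiffness defaults to 1/D = 10 MPa, roughly 200x the matrix shear modulus
#' 2cb, i.e. near-incompressible.
#'
#' Either \code{c} or \code{A} (but not both) may be zero, which yields a
#' matrix-only or fiber-only material; that degenerate form is used by the
#' relaxation test drivers.
#'
#' @param c,b matrix parameters (MPa, dimensionless).
#' @param A,a passive fiber parameters (MPa, dimensionless).
#' @param T0M maximum active muscle tension (MPa).
#' @param theta activation level in \[0, 1\].
#' @param D volumetric penalty constant (1/MPa); the penalty stiffness is 1/D.
#' @return Object of class \code{"martins_params"}.
#' @export
martins_params <- function(c = 0.0185, b = 1.1730, A = 0.0280, a = 0.6215,
                           T0M = 0.682, theta = 0, D = 0.1) {
  stopifnot(c >= 0, A >= 0, c + A > 0, b > 0, a > 0, D > 0,
            T0M >= 0, theta >= 0, theta <= 1)
  structure(list(c = c, b = b, A = A, a = a, T0M = T0M, theta = theta, D = D),
            class = "martins_params")
}

#' Linear elastic parameters
#'
#' @param E Young's modulus (in the unit given by \code{unit}).
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @param unit unit of \code{E}, recorded for bookkeeping ("kPa" or "MPa").
#' @return Object of class \code{"linear_elastic_params"}.
#' @export
linear_elastic_params <- function(E, nu, unit = "MPa") {
  stopifnot(E > 0, nu > -1, nu < 0.5, unit %in% c("kPa", "MPa"))
  structure(list(E = E, nu = nu, unit = unit), class = "linear_elastic_params")
}

#' Neo-Hookean parameters
#'
#' Energy \eqn{U = c_{10}(\bar{I}_1 - 3) + (1/D)(J-1)^2}.
#'
#' @param c10 material constant (MPa).
#' @param D volumetric penalty constant (1/MPa).
#' @return Object of class \code{"neo_hookean_params"}.
#' @export
neo_hookean_params <- function(c10 = 0.1, D = 0.1) {
  stopifnot(c10 > 0, D > 0)
  structure(list(c10 = c10, D = D), class = "neo_hookean_params")
}

# deviatoric part of a 3x3 tensor
dev3 <- function(M) M - diag(sum(diag(M)) / 3, 3)

# energy-derivative pair for the Martins model at a state:
# dU/dIbar1 and dU/dlambdabar_f (fiber passive + active)
martins_derivs <- function(state, p) {
  dU_dI1 <- p$c * p$b * exp(p$b * (state$Ibar1 - 3))
  e <- state$lambdabar_f - 1
  dU_dlf <- 2 * p$A * p$a * e * exp(p$a * e^2) +
    p$theta * p$T0M * (1 - 4 * e^2)
  list(dU_dI1 = dU_dI1, dU_dlf = dU_dlf)
}

#' Strain energy density of the transversely isotropic muscle model
#'
#' @param state a [deformation_state()].
#' @param p a [martins_params()] set.
#' @param parts if \code{TRUE}, return the named breakdown
#'   \code{c(Um, UfPE, UfSE, UJ)} instead of the total.
#' @return Energy density in MPa.
#' @examples
#' p <- martins_params()
#' lam <- 1.1
#' st <- deformation_state(diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))))
#' martins_energy(st, p, parts = TRUE)
#' @export
martins_energy <- function(state, p, parts = FALSE) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(p, "martins_params"))
  Um <- p$c * (exp(p$b * (state$Ibar1 - 3)) - 1)
  e <- state$lambdabar_f - 1
  UfPE <- p$A * (exp(p$a * e^2) - 1)
  # closed form of the active integral int_1^lf [-4(x-1)^2 + 1] dx
  UfSE <- p$theta * p$T0M * (e - (4 / 3) * e^3)
  UJ <- (1 / p$D) * (state$J - 1)^2
  if (parts) c(Um = Um, UfPE = UfPE, UfSE = UfSE, UJ = UJ)
  else Um + UfPE + UfSE + UJ
}

#' Neo-Hookean strain energy density
#'
#' @inheritParams martins_energy
#' @param p a [neo_hookean_params()] set.
#' @return Energy density in MPa.
#' @export
neo_hookean_energy <- function(state, p) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(p, "neo_hookean_params"))
  p$c10 * (state$Ibar1 - 3) + (1 / p$D) * (state$J - 1)^2
}

# Cauchy stress from isochoric energy derivatives + volumetric penalty:
#   sigma = (2/J) W1 dev(bbar) + (1/J) Wl lf dev(m x m) + (2/D)(J-1) I
# with bbar = J^{-2/3} F F^T and m the unit spatial fiber direction.
iso_cauchy <- function(state, dU_dI1, dU_dlf, D) {
  F <- state$F
  J <- state$J
  bbar <- J^(-2 / 3) * tcrossprod(F)
  sig <- (2 / J) * dU_dI1 * dev3(bbar)
  if (dU_dlf != 0) {
    m <- as.numeric(F %*% state$N)
    m <- m / sqrt(sum(m^2))
    sig <- sig + (1 / J) * dU_dlf * state$lambdabar_f * dev3(tcrossprod(m))
  }
  sig + diag((2 / D) * (J - 1), 3)
}

is_uniaxial_state <- function(state, tol = 1e-9) {
  F <- state$F
  lam <- F[1, 1]
  off <- F; diag(off) <- 0
  lam > 0 &&
    max(abs(off)) < tol &&
    abs(F[2, 2] - 1 / sqrt(lam)) < tol &&
    abs(F[3, 3] - 1 / sqrt(lam)) < tol &&
    max(abs(state$N - c(1, 0, 0))) < tol
}

#' Cauchy stress of the transversely isotropic muscle model
#'
#' In \code{mode = "general"} the full symmetric Cauchy stress tensor is
#' returned, with the hydrostatic part supplied by the volumetric penalty
#' \eqn{(2/D)(J-1)}. In \code{mode = "uniaxial"} the state must be
#' incompressible uniaxial along the fiber axis,
#' \eqn{F = \mathrm{diag}(\lambda, \lambda^{-1/2}, \lambda^{-1/2})} with
#' \code{N = (1,0,0)}; the pressure is then eliminated analytically by the
#' traction-free lateral condition and the returned tensor has exactly zero
#' lateral components.
#'
#' @inheritParams martins_energy
#' @param mode \code{"general"} or \code{"uniaxial"} (convenience mode).
#' @return 3x3 symmetric Cauchy stress (MPa), with attribute
#'   \code{"axial"} in uniaxial mode.
#' @export
martins_cauchy_stress <- function(state, p, mode = c("general", "uniaxial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "deformation_state"),
            inherits(p, "martins_params"))
  d <- martins_derivs(state, p)
  if (mode == "general") {
    return(iso_cauchy(state, d$dU_dI1, d$dU_dlf, p$D))
  }
  if (!is_uniaxial_state(state)) {
    stop("uniaxial mode requires F = diag(lambda, lambda^-1/2, lambda^-1/2) ",
         "with the fiber along axis 1")
  }
  sig <- iso_cauchy(state, d$dU_dI1, d$dU_dlf, p$D)
  axial <- sig[1, 1] - sig[2, 2]          # lateral traction-free pressure
  out <- diag(c(axial, 0, 0))
  attr(out, "axial") <- axial
  out
}

#' Cauchy stress of the Neo-Hookean model
#'
#' Same conventions as [martins_cauchy_stress()]; the closed-form
#' incompressible uniaxial axial stress is \eqn{2 c_{10} (\lambda^2 -
#' 1/\lambda)}.
#'
#' @inheritParams martins_cauchy_stress
#' @param p a [neo_hookean_params()] set.
#' @export
neo_hookean_stress <- function(state, p, mode = c("general", "uniaxial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "deformation_state"),
            inherits(p, "neo_hookean_params"))
  if (mode == "general") {
    return(iso_cauchy(state, p$c10, 0, p$D))
  }
  if (!is_uniaxial_state(state)) {
    stop("uniaxial mode requires F = diag(lambda, lambda^-1/2, lambda^-1/2)")
  }
  sig <- iso_cauchy(state, p$c10, 0, p$D)
  axial <- sig[1, 1] - sig[2, 2]
  out <- diag(c(axial, 0, 0))
  attr(out, "axial") <- axial
  out
}

#' Uniaxial linear elastic stress
#'
#' Small-strain engineering convention \eqn{\sigma = E \varepsilon}, kept as
#' the one-dimensional law for ring segments modeled as linear elastic even
#' at large hiatal stretch (the constitutive description is deliberately as
#' simple as the tissue assignment it represents).
#'
#' @param engineering_strain scalar strain \eqn{\varepsilon = \lambda - 1},
#'   must exceed -1.
#' @param p a [linear_elastic_params()] set.
#' @return Stress in the same unit family as \code{p$E}.
#' @export
linear_elastic_stress <- function(engineering_strain, p) {
  stopifnot(inherits(p, "linear_elastic_params"),
            all(engineering_strain > -1))
  p$E * engineering_strain
}

#' Equilibrium uniaxial stress split for the muscle model
#'
#' Incompressible uniaxial stress along the fiber direction, split into the
#' isotropic-matrix and fiber contributions; the viscoelastic branches
#' shadow these two parts separately.
#'
#' @param lambda axial stretch (vectorised).
#' @param p a [martins_params()] set.
#' @return A list with numeric vectors \code{matrix} and \code{fiber} (MPa).
#' @export
uniaxial_stress_split <- function(lambda, p) {
  stopifnot(inherits(p, "martins_params"), all(lambda > 0))
  Ibar1 <- lambda^2 + 2 / lambda
  e <- lambda - 1
  W1 <- p$c * p$b * exp(p$b * (Ibar1 - 3))
  Wl <- 2 * p$A * p$a * e * exp(p$a * e^2) + p$theta * p$T0M * (1 - 4 * e^2)
  list(matrix = 2 * W1 * (lambda^2 - 1 / lambda), fiber = lambda * Wl)
}
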