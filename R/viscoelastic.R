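#' Generalized-Maxwell branch sets
#'
#' A branch set is a data.frame with columns \code{B} (dimensionless
#' stiffness ratio) and \code{tau} (relaxation time, s). Each branch is a
#' spring--dashpot (Maxwell) element in parallel with the long-term
#' hyperelastic response; the reduced relaxation function is
#' \eqn{g(t) = 1 + \sum_\alpha B_\alpha e^{-t/\tau_\alpha}}, so the
#' instantaneous stiffness is \eqn{(1 + \sum B)} times the equilibrium one.
#'
#' \code{matrix_branches()} and \code{fiber_branches()} return the default
#' pelvic-floor branch sets: matrix (B, tau) = (1.5, 20 s), (0.7, 400 s),
#' (0.5, 5000 s); fiber (1.2, 0.9 s), (0.5, 250 s), (0.3, 3500 s).
#'
#' @param B numeric vector of stiffness ratios, all > 0.
#' @param tau numeric vector of relaxation times (s), all > 0.
#' @return A data.frame of class \code{"maxwell_branches"}.
#' @export
maxwell_branches <- function(B, tau) {
  stopifnot(length(B) == length(tau), all(B > 0), all(tau > 0))
  structure(data.frame(B = as.numeric(B), tau = as.numeric(tau)),
            class = c("maxwell_branches", "data.frame"))
}

#' @rdname maxwell_branches
#' @export
matrix_branches <- function() maxwell_branches(B = c(1.5, 0.7, 0.5),
                                               tau = c(20, 400, 5000))

#' @rdname maxwell_branches
#' @export
fiber_branches <- function() maxwell_branches(B = c(1.2, 0.5, 0.3),
                                              tau = c(0.9, 250, 3500))

#' Reduced relaxation function g(t)
#'
#' \eqn{g(t) = 1 + \sum_\alpha B_\alpha e^{-t/\tau_\alpha}}: g(0) = 1 +
#' \eqn{\sum B}, monotonically decreasing, g(Inf) = 1.
#'
#' @param branches a [maxwell_branches()] set.
#' @param t time(s) in seconds, >= 0 (vectorised).
#' @return Dimensionless relaxation coefficient(s).
#' @examples
#' relaxation_coefficient(matrix_branches(), 0)    # 3.7
#' relaxation_coefficient(matrix_branches(), 60)   # 2.1712
#' @export
relaxation_coefficient <- function(branches, t) {
  stopifnot(inherits(branches, "maxwell_branches"))
  if (any(t < 0)) stop("relaxation time argument t must be non-negative")
  vapply(t, function(ti) 1 + sum(branches$B * exp(-ti / branches$tau)),
         numeric(1))
}

#' Internal overstress state of a generalized-Maxwell material
#'
#' Stress-like internal variables, one accumulator per branch, all zero at
#' t = 0. The accumulators have whatever shape the elastic stress they
#' shadow has (scalars for the uniaxial ring drivers).
#'
#' @param branches a [maxwell_branches()] set.
#' @param shape prototype of the shadowed stress (default scalar 0).
#' @return Object of class \code{"visco_state"}.
#' @export
visco_state <- function(branches, shape = 0) {
  stopifnot(inherits(branches, "maxwell_branches"))
  structure(
    list(H = lapply(seq_len(nrow(branches)), function(i) shape * 0),
         branches = branches, time = 0),
    class = "visco_state"
  )
}

#' One step of the viscoelastic overstress recurrence
#'
#' Exponential (Holzapfel-type) integrator on stress-like internal
#' variables: per branch,
#' \deqn{H_\alpha \leftarrow e^{-\Delta t/\tau_\alpha} H_\alpha +
#'   B_\alpha e^{-\Delta t/(2\tau_\alpha)} \Delta \bar{S},}
#' where \eqn{\Delta \bar{S}} is the increment of the equilibrium elastic
#' stress over the step. The midpoint factor makes the update second-order
#' accurate and exact for piecewise-constant stress rates. The total stress
#' is the equilibrium elastic stress plus \eqn{\sum_\alpha H_\alpha}.
#'
#' @param state a [visco_state()].
#' @param dS elastic stress increment over the step (same shape as the
#'   accumulators).
#' @param dt time step (s), >= 0.
#' @return Updated \code{"visco_state"} with element \code{overstress}
#'   attached as attribute \code{"overstress"} (sum over branches).
#' @export
update_overstress <- function(state, dS, dt) {
  stopifnot(inherits(state, "visco_state"))
  if (dt < 0) stop("dt must be non-negative")
  br <- state$branches
  for (i in seq_len(nrow(br))) {
    state$H[[i]] <- exp(-dt / br$tau[i]) * state$H[[i]] +
      br$B[i] * exp(-dt / (2 * br$tau[i])) * dS
  }
  state$time <- state$time + dt
  attr(state, "overstress") <- Reduce(`+`, state$H)
  state
}

#' Total overstress carried by a visco state
#'
#' @param state a [visco_state()].
#' @return Sum of the branch accumulators.
#' @export
total_overstress <- function(state) {
  stopifnot(inherits(state, "visco_state"))
  Reduce(`+`, state$H)
}

#' Step-relaxation test driver
#'
#' Applies an instantaneous stretch \code{lambda_hold} to a uniaxial,
#' incompressible muscle-model specimen at t = 0 and holds it, integrating
#' the matrix and fiber overstress recurrences on their respective
#' equilibrium stress contributions. The instantaneous-to-equilibrium
#' stress ratio equals the branch sum \eqn{1 + \sum B} of whichever branch
#' set shadows the (single) non-zero stress contribution.
#'
#' @param lambda_hold held stretch (> 0).
#' @param duration hold duration (s).
#' @param dt time step (s); values coarser than min(tau)/10 are accepted but
#'   flagged in the result's \code{dt_warning} attribute.
#' @param p a [martins_params()] set (use \code{A = 0} for a matrix-only
#'   specimen or \code{c = 0} for a fiber-only one).
#' @param branches_matrix,branches_fiber branch sets shadowing the matrix
#'   and fiber stress contributions; \code{NULL} disables a set.
#' @return data.frame with columns \code{time}, \code{stress} (MPa),
#'   \code{stress_matrix}, \code{stress_fiber}.
#' @examples
#' tr <- step_relaxation_test(1.2, duration = 100, dt = 1,
#'                            p = martins_params(A = 0),
#'                            branches_fiber = NULL)
#' tr$stress[1] / uniaxial_stress_split(1.2, martins_params(A = 0))$matrix
#' @export
step_relaxation_test <- function(lambda_hold, duration, dt = NULL,
                                 p = martins_params(),
                                 branches_matrix = matrix_branches(),
                                 branches_fiber = fiber_branches()) {
  stopifnot(lambda_hold > 0, duration > 0)
  taus <- c(if (!is.null(branches_matrix)) branches_matrix$tau,
            if (!is.null(branches_fiber)) branches_fiber$tau)
  if (length(taus) == 0) stop("at least one branch set is required")
  if (is.null(dt)) dt <- min(taus) / 10
  dt_warning <- dt > min(taus) / 10
  eq <- uniaxial_stress_split(lambda_hold, p)
  times <- seq(0, duration, by = dt)
  sm <- visco_state(if (is.null(branches_matrix)) maxwell_branches(1, 1)
                    else branches_matrix)
  sf <- visco_state(if (is.null(branches_fiber)) maxwell_branches(1, 1)
                    else branches_fiber)
  # instantaneous application: full elastic increment at dt = 0
  if (!is.null(branches_matrix)) sm <- update_overstress(sm, eq$matrix, 0)
  if (!is.null(branches_fiber)) sf <- update_overstress(sf, eq$fiber, 0)
  n <- length(times)
  over_m <- over_f <- numeric(n)
  over_m[1] <- if (is.null(branches_matrix)) 0 else total_overstress(sm)
  over_f[1] <- if (is.null(branches_fiber)) 0 else total_overstress(sf)
  for (k in seq_len(n - 1)) {
    if (!is.null(branches_matrix)) {
      sm <- update_overstress(sm, 0, dt)
      over_m[k + 1] <- total_overstress(sm)
    }
    if (!is.null(branches_fiber)) {
      sf <- update_overstress(sf, 0, dt)
      over_f[k + 1] <- total_overstress(sf)
    }
  }
  out <- data.frame(
    time = times,
    stress_matrix = eq$matrix + over_m,
    stress_fiber = eq$fiber + over_f
  )
  out$stress <- out$stress_matrix + out$stress_fiber
  attr(out, "dt_warning") <- dt_warning
  attr(out, "equilibrium") <- eq$matrix + eq$fiber
  out
}
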