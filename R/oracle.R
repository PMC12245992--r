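#' Numerical Cauchy stress by central differences of a strain energy
#'
#' Independent verification oracle for analytic stress implementations.
#' Differentiates an energy density \code{energy_fn(F)} component-wise with a
#' central-difference stencil to obtain the first Piola--Kirchhoff stress
#' \eqn{P_{ij} = \partial U / \partial F_{ij}} (truncation error
#' \eqn{O(\mathrm{step}^2)}), then pushes forward to Cauchy stress
#' \eqn{\sigma = J^{-1} P F^T}.
#'
#' @param energy_fn function of a 3x3 matrix returning a scalar energy
#'   density; must be finite on the stencil around \code{F}.
#' @param state a [deformation_state()]; only its \code{F} is used.
#' @param step finite-difference step, in \[1e-8, 1e-4\].
#' @return 3x3 Cauchy stress tensor.
#' @examples
#' p <- neo_hookean_params(c10 = 0.1)
#' lam <- 1.5
#' st <- deformation_state(diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))))
#' sig <- numerical_stress_oracle(
#'   function(F) neo_hookean_energy(deformation_state(F), p), st)
#' sig[1, 1] - sig[2, 2]  # 2 * c10 * (lam^2 - 1/lam)
#' @export
numerical_stress_oracle <- function(energy_fn, state, step = 1e-6) {
  stopifnot(is.function(energy_fn), inherits(state, "deformation_state"),
            step >= 1e-8, step <= 1e-4)
  F <- state$F
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + step
      Fm <- F; Fm[i, j] <- Fm[i, j] - step
      up <- energy_fn(Fp)
      um <- energy_fn(Fm)
      if (!is.finite(up) || !is.finite(um)) {
        stop("oracle-domain error: non-finite energy in the difference stencil")
      }
      P[i, j] <- (up - um) / (2 * step)
    }
  }
  (P %*% t(F)) / det(F)
}
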