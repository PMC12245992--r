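# shared fixtures, computed once per test run

# random well-conditioned isochoric deformation gradient
random_isochoric_F <- function(spread = 0.3) {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -spread, spread), 3)
    if (det(F) > 0.3) break
  }
  F / det(F)^(1 / 3)
}

# incompressible uniaxial state along the fiber axis
uniaxial_state <- function(lambda) {
  deformation_state(diag(c(lambda, 1 / sqrt(lambda), 1 / sqrt(lambda))),
                    c(1, 0, 0))
}

# the default 12-scenario sweep is used by several files; run it once
default_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_sweep()
    cache
  }
})
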