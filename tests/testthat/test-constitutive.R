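test_that("deformation state computes isochoric invariants", {
  st <- deformation_state(diag(3), c(1, 0, 0))
  expect_equal(st$J, 1)
  expect_equal(st$Ibar1, 3)
  expect_equal(st$lambdabar_f, 1)

  # incompressible uniaxial: Ibar1 = lambda^2 + 2/lambda
  lam <- 1.1
  st <- uniaxial_state(lam)
  expect_equal(st$J, 1, tolerance = 1e-12)
  expect_equal(st$Ibar1, lam^2 + 2 / lam, tolerance = 1e-12)
  expect_equal(st$Ibar1, 3.02818, tolerance = 1e-5)
  expect_equal(st$lambdabar_f, 1.1, tolerance = 1e-12)

  # pure dilation leaves the isochoric measures at their reference values
  st <- deformation_state(2 * diag(3), c(0, 0, 1))
  expect_equal(st$J, 8)
  expect_equal(st$Ibar1, 3, tolerance = 1e-12)
  expect_equal(st$lambdabar_f, 1, tolerance = 1e-12)
})

test_that("degenerate deformation inputs are rejected", {
  Fneg <- diag(c(-1, 1, 1))
  expect_error(deformation_state(Fneg), "det")
  expect_error(deformation_state(diag(3), c(1, 1, 0)), "unit")
})

test_that("muscle strain energy matches closed-form evaluation", {
  p <- martins_params()
  expect_equal(martins_energy(deformation_state(diag(3)), p), 0)

  # frozen closed-form values at lambda = 1.1, passive, incompressible:
  # Um = c(e^{b(I1-3)}-1), UfPE = A(e^{a(l-1)^2}-1), UJ = 0
  parts <- martins_energy(uniaxial_state(1.1), p, parts = TRUE)
  expect_equal(unname(parts["Um"]), 6.217801e-4, tolerance = 1e-6)
  expect_equal(unname(parts["UfPE"]), 1.745619e-4, tolerance = 1e-6)
  expect_equal(unname(parts["UfSE"]), 0)
  expect_equal(unname(parts["UJ"]), 0, tolerance = 1e-20)
  expect_equal(sum(parts), 7.96342e-4, tolerance = 1e-6)
})

test_that("activation level theta = 0 makes T0M inert", {
  st <- uniaxial_state(1.3)
  p1 <- martins_params(T0M = 0.682)
  p2 <- martins_params(T0M = 99)
  expect_identical(martins_energy(st, p1), martins_energy(st, p2))
  expect_identical(martins_cauchy_stress(st, p1), martins_cauchy_stress(st, p2))

  # with activation on, the active energy has the closed antiderivative
  # theta*T0M*[(l-1) - 4/3 (l-1)^3]
  pa <- martins_params(theta = 0.5, T0M = 0.682)
  e <- 0.3
  parts <- martins_energy(uniaxial_state(1.3), pa, parts = TRUE)
  expect_equal(unname(parts["UfSE"]), 0.5 * 0.682 * (e - (4 / 3) * e^3),
               tolerance = 1e-12)
})

test_that("analytic Cauchy stress matches the numerical oracle", {
  p <- martins_params()
  st <- uniaxial_state(1.1)
  num <- numerical_stress_oracle(
    function(F) martins_energy(deformation_state(F), p), st)
  ana <- martins_cauchy_stress(st, p)
  expect_equal(ana, num, tolerance = 1e-5)
  # convenience mode: lateral traction-free axial component
  axial <- attr(martins_cauchy_stress(st, p, mode = "uniaxial"), "axial")
  expect_equal(axial, num[1, 1] - num[2, 2], tolerance = 1e-5)

  # oracle equivalence on seeded random isochoric states, both models
  set.seed(42)
  nh <- neo_hookean_params(c10 = 0.1)
  for (i in 1:20) {
    st <- deformation_state(random_isochoric_F(), c(1, 0, 0))
    num <- numerical_stress_oracle(
      function(F) martins_energy(deformation_state(F), p), st)
    expect_equal(martins_cauchy_stress(st, p), num,
                 tolerance = 1e-5 * max(abs(num)))
    numn <- numerical_stress_oracle(
      function(F) neo_hookean_energy(deformation_state(F), nh), st)
    expect_equal(neo_hookean_stress(st, nh), numn,
                 tolerance = 1e-5 * max(abs(numn)))
  }
})

test_that("uniaxial convenience mode rejects non-uniaxial states", {
  st <- deformation_state(random_isochoric_F(), c(1, 0, 0))
  expect_error(martins_cauchy_stress(st, martins_params(), "uniaxial"),
               "uniaxial")
})

test_that("volumetric penalty sets the mean stress under pure dilation", {
  # J = 1.01, 1/D = 10 MPa: deviatoric terms vanish, mean stress =
  # (2/D)(J-1) = 0.2 MPa
  J <- 1.01
  st <- deformation_state(J^(1 / 3) * diag(3))
  sig <- martins_cauchy_stress(st, martins_params(D = 0.1))
  expect_equal(mean(diag(sig)), 0.2, tolerance = 1e-10)
  expect_equal(sig - diag(mean(diag(sig)), 3), matrix(0, 3, 3),
               tolerance = 1e-12)
})

test_that("Neo-Hookean uniaxial stress matches the closed form", {
  nh <- neo_hookean_params(c10 = 0.1)
  lam <- 1.5
  st <- uniaxial_state(lam)
  expect_equal(attr(neo_hookean_stress(st, nh, "uniaxial"), "axial"),
               2 * 0.1 * (lam^2 - 1 / lam), tolerance = 1e-10)
  expect_equal(2 * 0.1 * (lam^2 - 1 / lam), 0.31667, tolerance = 1e-4)
  num <- numerical_stress_oracle(
    function(F) neo_hookean_energy(deformation_state(F), nh), st)
  expect_equal(num[1, 1] - num[2, 2], 0.31667, tolerance = 1e-4)
})

test_that("linear elastic law is sigma = E * strain", {
  pk <- linear_elastic_params(E = 23.8, nu = 0.49, unit = "kPa")
  expect_equal(linear_elastic_stress(0, pk), 0)
  expect_equal(linear_elastic_stress(0.1, pk), 2.38)
  expect_equal(linear_elastic_stress(2.01, pk), 47.838)
  expect_error(linear_elastic_stress(-1.5, pk))
})

test_that("all models return zero stress and energy at the reference state", {
  id <- deformation_state(diag(3))
  p <- martins_params()
  nh <- neo_hookean_params()
  expect_equal(martins_energy(id, p), 0)
  expect_equal(neo_hookean_energy(id, nh), 0)
  expect_equal(martins_cauchy_stress(id, p), matrix(0, 3, 3))
  expect_equal(neo_hookean_stress(id, nh), matrix(0, 3, 3))
})

test_that("small-strain shear response recovers the matrix shear modulus 2cb", {
  # simple shear in the 1-2 plane with the fiber along axis 3: the fiber is
  # unstretched, so sigma_12 / gamma -> 2cb as gamma -> 0 (0.0434 MPa)
  p <- martins_params()
  gam <- 1e-4
  F <- diag(3); F[1, 2] <- gam
  st <- deformation_state(F, c(0, 0, 1))
  sig <- martins_cauchy_stress(st, p)
  mu <- 2 * p$c * p$b
  expect_equal(mu, 0.043401, tolerance = 1e-4)
  expect_equal(sig[1, 2] / gam, mu, tolerance = 0.01 * mu)
})

test_that("energy is objective under superposed rotations", {
  p <- martins_params()
  set.seed(7)
  F <- random_isochoric_F()
  u0 <- martins_energy(deformation_state(F, c(1, 0, 0)), p)
  for (i in 1:50) {
    # random rotation via QR of a Gaussian matrix
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    u <- martins_energy(deformation_state(Q %*% F, c(1, 0, 0)), p)
    expect_lt(abs(u - u0), 1e-12)
  }
})

test_that("numerical oracle is exact for a quadratic test energy", {
  # U = k/2 ||F - I||^2 has zero gradient at F = I
  sig <- numerical_stress_oracle(
    function(F) 0.5 * 3 * sum((F - diag(3))^2),
    deformation_state(diag(3)))
  expect_equal(sig, matrix(0, 3, 3), tolerance = 1e-9)
  expect_error(numerical_stress_oracle(function(F) NaN,
                                       deformation_state(diag(3))),
               "oracle-domain")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(martins_params(c = 0, A = 0))
  expect_error(martins_params(theta = 1.5))
  expect_error(linear_elastic_params(E = -1, nu = 0.3))
  expect_error(linear_elastic_params(E = 1, nu = 0.5))
  expect_error(neo_hookean_params(c10 = 0))
  expect_silent(martins_params(A = 0))   # matrix-only specimen
  expect_silent(martins_params(c = 0))   # fiber-only specimen
})
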