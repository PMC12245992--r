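test_that("reduced relaxation function has the Prony closed form", {
  mb <- matrix_branches()
  fb <- fiber_branches()
  expect_equal(relaxation_coefficient(mb, 0), 3.7)
  expect_equal(relaxation_coefficient(fb, 0), 3.0)
  # 1 + 1.5 e^-3 + 0.7 e^-0.15 + 0.5 e^-0.012
  expect_equal(relaxation_coefficient(mb, 60),
               1 + 1.5 * exp(-3) + 0.7 * exp(-0.15) + 0.5 * exp(-0.012))
  expect_equal(relaxation_coefficient(mb, 60), 2.1712, tolerance = 1e-4)
  # monotone decreasing toward 1
  ts <- seq(0, 2e4, length.out = 200)
  g <- relaxation_coefficient(mb, ts)
  expect_true(all(diff(g) < 0))
  expect_equal(relaxation_coefficient(mb, 1e9), 1, tolerance = 1e-12)
  expect_error(relaxation_coefficient(mb, -1), "non-negative")
})

test_that("overstress recurrence is inert for dt = 0 and dS = 0", {
  s <- visco_state(matrix_branches())
  s <- update_overstress(s, 2.5, 10)    # load something first
  h0 <- s$H
  s1 <- update_overstress(s, 0, 0)
  expect_equal(s1$H, h0)
  expect_error(update_overstress(s, 0, -1), "non-negative")
})

test_that("overstress decays below 1% after five max relaxation times", {
  br <- matrix_branches()
  s <- update_overstress(visco_state(br), 1, 0)   # unit step load
  h0 <- total_overstress(s)
  t_end <- 5 * max(br$tau)
  dt <- 100
  for (k in seq_len(t_end / dt)) s <- update_overstress(s, 0, dt)
  expect_lt(total_overstress(s) / h0, 0.01)
})

test_that("sampled step response reproduces g(t) within 1%", {
  # each branch on its own: unit step at t = 0, sampled at tau/20 over
  # [0, 3 tau], against the closed form 1 + B exp(-t/tau)
  all_br <- rbind(matrix_branches(), fiber_branches())
  for (i in seq_len(nrow(all_br))) {
    br <- maxwell_branches(all_br$B[i], all_br$tau[i])
    dt <- br$tau / 20
    s <- update_overstress(visco_state(br), 1, 0)
    g_sim <- 1 + total_overstress(s)
    for (k in 1:60) {
      s <- update_overstress(s, 0, dt)
      g_sim <- c(g_sim, 1 + total_overstress(s))
    }
    g_ref <- relaxation_coefficient(br, seq(0, 60) * dt)
    expect_equal(g_sim, g_ref, tolerance = 0.01)
  }
})

test_that("step relaxation reaches the branch-sum stress ratio", {
  # matrix-only specimen: instantaneous/equilibrium = 1 + sum(B) = 3.7
  tr <- step_relaxation_test(1.2, duration = 25000, dt = 2,
                             p = martins_params(A = 0),
                             branches_fiber = NULL)
  n <- nrow(tr)
  expect_equal(tr$stress[1] / tr$stress[n], 3.7, tolerance = 0.01 * 3.7)
  expect_true(all(diff(tr$stress) < 0))
  # fiber-only specimen with fiber branches: ratio 3.0
  trf <- step_relaxation_test(1.2, duration = 18000, dt = 2,
                              p = martins_params(c = 0),
                              branches_matrix = NULL)
  expect_equal(trf$stress[1] / trf$stress[nrow(trf)], 3.0,
               tolerance = 0.01 * 3.0)
  # sigma(60 s)/sigma(inf) = g(60) for the matrix branch set
  i60 <- which(tr$time == 60)
  expect_equal(tr$stress[i60] / tr$stress[n], 2.171, tolerance = 0.01 * 2.171)
})

test_that("relaxation stress ratio is independent of the held stretch", {
  r <- sapply(c(1.1, 1.5), function(lam) {
    tr <- step_relaxation_test(lam, duration = 25000, dt = 5,
                               p = martins_params(A = 0),
                               branches_fiber = NULL)
    tr$stress[1] / tr$stress[nrow(tr)]
  })
  expect_equal(r[1], r[2], tolerance = 0.01 * r[1])
})

test_that("total stress never falls below equilibrium on monotone loading", {
  # ramp the stretch up over a slow history and check sigma >= sigma_eq
  p <- martins_params()
  lams <- seq(1, 1.8, length.out = 200)
  eq <- uniaxial_stress_split(lams, p)
  sm <- visco_state(matrix_branches())
  sf <- visco_state(fiber_branches())
  for (k in 2:length(lams)) {
    sm <- update_overstress(sm, eq$matrix[k] - eq$matrix[k - 1], 5)
    sf <- update_overstress(sf, eq$fiber[k] - eq$fiber[k - 1], 5)
    tot <- eq$matrix[k] + eq$fiber[k] +
      total_overstress(sm) + total_overstress(sf)
    expect_gte(tot, eq$matrix[k] + eq$fiber[k])
  }
})

test_that("matrix and fiber branch sets act independently", {
  # switching the fiber branches off must not change the matrix trace
  a <- default_anatomy()
  p <- pull_protocol(60, 60, 2)
  mats <- default_materials()
  mats_nofiber <- mats
  mats_nofiber$pfm <- martins_params(A = 1e-12)  # fiber stress ~ 0
  r1 <- simulate_vad(p, a$head, a$rings, mats)
  r2 <- simulate_vad(p, a$head, a$rings, mats_nofiber)
  # recompute matrix-only overstress directly from the recurrence and
  # compare with the simulated trace minus its fiber part
  lam <- r1$series$stretch_levator
  eq <- uniaxial_stress_split(lam, mats$pfm)
  sm <- visco_state(mats$branches_matrix)
  over_m <- numeric(length(lam))
  for (k in 2:length(lam)) {
    dt <- r1$series$time[k] - r1$series$time[k - 1]
    sm <- update_overstress(sm, eq$matrix[k] - eq$matrix[k - 1], dt)
    over_m[k] <- total_overstress(sm)
  }
  expect_equal(r2$series$sigma1_levator, eq$matrix + over_m,
               tolerance = 1e-6)
})

test_that("halving the time step changes the stress trace by < 0.5%", {
  a <- default_anatomy()
  r1 <- simulate_vad(pull_protocol(60, 60, 2, dt = 1), a$head, a$rings)
  r2 <- simulate_vad(pull_protocol(60, 60, 2, dt = 0.5), a$head, a$rings)
  m <- match(round(r1$series$time, 9), round(r2$series$time, 9))
  expect_false(anyNA(m))
  d <- max(abs(r1$series$sigma1_levator - r2$series$sigma1_levator[m]))
  expect_lt(d / max(r1$series$sigma1_levator), 0.005)
})
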