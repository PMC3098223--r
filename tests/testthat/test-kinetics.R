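test_that("rate law matches the Michaelis-Menten/Hill form", {
  mm <- branch_kinetics("v10", vmax = 2, km = 1)
  expect_equal(reaction_rate(mm, 1), 1)     # half-saturation
  expect_equal(reaction_rate(mm, 0), 0)
  expect_lt(abs(reaction_rate(mm, 1e9) - 2), 1e-8)
  hill <- branch_kinetics("v10", vmax = 2, km = 1, hill_n = 4)
  expect_equal(reaction_rate(hill, 1), 1)   # Hill at c = km
  expect_error(reaction_rate(mm, -0.1), ">= 0")
  expect_error(branch_kinetics("v10", vmax = 0, km = 1))
  expect_error(branch_kinetics("v10", vmax = 1, km = -1))
  expect_error(branch_kinetics("v10", vmax = 1, km = 1, hill_n = 0.5))
  expect_error(branch_kinetics("v2", 1, 1), "must be one of")
  # Hill with n = 1 is Michaelis-Menten to machine precision
  h1 <- branch_kinetics("v10", vmax = 1.7, km = 0.3, hill_n = 1)
  m1 <- branch_kinetics("v10", vmax = 1.7, km = 0.3)
  cs <- c(0, 0.01, 0.3, 2, 50)
  expect_identical(reaction_rate(h1, cs), reaction_rate(m1, cs))
})

test_that("the branch model counts its free parameters", {
  expect_equal(n_free_parameters(reference_branch_model()), 16L)
  expect_equal(n_free_parameters(reference_branch_model(hill_n = 2)), 24L)
  ks <- lapply(c("v10", "v11", "v12"), branch_kinetics, vmax = 1, km = 1)
  expect_error(branch_model(ks, 1), "exactly the 8")
  expect_error(branch_model(reference_branch_model()$kinetics, influx = 0))
})

test_that("steady state matches the closed-form concentrations", {
  # symmetric model: every step vmax=2, km=1, J=0.5
  m <- reference_branch_model(J = 0.5, vmax = 2, km = 1)
  st <- steady_state(m)
  expect_true(st$converged)
  expect_lt(st$residual, 1e-9)
  # caffeoyl-CoA: 2 * 2c/(1+c) = 0.5 -> c = 1/7
  expect_equal(unname(st$concentrations[["caffeoyl_CoA"]]), 1 / 7,
               tolerance = 1e-10)
  # feruloyl-CoA carries u = 0.25: c = km*u/(vmax-u) = 0.25/1.75
  expect_equal(unname(st$concentrations[["feruloyl_CoA"]]), 0.25 / 1.75,
               tolerance = 1e-10)
  # conservation and symmetric branch ratios
  expect_equal(st$g_flux + st$s_flux, 0.5, tolerance = 1e-10)
  expect_equal(unname(st$fluxes[["v14"]]), unname(st$fluxes[["v16"]]),
               tolerance = 1e-10)
})

test_that("capacity shortfalls are reported as non-convergence", {
  ks <- reference_branch_model(J = 1.5)$kinetics
  ks$v10$vmax <- 0.5
  ks$v11$vmax <- 0.5
  st <- steady_state(branch_model(ks, 1.5))
  expect_false(st$converged)
  expect_match(st$diagnostic, "caffeoyl-CoA")
  # bottleneck further down the cascade
  ks2 <- reference_branch_model(J = 0.5)$kinetics
  ks2$v13$vmax <- 0.2
  ks2$v10$vmax <- 1e-6  # nearly everything must go through v11 -> v13
  st2 <- steady_state(branch_model(ks2, 0.5))
  expect_false(st2$converged)
})

test_that("symmetric G/S kinetics give S/G = 1 when the alcohol route is closed", {
  ks <- reference_branch_model(J = 0.5)$kinetics
  ks$v20$vmax <- 1e-12  # effectively disabled
  st <- steady_state(branch_model(ks, 0.5))
  expect_true(st$converged)
  expect_equal(st$sg_ratio, 1, tolerance = 1e-6)
})

test_that("algebraic steady state agrees with stiff ODE integration", {
  set.seed(303)
  cfg <- sampling_config(n_draws = 1, seed = 303)
  checked <- 0
  while (checked < 8) {
    model <- sample_parameter_set(cfg)
    st <- steady_state(model)
    if (!st$converged) next
    checked <- checked + 1
    out <- integrate_branch_model(model, times = c(0, 10^(2:5)),
                                  rtol = 1e-10, atol = 1e-12)
    yend <- out[nrow(out), -1]
    expect_equal(unname(yend), unname(st$concentrations), tolerance = 1e-6)
  }
})

test_that("perturbation response is conservative and null at factor one", {
  m <- reference_branch_model(J = 0.5)
  r0 <- perturbation_response(m, "CCoAOMT", 1)
  expect_equal(r0$relative_change, 0)
  r <- perturbation_response(m, "CCR1", 0.4)
  expect_true(r$converged)
  # flux conservation holds in both states
  st <- steady_state(m)
  expect_equal(st$g_flux + st$s_flux, 0.5, tolerance = 1e-8)
  expect_error(perturbation_response(m, "CCoAOMT", 0))
  expect_error(perturbation_response(m, "CAD", 0.5))
  # far from saturation with the shunt closed, the branch ratio is
  # insensitive to an upstream knockdown
  ks <- reference_branch_model(J = 0.01, vmax = 5, km = 10)$kinetics
  ks$v10$vmax <- 1e-9
  lin <- branch_model(ks, 0.01)
  rl <- perturbation_response(lin, "CCoAOMT", 0.2)
  expect_true(rl$converged)
  expect_lt(abs(rl$relative_change), 1e-6)
})
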