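test_that("oxygen protocol follows the left-open/right-closed cyclic schedule", {
  pr <- oxygen_protocol(period = 10, bias = 0.5, c1 = 1, c2 = 0.4)
  expect_identical(oxygen_at(pr, 3), 1)
  # the phase-switch instant belongs to the phase it closes
  expect_identical(oxygen_at(pr, 5), 1)
  expect_identical(oxygen_at(pr, 5 + 1e-9), 0.4)
  expect_identical(oxygen_at(pr, 10), 0.4)
  expect_identical(oxygen_at(pr, 10 + 1e-9), 1)
  expect_identical(oxygen_at(pr, 0), 1)

  # asymmetric bias: normoxic phase is (0, 7.5], hypoxic (7.5, 10]
  pr2 <- oxygen_protocol(period = 10, bias = 0.25)
  tab <- oxygen_at(pr2, c(1, 7.5, 7.6, 8, 10, 12))
  expect_equal(tab, c(1, 1, 0.4, 0.4, 0.4, 1))

  prc <- oxygen_protocol(mode = "constant", level = 0.4)
  expect_equal(oxygen_at(prc, c(0, 17)), c(0.4, 0.4))
  expect_error(oxygen_at(pr, -1), "non-negative")
})

test_that("protocol validation rejects degenerate cycles", {
  expect_error(oxygen_protocol(bias = 0), "bias")
  expect_error(oxygen_protocol(bias = 1), "bias")
  expect_error(oxygen_protocol(period = 0), "period")
  expect_error(oxygen_protocol(c1 = 0.3, c2 = 0.4), "c2")
  expect_error(oxygen_protocol(mode = "constant"), "level")
})

test_that("beta switches between induction and erasure at the threshold", {
  p <- model_params(beta_l = 2, beta_h = 20)
  expect_identical(select_beta(0.4, p), 2)
  expect_identical(select_beta(1, p), 20)
  # tie-break: c = c_H counts as the normoxic side, like the Heaviside
  expect_identical(select_beta(p$c_H, p), 20)
  expect_error(select_beta(-0.1, p), "non-negative")
})

test_that("phenotype velocity law and its equilibrium", {
  p <- model_params()
  # both numerator terms vanish at the injection coordinate under normoxia
  expect_identical(phenotype_velocity(0.5, 1, p), 0)
  expect_equal(phenotype_velocity(0.5, 0.4, p), -0.24)
  # equilibrium trait: root of the numerator at the hypoxic level
  mu_star <- hypoxic_equilibrium_phenotype(0.4, p)
  expect_equal(mu_star, 0.02)
  expect_equal(phenotype_velocity(mu_star, 0.4, p), 0)
  # stability: negative above, positive below
  expect_lt(phenotype_velocity(mu_star + 0.1, 0.4, p), 0)
  expect_gt(phenotype_velocity(mu_star - 0.01, 0.4, p), 0)
  # memoryless: velocity vanishes at mu_hn0 for any oxygen level
  p0 <- model_params(alpha = 0)
  for (cc in c(0, 0.4, 0.7, 1))
    expect_identical(phenotype_velocity(0.5, cc, p0), 0)
  expect_error(phenotype_velocity(0.5, 0.4, p, beta = 0), "positive")
})

test_that("parameter validation enforces the model's constraints", {
  expect_error(model_params(beta_l = 0), "beta")
  expect_error(model_params(c_N = 0.6, c_H = 0.5), "thresholds")
  expect_error(model_params(mu_hn0 = 0), "mu_hn0")
  expect_error(model_params(mu_nh = -1), "non-negative")
  # memory too strong for the protocol's hypoxic level: caught at model level
  expect_error(
    invasion_model(model_params(), oxygen_protocol(c2 = 0.3),
                   grids = coarse_grids()),
    "positive")
  expect_error(hypoxic_equilibrium_phenotype(0.3, model_params()), "alpha")
  expect_error(hypoxic_equilibrium_phenotype(0.6, model_params()), "c_H")
  # memoryless equilibrium is the injection coordinate
  expect_equal(hypoxic_equilibrium_phenotype(0.4, model_params(alpha = 0)),
               0.5)
})

test_that("oxygen gating activates exactly the printed reaction branches", {
  p <- model_params()
  # intermediate oxygen: only the normoxic->hypoxic transition acts
  expect_equal(reaction_normoxic(0.5, 0.2, 0.1, 99, 0.4, p), -0.25)
  # normoxia, volume-filled: proliferation shuts off
  expect_equal(reaction_normoxic(0.5, 0, 0.5, 0, 1, p), 0)
  # below the necrotic threshold both loss terms act
  expect_equal(reaction_normoxic(1, 0, 0, 0, 0.05, p), -0.501)
  # at c = c_H exactly, no branch is active (Heaviside(0) = 0)
  expect_equal(reaction_normoxic(0.7, 0.1, 0.1, 5, p$c_H, p), 0)
  # normoxia: gain is the phenotype first moment plus logistic growth
  expect_equal(reaction_normoxic(0.2, 0.1, 0.3, 0.04, 1, p),
               0.1 * 0.2 * (1 - 0.2 - 0.1 - 0.3) + 0.04)
})

test_that("hypoxic local reactions inject, escape and die by regime", {
  p <- model_params()
  dmu <- 0.01
  # injection scaled by 1/dmu so its mu-integral equals the normoxic loss
  gain <- reaction_hypoxic_local(0, 0.5, n = 0.2, c = 0.4,
                                 is_injection_node = TRUE, dmu = dmu, p)
  expect_equal(gain, 10)
  expect_equal(gain * dmu, p$mu_nh * 0.2)   # discrete mass balance
  # escape under normoxia at the trait-dependent rate
  expect_equal(reaction_hypoxic_local(0.3, 0.5, 0, 1, FALSE, dmu, p), -0.15)
  # intermediate oxygen, non-injection node: nothing happens
  expect_identical(reaction_hypoxic_local(0.3, 0.2, 1, 0.4, FALSE, dmu, p), 0)
  # necrosis below c_N
  expect_equal(reaction_hypoxic_local(0.4, 0.2, 0, 0.05, FALSE, dmu, p),
               -p$gamma_h * 0.4)
  expect_error(
    reaction_hypoxic_local(0, 0.3, 0, 0.4, TRUE, dmu, p), "injection")
})

test_that("phenotype quadrature is the rectangle rule", {
  g <- coarse_grids()
  expect_identical(integrated_H(numeric(g$M), g$dmu), 0)
  expect_equal(integrated_H(rep(1, g$M), g$dmu), g$M * g$dmu)
  # single-node spike of mass m
  h <- numeric(g$M)
  h[7] <- 0.3 / g$dmu
  expect_equal(integrated_H(h, g$dmu), 0.3)
  expect_equal(phenotype_first_moment(h, g$mu, g$dmu), 0.3 * g$mu[7])
  # matrix form reduces row-wise
  hm <- rbind(h, 2 * h)
  expect_equal(unname(integrated_H(hm, g$dmu)), c(0.3, 0.6))
})
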