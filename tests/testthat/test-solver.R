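test_that("initial state reproduces the slab profile with unit tumor mass", {
  st <- initialize_state(sim_grids())
  g <- st$grids
  expect_equal(st$n[g$x == 5], 0.5)
  expect_equal(st$n[g$x == 2], 0)
  expect_equal(st$e[g$x == 2], 0.5)
  expect_equal(st$e[g$x == 5], 0)
  expect_true(all(st$h == 0))
  # interface nodes carry the mean of the one-sided limits, so the
  # rectangle-rule mass is exactly the continuum value n0 * (b - a)
  expect_equal(st$n[g$x == 4], 0.25)
  expect_equal(st$e[g$x == 6], 0.25)
  expect_equal(tumor_volume(st), 1)
  # support edge of the initial tumor
  expect_equal(tumor_right_boundary(st, interpolate = FALSE), 6)
  expect_lt(abs(tumor_right_boundary(st) - 6), 2 * g$dx)
  expect_error(initialize_state(g, a = 6, b = 4), "a < b")
})

test_that("timestep respects diffusion, advection and positivity bounds", {
  g <- sim_grids()          # dx = 0.05, dmu = 0.01
  p <- model_params()       # D_h = 0.01, beta_l = 2
  pr <- oxygen_protocol()   # c2 = 0.4
  dt <- cfl_timestep(g, p, pr)
  # worst trait speed: |v| at mu = 1 under hypoxia
  expect_equal(attr(dt, "f_max"), 0.49)
  expect_equal(as.numeric(dt),
               0.9 * min(0.05^2 / (2 * 0.01), 0.01 / 0.49, 1 / 15))
  # diffusion bound alone
  expect_equal(g$dx^2 / (2 * p$D_h), 0.125)
  # memoryless: advection bound dropped, f_max = 0
  dt0 <- cfl_timestep(g, model_params(alpha = 0), pr)
  expect_identical(attr(dt0, "f_max"), 0)
  expect_equal(as.numeric(dt0), 0.9 * min(0.125, 1 / 15))
})

test_that("spatial fluxes are conservative, symmetric and Laplacian-like", {
  g <- coarse_grids()
  p <- model_params()
  # uniform h and e: every difference vanishes
  st <- make_state(g, h = matrix(0.2, g$N, g$M), e = rep(0.3, g$N))
  expect_equal(max(abs(spatial_flux_update(st, p))), 0)
  # conservation: column sums (spatial rectangle integral) vanish
  h <- matrix(0, g$N, g$M)
  h[12:18, 5] <- c(1, 3, 2, 5, 4, 1, 2) / 10
  st <- make_state(g, h = h, e = 0.4 * sin(g$x) + 0.4,
                   n = 0.1 * exp(-(g$x - 5)^2))
  upd <- spatial_flux_update(st, p)
  expect_lt(max(abs(colSums(upd) * g$dx)), 1e-14)
  # small interior spike with free volume ~ 1: 3-point Laplacian
  h2 <- matrix(0, g$N, g$M)
  h2[20, 3] <- 1e-6
  st2 <- make_state(g, h = h2)
  upd2 <- spatial_flux_update(st2, p)
  lap <- p$D_h * c(0, diff(diff(h2[, 3])), 0) / g$dx^2
  lap[1] <- p$D_h * (h2[2, 3] - h2[1, 3]) / g$dx^2
  expect_equal(upd2[, 3], lap, tolerance = 1e-6)
  # haptotaxis moves mass up the ECM gradient (diffusion off to isolate it)
  h3 <- matrix(0, g$N, g$M)
  h3[20, 3] <- 1
  st3 <- make_state(g, h = h3, e = g$x / 20)  # ECM increasing to the right
  upd3 <- spatial_flux_update(st3, model_params(D_h = 0))
  # mean position of the rate-of-change field shifts mass rightward
  expect_gt(sum(g$x * upd3[, 3]), 0)
})

test_that("trait advection is conservative and drifts to the equilibrium", {
  g <- coarse_grids()
  p <- model_params()
  # zero state stays zero
  expect_equal(max(abs(phenotype_advection_update(make_state(g), 0.4, p))), 0)
  # per-x phenotype mass is preserved exactly (zero boundary fluxes)
  set.seed(41)
  h <- matrix(rexp(g$N * g$M), g$N, g$M)
  st <- make_state(g, h = h)
  for (cc in c(0.4, 1)) {
    upd <- phenotype_advection_update(st, cc, p)
    expect_lt(max(abs(rowSums(upd) * g$dmu)), 1e-12)
  }
  # a spike at mu_hn0 under sustained hypoxia drifts toward mu* = 0.02;
  # oracle: the characteristic ODE d(mu)/dt = v(mu), solved in closed form
  # mu(t) = mu* + (mu0 - mu*) exp(-t / beta_l)
  gf <- sim_grids(N = 3)   # fine trait mesh so mu* = 0.02 is a node
  hf <- matrix(0, gf$N, gf$M)
  hf[1, gf$injection_index] <- 1 / gf$dmu
  stf <- make_state(gf, h = hf)
  dt <- 0.9 * gf$dmu / 0.49
  mean_mu <- function(s) sum(s$h[1, ] * gf$mu) / sum(s$h[1, ])
  t_end <- 5 * p$beta_l
  for (k in seq_len(round(t_end / dt))) {
    stf$h <- stf$h + dt * phenotype_advection_update(stf, 0.4, p)
    expect_gte(min(stf$h), 0)
  }
  mu_ode <- 0.02 + (0.5 - 0.02) * exp(-t_end / p$beta_l)
  expect_lt(abs(mean_mu(stf) - mu_ode), 0.02)
  # much later the mean parks on the equilibrium node itself
  for (k in seq_len(round((20 * p$beta_l - t_end) / dt))) {
    stf$h <- stf$h + dt * phenotype_advection_update(stf, 0.4, p)
  }
  expect_lt(abs(mean_mu(stf) - 0.02), 1e-3)
})

test_that("one step conserves cell mass in the pure-transition regime", {
  g <- coarse_grids()
  p <- model_params()
  pr <- oxygen_protocol(mode = "constant", level = 0.4)
  st <- initialize_state(g)
  dt <- as.numeric(cfl_timestep(g, p, pr))
  mass <- function(s)
    spatial_integral(s$n + integrated_H(s$h, g$dmu), g$dx)
  m0 <- mass(st)
  for (k in 1:50) st <- step_state(st, pr, p, g, dt)
  expect_lt(abs(mass(st) - m0), 1e-12)
  # ECM is non-increasing everywhere once hypoxic cells exist
  st2 <- step_state(st, pr, p, g, dt)
  expect_true(all(st2$e <= st$e + 1e-15))
})

test_that("step matches the composition of the exported operators", {
  g <- coarse_grids()
  p <- model_params()
  pr <- oxygen_protocol(period = 5, bias = 0.5)
  st <- initialize_state(g)
  dt <- 0.01
  for (k in 1:30) st <- step_state(st, pr, p, g, dt)
  cc <- oxygen_at(pr, st$t)
  Hx <- integrated_H(st$h, g$dmu)
  mom <- phenotype_first_moment(st$h, g$mu, g$dmu)
  dn <- reaction_normoxic(st$n, Hx, st$e, mom, cc, p)
  dh <- spatial_flux_update(st, p) + phenotype_advection_update(st, cc, p)
  for (j in seq_len(g$M))
    dh[, j] <- dh[, j] + reaction_hypoxic_local(
      st$h[, j], g$mu[j], st$n, cc, j == g$injection_index, g$dmu, p)
  nxt <- step_state(st, pr, p, g, dt)
  expect_equal(nxt$n, st$n + dt * dn, tolerance = 1e-14)
  expect_equal(nxt$h, st$h + dt * dh, tolerance = 1e-14)
  expect_equal(nxt$e, st$e * (1 - p$delta * dt * Hx), tolerance = 1e-14)
})

test_that("step aborts on states that violate positivity beyond tolerance", {
  g <- coarse_grids()
  p <- model_params()
  pr <- oxygen_protocol(mode = "constant", level = 0.4)
  st <- initialize_state(g)
  st$n[3] <- -1
  expect_error(step_state(st, pr, p, g, 0.01), "negative")
  st2 <- initialize_state(g)
  st2$h[5, 5] <- NaN
  expect_error(step_state(st2, pr, p, g, 0.01), "non-finite")
})

test_that("simulate agrees with the reference stepper and is deterministic", {
  m <- coarse_model(protocol = oxygen_protocol(period = 5, t_final = 60))
  sim <- simulate(m, t_final = 2)
  ref <- run_reference(m, 2, sim$dt)
  expect_equal(sim$final_state$h, ref$h, tolerance = 1e-13)
  expect_equal(sim$final_state$n, ref$n, tolerance = 1e-13)
  expect_equal(sim$final_state$e, ref$e, tolerance = 1e-13)
  # bit-for-bit determinism of repeated runs
  sim2 <- simulate(m, t_final = 2)
  expect_identical(sim$obs, sim2$obs)
  expect_identical(sim$final_state$h, sim2$final_state$h)
  # t_final = 0: only the initial record
  sim0 <- simulate(m, t_final = 0)
  expect_equal(nrow(sim0$obs), 1)
  expect_equal(sim0$obs$volume, 1)
})

test_that("memoryless dynamics stay localized at the injection trait", {
  m <- coarse_model(params = model_params(alpha = 0),
                    protocol = oxygen_protocol(period = 5, t_final = 60))
  sim <- simulate(m, t_final = 12)
  h <- sim$final_state$h
  j0 <- m$grids$injection_index
  expect_gt(sum(h[, j0]), 0)
  expect_identical(max(abs(h[, -j0])), 0)
  expect_equal(sim$obs$mean_phenotype[nrow(sim$obs)], 0.5)
})

test_that("oxygen-rich dynamics never create hypoxic cells and freeze ECM", {
  m <- coarse_model(protocol = oxygen_protocol(mode = "constant", level = 1,
                                               t_final = 60))
  sim <- simulate(m, t_final = 10)
  expect_identical(max(sim$obs$h_tot), 0)
  expect_identical(sim$final_state$e, initialize_state(m$grids)$e)
  # normoxic mass grows toward the local free volume
  expect_gt(sim$obs$n_tot[nrow(sim$obs)], sim$obs$n_tot[1])
})
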