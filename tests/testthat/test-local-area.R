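test_that("excitatory transfer function matches its closed form", {
  p <- fx$params
  # removable singularity at threshold input b/a: limit is 1/d
  expect_equal(phi_excitatory(p$b / p$a, p), 1 / p$d, tolerance = 1e-12)
  # direct evaluation away from threshold
  expect_equal(phi_excitatory(1.0, p), 81, tolerance = 1e-8)
  expect_lt(phi_excitatory(0, p), 1e-5)
  expect_gt(phi_excitatory(0, p), 0)
  # continuity: agreement with the series 1/d + x/2 + d x^2 / 12 near zero
  x <- c(-1e-6, -1e-9, 1e-9, 1e-6)
  I <- (x + p$b) / p$a
  series <- 1 / p$d + x / 2 + p$d * x^2 / 12
  expect_equal(phi_excitatory(I, p), series, tolerance = 1e-9)
  expect_error(phi_excitatory(NaN, p), "finite")
})

test_that("inhibitory transfer function is threshold-linear with baseline r0", {
  p <- fx$params
  expect_equal(phi_inhibitory(0, p), 0)
  # at threshold input c0/c1 the rate equals the baseline r0
  expect_equal(phi_inhibitory(p$c0 / p$c1, p), p$r0, tolerance = 1e-10)
  # linear branch: (c1 I - c0)/g_I + r0
  expect_equal(phi_inhibitory(0.5, p),
               (615 * 0.5 - 177) / 4 + 5.5, tolerance = 1e-10)
  expect_error(phi_inhibitory(Inf, p), "finite")
})

test_that("parameter validation rejects inconsistent circuits", {
  expect_error(local_circuit_params(tau_N = 0), "positive")
  expect_error(local_circuit_params(J_EI = 0.3), "J_EI")
  expect_error(local_circuit_params(J_s = -0.1), "J_s")
  expect_error(local_circuit_params(g_I = -1), "> 0")
})

test_that("population currents sum couplings, background, inputs and noise", {
  p <- fx$params
  s <- area_state(p)
  I <- population_currents(s, p)
  expect_equal(unname(I["I_A"]), p$I0_A)
  expect_equal(unname(I["I_C"]), p$I0_C)
  s["S_A"] <- 0.1; s["S_B"] <- 0.05; s["S_C"] <- 0.1
  I <- population_currents(s, p)
  expect_equal(unname(I["I_A"]), 0.331065, tolerance = 1e-9)
  expect_equal(unname(I["I_C"]), 0.2705, tolerance = 1e-9)
  # net input and stimulus are additive
  I2 <- population_currents(s, p, net_input = c(0.1, 0, 0),
                            stim = c(0, 0.2, 0))
  expect_equal(unname(I2["I_A"] - I["I_A"]), 0.1)
  expect_equal(unname(I2["I_B"] - I["I_B"]), 0.2)
  expect_error(population_currents(s, p, net_input = c(NA, 0, 0)), "finite")
})

test_that("gating variables follow their closed-form decay", {
  # with rates clamped near zero S_A decays as exp(-t / tau_N)
  p <- local_circuit_params(b = 1e6, sigma_A = 0, sigma_B = 0)  # phi ~ 0
  s <- area_state(p)
  s["S_A"] <- 0.5
  dt <- 1e-4
  for (i in seq_len(600)) s <- step_area(s, p, dt, deterministic = TRUE)
  expect_equal(unname(s["S_A"]), 0.5 * exp(-1), tolerance = 1e-3)
  expect_error(step_area(s, p, dt = -1), "positive")
  expect_error(step_area(s, p, dt = 1), "tau_r")
})

test_that("OU noise reaches its stationary standard deviation", {
  p <- fx$params
  s <- area_state(p)
  set.seed(11)
  dt <- 5e-4
  xs <- numeric(40000)
  for (i in seq_along(xs)) {
    s <- step_area(s, p, dt)
    xs[i] <- s["x_A"]
  }
  target <- p$sigma_A * sqrt(p$tau_noise / 2)
  expect_equal(sd(xs[-(1:200)]), target, tolerance = 0.05)
})

test_that("noise-free stepping is deterministic and stays at fixed points", {
  p <- fx$params
  sp <- spontaneous_state(p)
  s1 <- s2 <- sp
  for (i in 1:100) {
    s1 <- step_area(s1, p, 5e-4, deterministic = TRUE)
    s2 <- step_area(s2, p, 5e-4, deterministic = TRUE)
  }
  expect_identical(s1, s2)
  expect_equal(max(abs(s1[1:6] - sp[1:6])), 0, tolerance = 1e-6)
})

test_that("isolated area is monostable at baseline, bistable past threshold", {
  fps <- find_fixed_points(fx$params)
  expect_equal(sum(fps$stable), 1)
  # spontaneous fixed point is symmetric across the selective pools
  expect_equal(fps$S_A[fps$stable], fps$S_B[fps$stable], tolerance = 1e-8)

  p <- fx$params
  p$J_s <- 0.48
  p$J_IE <- balance_jie(0.48, fx$const, fx$params)
  fps2 <- find_fixed_points(p)
  expect_gte(sum(fps2$stable), 3)           # spontaneous + 2 memory states
  expect_gte(nrow(fps2), 5)                 # plus the saddle pair
  # memory states are selective (asymmetric)
  expect_gte(sum(fps2$stable & abs(fps2$r_A - fps2$r_B) > 1), 2)
})

test_that("critical coupling scan brackets and refines the bifurcation", {
  cj <- critical_coupling_scan(fx$params, Js_range = c(0.45, 0.48),
                               tol = 5e-4)
  expect_gt(cj, 0.45)
  expect_lt(cj, 0.48)
  # just below: monostable; just above: bistable
  below <- fx$params; below$J_s <- cj - 0.002
  below$J_IE <- balance_jie(below$J_s, fx$const, fx$params)
  above <- fx$params; above$J_s <- cj + 0.002
  above$J_IE <- balance_jie(above$J_s, fx$const, fx$params)
  expect_equal(sum(find_fixed_points(below)$stable), 1)
  expect_gt(sum(find_fixed_points(above)$stable), 1)
  expect_error(critical_coupling_scan(fx$params, Js_range = c(0.30, 0.35)),
               "bracket")
})
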