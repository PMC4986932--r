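# Closed-form Ih component model: activation, kinetics, step currents.

test_that("Boltzmann activation evaluates correctly and stays in (0,1)", {
  # midpoint
  expect_equal(boltzmann(-100, Vh = -100, k = -6), 0.5)
  # direct evaluations with the slow benchmark component
  expect_equal(boltzmann(-130, -100, -6), 0.99331, tolerance = 1e-4)
  expect_equal(boltzmann(-70, -100, -6), 0.00669, tolerance = 1e-3)
  # bounded and monotone decreasing for k < 0
  v <- seq(-200, 50, by = 1)
  a <- boltzmann(v, -100, -6)
  expect_true(all(a > 0 & a < 1))
  expect_true(all(diff(a) < 0))
  expect_error(boltzmann(-100, -100, 0), "non-zero")
})

test_that("Gaussian time constant peaks at M with value A + B", {
  expect_equal(tau_gaussian(-80, M = -80, S = 80, A = 1000, B = 60), 1060)
  # one width away from the peak
  expect_equal(tau_gaussian(-80 + 80, -80, 80, 1000, 60), 60 + 1000 / exp(1))
  expect_equal(tau_gaussian(-160, -80, 80, 1000, 60), 427.8794, tolerance = 1e-6)
  v <- seq(-250, 50, by = 0.5)
  tau <- tau_gaussian(v, -80, 40, 250, 40)
  expect_true(all(tau > 40 & tau <= 290))
  expect_equal(v[which.max(tau)], -80)
  expect_error(tau_gaussian(-80, -80, 0, 250, 40), "positive")
})

test_that("parameter validation enforces the component invariants", {
  expect_error(ih_component(-100, -6, -80, -1, 1000, 60, 3), "S")
  expect_error(ih_component(-100, -6, -80, 80, 0, 60, 3), "A")
  expect_error(ih_component(-100, -6, -80, 80, 1000, 0, 3), "B")
  expect_error(ih_component(-100, -6, -80, 80, 1000, 60, -3), "G")
  expect_error(ih_component(-100, 0, -80, 80, 1000, 60, 3), "k")
  expect_silent(validate_ih_params(table1_params()))
})

test_that("step current has the closed-form endpoints and relaxation", {
  p <- table1_params()
  slow <- p[p$component == "slow", ]
  # t -> infinity limit at -150 mV: G * r_inf * (Vs - Eh)
  lim <- ih_step_current(1e7, slow, Vps = -60, Vs = -150)$current
  expect_equal(lim, -341.9, tolerance = 1e-3)
  # t = 0 pinned at the pre-step steady state (~0 for Ih)
  init <- ih_step_current(0, slow, Vps = -60, Vs = -150)$current
  expect_equal(init, 3 * boltzmann(-60, -100, -6) * (-150 + 36))
  expect_lt(abs(init), 1)
  # Vps == Vs: constant trace
  flat <- ih_step_current(seq(0, 1000, 10), slow, Vps = -90, Vs = -90)$current
  expect_equal(flat, rep(flat[1], length(flat)))
  # monotone relaxation between endpoints with tau evaluated at Vs
  tr <- ih_step_current(seq(0, 5000, 1), slow, Vps = -60, Vs = -150)$current
  expect_true(all(diff(tr) < 0))
  tau <- tau_gaussian(-150, -80, 80, 1000, 60)
  at_tau <- ih_step_current(tau, slow, Vps = -60, Vs = -150)$current
  expect_equal((at_tau - lim) / (init - lim), exp(-1), tolerance = 1e-12)
  expect_error(ih_step_current(-1, slow, Vps = -60, Vs = -150), "non-negative")
})

test_that("total current is the sum of components and linear in G", {
  p <- table1_params()
  t <- seq(0, 4000, 5)
  total <- ih_step_current(t, p, Vps = -60, Vs = -150)$current
  by_comp <- ih_step_current(t, p, Vps = -60, Vs = -150, by_component = TRUE)
  expect_equal(total, by_comp$slow + by_comp$fast)
  # zero fast conductance leaves the slow component alone
  p0 <- p
  p0$G[p0$component == "fast"] <- 0
  slow_only <- ih_step_current(t, p0, Vps = -60, Vs = -150)$current
  expect_equal(slow_only, by_comp$slow)
  # doubling both conductances doubles the current
  p2 <- p
  p2$G <- 2 * p2$G
  expect_equal(ih_step_current(t, p2, Vps = -60, Vs = -150)$current, 2 * total)
  # identical parameter sets give exactly twice the single component
  pp <- p[c(1, 1), ]
  pp$component <- c("a", "b")
  slow1 <- ih_step_current(t, p[1, ], Vps = -60, Vs = -150)$current
  expect_equal(ih_step_current(t, pp, Vps = -60, Vs = -150)$current, 2 * slow1)
})

test_that("closed-form step and tail currents agree with an ODE gate oracle", {
  p <- table1_params()
  fast <- p[p$component == "fast", ]
  t_step <- 2000
  prog <- tibble::tibble(V = c(-60, -150, -60), duration = c(500, t_step, 1000))
  oracle <- ode_gate_trace(fast, prog, dt = 0.01)
  # sample a few times within the step and the tail
  for (ts in c(50, 300, 1500)) {
    r_oracle <- oracle$r[which.min(abs(oracle$t - (500 + ts)))]
    i_closed <- ih_step_current(ts, fast, Vps = -60, Vs = -150)$current
    i_oracle <- fast$G * r_oracle * (-150 + 36)
    expect_equal(i_closed, i_oracle, tolerance = 5e-3)
  }
  for (ts in c(20, 100, 400)) {
    r_oracle <- oracle$r[which.min(abs(oracle$t - (500 + t_step + ts)))]
    i_closed <- ih_deactivation_current(ts, fast,
      Vps = -60, Vs = -150,
      t_step = t_step
    )$current
    i_oracle <- fast$G * r_oracle * (-60 + 36)
    expect_equal(i_closed, i_oracle, tolerance = 5e-3)
  }
})

test_that("deactivation limits: zero-duration step and long-step tail", {
  p <- table1_params()
  slow <- p[p$component == "slow", ]
  # zero-duration step: tail identical to holding at Vps
  tail0 <- ih_deactivation_current(seq(0, 500, 1), slow,
    Vps = -60, Vs = -150,
    t_step = 0
  )$current
  hold <- ih_step_current(seq(0, 500, 1), slow, Vps = -60, Vs = -60)$current
  expect_equal(tail0, hold)
  # after an infinitely long step the tail converges back to the pre-step
  # steady state
  lim <- ih_deactivation_current(1e7, slow,
    Vps = -60, Vs = -150,
    t_step = 1e7
  )$current
  expect_equal(lim, slow$G * boltzmann(-60, slow$Vh, slow$k) * (-60 + 36))
})
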