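# Conductance-based vestibular ganglion neuron model: configuration,
# cAMP modulation, integration sanity, firing phenotypes and metrics.

test_that("cAMP modulation transforms the Ih parameters as specified", {
  p <- fig3_params()
  mod <- apply_camp(p)
  # conductances scale by 1.91
  expect_equal(mod$G, p$G * 1.91)
  expect_equal(mod$G[mod$component == "slow"], 3 * 1.91)
  # half-activations shift +12 mV toward depolarisation
  expect_equal(mod$Vh, p$Vh + 12)
  expect_equal(mod$Vh[mod$component == "slow"], -96.6)
  # kinetics divide component-specifically (A and B)
  expect_equal(
    mod$A[mod$component == "slow"] / p$A[p$component == "slow"], 1 / 5.31
  )
  expect_equal(
    (mod$A + mod$B)[mod$component == "fast"] /
      (p$A + p$B)[p$component == "fast"], 1 / 2.87
  )
  # slope, Gaussian location and width untouched
  expect_equal(mod$k, p$k)
  expect_equal(mod$M, p$M)
  expect_equal(mod$S, p$S)
  # identity modulation is a no-op
  id <- camp_modulation(1, 0, 1, 1)
  expect_equal(apply_camp(p, id), p)
  # A-only variant leaves B alone
  mod2 <- apply_camp(p, camp_modulation(divide_base = FALSE))
  expect_equal(mod2$B, p$B)
})

test_that("passive membrane relaxes to the leak reversal", {
  cfg <- neuron_config("sustained",
    ih = NULL, G_Na = 0, G_KH = 0, G_KL = 0
  )
  rs <- resting_state(cfg, t_settle = 1000)
  expect_equal(rs$V, -67, tolerance = 1e-3)
  sim <- simulate_neuron(cfg, stim_none(), t_end = 100)
  expect_equal(sim$trajectory$V, rep(-67, nrow(sim$trajectory)), tolerance = 1e-3)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("gating variables stay within [0,1] under strong stimulation", {
  cfg <- neuron_config("sustained", ih = fig3_params())
  sim <- simulate_neuron(cfg,
    stim_step(-400, onset = 5, duration = 100) +
      stim_step(500, onset = 120, duration = 100),
    t_end = 250, record_gates = TRUE
  )
  g <- as.matrix(sim$trajectory[, ihtrace:::gate_names()])
  expect_true(all(g >= 0 & g <= 1))
})

test_that("sustained phenotype fires repetitively, transient fires once", {
  ih <- fig3_params()
  sus <- neuron_config("sustained", ih = ih)
  tra <- neuron_config("transient", ih = ih)
  expect_equal(sus$G_KL, 0)
  expect_equal(tra$G_KL, 50)
  s1 <- simulate_neuron(sus, stim_step(300, onset = 10, duration = 200), t_end = 250)
  s2 <- simulate_neuron(tra, stim_step(300, onset = 10, duration = 200), t_end = 250)
  expect_gte(nrow(s1$spikes), 3)
  expect_equal(nrow(s2$spikes), 1)
})

test_that("hyperpolarizing steps produce an Ih-dependent sag", {
  ih <- fig3_params()
  cfg <- neuron_config("sustained", ih = ih)
  no_ih <- neuron_config("sustained", ih = NULL)
  stim <- stim_step(-120, onset = 50, duration = 500)
  s_ih <- simulate_neuron(cfg, stim, t_end = 600)
  s_no <- simulate_neuron(no_ih, stim, t_end = 600)
  seg <- function(sim) sim$trajectory$V[sim$trajectory$t > 50 & sim$trajectory$t < 550]
  v_ih <- seg(s_ih)
  # sag: trough early in the step, then relaxation back toward rest
  trough_t <- which.min(v_ih)
  expect_lt(trough_t, 0.6 * length(v_ih))
  sag <- v_ih[length(v_ih)] - min(v_ih)
  expect_gt(sag, 1) # depolarizing sag of at least 1 mV
  # without Ih the voltage stays at its floor (no comparable sag)
  v_no <- seg(s_no)
  sag_no <- v_no[length(v_no)] - min(v_no)
  expect_lt(sag_no, sag / 4)
})

test_that("halving dt leaves spike times essentially unchanged", {
  cfg <- neuron_config("sustained", ih = fig3_params())
  stim <- stim_step(300, onset = 10, duration = 80)
  a <- simulate_neuron(cfg, stim, t_end = 100, dt = 0.01, record_every = 1)
  b <- simulate_neuron(cfg, stim, t_end = 100, dt = 0.005, record_every = 1)
  expect_equal(nrow(a$spikes), nrow(b$spikes))
  expect_lt(max(abs(a$spikes$time - b$spikes$time)), 0.05)
})

test_that("EPSC threshold bisection honours its contract", {
  cfg <- neuron_config("sustained", ih = fig3_params())
  init <- resting_state(cfg)
  thr <- find_threshold_epsc(cfg, init = init, tol_pA = 2)
  fires <- function(amp) {
    sim <- simulate_neuron(cfg, stim_epsc(amp, onset = 1),
      t_end = 30,
      init = init, record_every = 1
    )
    nrow(sim$spikes) >= 1
  }
  expect_true(fires(thr))
  expect_false(fires(0.95 * thr))
  # no sodium conductance, no AP: explicit error (bracket kept within the
  # range where a passive EPSP cannot cross the spike threshold)
  cfg0 <- neuron_config("sustained", ih = fig3_params(), G_Na = 0)
  expect_error(find_threshold_epsc(cfg0, upper = 300), "upper bracket")
})

test_that("metrics recover a constructed double-exponential EPSP", {
  # synthetic trajectory: flat baseline then a double-exponential bump
  t <- seq(0, 80, by = 0.02)
  onset <- 10
  s <- pmax(t - onset, 0)
  v <- -65 + 12 * (exp(-s / 6) - exp(-s / 0.5)) / 0.83 * (t > onset)
  sim <- structure(
    list(
      trajectory = tibble::tibble(t = t, V = v),
      spikes = tibble::tibble(time = numeric(0), peak = numeric(0))
    ),
    class = "ih_sim"
  )
  m <- sim_metrics(sim, stim_onset = onset, double_exp_tol = 0.005)
  expect_equal(m$n_ap, 0)
  expect_true(is.na(m$ap_latency_ms))
  expect_equal(m$resting_mV, -65, tolerance = 0.01)
  expect_equal(m$epsp_amplitude_mV, max(v) + 65, tolerance = 0.05)
  # decay fit should recover the slow constant (single- or double-exp)
  expect_equal(max(m$epsp_decay_ms, m$epsp_decay2_ms, na.rm = TRUE), 6,
    tolerance = 0.25
  )
})

test_that("flat trace yields zero amplitude and no spikes", {
  sim <- structure(
    list(
      trajectory = tibble::tibble(t = seq(0, 50, 0.1), V = rep(-64, 501)),
      spikes = tibble::tibble(time = numeric(0), peak = numeric(0))
    ),
    class = "ih_sim"
  )
  m <- sim_metrics(sim, stim_onset = 10)
  expect_equal(m$n_ap, 0)
  expect_equal(m$epsp_amplitude_mV, 0)
})

test_that("deeper conditioning lowers the release potential and shortens AP latency", {
  ih <- fig3_params()
  cfg <- neuron_config("sustained", ih = ih)
  base <- conditioning_protocol(cfg,
    conditioning = -65, cond_duration = 600,
    epsc_amplitude = NULL
  )
  deep <- conditioning_protocol(cfg,
    conditioning = -105, cond_duration = 600,
    epsc_amplitude = base$epsc_amplitude
  )
  mb <- sim_metrics(base)
  md <- sim_metrics(deep)
  # 5 ms after release from a deep conditioning hold the membrane has not
  # fully recovered: the pre-EPSC potential is more hyperpolarized
  expect_lt(md$resting_mV, mb$resting_mV)
  # yet the accrued Ih drive makes the EPSC-evoked spike come sooner
  expect_gte(mb$n_ap, 1)
  expect_gte(md$n_ap, 1)
  expect_lt(md$ap_latency_ms, mb$ap_latency_ms)
})
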