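# Shared fixtures for the test suite. All synthetic inputs are generated
# in code; sizes are kept small where the property under test allows it.

# a reduced-resolution protocol for tests that only need qualitative
# structure (keeps optimizer-heavy tests fast)
coarse_protocol <- function(t_step = 4000, sample_interval = 4) {
  clamp_protocol(
    t_step = t_step, t_post = 1000,
    sample_interval = sample_interval
  )
}

# one-component parameter table
one_component_params <- function(G = 3) {
  ih_component(
    Vh = -100, k = -6, M = -80, S = 80, A = 1000, B = 60, G = G,
    component = "c1"
  )
}

# forward-Euler ODE oracle for the gate relaxation
# dr/dt = (r_inf(V) - r)/tau_r(V) under a piecewise-constant voltage
# program; independent of the closed-form path under test
ode_gate_trace <- function(params, v_program, dt = 0.01, r0 = NULL) {
  stopifnot(all(c("V", "duration") %in% names(v_program)))
  p <- as.list(params[1, ])
  r <- if (is.null(r0)) boltzmann(v_program$V[1], p$Vh, p$k) else r0
  out_t <- numeric(0)
  out_r <- numeric(0)
  t_now <- 0
  for (i in seq_len(nrow(v_program))) {
    V <- v_program$V[i]
    n <- round(v_program$duration[i] / dt)
    rinf <- boltzmann(V, p$Vh, p$k)
    tau <- tau_gaussian(V, p$M, p$S, p$A, p$B)
    rr <- numeric(n)
    for (j in seq_len(n)) {
      r <- r + dt * (rinf - r) / tau
      rr[j] <- r
    }
    out_t <- c(out_t, t_now + dt * seq_len(n))
    out_r <- c(out_r, rr)
    t_now <- t_now + n * dt
  }
  tibble::tibble(t = out_t, r = out_r)
}
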