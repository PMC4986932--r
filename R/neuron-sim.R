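#' Configure a sustained or transient vestibular ganglion neuron model
#'
#' Single-compartment conductance-based model with a fast sodium current,
#' high- and low-threshold potassium currents, a leak, and up to two Ih
#' components (slow/fast HCN gates) described by [ih_component()] tables.
#' The Na/K gating kinetics follow the cochlear-nucleus model family
#' (Rothman-Manis rate equations); the two firing phenotypes differ only
#' in the low-threshold potassium conductance: `G_KL = 0` nS (sustained,
#' tonic firing) versus `G_KL = 50` nS (transient, single onset spike).
#'
#' Membrane capacitance (12 pF), leak conductance (2 nS) and the sodium
#' conductance (1000 nS) are the cited model family's standard values,
#' not measured quantities, and can be overridden. The Ih kinetic curves
#' are identified at room temperature, so the Ih gate time constants are
#' divided by `Q10^((temperature - recording_temperature)/10)` (about 5.2
#' at the defaults). The Na/K gating rates are used in their native
#' formulation (`q_gates = 1`): dividing them by the same factor
#' abolishes the sustained phenotype's tonic firing through
#' depolarization block, and the phenotypes are defined by reproducing
#' the observed firing patterns. Both factors can be overridden.
#'
#' @param phenotype `"sustained"` or `"transient"`.
#' @param ih An `ih_params` tibble with 0-2 rows labelled slow/fast (a
#'   component is dropped by setting `G = 0` or omitting its row).
#' @param C Membrane capacitance, pF.
#' @param G_Na,G_KH,G_KL,G_l Maximal conductances, nS. `G_KL = NULL`
#'   picks the phenotype default.
#' @param E_Na,E_K,E_h,E_l Reversal potentials, mV.
#' @param temperature,recording_temperature,Q10 Temperature scaling of
#'   the Ih gate kinetics (degrees C; dimensionless Q10).
#' @param q_gates Division factor applied to the Na/K gating time
#'   constants (default 1; see Details).
#' @return A list of class `neuron_config`.
#' @export
neuron_config <- function(phenotype = c("sustained", "transient"),
                          ih = fig3_params(),
                          C = 12, G_Na = 1000, G_KH = 140, G_KL = NULL,
                          G_l = 2, E_Na = 50, E_K = -77, E_h = -36, E_l = -67,
                          temperature = 37, recording_temperature = 22,
                          Q10 = 3, q_gates = 1) {
  phenotype <- match.arg(phenotype)
  if (is.null(G_KL)) G_KL <- if (phenotype == "sustained") 0 else 50
  if (any(c(C, G_Na, G_KH, G_KL, G_l) < 0) || C == 0) {
    stop("capacitance and conductances must be non-negative (C > 0)", call. = FALSE)
  }
  slow <- ih_row_or_zero(ih, "slow")
  fast <- ih_row_or_zero(ih, "fast")
  q <- Q10^((temperature - recording_temperature) / 10)
  structure(
    list(
      phenotype = phenotype,
      C = C, G_Na = G_Na, G_KH = G_KH, G_KL = G_KL, G_l = G_l,
      E_Na = E_Na, E_K = E_K, E_h = E_h, E_l = E_l,
      ih_slow = slow, ih_fast = fast,
      q_gates = q_gates, q_ih = q,
      temperature = temperature, Q10 = Q10
    ),
    class = "neuron_config"
  )
}

#' Calibrated Ih parameters for the rebound-firing study
#'
#' The maximal conductances of the identified slow/fast components were
#' never reported numerically, so the rebound simulations require a
#' calibration. This fixture uses the identified characteristic curves
#' ([fig3_params()], `"results_text"` width assignment) with
#' `G_slow = 2.5` nS and `G_fast = 1.7` nS, chosen once so that the
#' sustained model with the slow component alone fires 1/2/3 rebound APs
#' for increasing durations of a -250 pA step and reaches 1/5/7 APs at
#' -300 pA, while the fast component alone fires exactly one rebound AP
#' for -250 to -350 pA steps of any duration. Simulations of this study
#' run the Ih kinetics as identified (`temperature = 22`): the
#' control-vs-cAMP duration-coding contrast requires slow activation of
#' hundreds of ms at the conditioning potential and disappears if the
#' identified time constants are Q10-accelerated.
#'
#' @return An `ih_params` tibble (slow and fast rows).
#' @export
rebound_study_params <- function() {
  fig3_params("results_text", G_slow = 2.5, G_fast = 1.7)
}

ih_row_or_zero <- function(ih, label) {
  zero <- c(Vh = -100, k = -6, M = -80, S = 80, A = 1000, B = 60, G = 0)
  if (is.null(ih)) {
    return(zero)
  }
  row <- ih[ih$component == label, ]
  if (nrow(row) == 0) {
    return(zero)
  }
  unlist(row[1, c("Vh", "k", "M", "S", "A", "B", "G")])
}

#' Restrict a config to a subset of Ih components
#'
#' Convenience for the component-isolation simulations: returns a copy of
#' the config with only the requested Ih components carried (others get
#' zero conductance).
#'
#' @param config A [neuron_config()].
#' @param components Character subset of `c("slow", "fast")`, possibly
#'   empty.
#' @return A `neuron_config`.
#' @export
with_ih_components <- function(config, components) {
  if (!"slow" %in% components) config$ih_slow["G"] <- 0
  if (!"fast" %in% components) config$ih_fast["G"] <- 0
  config
}

#' cAMP modulation of the Ih components
#'
#' Intracellular cAMP potentiates HCN channels: the maximal conductances
#' of both components grow by a factor 1.91, the activation curves shift
#' 12 mV toward depolarisation (no change in slope), and the kinetics
#' accelerate component-specifically - the fast-component time constants
#' divide by 2.87 and the slow-component ones by 5.31. By default both
#' the Gaussian amplitude `A` and the base `B` are divided (a uniform
#' speed-up of the kinetic curve); set `divide_base = FALSE` to divide
#' only `A`.
#'
#' @param conductance_factor Multiplier on `G` (both components).
#' @param shift_mV Depolarising shift of `Vh`, mV (both components).
#' @param fast_divisor,slow_divisor Kinetic divisors.
#' @param divide_base Divide `B` as well as `A`.
#' @return A list of class `camp_modulation`.
#' @export
camp_modulation <- function(conductance_factor = 1.91, shift_mV = 12,
                            fast_divisor = 2.87, slow_divisor = 5.31,
                            divide_base = TRUE) {
  if (any(c(conductance_factor, fast_divisor, slow_divisor) <= 0)) {
    stop("modulation factors must be positive", call. = FALSE)
  }
  structure(
    list(
      conductance_factor = conductance_factor, shift_mV = shift_mV,
      fast_divisor = fast_divisor, slow_divisor = slow_divisor,
      divide_base = divide_base
    ),
    class = "camp_modulation"
  )
}

#' @rdname camp_modulation
#' @param params An `ih_params` tibble with slow/fast rows.
#' @param mod A `camp_modulation` (identity: factors 1, shift 0).
#' @return `apply_camp()` returns the modulated `ih_params` tibble.
#' @export
apply_camp <- function(params, mod = camp_modulation()) {
  params <- as_ih_params(params)
  out <- params
  out$G <- out$G * mod$conductance_factor
  out$Vh <- out$Vh + mod$shift_mV
  div <- ifelse(out$component == "slow", mod$slow_divisor, mod$fast_divisor)
  out$A <- out$A / div
  if (isTRUE(mod$divide_base)) out$B <- out$B / div
  as_ih_params(out)
}

# ---- stimulus specifications -------------------------------------------

#' Stimulus specifications for neuron simulations
#'
#' `stim_step()` is a rectangular current step (pA; negative =
#' hyperpolarising). `stim_epsc()` is a double-exponential synaptic
#' current (rise 0.05 ms, decay 5 ms by default) normalised so `amplitude`
#' is its peak. `stim_none()` injects nothing. Stimuli combine with `+`.
#'
#' @param amplitude Peak current, pA.
#' @param onset Onset time, ms.
#' @param duration Step duration, ms.
#' @param tau_rise,tau_decay EPSC time constants, ms
#'   (`tau_rise < tau_decay`).
#' @return A list of class `stim_spec`.
#' @export
stim_step <- function(amplitude, onset, duration) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  new_stim(list(list(kind = "step", amplitude = amplitude, onset = onset,
    duration = duration)))
}

#' @rdname stim_step
#' @export
stim_epsc <- function(amplitude, onset, tau_rise = 0.05, tau_decay = 5) {
  if (tau_rise >= tau_decay) stop("tau_rise must be < tau_decay", call. = FALSE)
  new_stim(list(list(kind = "epsc", amplitude = amplitude, onset = onset,
    tau_rise = tau_rise, tau_decay = tau_decay)))
}

#' @rdname stim_step
#' @export
stim_none <- function() new_stim(list())

new_stim <- function(parts) structure(list(parts = parts), class = "stim_spec")

#' @export
`+.stim_spec` <- function(e1, e2) new_stim(c(e1$parts, e2$parts))

# materialise a stim_spec as a per-step current vector
stim_current <- function(stim, dt, n_steps) {
  t <- (seq_len(n_steps) - 1) * dt
  out <- numeric(n_steps)
  for (p in stim$parts) {
    if (p$kind == "step") {
      out <- out + p$amplitude * (t >= p$onset & t < p$onset + p$duration)
    } else if (p$kind == "epsc") {
      s <- pmax(t - p$onset, 0)
      raw <- exp(-s / p$tau_decay) - exp(-s / p$tau_rise)
      tpk <- log(p$tau_decay / p$tau_rise) /
        (1 / p$tau_rise - 1 / p$tau_decay)
      peak <- exp(-tpk / p$tau_decay) - exp(-tpk / p$tau_rise)
      out <- out + (t > p$onset) * p$amplitude * raw / peak
    }
  }
  out
}

# ---- integration -------------------------------------------------------

config_pars <- function(config) {
  c(
    config$C, config$G_Na, config$G_KH, config$G_KL, config$G_l,
    config$E_Na, config$E_K, config$E_h, config$E_l,
    config$q_gates, config$q_ih
  )
}

#' Resting state of a neuron model
#'
#' Integrates the model without stimulation until the voltage settles,
#' returning the resting potential and gate values (used to initialise
#' simulations).
#'
#' @param config A [neuron_config()].
#' @param t_settle Settling time, ms.
#' @param dt Time step, ms.
#' @param v0 Starting voltage, mV.
#' @return A list with `V` (mV) and `gates` (named fractions).
#' @export
resting_state <- function(config, t_settle = 2000, dt = 0.01, v0 = -65) {
  g0 <- vgn_steady_gates(v0, config$ih_slow, config$ih_fast)
  n <- round(t_settle / dt)
  out <- vgn_integrate(
    config_pars(config), config$ih_slow, config$ih_fast,
    v0, g0, dt,
    stim = numeric(n), clamp = rep(NA_real_, n),
    thin = n, record_gates = TRUE
  )
  last <- length(out$V)
  gates <- out$gates[last, ]
  names(gates) <- gate_names()
  list(V = out$V[last], gates = gates)
}

gate_names <- function() c("m", "h", "n", "p", "w", "z", "r_slow", "r_fast")

#' Simulate a neuron model under a stimulus
#'
#' Integrates the membrane equation with exponential-Euler gate updates at
#' a fixed step (default 0.01 ms). Gating is initialised at the model's
#' resting state (or a supplied state), and spikes are detected as upward
#' crossings of the threshold with refractory grouping.
#'
#' @param config A [neuron_config()].
#' @param stim A [stim_step()]/[stim_epsc()] combination.
#' @param t_end Simulated time, ms.
#' @param dt Integration step, ms.
#' @param clamp Optional tibble with columns `from`, `to`, `V` describing
#'   voltage-clamp epochs (ms, mV); the membrane is held at `V` inside
#'   each epoch (used by [conditioning_protocol()]).
#' @param init Optional list `(V, gates)` (e.g. from [resting_state()]).
#' @param record_every Record every k-th step.
#' @param record_gates Include gate trajectories in the output.
#' @param spike_threshold,refractory Spike detection: threshold (mV) and
#'   minimum separation (ms).
#' @return An object of class `ih_sim`: list with `trajectory` (tibble
#'   `t`, `V`, gates if requested), `spikes` (tibble of spike peak times
#'   and peak voltages), `config`, `stim`, `dt`.
#' @export
simulate_neuron <- function(config, stim = stim_none(), t_end, dt = 0.01,
                            clamp = NULL, init = NULL, record_every = 10,
                            record_gates = FALSE,
                            spike_threshold = -10, refractory = 1) {
  if (t_end <= 0 || dt <= 0) stop("t_end and dt must be positive", call. = FALSE)
  n <- round(t_end / dt)
  if (is.null(init)) init <- resting_state(config, dt = dt)
  stim_vec <- stim_current(stim, dt, n)
  clamp_vec <- rep(NA_real_, n)
  if (!is.null(clamp)) {
    t <- (seq_len(n) - 1) * dt
    for (j in seq_len(nrow(clamp))) {
      clamp_vec[t >= clamp$from[j] & t < clamp$to[j]] <- clamp$V[j]
    }
  }
  out <- vgn_integrate(
    config_pars(config), config$ih_slow, config$ih_fast,
    init$V, init$gates, dt, stim_vec, clamp_vec,
    thin = record_every, record_gates = record_gates
  )
  traj <- tibble::tibble(t = out$t, V = out$V)
  if (record_gates) {
    g <- tibble::as_tibble(as.data.frame(out$gates))
    names(g) <- gate_names()
    traj <- dplyr::bind_cols(traj, g)
  }
  spikes <- detect_spikes(traj$t, traj$V,
    threshold = spike_threshold,
    refractory = refractory
  )
  structure(
    list(
      trajectory = traj, spikes = spikes, config = config, stim = stim,
      dt = dt, record_every = record_every
    ),
    class = "ih_sim"
  )
}

#' Detect action potentials in a voltage trajectory
#'
#' Upward crossings of the threshold are grouped within the refractory
#' window; each spike time is the local voltage peak of its crossing.
#'
#' @param t,V Time (ms) and voltage (mV) samples.
#' @param threshold Crossing threshold, mV.
#' @param refractory Minimum spike separation, ms.
#' @return A tibble with columns `time` and `peak` (one row per spike).
#' @export
detect_spikes <- function(t, V, threshold = -10, refractory = 1) {
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  if (length(up) == 0) {
    return(tibble::tibble(time = numeric(0), peak = numeric(0)))
  }
  # group crossings closer than the refractory window
  keep <- c(TRUE, diff(t[up]) > refractory)
  up <- up[keep]
  peaks <- purrr::map_dfr(seq_along(up), function(j) {
    i0 <- up[j]
    i1 <- if (j < length(up)) up[j + 1] else length(V)
    # peak within this crossing's window, bounded by where V falls back
    seg <- i0:i1
    below <- which(V[seg] < threshold & seq_along(seg) > 1)
    if (length(below) > 0) seg <- seg[1:below[1]]
    ipk <- seg[which.max(V[seg])]
    tibble::tibble(time = t[ipk], peak = V[ipk])
  })
  peaks
}

# ---- protocols ---------------------------------------------------------

#' Threshold EPSC amplitude
#'
#' Bisection on the peak amplitude of a double-exponential EPSC for the
#' minimal amplitude that elicits at least one action potential. Callers
#' typically scale the result by 1.10 for a "10% above threshold"
#' stimulus.
#'
#' @param config A [neuron_config()].
#' @param tau_rise,tau_decay EPSC shape, ms.
#' @param lower,upper Bracket, pA (an error is raised if no spike occurs
#'   at `upper`).
#' @param tol_pA Bisection tolerance, pA.
#' @param t_end Simulated window per evaluation, ms.
#' @param dt Integration step, ms.
#' @param init Optional precomputed [resting_state()].
#' @return Threshold amplitude, pA.
#' @export
find_threshold_epsc <- function(config, tau_rise = 0.05, tau_decay = 5,
                                lower = 0, upper = 20000, tol_pA = 1,
                                t_end = 30, dt = 0.01, init = NULL) {
  if (is.null(init)) init <- resting_state(config, dt = dt)
  fires <- function(amp) {
    sim <- simulate_neuron(config,
      stim = stim_epsc(amp, onset = 1, tau_rise = tau_rise, tau_decay = tau_decay),
      t_end = t_end, dt = dt, init = init, record_every = 1
    )
    nrow(sim$spikes) >= 1
  }
  if (!fires(upper)) stop("no action potential at the upper bracket", call. = FALSE)
  lo <- lower
  hi <- upper
  while (hi - lo > tol_pA) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Conditioning protocol: Ih activation followed by an EPSC
#'
#' Reproduces the excitability protocol: the membrane is held at a
#' conditioning potential (default -105 mV) for 500 ms - long enough for
#' the Ih gates to approach steady state - then released to rest for a
#' 5-ms gap, after which a double-exponential EPSC is delivered. The
#' conditioning is applied as a voltage-clamp hold by default; a
#' current-step variant is selected with `mode = "current"` (the
#' conditioning amplitude then is in pA).
#'
#' @param config A [neuron_config()].
#' @param conditioning Conditioning potential (mV, `mode = "voltage"`) or
#'   current amplitude (pA, `mode = "current"`).
#' @param epsc_amplitude EPSC peak, pA; default 1.10 x threshold of the
#'   unconditioned model.
#' @param cond_duration Conditioning duration, ms. A warning is issued
#'   when shorter than three slow-component time constants.
#' @param gap Delay at rest between conditioning offset and EPSC, ms.
#' @param t_after Simulated time after the EPSC, ms.
#' @param mode Conditioning as a voltage hold or a current step.
#' @param dt Integration step, ms.
#' @param record_gates Forwarded to [simulate_neuron()].
#' @return An `ih_sim` with extra fields `epsc_onset` (ms) and
#'   `baseline_index` marking the protocol timing, suitable for
#'   [sim_metrics()].
#' @export
conditioning_protocol <- function(config, conditioning = -105,
                                  epsc_amplitude = NULL,
                                  cond_duration = 500, gap = 5, t_after = 60,
                                  mode = c("voltage", "current"), dt = 0.01,
                                  record_gates = FALSE) {
  mode <- match.arg(mode)
  init <- resting_state(config, dt = dt)
  if (is.null(epsc_amplitude)) {
    thr <- find_threshold_epsc(config, dt = dt, init = init)
    epsc_amplitude <- 1.10 * thr
  }
  tau_slow_peak <- (config$ih_slow[["A"]] + config$ih_slow[["B"]]) / config$q_ih
  if (config$ih_slow[["G"]] > 0 && cond_duration < 3 * tau_slow_peak) {
    warning("conditioning shorter than 3 slow-component time constants; ",
      "Ih may not reach steady state",
      call. = FALSE
    )
  }
  pre <- 20 # ms at rest before conditioning
  epsc_onset <- pre + cond_duration + gap
  t_end <- epsc_onset + t_after
  stim <- stim_epsc(epsc_amplitude, onset = epsc_onset)
  clamp <- NULL
  if (mode == "voltage") {
    clamp <- tibble::tibble(from = pre, to = pre + cond_duration, V = conditioning)
  } else {
    stim <- stim + stim_step(conditioning, onset = pre, duration = cond_duration)
  }
  sim <- simulate_neuron(config,
    stim = stim, t_end = t_end, dt = dt,
    clamp = clamp, init = init, record_every = 1, record_gates = record_gates
  )
  sim$epsc_onset <- epsc_onset
  sim$epsc_amplitude <- epsc_amplitude
  sim
}

#' Rebound firing map over stimulus amplitude and duration
#'
#' Applies hyperpolarising current steps of every (amplitude, duration)
#' combination and counts the action potentials fired after stimulus
#' offset (rebound APs).
#'
#' @param config A [neuron_config()].
#' @param amplitudes Step amplitudes, pA (negative = hyperpolarising).
#' @param durations Step durations, ms.
#' @param t_after Window after stimulus offset in which rebound APs are
#'   counted, ms.
#' @param dt Integration step, ms.
#' @return A tibble with columns `amplitude`, `duration`, `n_ap`.
#' @export
rebound_map <- function(config, amplitudes = c(-250, -300),
                        durations = c(100, 300, 500, 700, 1000),
                        t_after = 400, dt = 0.01) {
  if (any(amplitudes >= 0)) stop("amplitudes must be hyperpolarising (< 0 pA)", call. = FALSE)
  init <- resting_state(config, dt = dt)
  grid <- tidyr::expand_grid(amplitude = amplitudes, duration = durations)
  grid$n_ap <- purrr::pmap_int(grid, function(amplitude, duration) {
    onset <- 20
    sim <- simulate_neuron(config,
      stim = stim_step(amplitude, onset = onset, duration = duration),
      t_end = onset + duration + t_after, dt = dt, init = init,
      record_every = 2
    )
    sum(sim$spikes$time > onset + duration)
  })
  grid
}

#' Response metrics of a simulated protocol
#'
#' Extracts the quantities used to characterise excitability: AP latency
#' (stimulus onset to the first spike peak; `NA` when no spike fired),
#' resting potential (the voltage immediately before the stimulus), EPSP
#' amplitude (peak depolarisation minus baseline) and the EPSP decay time
#' constant from an exponential fit to the falling phase. When a single
#' exponential leaves more than `double_exp_tol` of the falling-phase
#' variance unexplained, a double exponential is fitted and both time
#' constants are reported.
#'
#' @param sim An `ih_sim`, typically from [conditioning_protocol()].
#' @param stim_onset Stimulus onset, ms; defaults to the sim's
#'   `epsc_onset` when present.
#' @param double_exp_tol Fraction of falling-phase variance above which
#'   the double-exponential fit is reported.
#' @return A one-row tibble: `n_ap`, `ap_latency_ms`, `resting_mV`,
#'   `epsp_amplitude_mV`, `epsp_decay_ms` (fast/primary), a second
#'   constant `epsp_decay2_ms` (`NA` unless double-exponential), and
#'   `decay_model` ("single" or "double").
#' @export
sim_metrics <- function(sim, stim_onset = NULL, double_exp_tol = 0.01) {
  stim_onset <- stim_onset %||% sim$epsc_onset
  if (is.null(stim_onset)) stop("stim_onset is required", call. = FALSE)
  traj <- sim$trajectory
  pre <- traj$V[traj$t < stim_onset]
  baseline <- if (length(pre) > 0) pre[length(pre)] else traj$V[1]
  post <- traj[traj$t >= stim_onset, ]
  spikes <- sim$spikes[sim$spikes$time >= stim_onset, ]
  latency <- if (nrow(spikes) > 0) spikes$time[1] - stim_onset else NA_real_

  ipk <- which.max(post$V)
  amp <- post$V[ipk] - baseline
  decay <- c(NA_real_, NA_real_)
  model <- NA_character_
  if (is.finite(amp) && amp > 0.5 && nrow(spikes) == 0) {
    fall <- post[ipk:nrow(post), ]
    y <- fall$V - baseline
    keep <- seq_len(max(which(y > 0.05 * amp)))
    y <- y[keep]
    ts <- fall$t[keep] - fall$t[1]
    fit1 <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log(amp), log(5)),
        fn = function(p) exp(p[1]) * exp(-ts / exp(p[2])) - y
      ),
      error = function(e) NULL
    )
    if (!is.null(fit1)) {
      frac <- sum(fit1$fvec^2) / sum((y - mean(y))^2)
      decay[1] <- exp(fit1$par[2])
      model <- "single"
      if (frac > double_exp_tol) {
        fit2 <- tryCatch(
          minpack.lm::nls.lm(
            par = c(log(amp / 2), log(2), log(amp / 2), log(10)),
            fn = function(p) {
              exp(p[1]) * exp(-ts / exp(p[2])) +
                exp(p[3]) * exp(-ts / exp(p[4])) - y
            }
          ),
          error = function(e) NULL
        )
        if (!is.null(fit2) && sum(fit2$fvec^2) < sum(fit1$fvec^2)) {
          taus <- sort(exp(fit2$par[c(2, 4)]))
          decay <- taus
          model <- "double"
        }
      }
    }
  }
  tibble::tibble(
    n_ap = nrow(spikes),
    ap_latency_ms = latency,
    resting_mV = baseline,
    epsp_amplitude_mV = amp,
    epsp_decay_ms = decay[1],
    epsp_decay2_ms = decay[2],
    decay_model = model
  )
}
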