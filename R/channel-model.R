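#' Construct an Ih component parameter set
#'
#' An Ih (HCN) component is fully described by seven parameters: the
#' Boltzmann activation curve (half-activation voltage `Vh`, slope factor
#' `k`), the Gaussian kinetic curve (voltage of maximal time constant `M`,
#' width `S`, amplitude `A`, base `B`) and the maximal conductance `G`.
#' Units are mV (voltages), ms (times) and nS (conductance) throughout the
#' package, so that conductance times driving force is in pA
#' (1 nS x 1 mV = 1 pA).
#'
#' @param Vh Half-activation voltage (mV).
#' @param k Boltzmann slope factor (mV); negative for a
#'   hyperpolarization-activated current. Must be non-zero.
#' @param M Voltage at which the time constant is maximal (mV).
#' @param S Width of the Gaussian kinetic curve (mV); must be positive.
#' @param A Amplitude of the Gaussian kinetic curve (ms); must be positive.
#' @param B Base (minimum) time constant (ms); must be positive.
#' @param G Maximal conductance (nS); must be non-negative.
#' @param component Label for the component ("slow", "fast", ...).
#'
#' @return A one-row tibble of class `ih_params` with columns
#'   `component, Vh, k, M, S, A, B, G`. Multiple components are represented
#'   by row-binding such tibbles.
#' @export
#' @examples
#' slow <- ih_component(Vh = -100, k = -6, M = -80, S = 80, A = 1000, B = 60, G = 3)
#' ih_activation(c(-130, -70), slow)
ih_component <- function(Vh, k, M, S, A, B, G, component = "slow") {
  p <- tibble::tibble(
    component = as.character(component),
    Vh = as.numeric(Vh), k = as.numeric(k), M = as.numeric(M),
    S = as.numeric(S), A = as.numeric(A), B = as.numeric(B),
    G = as.numeric(G)
  )
  validate_ih_params(p)
  class(p) <- c("ih_params", class(p))
  p
}

#' @rdname ih_component
#' @param x An object to validate as an `ih_params` table.
#' @export
validate_ih_params <- function(x) {
  need <- c("component", "Vh", "k", "M", "S", "A", "B", "G")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("ih_params is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(as.matrix(x[, need[-1]])))) {
    stop("ih_params contains non-finite values", call. = FALSE)
  }
  if (any(x$k == 0)) stop("slope factor k must be non-zero", call. = FALSE)
  if (any(x$S <= 0)) stop("Gaussian width S must be positive", call. = FALSE)
  if (any(x$A <= 0)) stop("kinetic amplitude A must be positive", call. = FALSE)
  if (any(x$B <= 0)) stop("base time constant B must be positive", call. = FALSE)
  if (any(x$G < 0)) stop("maximal conductance G must be non-negative", call. = FALSE)
  if (anyDuplicated(x$component)) {
    stop("component labels must be unique", call. = FALSE)
  }
  invisible(x)
}

as_ih_params <- function(x) {
  validate_ih_params(x)
  if (!inherits(x, "ih_params")) class(x) <- c("ih_params", class(x))
  x
}

#' Boltzmann steady-state activation
#'
#' Steady-state open fraction of an Ih gate,
#' `r_inf(V) = 1 / (1 + exp(-(V - Vh)/k))`. With `k < 0` the curve
#' decreases with voltage, as appropriate for a
#' hyperpolarization-activated current.
#'
#' @param V Membrane voltage(s), mV.
#' @param Vh Half-activation voltage, mV.
#' @param k Slope factor, mV (non-zero).
#' @return Activation fraction(s) in (0, 1).
#' @export
boltzmann <- function(V, Vh, k) {
  if (any(k == 0)) stop("slope factor k must be non-zero", call. = FALSE)
  1 / (1 + exp(-(V - Vh) / k))
}

#' Gaussian voltage dependence of the activation time constant
#'
#' `tau_r(V) = B + A * exp(-(M - V)^2 / S^2)`: a bell-shaped curve peaking
#' at `A + B` ms at `V = M`, with base `B`.
#'
#' @param V Membrane voltage(s), mV.
#' @param M Voltage of the maximum, mV.
#' @param S Width, mV (positive).
#' @param A Amplitude, ms (positive).
#' @param B Base time constant, ms (positive).
#' @return Time constant(s) in ms, in `(B, A + B]`.
#' @export
tau_gaussian <- function(V, M, S, A, B) {
  if (any(S <= 0)) stop("Gaussian width S must be positive", call. = FALSE)
  B + A * exp(-(M - V)^2 / S^2)
}

#' Evaluate the characteristic curves of Ih components
#'
#' Tidy wrappers around [boltzmann()] and [tau_gaussian()] evaluating the
#' activation and kinetic curves of each component in an `ih_params` table.
#'
#' @param V Voltage grid, mV.
#' @param params An `ih_params` tibble (one row per component).
#' @return A tibble with columns `component`, `V` and `activation`
#'   (for `ih_activation`) or `tau` in ms (for `ih_time_constant`).
#' @export
ih_activation <- function(V, params) {
  params <- as_ih_params(params)
  purrr::pmap_dfr(
    params[, c("component", "Vh", "k")],
    function(component, Vh, k) {
      tibble::tibble(component = component, V = V, activation = boltzmann(V, Vh, k))
    }
  )
}

#' @rdname ih_activation
#' @export
ih_time_constant <- function(V, params) {
  params <- as_ih_params(params)
  purrr::pmap_dfr(
    params[, c("component", "M", "S", "A", "B")],
    function(component, M, S, A, B) {
      tibble::tibble(component = component, V = V, tau = tau_gaussian(V, M, S, A, B))
    }
  )
}

#' Closed-form Ih current during a voltage step
#'
#' Under a piecewise-constant voltage-clamp step from a pre-step potential
#' `Vps` to a step potential `Vs`, each Ih component relaxes exponentially
#' from its pre-step steady state towards its step steady state with the
#' time constant evaluated at `Vs`:
#' \deqn{I_h(t) = G [r_\infty(V_s) + (r_\infty(V_{ps}) - r_\infty(V_s))
#'   e^{-t/\tau_r(V_s)}] (V_s - E_h).}
#' `ih_step_current()` evaluates this per component and sums across
#' components (total current); component-resolved output is available with
#' `by_component = TRUE`.
#'
#' @param t Times since step onset, ms (non-negative).
#' @param params An `ih_params` tibble, one row per component.
#' @param Vps Pre-step (holding) potential, mV.
#' @param Vs Step potential, mV.
#' @param Eh Ih reversal potential, mV (default -36).
#' @param r0 Optional initial activation per component (fractions). Default
#'   is the steady state at `Vps`, the appropriate choice when the
#'   pre-step has been held long enough for equilibration.
#' @param by_component Return one column of current per component instead
#'   of their sum.
#' @return A tibble with columns `t` and `current` (pA), or `t` plus one
#'   current column per component when `by_component = TRUE`.
#' @export
#' @examples
#' p <- table1_params()
#' ih_step_current(seq(0, 4000, 10), p, Vps = -60, Vs = -150)
ih_step_current <- function(t, params, Vps, Vs, Eh = -36, r0 = NULL,
                            by_component = FALSE) {
  params <- as_ih_params(params)
  if (any(t < 0)) stop("t must be non-negative (measured from step onset)", call. = FALSE)
  if (is.null(r0)) r0 <- boltzmann(Vps, params$Vh, params$k)
  if (length(r0) != nrow(params)) {
    stop("r0 must supply one initial activation per component", call. = FALSE)
  }
  mat <- step_current_matrix(t, params, Vs, r0, Eh)
  if (by_component) {
    out <- tibble::as_tibble(as.data.frame(mat))
    names(out) <- params$component
    dplyr::bind_cols(tibble::tibble(t = t), out)
  } else {
    tibble::tibble(t = t, current = rowSums(mat))
  }
}

# t x component matrix of currents for a constant-voltage segment starting
# from activations r0; kinetics and driving force evaluated at Vs.
step_current_matrix <- function(t, params, Vs, r0, Eh) {
  rinf <- boltzmann(Vs, params$Vh, params$k)
  tau <- tau_gaussian(Vs, params$M, params$S, params$A, params$B)
  drive <- Vs - Eh
  m <- vapply(seq_len(nrow(params)), function(i) {
    params$G[i] * (rinf[i] + (r0[i] - rinf[i]) * exp(-t / tau[i])) * drive
  }, numeric(length(t)))
  matrix(m, nrow = length(t))
}

# activation reached at time t for each component (same relaxation)
step_activation_at <- function(t, params, Vs, r0) {
  rinf <- boltzmann(Vs, params$Vh, params$k)
  tau <- tau_gaussian(Vs, params$M, params$S, params$A, params$B)
  rinf + (r0 - rinf) * exp(-t / tau)
}

#' Closed-form Ih tail (deactivation) current after a voltage step
#'
#' After the step the command returns to the post-step potential (normally
#' the holding potential). The same symmetric first-order kinetics apply:
#' the gate relaxes from the activation reached at step offset towards the
#' steady state at the post-step potential, with the time constant
#' evaluated at the post-step potential.
#'
#' @param t Times since step offset, ms (non-negative).
#' @inheritParams ih_step_current
#' @param Vpost Post-step potential, mV.
#' @param t_step Duration of the preceding step, ms (used to compute the
#'   activation reached at offset).
#' @return As [ih_step_current()].
#' @export
ih_deactivation_current <- function(t, params, Vps, Vs, t_step, Vpost = Vps,
                                    Eh = -36, by_component = FALSE) {
  params <- as_ih_params(params)
  if (any(t < 0)) stop("t must be non-negative (measured from step offset)", call. = FALSE)
  if (t_step < 0) stop("t_step must be non-negative", call. = FALSE)
  r_on <- boltzmann(Vps, params$Vh, params$k)
  r_off <- step_activation_at(t_step, params, Vs, r_on)
  ih_step_current(t, params, Vps = Vps, Vs = Vpost, Eh = Eh, r0 = r_off,
    by_component = by_component)
}
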