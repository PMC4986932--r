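#' Fit one voltage-clamp trace (single-trace baseline, per-step stage)
#'
#' The classical identification approach fits each trace independently
#' with the step-current model, estimating for the step potential `Vs`
#' one triple per component: maximal conductance `G`, steady-state
#' activation `r` and time constant `tau`. The initial activation is
#' pinned at the steady state of the pre-step potential, which is 0 for
#' Ih, so the fitted model is
#' `I(t) = sum_c G_c r_c (1 - exp(-t/tau_c)) (Vs - Eh)`.
#' Only the product `G_c r_c` is constrained by a single trace; the
#' degeneracy of the split is intrinsic to this baseline and deliberately
#' preserved.
#'
#' Search bounds follow the benchmark convention: `G` within the region's
#' conductance bounds, `r` in `[0, 1]`, and `tau` within
#' `(A + B) * (1 -/+ tol)` of the region centre's peak time constant.
#'
#' @param t,current Sampled trace (ms from step onset, pA).
#' @param Vs Step potential, mV.
#' @param Vps Pre-step potential, mV.
#' @param region A [search_region()]; its components set the model order.
#' @param Eh Ih reversal potential, mV.
#' @param seed Seed for the random initialization inside the bounds.
#' @param init Optional explicit initial vector `(G, r, tau)` per
#'   component, overriding the random draw.
#' @param optimizer `"powell"` (default) or `"lm"`, as in
#'   [full_trace_trial()].
#' @param maxiter Iteration cap.
#' @param line_search Line-search mode of [powell_min()].
#' @param polish Refine the Powell solution with bounded
#'   Levenberg-Marquardt (default `TRUE`).
#' @return A tibble with one row per component: `Vs`, `component`
#'   (labelled by tau ordering, smallest = fast), `G`, `r`, `tau`, the
#'   trace residual sum of squares `rss`, and `flagged` (`TRUE` when
#'   `Vs == Vps`, where amplitude is ~0 and `tau` is unidentifiable).
#' @export
fit_trace <- function(t, current, Vs, Vps, region, Eh = -36, seed = NULL,
                      init = NULL, optimizer = c("powell", "lm"),
                      maxiter = 60, line_search = "bracket", polish = TRUE) {
  optimizer <- match.arg(optimizer)
  if (length(t) != length(current)) stop("t and current lengths differ", call. = FALSE)
  b <- single_trace_bounds(region)
  n_par <- length(b$lower)
  if (length(t) < n_par) stop("fewer samples than parameters", call. = FALSE)
  if (is.null(init)) {
    init <- withr_seed(seed %||% sample.int(2^31 - 1, 1), {
      stats::runif(n_par, b$lower, b$upper)
    })
  }
  drive <- Vs - Eh
  model <- function(theta) {
    m <- matrix(theta, nrow = 3)
    out <- 0
    for (i in seq_len(ncol(m))) {
      out <- out + m[1, i] * m[2, i] * (1 - exp(-t / m[3, i])) * drive
    }
    out
  }
  if (optimizer == "powell") {
    ssq <- function(theta) single_trace_ssq(theta, t, drive, current)
    fit <- powell_min(init, ssq, lower = b$lower, upper = b$upper,
      maxiter = maxiter, line_search = line_search)
    par <- fit$par
    rss <- ssq(par)
    if (polish) {
      pol <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = par, lower = b$lower, upper = b$upper,
          fn = function(theta) model(theta) - current,
          control = minpack.lm::nls.lm.control(maxiter = 60)
        )),
        error = function(e) NULL
      )
      if (!is.null(pol) && sum(pol$fvec^2) <= rss) {
        par <- pol$par
        rss <- sum(pol$fvec^2)
      }
    }
  } else {
    fit <- minpack.lm::nls.lm(
      par = init, lower = b$lower, upper = b$upper,
      fn = function(theta) model(theta) - current,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)
    )
    par <- fit$par
    rss <- sum(fit$fvec^2)
  }
  m <- matrix(par, nrow = 3)
  degenerate <- isTRUE(all.equal(Vs, Vps))
  est <- tibble::tibble(
    Vs = Vs,
    component = b$component,
    G = m[1, ], r = m[2, ], tau = m[3, ],
    rss = rss,
    flagged = degenerate
  )
  # label components by time constant: smallest tau = fast (ties broken
  # by amplitude G * r)
  est <- est[order(-est$tau, -(est$G * est$r)), ]
  est$component <- canonical_labels(nrow(est))
  est
}

single_trace_bounds <- function(region) {
  tol <- region_tol(region)
  rv <- region_vectors(region)
  centre <- vector_to_params(rv$centre, rv$component)
  g_lower <- region$lower[region$param == "G"]
  g_upper <- region$upper[region$param == "G"]
  tau_peak <- centre$A + centre$B
  tau_lower <- pmax(1e-3, tau_peak * (1 - tol))
  tau_upper <- tau_peak * (1 + tol)
  list(
    component = centre$component,
    lower = as.numeric(rbind(g_lower, 0, tau_lower)),
    upper = as.numeric(rbind(g_upper, 1, tau_upper))
  )
}

#' Assemble characteristic-curve parameters from per-step estimates
#'
#' Second stage of the single-trace method: per component, the maximal
#' conductance is the mean of the per-step `G`, the activation points
#' `r(Vs)` are fitted with a Boltzmann curve (yielding `Vh`, `k`) and the
#' time-constant points `tau(Vs)` with a Gaussian curve (yielding `M`,
#' `S`, `A`, `B`). Both curve fits are bounded multi-start nonlinear
#' least squares. Steps flagged as degenerate (zero driving force) are
#' excluded from the curve fits.
#'
#' @param estimates Row-bound output of [fit_trace()] over all steps.
#' @param region A [search_region()] providing curve-parameter bounds.
#' @param restarts Random restarts per curve fit.
#' @param seed Seed for the restarts.
#' @param line_search Line-search mode of [powell_min()].
#' @return An `ih_params` tibble (one row per component) with attribute
#'   `curve_rss` (tibble of per-component Boltzmann/Gaussian residuals).
#' @export
assemble_single <- function(estimates, region, restarts = 5, seed = NULL,
                            line_search = "bracket") {
  usable <- estimates[!estimates$flagged, ]
  n_steps <- length(unique(usable$Vs))
  if (n_steps < 4) stop("need at least 4 usable steps to assemble curves", call. = FALSE)
  seeds <- withr_seed(seed %||% sample.int(2^31 - 1, 1), {
    sample.int(2^31 - 1, 2 * length(unique(usable$component)))
  })
  comps <- unique(usable$component)
  rows <- vector("list", length(comps))
  rss <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    comp <- comps[i]
    e <- usable[usable$component == comp, ]
    reg <- region[region$component == comp, ]
    bfit <- curve_fit_multistart(
      par_names = c("Vh", "k"),
      fn = function(p) boltzmann(e$Vs, p[1], p[2]) - e$r,
      region = reg, restarts = restarts, seed = seeds[2 * i - 1],
      line_search = line_search
    )
    gfit <- curve_fit_multistart(
      par_names = c("M", "S", "A", "B"),
      fn = function(p) tau_gaussian(e$Vs, p[1], p[2], p[3], p[4]) - e$tau,
      region = reg, restarts = restarts, seed = seeds[2 * i],
      line_search = line_search
    )
    rows[[i]] <- tibble::tibble(
      component = comp,
      Vh = bfit$par[1], k = bfit$par[2],
      M = gfit$par[1], S = gfit$par[2], A = gfit$par[3], B = gfit$par[4],
      G = mean(e$G)
    )
    rss[[i]] <- tibble::tibble(
      component = comp, boltzmann_rss = bfit$rss, gaussian_rss = gfit$rss
    )
  }
  out <- as_ih_params(dplyr::bind_rows(rows))
  attr(out, "curve_rss") <- dplyr::bind_rows(rss)
  out
}

# bounded LM curve fit with random restarts; bounds from the region rows
# when available, wide physiological defaults otherwise
curve_fit_multistart <- function(par_names, fn, region = NULL, restarts = 5,
                                 seed = NULL, line_search = "bracket") {
  defaults <- list(
    Vh = c(-250, -10), k = c(-60, -0.1),
    M = c(-250, 0), S = c(1e-3, 300), A = c(1e-3, 6000), B = c(1e-3, 2000)
  )
  lower <- upper <- numeric(length(par_names))
  for (j in seq_along(par_names)) {
    row <- if (!is.null(region)) region[region$param == par_names[j], ] else NULL
    if (!is.null(row) && nrow(row) == 1) {
      lower[j] <- row$lower
      upper[j] <- row$upper
    } else {
      lower[j] <- defaults[[par_names[j]]][1]
      upper[j] <- defaults[[par_names[j]]][2]
    }
  }
  inits <- withr_seed(seed %||% sample.int(2^31 - 1, 1), {
    matrix(stats::runif(restarts * length(lower), lower, upper), nrow = restarts)
  })
  ssq <- function(p) sum(fn(p)^2)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      powell_min(inits[r, ], ssq, lower = lower, upper = upper, maxiter = 60,
        line_search = line_search),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- ssq(fit$par)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("curve fit failed in all restarts", call. = FALSE)
  best
}

#' Single-trace identification pipeline with multi-start trials
#'
#' Runs the complete classical baseline: every trace is fitted
#' independently ([fit_trace()]), the per-step estimates are assembled
#' into characteristic-curve parameters ([assemble_single()]), and the
#' whole pipeline is repeated `n_trials` times from fresh random
#' initializations. Trials are ranked by the summed per-trace residual;
#' the best `keep_fraction` are retained and their parameter tables
#' averaged after canonical relabelling, exactly as for
#' [identify_full()].
#'
#' @inheritParams identify_full
#' @param restarts Random restarts for each Boltzmann/Gaussian curve fit.
#' @return An `ih_fit` object (see [identify_full()]), `method =
#'   "single_trace"`. Trial records additionally carry the per-step
#'   estimate tables.
#' @export
identify_single <- function(traces, region, n_trials = 50, keep_fraction = 0.28,
                            seed = NULL, restarts = 5,
                            optimizer = c("powell", "lm"), maxiter = 60,
                            line_search = "bracket", polish = TRUE) {
  optimizer <- match.arg(optimizer)
  protocol <- traces_protocol(traces)
  Eh <- traces_eh(traces)
  act <- traces[traces$segment == "activation", ]
  by_step <- split(act, factor(act$Vs, levels = protocol$step_voltages))
  trial_seeds <- withr_seed(seed %||% sample.int(2^31 - 1, 1), {
    sample.int(2^31 - 1, n_trials)
  })
  trials <- purrr::map_dfr(trial_seeds, function(s) {
    step_seeds <- withr_seed(s, sample.int(2^31 - 1, length(by_step) + 1))
    est <- purrr::imap_dfr(by_step, function(df, i) {
      fit_trace(df$t, df$current,
        Vs = df$Vs[1], Vps = protocol$v_hold,
        region = region, Eh = Eh,
        seed = step_seeds[match(i, names(by_step))], optimizer = optimizer,
        maxiter = maxiter, line_search = line_search, polish = polish
      )
    })
    params <- assemble_single(est, region,
      restarts = restarts,
      seed = step_seeds[length(step_seeds)], line_search = line_search
    )
    tibble::tibble(
      init = list(NULL),
      estimate = list(params_to_vector(params)),
      rss = sum(est$rss[!duplicated(est$Vs)]),
      converged = TRUE,
      seed = s,
      estimates = list(est)
    )
  })
  # finish_fit expects estimate vectors in region component order; the
  # assembled tables are already labelled canonically, matching
  # search_region centres built from canonical tables
  fit <- finish_fit(trials, region, traces,
    keep_fraction = keep_fraction,
    method = "single_trace", seed = seed
  )
  fit
}
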