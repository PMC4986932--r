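#' Search region for parameter identification
#'
#' Both identification methods draw random initial parameter vectors
#' uniformly inside a box, and constrain the optimization to it. The box
#' is built per parameter as `centre * (1 - tol)` to `centre * (1 + tol)`
#' (sides swapped for negative centres), the conventional "tol = 80%
#' around the true values" region used for the simulation benchmark. For
#' recorded data the centre must be a user-supplied rough estimate.
#'
#' @param centre An `ih_params` tibble giving the region centre (for
#'   benchmarks, the generating parameters).
#' @param tol Half-width of the region as a fraction of the centre value.
#' @return A tibble of class `ih_region` with columns `component`,
#'   `param`, `centre`, `lower`, `upper` (7 rows per component, in the
#'   canonical order Vh, k, M, S, A, B, G).
#' @export
search_region <- function(centre, tol = 0.8) {
  centre <- as_ih_params(centre)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  long <- tidyr::pivot_longer(centre, -"component",
    names_to = "param", values_to = "centre"
  )
  lo <- long$centre * (1 - tol)
  hi <- long$centre * (1 + tol)
  out <- dplyr::mutate(long,
    lower = pmin(lo, hi),
    upper = pmax(lo, hi)
  )
  # keep positivity invariants of S, A, B and non-negativity of G even for
  # tol >= 1, and forbid k from crossing zero
  eps <- 1e-6
  pos <- out$param %in% c("S", "A", "B")
  out$lower[pos] <- pmax(out$lower[pos], eps)
  out$lower[out$param == "G"] <- pmax(out$lower[out$param == "G"], 0)
  kk <- out$param == "k"
  out$upper[kk] <- ifelse(out$centre[kk] < 0, pmin(out$upper[kk], -eps), out$upper[kk])
  out$lower[kk] <- ifelse(out$centre[kk] > 0, pmax(out$lower[kk], eps), out$lower[kk])
  bad <- out$lower >= out$upper
  if (any(bad)) {
    stop("degenerate search region for: ",
      paste(out$param[bad], collapse = ", "),
      call. = FALSE
    )
  }
  attr(out, "tol") <- tol
  class(out) <- c("ih_region", class(out))
  out
}

region_tol <- function(region) attr(region, "tol") %||% 0.8

param_order <- c("Vh", "k", "M", "S", "A", "B", "G")

region_vectors <- function(region) {
  region <- region[order(match(region$component, unique(region$component)),
    match(region$param, param_order)
  ), ]
  list(
    component = region$component[region$param == "Vh"],
    lower = region$lower, upper = region$upper, centre = region$centre
  )
}

vector_to_params <- function(theta, components) {
  k <- length(components)
  stopifnot(length(theta) == 7 * k)
  m <- matrix(theta, nrow = k, byrow = TRUE)
  colnames(m) <- param_order
  p <- tibble::as_tibble(as.data.frame(m))
  p <- dplyr::mutate(p, component = components, .before = 1)
  as_ih_params(p)
}

params_to_vector <- function(params) {
  as.numeric(t(as.matrix(params[, param_order])))
}

# order components slow -> fast by peak time constant A + B
canonical_order <- function(params) {
  params[order(-(params$A + params$B)), ]
}

canonical_labels <- function(n) {
  if (n == 1) "c1" else if (n == 2) c("slow", "fast") else paste0("c", seq_len(n))
}

# relabel a fitted params table canonically (slow = largest A + B)
relabel_components <- function(params) {
  params <- canonical_order(params)
  params$component <- canonical_labels(nrow(params))
  as_ih_params(params)
}

# Fast residual factory for the full-trace objective. Precomputes the
# sample grids and the observed current matrices once; the returned
# closure evaluates model - data for a candidate parameter vector with
# plain matrix arithmetic (the tidy trace representation is too slow for
# an optimizer inner loop).
make_full_objective <- function(traces, region, include_deactivation) {
  protocol <- traces_protocol(traces)
  Eh <- traces_eh(traces)
  rv <- region_vectors(region)
  n_comp <- length(rv$component)
  tt <- protocol_times(protocol, if (include_deactivation) "both" else "activation")
  vs <- protocol$step_voltages
  obs_act <- traces_matrix(traces, "activation")
  obs_tail <- if (include_deactivation) traces_matrix(traces, "deactivation") else NULL
  drive_act <- matrix(vs - Eh, nrow = length(tt$t_act), ncol = length(vs), byrow = TRUE)
  function(theta) {
    pm <- matrix(theta, nrow = n_comp, byrow = TRUE) # rows: comps, cols Vh..G
    act <- matrix(0, length(tt$t_act), length(vs))
    tail <- if (include_deactivation) {
      matrix(0, length(tt$t_tail), length(vs))
    } else {
      NULL
    }
    for (i in seq_len(n_comp)) {
      Vh <- pm[i, 1]; k <- pm[i, 2]; M <- pm[i, 3]; S <- pm[i, 4]
      A <- pm[i, 5]; B <- pm[i, 6]; G <- pm[i, 7]
      r0 <- boltzmann(protocol$v_hold, Vh, k)
      rinf <- boltzmann(vs, Vh, k)
      tau <- tau_gaussian(vs, M, S, A, B)
      decay <- exp(outer(tt$t_act, 1 / tau, function(a, b) -a * b))
      ract <- matrix(rinf, nrow(decay), ncol(decay), byrow = TRUE) +
        matrix(r0 - rinf, nrow(decay), ncol(decay), byrow = TRUE) * decay
      act <- act + G * ract * drive_act
      if (include_deactivation) {
        r_off <- rinf + (r0 - rinf) * exp(-protocol$t_step / tau)
        rinf_p <- boltzmann(protocol$v_post, Vh, k)
        tau_p <- tau_gaussian(protocol$v_post, M, S, A, B)
        dtail <- exp(-tt$t_tail / tau_p)
        rtail <- rinf_p + outer(dtail, r_off - rinf_p)
        tail <- tail + G * rtail * (protocol$v_post - Eh)
      }
    }
    if (include_deactivation) {
      c(act - obs_act, tail - obs_tail)
    } else {
      c(act - obs_act)
    }
  }
}

# scalar sum-of-squares counterpart (compiled hot path, used by Powell)
make_full_ssq <- function(traces, region, include_deactivation) {
  protocol <- traces_protocol(traces)
  Eh <- traces_eh(traces)
  tt <- protocol_times(protocol, if (include_deactivation) "both" else "activation")
  obs_act <- traces_matrix(traces, "activation")
  obs_tail <- if (include_deactivation) {
    traces_matrix(traces, "deactivation")
  } else {
    matrix(0, 0, 0)
  }
  force(tt)
  function(theta) {
    full_trace_ssq(
      theta, tt$t_act, tt$t_tail, protocol$step_voltages,
      protocol$v_hold, protocol$v_post, protocol$t_step, Eh,
      obs_act, obs_tail
    )
  }
}

#' One full-trace identification trial
#'
#' The full-trace method estimates the activation curve, kinetic curve and
#' maximal conductance of every component simultaneously, by nonlinear
#' least squares on all traces of the voltage-clamp experiment at once.
#' One trial draws a random initial parameter vector uniformly inside the
#' search region and minimizes the sum over all traces and sample times of
#' the squared difference between the modelled and observed currents,
#' subject to the region bounds (bounded Levenberg-Marquardt).
#'
#' @param traces An `ih_traces` tibble.
#' @param region An [search_region()] table; its components define the
#'   model order (1, 2 or 3 components).
#' @param seed Integer seed for the random initialization.
#' @param include_deactivation Include the post-step tail segment in the
#'   fitted error (default `TRUE` whenever the trace set carries a tail;
#'   set `FALSE` to fit the activation segment alone).
#' @param init Optional explicit initial vector (overrides random draw).
#' @param optimizer `"powell"` (default; direction-set minimization
#'   followed by a Levenberg-Marquardt polish when `polish = TRUE`) or
#'   `"lm"` (bounded Levenberg-Marquardt on the residual vector alone).
#' @param maxiter Iteration cap (outer iterations for Powell, LM
#'   iterations otherwise).
#' @param polish After the Powell stage, descend to the bottom of the
#'   selected basin with a bounded Levenberg-Marquardt refinement
#'   (default `TRUE`; ignored for `optimizer = "lm"`).
#' @param line_search Line-search mode of [powell_min()].
#' @return A one-row tibble (a trial record) with the initial and final
#'   parameter vectors (list columns), the residual sum of squares `rss`,
#'   a convergence flag and the seed.
#' @export
full_trace_trial <- function(traces, region, seed = NULL,
                             include_deactivation = TRUE, init = NULL,
                             optimizer = c("powell", "lm"), maxiter = 40,
                             polish = TRUE, line_search = "bracket") {
  optimizer <- match.arg(optimizer)
  include_deactivation <- include_deactivation &&
    any(traces$segment == "deactivation")
  rv <- region_vectors(region)
  if (is.null(init)) {
    init <- withr_seed(seed %||% sample.int(2^31 - 1, 1), {
      stats::runif(length(rv$lower), rv$lower, rv$upper)
    })
  }
  if (optimizer == "powell") {
    ssq <- make_full_ssq(traces, region, include_deactivation)
    fit <- powell_min(init, ssq,
      lower = rv$lower, upper = rv$upper,
      maxiter = maxiter, line_search = line_search
    )
    est <- fit$par
    conv <- fit$converged
    if (polish) {
      objective <- make_full_objective(traces, region, include_deactivation)
      pol <- suppressWarnings(minpack.lm::nls.lm(
        par = est, lower = rv$lower, upper = rv$upper, fn = objective,
        control = minpack.lm::nls.lm.control(maxiter = 60)
      ))
      if (sum(pol$fvec^2) <= ssq(est)) {
        est <- pol$par
        conv <- TRUE
      }
    }
    rss <- ssq(est)
  } else {
    objective <- make_full_objective(traces, region, include_deactivation)
    fit <- minpack.lm::nls.lm(
      par = init,
      lower = rv$lower, upper = rv$upper,
      fn = objective,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)
    )
    est <- fit$par
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
  }
  tibble::tibble(
    init = list(init),
    estimate = list(est),
    rss = rss,
    converged = conv,
    seed = seed %||% NA_integer_
  )
}

#' Full-trace identification with multi-start and best-mode selection
#'
#' Runs `n_trials` independent [full_trace_trial()]s from random starting
#' points, retains the fraction of trials with the smallest residual (the
#' first mode of the residual distribution; 14 of 50 at the defaults) and
#' averages their parameter vectors after relabelling components
#' canonically (slow = largest peak time constant A + B).
#'
#' @inheritParams full_trace_trial
#' @param n_trials Number of random-start trials.
#' @param keep_fraction Fraction of trials retained (smallest residuals),
#'   or `"mode"` to detect the first mode of the residual distribution by
#'   the largest gap in the sorted log-residuals.
#' @param seed Master seed; per-trial seeds are spawned from it.
#' @return An object of class `ih_fit`: a list with elements `params`
#'   (the averaged `ih_params` tibble), `trials` (all trial records, with
#'   a `kept` flag and per-trial relabelled parameter tables), `method`,
#'   `region`, `n_components` and the call settings. Use [tidy()] /
#'   [glance()] to extract tidy summaries.
#' @export
#' @examples
#' \donttest{
#' ts <- synthesize_traces(table1_params(), noise_sd = 10, seed = 1)
#' fit <- identify_full(ts, search_region(table1_params(), 0.8),
#'   n_trials = 4, seed = 1
#' )
#' tidy(fit)
#' }
identify_full <- function(traces, region, n_trials = 50, keep_fraction = 0.28,
                          seed = NULL, include_deactivation = TRUE,
                          optimizer = c("powell", "lm"), maxiter = 40,
                          polish = TRUE, line_search = "bracket") {
  optimizer <- match.arg(optimizer)
  if (n_trials < 1) stop("n_trials must be at least 1", call. = FALSE)
  trial_seeds <- withr_seed(seed %||% sample.int(2^31 - 1, 1), {
    sample.int(2^31 - 1, n_trials)
  })
  trials <- purrr::map_dfr(trial_seeds, function(s) {
    full_trace_trial(traces, region,
      seed = s,
      include_deactivation = include_deactivation, optimizer = optimizer,
      maxiter = maxiter, polish = polish, line_search = line_search
    )
  })
  if (!any(trials$converged)) {
    warning("no full-trace trial converged; results use all trials", call. = FALSE)
  }
  finish_fit(trials, region, traces,
    keep_fraction = keep_fraction,
    method = "full_trace", seed = seed,
    include_deactivation = include_deactivation
  )
}

# shared: rank trials, keep first mode, average kept parameter tables
finish_fit <- function(trials, region, traces, keep_fraction, method, seed,
                       include_deactivation = FALSE) {
  components <- region_vectors(region)$component
  trials$params <- purrr::map(trials$estimate, function(th) {
    relabel_components(vector_to_params(th, components))
  })
  n_keep <- if (identical(keep_fraction, "mode")) {
    residual_mode_count(trials$rss)
  } else {
    max(1L, round(nrow(trials) * keep_fraction))
  }
  ord <- order(trials$rss)
  trials$kept <- seq_len(nrow(trials)) %in% ord[seq_len(n_keep)]
  kept_tabs <- trials$params[trials$kept]
  mean_tab <- kept_tabs[[1]]
  if (length(kept_tabs) > 1) {
    arr <- vapply(kept_tabs, function(p) as.matrix(p[, param_order]),
      matrix(0, nrow(mean_tab), length(param_order))
    )
    mean_mat <- apply(arr, c(1, 2), mean)
    mean_tab[, param_order] <- as.data.frame(mean_mat)
  }
  structure(
    list(
      params = as_ih_params(mean_tab),
      trials = trials,
      method = method,
      region = region,
      n_components = nrow(mean_tab),
      keep_fraction = keep_fraction,
      seed = seed,
      include_deactivation = include_deactivation,
      protocol = traces_protocol(traces),
      Eh = traces_eh(traces)
    ),
    class = "ih_fit"
  )
}

# first mode of the residual distribution: trials before the largest
# relative gap in the sorted log residuals (fallback when the gap is at
# the very start: keep at least 2 trials)
residual_mode_count <- function(rss) {
  n <- length(rss)
  if (n < 3) {
    return(n)
  }
  s <- sort(log(rss + .Machine$double.eps))
  gaps <- diff(s)
  cut <- which.max(gaps)
  max(2L, cut)
}

#' Compare model orders (number of Ih components)
#'
#' Fits the trace set with 1-, 2- (and optionally 3-) component models via
#' [identify_full()] and compares the goodness of fit of the retained
#' trials between orders with two-sample t-tests. A higher order is only
#' warranted when its GoF is significantly larger.
#'
#' @inheritParams identify_full
#' @param centre An `ih_params` tibble used to centre the search region of
#'   the largest order; lower orders reuse its first rows.
#' @param orders Integer vector of model orders to compare.
#' @param tol Region half-width fraction.
#' @param alpha Significance level for the pairwise t-tests.
#' @param var_equal Classical Student's t-test (`TRUE`, default) or Welch.
#' @return A list of class `ih_order_report` with `fits` (per order),
#'   `gof` (tibble of per-kept-trial GoF values) and `tests` (pairwise
#'   t-test table).
#' @export
model_order_compare <- function(traces, centre, orders = c(1, 2),
                                tol = 0.8, n_trials = 50, keep_fraction = 0.28,
                                seed = NULL, alpha = 0.05, var_equal = TRUE,
                                maxiter = 60) {
  if (length(orders) < 2) stop("need at least two model orders", call. = FALSE)
  centre <- as_ih_params(canonical_order(centre))
  seeds <- withr_seed(seed %||% sample.int(2^31 - 1, 1), {
    sample.int(2^31 - 1, length(orders))
  })
  fits <- purrr::map2(orders, seeds, function(k, s) {
    ctr <- centre[rep(seq_len(nrow(centre)), length.out = k), ]
    ctr$component <- canonical_labels(k)
    # duplicated rows for orders above the centre's size get perturbed
    # kinetics so the region is not degenerate between components
    if (k > nrow(centre)) {
      extra <- seq(nrow(centre) + 1, k)
      ctr$A[extra] <- ctr$A[extra] / 2
    }
    identify_full(traces, search_region(as_ih_params(ctr), tol),
      n_trials = n_trials, keep_fraction = keep_fraction, seed = s,
      maxiter = maxiter
    )
  })
  names(fits) <- paste0("order", orders)
  gof <- purrr::map2_dfr(orders, fits, function(k, fit) {
    kept <- fit$trials[fit$trials$kept, ]
    tibble::tibble(
      order = k,
      trial = seq_len(nrow(kept)),
      gof = vapply(kept$params, function(p) fit_gof(p, traces, fit), numeric(1))
    )
  })
  pairs <- utils::combn(orders, 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- gof$gof[gof$order == pairs[1, j]]
    b <- gof$gof[gof$order == pairs[2, j]]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    tibble::tibble(
      order_a = pairs[1, j], order_b = pairs[2, j],
      mean_gof_a = mean(a), mean_gof_b = mean(b),
      p_value = tt$p.value, significant = tt$p.value < alpha
    )
  })
  structure(list(fits = fits, gof = gof, tests = tests, alpha = alpha),
    class = "ih_order_report"
  )
}

# combined-current GoF of a parameter table against the observed traces
fit_gof <- function(params, traces, fit) {
  segment <- if (isTRUE(fit$include_deactivation)) "both" else "activation"
  keep <- traces$segment %in%
    (if (segment == "both") c("activation", "deactivation") else "activation")
  model <- noiseless_traces(params, fit$protocol, Eh = fit$Eh, segment = segment)
  goodness_of_fit(traces$current[keep], model$current)
}
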