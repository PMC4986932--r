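#' Tidy summaries of fits and reports
#'
#' `tidy()` on an `ih_fit` returns the final averaged parameters in long
#' form (`component`, `param`, `estimate`); on an `ih_error_report` the
#' per-parameter mean errors; on an `ih_method_comparison` the combined
#' error table of both methods. `glance()` on an `ih_fit` returns one row
#' of fit-level summaries (method, model order, trials, kept, best/median
#' residual).
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ih_fit <- function(x, ...) {
  tidyr::pivot_longer(x$params, -"component",
    names_to = "param", values_to = "estimate"
  )
}

#' @rdname tidy.ih_fit
#' @export
tidy.ih_error_report <- function(x, ...) x$errors

#' @rdname tidy.ih_fit
#' @export
tidy.ih_method_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$reports$single$errors, method = "single_trace"),
    dplyr::mutate(x$reports$full$errors, method = "full_trace")
  )
}

#' @rdname tidy.ih_fit
#' @export
glance.ih_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_components = x$n_components,
    n_trials = nrow(x$trials),
    n_kept = sum(x$trials$kept),
    min_rss = min(x$trials$rss),
    median_rss = stats::median(x$trials$rss),
    converged_fraction = mean(x$trials$converged)
  )
}

#' @rdname tidy.ih_fit
#' @export
glance.ih_method_comparison <- function(x, ...) {
  tibble::tibble(
    method = x$grand$method,
    grand_mean_error = x$grand$grand_mean_error,
    combined_gof = x$gof$gof[x$gof$scope == "combined"][
      match(x$grand$method, x$gof$method[x$gof$scope == "combined"])
    ]
  )
}

#' @export
print.ih_fit <- function(x, ...) {
  cat("<ih_fit> ", x$method, ", ", x$n_components, " component(s), ",
    nrow(x$trials), " trials (", sum(x$trials$kept), " kept)\n",
    sep = ""
  )
  print(x$params)
  invisible(x)
}

#' @export
print.ih_error_report <- function(x, ...) {
  cat("<ih_error_report> ", x$method, ": grand mean error ",
    sprintf("%.2f%%", x$grand_mean), "\n",
    sep = ""
  )
  print(x$errors)
  invisible(x)
}

#' @export
print.ih_method_comparison <- function(x, ...) {
  cat("<ih_method_comparison>\n")
  print(x$grand)
  print(x$gof)
  invisible(x)
}

#' Plot methods for traces, fits, sweeps and simulations
#'
#' `autoplot()` renders the standard diagnostic figure for each result
#' type: trace sets as current-vs-time panels per step potential; fits as
#' the identified activation and kinetic characteristic curves (against
#' reference curves when supplied); sweeps as error-vs-swept-variable
#' panels; simulations as the voltage trajectory with spike markers.
#'
#' @param object An `ih_traces`, `ih_fit`, `ih_sweep` or `ih_sim`.
#' @param ... Unused.
#' @param reference Optional `ih_params` overlaid as dashed reference
#'   curves (`ih_fit` method).
#' @param V Voltage grid for the characteristic curves, mV.
#' @return A ggplot object.
#' @name autoplot-ihtrace
NULL

#' @rdname autoplot-ihtrace
#' @export
autoplot.ih_traces <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$t, y = .data$current, group = .data$Vs,
      colour = factor(.data$Vs))
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time from step onset (ms)", y = "current (pA)",
      colour = "step (mV)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ihtrace
#' @export
autoplot.ih_fit <- function(object, reference = NULL,
                            V = seq(-160, -40, by = 1), ...) {
  act <- dplyr::mutate(ih_activation(V, object$params), curve = "activation")
  kin <- dplyr::mutate(ih_time_constant(V, object$params), curve = "kinetic")
  kin$value <- kin$tau
  act$value <- act$activation
  df <- dplyr::bind_rows(
    act[, c("component", "V", "curve", "value")],
    kin[, c("component", "V", "curve", "value")]
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$V, .data$value,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "voltage (mV)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ract <- dplyr::mutate(ih_activation(V, reference), curve = "activation",
      value = .data$activation)
    rkin <- dplyr::mutate(ih_time_constant(V, reference), curve = "kinetic",
      value = .data$tau)
    rdf <- dplyr::bind_rows(
      ract[, c("component", "V", "curve", "value")],
      rkin[, c("component", "V", "curve", "value")]
    )
    gg <- gg + ggplot2::geom_line(data = rdf, linetype = "dashed")
  }
  gg
}

#' @rdname autoplot-ihtrace
#' @export
autoplot.ih_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$error,
    colour = .data$method,
    linetype = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(
      x = unique(object$variable), y = "identification error (%)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ihtrace
#' @export
autoplot.ih_sim <- function(object, ...) {
  gg <- ggplot2::ggplot(
    object$trajectory,
    ggplot2::aes(.data$t, .data$V)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
  if (nrow(object$spikes) > 0) {
    gg <- gg + ggplot2::geom_point(
      data = object$spikes,
      ggplot2::aes(.data$time, .data$peak), colour = "red", size = 1
    )
  }
  gg
}

#' @export
print.ih_sim <- function(x, ...) {
  cat("<ih_sim> ", x$config$phenotype, " neuron, ",
    max(x$trajectory$t), " ms, ", nrow(x$spikes), " spike(s)\n",
    sep = ""
  )
  invisible(x)
}
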