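#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-layer summary of an optimized plan
#'
#' @param x an `elo_plan`.
#' @param ... unused.
#' @return Tibble with one row per energy layer: `layer_id`, `beam_id`,
#'   `energy_index`, `selected`, `n_spots_active`, `total_intensity`.
#' @method tidy elo_plan
#' @export
tidy.elo_plan <- function(x, ...) {
  case <- x$case
  lids <- rep(seq_along(case$influence$n_spots_per_layer),
    times = case$influence$n_spots_per_layer
  )
  dplyr::mutate(
    case$layers,
    selected = x$s == 1L,
    n_spots_active = as.integer(tapply(x$x > 0, lids, sum)),
    total_intensity = as.numeric(tapply(x$x, lids, sum))
  )
}

#' One-row summary of an optimized plan
#'
#' @param x an `elo_plan`.
#' @param ... unused.
#' @return Tibble with `mode`, `objective`, `ne`, `n_layers_active`,
#'   `n_spots_active`, `primal_residual`, `robust`, `n_scenarios`.
#' @method glance elo_plan
#' @export
glance.elo_plan <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    objective = x$f,
    ne = x$ne,
    n_layers_active = sum(x$s),
    n_spots_active = sum(x$x > 0),
    primal_residual = if (length(x$primal_residuals)) {
      x$primal_residuals[length(x$primal_residuals)]
    } else {
      NA_real_
    },
    robust = x$robust,
    n_scenarios = x$n_scenarios
  )
}

#' Convergence plot of an optimized plan
#'
#' Plan objective value per outer iterative-convex-relaxation iteration.
#'
#' @param object an `elo_plan`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot elo_plan
#' @export
autoplot.elo_plan <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$objective_history),
    objective = object$objective_history
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "outer iteration", y = "plan objective f",
      title = sprintf("Convergence (%s)", object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cumulative dose-volume histograms
#'
#' @param object an `elo_dvh` tibble from [dvh_curve()] (curves for several
#'   structures may be row-bound first).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot elo_dvh
#' @export
autoplot.elo_dvh <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$dose, y = 100 * .data$volume_fraction,
      colour = .data$structure
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "dose (% of prescription)", y = "volume (%)",
      colour = "structure"
    ) +
    ggplot2::theme_minimal()
}

#' Evaluation trace of a layer-count selection
#'
#' @param x an `elo_ne_selection`.
#' @param ... unused.
#' @return The trace tibble (`ne`, `error`, `phase`).
#' @method tidy elo_ne_selection
#' @export
tidy.elo_ne_selection <- function(x, ...) x$trace

#' One-row summary of a layer-count selection
#'
#' @param x an `elo_ne_selection`.
#' @param ... unused.
#' @return Tibble with `ne`, `error`, `epsilon`, `n_evaluations`, `warning`.
#' @method glance elo_ne_selection
#' @export
glance.elo_ne_selection <- function(x, ...) {
  tibble::tibble(
    ne = x$ne, error = x$error, epsilon = x$epsilon,
    n_evaluations = nrow(x$trace), warning = x$warning
  )
}

#' Plot the layer-count selection trace
#'
#' Relative objective error at every evaluated layer count, colored by
#' workflow phase, with the threshold and the selected count marked.
#'
#' @param object an `elo_ne_selection`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot elo_ne_selection
#' @export
autoplot.elo_ne_selection <- function(object, ...) {
  ggplot2::ggplot(
    object$trace,
    ggplot2::aes(x = .data$ne, y = .data$error, colour = .data$phase)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$epsilon, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$ne, linetype = "dotted") +
    ggplot2::labs(
      x = "number of energy layers", y = "relative objective error",
      colour = "phase"
    ) +
    ggplot2::theme_minimal()
}

#' Delivery-time breakdown as a tibble
#'
#' @param x an `elo_delivery_time`.
#' @param ... unused.
#' @return Tibble with `component`, `seconds`.
#' @method tidy elo_delivery_time
#' @export
tidy.elo_delivery_time <- function(x, ...) {
  tibble::tibble(
    component = c("elst", "sspt", "sswt", "total"),
    seconds = c(x$elst_s, x$sspt_s, x$sswt_s, x$total_s)
  )
}

#' QUBO solution as a tibble
#'
#' @param x a `qubo_solution`.
#' @param ... unused.
#' @return Tibble with `variable`, `value`.
#' @method tidy qubo_solution
#' @export
tidy.qubo_solution <- function(x, ...) {
  tibble::tibble(variable = seq_along(x$s), value = x$s)
}

#' @importFrom rlang .data
NULL
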