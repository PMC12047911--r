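#' Relative plan-objective error between a reduced-layer plan and the baseline
#'
#' `|f_qc - f_impt| / f_impt`: the quantity the layer-count selection
#' workflow thresholds against epsilon.
#'
#' @param f_qc objective value of the reduced-layer plan.
#' @param f_impt objective value of the all-layers baseline; must be > 0.
#' @return Nonnegative scalar.
#' @export
relative_error <- function(f_qc, f_impt) {
  if (f_impt <= 0) stop("baseline objective must be > 0", call. = FALSE)
  abs(f_qc - f_impt) / f_impt
}

#' Configuration of the layer-count selection workflow
#'
#' @param epsilon relative-error threshold (default 0.1).
#' @param increment ascent step for the coarse upward search (default 5).
#' @param ne_floor smallest layer count ever considered (default 1).
#' @return A list of class `elo_ne_config`.
#' @export
ne_config <- function(epsilon = 0.1, increment = 5L, ne_floor = 1L) {
  stopifnot(epsilon > 0, increment >= 1, ne_floor >= 1)
  structure(
    list(
      epsilon = epsilon, increment = as.integer(increment),
      ne_floor = as.integer(ne_floor)
    ),
    class = "elo_ne_config"
  )
}

# Caching wrapper: evaluate_error(ne) is called at most once per ne; every
# evaluation is appended to the trace.
make_cached_evaluator <- function(evaluate_error) {
  cache <- new.env(parent = emptyenv())
  trace <- new.env(parent = emptyenv())
  trace$rows <- list()
  list(
    error_at = function(ne, phase) {
      key <- as.character(ne)
      if (!is.null(cache[[key]])) {
        return(cache[[key]])
      }
      err <- evaluate_error(ne)
      cache[[key]] <- err
      trace$rows[[length(trace$rows) + 1L]] <-
        tibble::tibble(ne = as.integer(ne), error = err, phase = phase)
      err
    },
    trace = function() dplyr::bind_rows(trace$rows)
  )
}

#' Bisection lower bound for the number of energy layers
#'
#' Starting from the layer count of the baseline plan, repeatedly halves the
#' candidate count (ceiling rounding) and evaluates the relative objective
#' error, stopping at the first count whose error exceeds `epsilon`. If no
#' halved count ever exceeds the threshold the floor is returned.
#'
#' @param evaluate_error function `ne -> relative error` (typically wraps
#'   [run_qc()] against a solved [run_impt()] baseline).
#' @param n_start layer count of the baseline.
#' @param config an [ne_config()].
#' @return Integer lower bound with the evaluation trace attached as
#'   attribute `"trace"`.
#' @export
find_lower_bound <- function(evaluate_error, n_start, config = ne_config()) {
  ev <- make_cached_evaluator(evaluate_error)
  lb <- find_lower_bound_impl(ev, n_start, config)
  structure(lb, trace = ev$trace())
}

find_lower_bound_impl <- function(ev, n_start, config) {
  ne <- as.integer(n_start)
  if (ne <= config$ne_floor) {
    return(config$ne_floor)
  }
  repeat {
    ne <- max(as.integer(ceiling(ne / 2)), config$ne_floor)
    err <- ev$error_at(ne, "bisection")
    if (err > config$epsilon) {
      return(ne)
    }
    if (ne <= config$ne_floor) {
      return(config$ne_floor)
    }
  }
}

#' Select the number of active energy layers
#'
#' The practical workflow: a bisection descent finds a lower bound where the
#' relative objective error first exceeds `epsilon`; a coarse ascent in
#' steps of `increment` finds the first count meeting the threshold; a
#' unit-step scan of the bracketing interval then returns the smallest count
#' whose error is within `epsilon`. Every count is evaluated at most once.
#'
#' @inheritParams find_lower_bound
#' @param n_start baseline layer count; also the upper cap (returned with a
#'   warning if no count meets the threshold).
#' @return A list of class `elo_ne_selection`: `ne` (selected count), `error`
#'   (its relative error), `trace` (tibble of all evaluations: `ne`, `error`,
#'   `phase`), `epsilon`, `warning`.
#' @export
select_ne <- function(evaluate_error, n_start, config = ne_config()) {
  ev <- make_cached_evaluator(evaluate_error)
  n_start <- as.integer(n_start)
  warn <- FALSE

  lb <- find_lower_bound_impl(ev, n_start, config)
  err_lb <- ev$error_at(lb, "bisection")

  if (err_lb <= config$epsilon) {
    ne_star <- lb
  } else {
    # coarse ascent to the first passing count
    lower <- lb
    upper <- NA_integer_
    ne <- lb
    while (is.na(upper)) {
      ne <- min(ne + config$increment, n_start)
      err <- ev$error_at(ne, "ascent")
      if (err <= config$epsilon) {
        upper <- ne
      } else if (ne >= n_start) {
        warn <- TRUE
        upper <- n_start
      } else {
        lower <- ne
      }
    }
    # fine-tune: smallest count in (lower, upper] meeting the threshold
    ne_star <- upper
    if (!warn) {
      for (cand in seq(lower + 1L, upper)) {
        if (ev$error_at(cand, "fine_tune") <= config$epsilon) {
          ne_star <- cand
          break
        }
      }
    }
  }
  if (warn) {
    warning(sprintf(
      "no layer count <= %d meets epsilon = %g; returning %d",
      n_start, config$epsilon, n_start
    ))
  }
  structure(
    list(
      ne = as.integer(ne_star), error = ev$error_at(ne_star, "final"),
      trace = ev$trace(), epsilon = config$epsilon, warning = warn
    ),
    class = "elo_ne_selection"
  )
}

#' @export
print.elo_ne_selection <- function(x, ...) {
  cat(sprintf(
    "<elo_ne_selection: ne = %d (relative error %.3g, epsilon %.3g), %d evaluations%s>\n",
    x$ne, x$error, x$epsilon, nrow(x$trace),
    if (x$warning) ", threshold never met" else ""
  ))
  invisible(x)
}

#' Select the layer count for a case by running the optimizer
#'
#' Convenience wrapper that solves the all-layers baseline with
#' [run_impt()], counts its active layers as the starting point, and drives
#' [select_ne()] with an evaluator that runs [run_qc()] at each candidate
#' count under a fixed seed.
#'
#' @param case an `elo_case`.
#' @param terms objective terms.
#' @param config workflow [ne_config()].
#' @param opt_config optimizer [admm_config()].
#' @param qubo_method QUBO backend passed to [run_qc()].
#' @param scenarios optional `elo_scenarios`.
#' @return An `elo_ne_selection` with the chosen plan attached as `$plan` and
#'   the baseline as `$baseline`.
#' @export
select_ne_case <- function(case, terms = default_objective_terms(case),
                           config = ne_config(), opt_config = admm_config(),
                           qubo_method = "exact", scenarios = NULL) {
  baseline <- run_impt(case, terms, opt_config, scenarios = scenarios)
  if (baseline$f <= 0) stop("baseline objective is zero; selection is degenerate", call. = FALSE)
  n_start <- sum(tapply(baseline$x,
    rep(seq_along(case$influence$n_spots_per_layer),
      times = case$influence$n_spots_per_layer
    ),
    function(v) any(v > 0)
  ))
  plans <- new.env(parent = emptyenv())
  evaluator <- function(ne) {
    p <- run_qc(case, ne, terms, opt_config,
      qubo_method = qubo_method,
      scenarios = scenarios
    )
    plans[[as.character(ne)]] <- p
    relative_error(p$f, baseline$f)
  }
  sel <- select_ne(evaluator, n_start, config)
  sel$plan <- plans[[as.character(sel$ne)]]
  sel$baseline <- baseline
  sel
}
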