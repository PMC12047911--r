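#' Optimizer configuration
#'
#' Parameters of the iterative-convex-relaxation (ICR) outer loop, the inner
#' ADMM sweeps, the conjugate-gradient (CG) x-step, and the minimum monitor
#' unit (MMU) threshold.
#'
#' The augmented-Lagrangian weights are chosen dimension-free: `mu1` (the
#' x = z split weight) defaults to `mu1_scale` times an estimate of the
#' squared spectral norm of the stacked objective matrix, obtained by power
#' iteration; `mu2` (the layer-cardinality penalty) defaults to `mu2_scale`
#' times the mean squared column norm of the layer-dose matrix B at the
#' first binary step.
#'
#' @param mu1,mu2 explicit augmented-term weights; `NULL` (default) means the
#'   scaled estimates described above.
#' @param mu1_scale,mu2_scale scale factors for the estimated weights.
#' @param g_min MMU threshold: every delivered spot intensity must be 0 or at
#'   least `g_min` (intensity units).
#' @param cg_tol relative residual tolerance of the CG x-step.
#' @param cg_max_iter CG iteration cap.
#' @param admm_max_iter inner ADMM sweeps per outer ICR iteration.
#' @param icr_outer_iter outer ICR iterations (active-set refreshes).
#' @param primal_tol target for the primal residual `||x - z||`.
#' @param seed integer seed for the stochastic QUBO backends.
#' @return A list of class `elo_admm_config`.
#' @export
admm_config <- function(mu1 = NULL, mu2 = NULL,
                        mu1_scale = 0.05, mu2_scale = 1,
                        g_min = 1, cg_tol = 1e-6, cg_max_iter = 100L,
                        admm_max_iter = 6L, icr_outer_iter = 15L,
                        primal_tol = 1e-3, seed = 1L) {
  stopifnot(
    mu1_scale > 0, mu2_scale > 0, g_min > 0, cg_tol > 0, cg_tol < 1,
    cg_max_iter >= 1, admm_max_iter >= 1, icr_outer_iter >= 1, primal_tol > 0
  )
  structure(
    list(
      mu1 = mu1, mu2 = mu2, mu1_scale = mu1_scale, mu2_scale = mu2_scale,
      g_min = g_min, cg_tol = cg_tol, cg_max_iter = as.integer(cg_max_iter),
      admm_max_iter = as.integer(admm_max_iter),
      icr_outer_iter = as.integer(icr_outer_iter),
      primal_tol = primal_tol, seed = as.integer(seed)
    ),
    class = "elo_admm_config"
  )
}

#' Project intensities onto the minimum-monitor-unit feasible set
#'
#' Componentwise Euclidean projection onto `{0} U [g_min, Inf)`: values below
#' `g_min / 2` map to 0, values in `[g_min / 2, g_min)` map to `g_min`, and
#' values at or above `g_min` are unchanged. The tie at exactly `g_min / 2`
#' (equidistant from both pieces) resolves to `g_min`, keeping the spot
#' deliverable.
#'
#' @param v numeric vector.
#' @param g_min positive MMU threshold.
#' @return Projected vector, same length as `v`.
#' @export
project_mmu <- function(v, g_min) {
  if (g_min <= 0) stop("g_min must be > 0", call. = FALSE)
  out <- v
  out[v < g_min] <- ifelse(v[v < g_min] >= g_min / 2, g_min, 0)
  out
}

#' Assemble the scaled stacked objective matrix and target vector
#'
#' Stacks, per scenario and per objective term with a non-empty active set,
#' the active-voxel rows of the dose-influence matrix, each row block scaled
#' by `sqrt(w_s * omega / |Omega|)` so that `||A x - b||^2` equals the
#' (scenario-weighted) plan objective at the current active sets. Columns
#' belonging to layer `i` are multiplied by the binary selection `s[i]`.
#'
#' @param scenario_list list of influence lists (one per scenario; a single
#'   nominal case is a length-1 list).
#' @param weights scenario weights summing to 1.
#' @param active_list list (per scenario) of `elo_active_sets`.
#' @param terms objective terms.
#' @param s binary layer-selection vector, or `NULL` for all ones.
#' @return List with sparse `A` (dgCMatrix), numeric `b`, and `layer_cols`
#'   (list of column index vectors per layer).
#' @export
assemble_scaled_matrix <- function(scenario_list, weights, active_list, terms,
                                   s = NULL) {
  n_layers <- length(scenario_list[[1]]$blocks)
  ofs <- layer_offsets(scenario_list[[1]])
  layer_cols <- lapply(seq_len(n_layers), function(i) {
    if (ofs[i + 1] > ofs[i]) (ofs[i] + 1L):ofs[i + 1] else integer(0)
  })
  rows <- list()
  bs <- list()
  k <- 0L
  for (sc in seq_along(scenario_list)) {
    D <- do.call(cbind, scenario_list[[sc]]$blocks)
    for (ti in seq_along(terms)) {
      om <- active_list[[sc]][[ti]]
      tm <- terms[[ti]]
      if (length(om) == 0 || tm$weight == 0) next
      w <- sqrt(weights[sc] * tm$weight / length(om))
      k <- k + 1L
      rows[[k]] <- D[om, , drop = FALSE] * w
      bs[[k]] <- rep(w * tm$dose_level, length(om))
    }
  }
  if (k == 0L) stop("all active sets are empty: nothing to fit", call. = FALSE)
  A <- do.call(rbind, rows)
  b <- unlist(bs, use.names = FALSE)
  if (!is.null(s)) {
    A <- scale_layer_columns(A, layer_cols, s)
  }
  list(A = A, b = b, layer_cols = layer_cols)
}

scale_layer_columns <- function(A, layer_cols, s) {
  if (all(s == 1)) {
    return(A)
  }
  d <- rep(1, ncol(A))
  for (i in seq_along(layer_cols)) {
    if (s[i] == 0) d[layer_cols[[i]]] <- 0
  }
  A %*% Matrix::Diagonal(x = d)
}

# Power-iteration estimate of ||A||^2 (largest eigenvalue of A^T A).
estimate_sq_norm <- function(A, iters = 12L) {
  set.seed(0L)
  v <- stats::rnorm(ncol(A))
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(iters)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    if (lam <= 0) {
      return(1)
    }
    v <- w / lam
  }
  lam
}

#' Solve the regularized normal equations by conjugate gradient
#'
#' Solves `(A^T A + mu1 I) x = A^T b + mu1 (z - lambda1)` — the first-order
#' condition of the ADMM x-step — using only matrix-vector products with `A`
#' and its transpose. The system matrix is positive definite for any
#' `mu1 > 0`.
#'
#' @param A sparse or dense matrix.
#' @param b target vector (length `nrow(A)`).
#' @param z,lambda1 auxiliary and dual vectors (length `ncol(A)`).
#' @param mu1 positive split weight.
#' @param cg_tol relative residual tolerance.
#' @param cg_max_iter iteration cap; on non-convergence the best iterate is
#'   returned with a warning and `attr(x, "converged") = FALSE`.
#' @param x0 optional warm start.
#' @return The solution vector with attributes `converged` and `iterations`.
#' @export
solve_x <- function(A, b, z, lambda1, mu1, cg_tol = 1e-6, cg_max_iter = 200L,
                    x0 = NULL) {
  stopifnot(mu1 > 0)
  n <- ncol(A)
  op <- function(v) as.numeric(Matrix::crossprod(A, A %*% v)) + mu1 * v
  rhs <- as.numeric(Matrix::crossprod(A, b)) + mu1 * (z - lambda1)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  r <- rhs - op(x)
  p <- r
  rs <- sum(r^2)
  rhs_norm <- sqrt(sum(rhs^2))
  if (rhs_norm == 0) {
    out <- numeric(n)
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    return(out)
  }
  converged <- sqrt(rs) <= cg_tol * rhs_norm
  it <- 0L
  while (!converged && it < cg_max_iter) {
    it <- it + 1L
    Ap <- op(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    converged <- sqrt(rs_new) <= cg_tol * rhs_norm
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (!converged) {
    warning(sprintf(
      "CG did not reach tol %.1e within %d iterations (residual %.2e)",
      cg_tol, cg_max_iter, sqrt(rs) / rhs_norm
    ))
  }
  attr(x, "converged") <- converged
  attr(x, "iterations") <- it
  x
}

#' Update the ADMM dual variables
#'
#' `lambda1 <- lambda1 + x - z` (componentwise, for the x = z split) and
#' `lambda2 <- lambda2 + sum(s) - ne` (scalar, for the layer-count
#' constraint).
#'
#' @param lambda1 dual vector; `x`, `z` primal iterates.
#' @param lambda2 scalar dual; `s` binary selection; `ne` target layer count.
#' @return List with updated `lambda1`, `lambda2`.
#' @export
update_duals <- function(lambda1, x, z, lambda2, s, ne) {
  list(lambda1 = lambda1 + x - z, lambda2 = lambda2 + sum(s) - ne)
}

#' Build the layer-selection QUBO from the current plan state
#'
#' At fixed intensities `x` and active sets, the binary step minimizes
#' `||B s - b||^2 + mu2 (1's - ne + lambda2)^2`, where column `i` of `B` is
#' the active-voxel dose contributed by layer `i` at its current
#' intensities. Expanding the square gives a QUBO with coupling
#' `Q = B'B + mu2 11'`, linear vector `c = B'b + mu2 (ne - lambda2) 1`, and
#' constant `||b||^2 + mu2 (ne - lambda2)^2`, so for every binary `s`:
#' `energy(s) + constant` equals the original objective exactly.
#'
#' @param scenario_list,weights,active_list,terms as in
#'   [assemble_scaled_matrix()].
#' @param x current spot intensities.
#' @param mu2 cardinality penalty weight.
#' @param ne target number of active layers.
#' @param lambda2 scalar dual of the cardinality constraint.
#' @return A [qubo_problem()]; the layer-dose matrix is attached as
#'   attribute `"B"`.
#' @export
build_layer_qubo <- function(scenario_list, weights, active_list, terms, x,
                             mu2, ne, lambda2 = 0) {
  asm <- assemble_scaled_matrix(scenario_list, weights, active_list, terms, s = NULL)
  B <- layer_dose_matrix(asm$A, asm$layer_cols, x)
  layer_qubo(B, asm$b, mu2, ne, lambda2)
}

# Column i = A[, cols_i] %*% x_i: dose contribution of layer i at current x.
layer_dose_matrix <- function(A, layer_cols, x) {
  B <- matrix(0, nrow(A), length(layer_cols))
  for (i in seq_along(layer_cols)) {
    ci <- layer_cols[[i]]
    if (length(ci) > 0 && any(x[ci] != 0)) {
      B[, i] <- as.numeric(A[, ci, drop = FALSE] %*% x[ci])
    }
  }
  B
}

#' Layer-selection QUBO from an explicit layer-dose matrix
#'
#' @param B matrix whose column `i` holds layer `i`'s dose contribution on
#'   the active voxels (scaled as in [assemble_scaled_matrix()]).
#' @param b scaled target vector.
#' @param mu2,ne,lambda2 cardinality penalty weight, target count, dual.
#' @return A [qubo_problem()] with `B` attached as attribute.
#' @export
layer_qubo <- function(B, b, mu2, ne, lambda2 = 0) {
  if (ncol(B) == 0) stop("no layers to select over", call. = FALSE)
  N <- ncol(B)
  Q <- crossprod(B) + mu2 * matrix(1, N, N)
  cvec <- as.numeric(crossprod(B, b)) + mu2 * (ne - lambda2)
  const <- sum(b^2) + mu2 * (ne - lambda2)^2
  q <- qubo_problem(Q, cvec, const)
  attr(q, "B") <- B
  q
}

# Greedy cardinality repair: flip bits toward sum(s) == ne, choosing at each
# step the flip with the smallest increase of ||B s - b||^2.
repair_cardinality <- function(s, B, b, ne) {
  while (sum(s) != ne) {
    resid <- as.numeric(B %*% s - b)
    if (sum(s) > ne) {
      cand <- which(s == 1)
      deltas <- vapply(cand, function(i) {
        sum((resid - B[, i])^2) - sum(resid^2)
      }, numeric(1))
    } else {
      cand <- which(s == 0)
      deltas <- vapply(cand, function(i) {
        sum((resid + B[, i])^2) - sum(resid^2)
      }, numeric(1))
    }
    i <- cand[which.min(deltas)]
    s[i] <- 1L - s[i]
  }
  s
}

expand_selection <- function(s, layer_cols, n) {
  mask <- rep(TRUE, n)
  for (i in seq_along(layer_cols)) {
    if (s[i] == 0) mask[layer_cols[[i]]] <- FALSE
  }
  mask
}

# Shared ICR + ADMM engine behind run_impt() and run_qc(). When `s_fixed`
# is supplied the binary step is skipped and the selection stays frozen
# (used for the all-layers baseline and for the final restricted re-fit of
# a chosen selection).
solve_plan_core <- function(case, terms, config, ne, qubo_method = "exact",
                            scenarios = NULL, s_fixed = NULL) {
  freeze_s <- !is.null(s_fixed)
  stopifnot(inherits(case, "elo_case"), inherits(config, "elo_admm_config"))
  check_terms(terms, case$structures)
  if (is.null(scenarios)) {
    scenario_list <- list(case$influence)
    weights <- 1
  } else {
    stopifnot(inherits(scenarios, "elo_scenarios"))
    scenario_list <- scenarios$scenarios
    weights <- scenarios$weights
  }
  N <- length(case$influence$blocks)
  n <- sum(case$influence$n_spots_per_layer)
  if (ne < 1 || ne > N) {
    stop(sprintf("ne must be between 1 and %d (got %s)", N, ne), call. = FALSE)
  }

  x <- numeric(n)
  z <- numeric(n)
  lambda1 <- numeric(n)
  lambda2 <- 0
  s <- if (freeze_s) as.integer(s_fixed) else rep(1L, N)
  mu1 <- config$mu1
  mu2 <- config$mu2
  f_hist <- numeric(0)
  primal_hist <- numeric(0)
  layer_cols <- NULL
  B <- NULL
  b <- NULL
  best_s <- s
  best_f <- Inf

  robust_objective <- function(xe) {
    f <- 0
    for (sc in seq_along(scenario_list)) {
      dsc <- compute_dose(scenario_list[[sc]], xe)
      f <- f + weights[sc] * objective_at_dose(dsc, terms, case$structures)
    }
    f
  }

  for (k in seq_len(config$icr_outer_iter)) {
    x_eval <- x * expand_selection(s, layer_cols %||% list(), n)
    active_list <- lapply(scenario_list, function(inf) {
      update_active_sets(compute_dose(inf, x_eval), terms, case$structures)
    })
    asm <- assemble_scaled_matrix(scenario_list, weights, active_list, terms, s = NULL)
    layer_cols <- asm$layer_cols
    b <- asm$b
    if (is.null(mu1)) mu1 <- config$mu1_scale * estimate_sq_norm(asm$A)

    for (j in seq_len(config$admm_max_iter)) {
      As <- scale_layer_columns(asm$A, layer_cols, s)
      x <- solve_x(As, b, z, lambda1, mu1,
        cg_tol = config$cg_tol,
        cg_max_iter = config$cg_max_iter, x0 = x
      )
      if (!freeze_s) {
        B <- layer_dose_matrix(asm$A, layer_cols, x)
        if (is.null(mu2)) {
          mu2 <- config$mu2_scale * max(mean(colSums(B^2)), 1e-8)
        }
        q <- layer_qubo(B, b, mu2, ne, lambda2)
        sol <- solve_qubo(q,
          method = qubo_method,
          seed = config$seed + 7919L * k + j
        )
        s <- sol$s
        # deselected layers keep their intensities as shadow values so the
        # next binary step can still price re-selecting them; they are
        # zeroed (and the plan re-fit) only at termination
      }
      z <- project_mmu(x + lambda1, config$g_min)
      du <- update_duals(lambda1, x, z, lambda2, s, ne)
      lambda1 <- du$lambda1
      lambda2 <- du$lambda2
    }
    primal_hist <- c(primal_hist, sqrt(sum((x - z)^2)))
    f_k <- robust_objective(
      project_mmu(pmax(x, 0), config$g_min) * expand_selection(s, layer_cols, n)
    )
    f_hist <- c(f_hist, f_k)
    # remember the best selection seen; nonconvex ADMM iterates are not
    # monotone in the delivered-plan objective
    if (f_k < best_f) {
      best_f <- f_k
      best_s <- s
    }
  }

  if (!freeze_s) {
    s <- best_s
    B <- layer_dose_matrix(asm$A, layer_cols, x)
    if (sum(s) != ne) s <- repair_cardinality(s, B, b, ne)
    # restricted re-fit: the chosen selection defines a convex problem;
    # solve it cleanly so the reported plan is the best fit of those layers
    refit <- solve_plan_core(case, terms, config,
      ne = ne,
      scenarios = scenarios, s_fixed = s
    )
    refit$mode <- "qc"
    refit$ne <- ne
    refit$mu2 <- mu2
    refit$lambda2 <- lambda2
    refit$objective_history <- c(f_hist, refit$objective_history)
    refit$primal_residuals <- c(primal_hist, refit$primal_residuals)
    return(refit)
  }
  mask <- expand_selection(s, layer_cols, n)
  x[!mask] <- 0
  x <- project_mmu(pmax(x, 0), config$g_min)
  dose <- compute_dose(scenario_list[[1]], x)
  f <- robust_objective(x)

  structure(
    list(
      x = as.numeric(x), s = as.integer(s), f = f, dose = dose,
      ne = sum(s), mode = "impt",
      objective_history = f_hist, primal_residuals = primal_hist,
      mu1 = mu1, mu2 = mu2, lambda2 = lambda2,
      config = config, terms = terms, case = case,
      robust = !is.null(scenarios),
      n_scenarios = length(scenario_list)
    ),
    class = "elo_plan"
  )
}

#' Optimize an IMPT plan with all energy layers available
#'
#' The layer-selection-free baseline: ICR outer iterations refresh the DVH
#' active sets, and inner ADMM sweeps alternate the CG intensity step, the
#' MMU projection, and the dual update, with the binary selection frozen at
#' all ones. The returned intensities satisfy the MMU constraint exactly
#' (the last step is the projection).
#'
#' @param case an `elo_case`.
#' @param terms objective terms; default [default_objective_terms()].
#' @param config an [admm_config()].
#' @param scenarios optional `elo_scenarios` for robust optimization
#'   (scenario-weighted objective).
#' @return An `elo_plan` with fields `x`, `s`, `f`, `dose`,
#'   `objective_history`, `primal_residuals`, ...
#' @export
run_impt <- function(case, terms = default_objective_terms(case),
                     config = admm_config(), scenarios = NULL) {
  solve_plan_core(case, terms, config,
    ne = length(case$influence$blocks),
    scenarios = scenarios,
    s_fixed = rep(1L, length(case$influence$blocks))
  )
}

#' Optimize a plan with a fixed number of active energy layers
#'
#' Solves the mixed-integer layer-selection model: the ICR + ADMM engine of
#' [run_impt()] plus a binary step in every ADMM sweep, in the order
#' x (CG) -> s (QUBO) -> z (MMU projection) -> duals. The layer-selection
#' QUBO is solved with the requested backend. At termination the selection
#' is repaired, if needed, to exactly `ne` active layers (greedy smallest
#' marginal objective change), deselected layers are zeroed, and the final
#' intensities are re-fit and projected onto the MMU set.
#'
#' @inheritParams run_impt
#' @param ne number of active energy layers (1 to N).
#' @param qubo_method `"exact"`, `"anneal"`, or `"vqa"`.
#' @return An `elo_plan`; `sum(plan$s) == ne` always holds.
#' @export
run_qc <- function(case, ne, terms = default_objective_terms(case),
                   config = admm_config(), qubo_method = c("exact", "anneal", "vqa"),
                   scenarios = NULL) {
  qubo_method <- match.arg(qubo_method)
  solve_plan_core(case, terms, config,
    ne = ne, qubo_method = qubo_method,
    scenarios = scenarios
  )
}

#' @export
print.elo_plan <- function(x, ...) {
  cat(sprintf(
    "<elo_plan [%s]: f = %.4g, %d/%d layers active, %d spots delivered%s>\n",
    x$mode, x$f, sum(x$s), length(x$s), sum(x$x > 0),
    if (x$robust) sprintf(", robust (%d scenarios)", x$n_scenarios) else ""
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
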