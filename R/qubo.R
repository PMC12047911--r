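#' Quadratic unconstrained binary optimization (QUBO) problems
#'
#' A QUBO instance is the minimization of the energy
#' \deqn{E(s) = s^T Q s - 2 c^T s, \quad s \in \{0,1\}^N,}
#' where `Q` is a symmetric coupling matrix and `c` a linear vector. An
#' additive `constant` is carried alongside so that `E(s) + constant` can
#' represent an original least-squares objective exactly (see
#' [build_layer_qubo()]). Off-diagonal couplings are counted once through the
#' bilinear form `s^T Q s` with symmetric `Q`.
#'
#' @param Q symmetric numeric N x N matrix.
#' @param c numeric vector of length N.
#' @param constant scalar offset carried with the problem (does not affect the
#'   minimizer).
#' @return An object of class `qubo_problem` with fields `Q`, `c`, `constant`
#'   and `n`.
#' @seealso [solve_qubo_exact()], [solve_qubo_annealing()], [solve_qubo_vqa()]
#' @export
qubo_problem <- function(Q, c, constant = 0) {
  Q <- as.matrix(Q)
  c <- as.numeric(c)
  if (nrow(Q) != ncol(Q)) stop("`Q` must be square", call. = FALSE)
  if (nrow(Q) < 1L) stop("QUBO must have at least one variable", call. = FALSE)
  if (length(c) != nrow(Q)) stop("`c` must have length nrow(Q)", call. = FALSE)
  if (max(abs(Q - t(Q))) > 1e-8 * max(1, max(abs(Q)))) {
    stop("`Q` must be symmetric", call. = FALSE)
  }
  Q <- (Q + t(Q)) / 2
  structure(
    list(Q = Q, c = c, constant = as.numeric(constant), n = nrow(Q)),
    class = "qubo_problem"
  )
}

#' @export
print.qubo_problem <- function(x, ...) {
  cat(sprintf("<qubo_problem: %d binary variables, constant %.6g>\n", x$n, x$constant))
  invisible(x)
}

#' Evaluate the QUBO energy at one or more binary vectors
#'
#' @param q a [qubo_problem()].
#' @param s binary vector of length `q$n`, or a matrix with one configuration
#'   per row.
#' @return Numeric vector of energies `s^T Q s - 2 c^T s` (without the
#'   constant offset).
#' @export
qubo_energy <- function(q, s) {
  stopifnot(inherits(q, "qubo_problem"))
  S <- if (is.matrix(s)) s else matrix(s, nrow = 1L)
  if (ncol(S) != q$n) stop("configuration length must equal q$n", call. = FALSE)
  as.numeric(rowSums((S %*% q$Q) * S) - 2 * (S %*% q$c))
}

new_qubo_solution <- function(s, q, solver, diagnostics = list()) {
  structure(
    list(
      s = as.integer(s),
      energy = qubo_energy(q, s),
      solver = solver,
      diagnostics = diagnostics
    ),
    class = "qubo_solution"
  )
}

#' @export
print.qubo_solution <- function(x, ...) {
  cat(sprintf(
    "<qubo_solution [%s]: energy %.6g, s = %s>\n",
    x$solver, x$energy, paste(x$s, collapse = "")
  ))
  invisible(x)
}

# Decode basis-state integers k (0-based) into a 0/1 matrix whose first column
# is the most significant bit, so increasing k is lexicographic order on s.
decode_bits <- function(k, n) {
  S <- matrix(0L, nrow = length(k), ncol = n)
  for (i in seq_len(n)) {
    S[, i] <- bitwAnd(bitwShiftR(k, n - i), 1L)
  }
  S
}

# Energies of all 2^n basis states in index order (k = 0 .. 2^n - 1),
# computed in chunks to bound memory.
qubo_energy_spectrum <- function(q, chunk_bits = 16L) {
  n <- q$n
  total <- 2^n
  chunk <- min(total, 2^chunk_bits)
  out <- numeric(total)
  k0 <- 0
  while (k0 < total) {
    ks <- k0:(min(k0 + chunk, total) - 1)
    S <- decode_bits(as.integer(ks), n)
    out[ks + 1] <- qubo_energy(q, S)
    k0 <- k0 + chunk
  }
  out
}

#' Solve a QUBO exactly by exhaustive enumeration
#'
#' Enumerates all `2^N` configurations (chunked, so memory stays bounded) and
#' returns the global minimum. Ties are broken toward the lexicographically
#' smallest configuration. Intended as the ground-truth oracle for the
#' heuristic and variational solvers; refuses instances above `max_n`
#' variables.
#'
#' @param q a [qubo_problem()].
#' @param max_n enumeration bound (default 24).
#' @return A `qubo_solution` with fields `s`, `energy`, `solver`,
#'   `diagnostics`.
#' @export
solve_qubo_exact <- function(q, max_n = 24L) {
  stopifnot(inherits(q, "qubo_problem"))
  if (q$n > max_n) {
    stop(
      sprintf(
        "exact enumeration limited to %d variables (got %d); use solve_qubo_annealing() or solve_qubo_vqa()",
        max_n, q$n
      ),
      call. = FALSE
    )
  }
  n <- q$n
  total <- 2^n
  chunk <- min(total, 2^16)
  best_e <- Inf
  best_k <- 0
  k0 <- 0
  while (k0 < total) {
    ks <- k0:(min(k0 + chunk, total) - 1)
    e <- qubo_energy(q, decode_bits(as.integer(ks), n))
    i <- which.min(e) # first minimum: lexicographically smallest within chunk
    if (e[i] < best_e) {
      best_e <- e[i]
      best_k <- ks[i]
    }
    k0 <- k0 + chunk
  }
  s <- drop(decode_bits(as.integer(best_k), n))
  new_qubo_solution(s, q, "exact", diagnostics = list(states_enumerated = total))
}

# Energy change of flipping bit i given s and the cached product qs = Q %*% s.
flip_delta <- function(q, s, qs, i) {
  delta <- 1 - 2 * s[i]
  2 * delta * qs[i] + q$Q[i, i] - 2 * delta * q$c[i]
}

greedy_descent <- function(q, s) {
  qs <- drop(q$Q %*% s)
  repeat {
    deltas <- (1 - 2 * s) * (2 * qs - 2 * q$c) + diag(q$Q)
    i <- which.min(deltas)
    if (deltas[i] >= -1e-12) break
    delta <- 1 - 2 * s[i]
    s[i] <- s[i] + delta
    qs <- qs + delta * q$Q[, i]
  }
  s
}

#' Solve a QUBO by single-flip Metropolis simulated annealing
#'
#' Best-of-restarts annealing with a geometric temperature schedule, followed
#' by zero-temperature greedy descent from each restart's best state. The
#' all-zeros and all-ones configurations are always scored as candidates, so
#' the returned energy never exceeds either. Fully seeded and reproducible.
#'
#' @param q a [qubo_problem()].
#' @param n_sweeps sweeps (full passes over the N bits) per restart.
#' @param n_restarts independent restarts.
#' @param t_initial,t_final temperature schedule endpoints; by default scaled
#'   to the typical single-flip energy change of the instance.
#' @param seed integer seed.
#' @return A `qubo_solution`; `diagnostics$restart_energies` holds the best
#'   energy per restart.
#' @export
solve_qubo_annealing <- function(q, n_sweeps = 150L, n_restarts = 10L,
                                 t_initial = NULL, t_final = NULL, seed = 1L) {
  stopifnot(inherits(q, "qubo_problem"))
  n <- q$n
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # Temperature scale from sampled single-flip moves at random states.
  if (is.null(t_initial)) {
    probe <- replicate(32, {
      s <- sample(0:1, n, replace = TRUE)
      qs <- drop(q$Q %*% s)
      abs(flip_delta(q, s, qs, sample.int(n, 1)))
    })
    t_initial <- max(mean(probe), 1e-9)
  }
  if (is.null(t_final)) t_final <- 1e-3 * t_initial
  temps <- t_initial * (t_final / t_initial)^(seq_len(n_sweeps) / n_sweeps)

  best_s <- integer(n)
  best_e <- min(qubo_energy(q, rep(0L, n)), qubo_energy(q, rep(1L, n)))
  if (qubo_energy(q, rep(1L, n)) < qubo_energy(q, rep(0L, n))) best_s <- rep(1L, n)
  restart_energies <- numeric(n_restarts)

  for (r in seq_len(n_restarts)) {
    s <- sample(0:1, n, replace = TRUE)
    qs <- drop(q$Q %*% s)
    e <- qubo_energy(q, s)
    r_best_s <- s
    r_best_e <- e
    for (t in temps) {
      for (i in sample.int(n)) {
        d <- flip_delta(q, s, qs, i)
        if (d <= 0 || stats::runif(1) < exp(-d / t)) {
          delta <- 1 - 2 * s[i]
          s[i] <- s[i] + delta
          qs <- qs + delta * q$Q[, i]
          e <- e + d
          if (e < r_best_e) {
            r_best_e <- e
            r_best_s <- s
          }
        }
      }
    }
    r_best_s <- greedy_descent(q, r_best_s)
    r_best_e <- qubo_energy(q, r_best_s)
    restart_energies[r] <- r_best_e
    if (r_best_e < best_e) {
      best_e <- r_best_e
      best_s <- r_best_s
    }
  }
  new_qubo_solution(
    best_s, q, "annealing",
    diagnostics = list(restart_energies = restart_energies, seed = seed)
  )
}

#' Map a QUBO to an Ising model
#'
#' Substitutes `s = (1 - sigma) / 2` with spins `sigma` in `{-1, +1}`, giving
#' couplings `J`, fields `h`, and an `offset` such that for every binary `s`:
#' `qubo_energy(q, s) = sum_{i<j} J_ij sigma_i sigma_j + sum_i h_i sigma_i +
#' offset`. This is the cost-Hamiltonian form that the variational quantum
#' solver diagonalizes.
#'
#' @param q a [qubo_problem()].
#' @return List with matrix `J` (upper-triangular couplings), vector `h`,
#'   scalar `offset`.
#' @export
qubo_to_ising <- function(q) {
  Q <- q$Q
  J <- Q / 2
  J[lower.tri(J, diag = TRUE)] <- 0
  h <- q$c - rowSums(Q) / 2
  offset <- sum(Q) / 4 + sum(diag(Q)) / 4 - sum(q$c)
  list(J = J, h = h, offset = offset)
}

#' Evaluate an Ising energy at a spin configuration
#'
#' @param ising list from [qubo_to_ising()].
#' @param sigma spin vector in `{-1, +1}`.
#' @return Scalar energy including the offset.
#' @export
ising_energy <- function(ising, sigma) {
  drop(sigma %*% ising$J %*% sigma) + sum(ising$h * sigma) + ising$offset
}

# Apply exp(-i beta X_j) for every qubit j to a statevector psi indexed by
# basis integers 0 .. 2^n - 1 (bit n - j is qubit j's value; see decode_bits).
apply_mixer <- function(psi, beta, n) {
  cb <- cos(beta)
  sb <- sin(beta)
  idx_all <- 0:(length(psi) - 1)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, n - i)
    zero <- which(bitwAnd(idx_all, bit) == 0L)
    one <- zero + bit
    a0 <- psi[zero]
    a1 <- psi[one]
    psi[zero] <- cb * a0 - 1i * sb * a1
    psi[one] <- cb * a1 - 1i * sb * a0
  }
  psi
}

qaoa_state <- function(spectrum_scaled, gammas, betas, n) {
  psi <- rep(complex(real = 1 / sqrt(length(spectrum_scaled))), length(spectrum_scaled))
  for (l in seq_along(gammas)) {
    psi <- psi * exp(-1i * gammas[l] * spectrum_scaled)
    psi <- apply_mixer(psi, betas[l], n)
  }
  psi
}

#' Solve a QUBO with a QAOA-style variational statevector routine
#'
#' Maps the QUBO to a diagonal cost Hamiltonian on `N` qubits (binary
#' variables correspond to spin states through `s = (1 - sigma)/2`), applies
#' `depth` alternating layers of cost-phase and transverse-field mixer
#' unitaries to the uniform superposition, and optimizes the `2 * depth`
#' circuit parameters with a derivative-free Nelder-Mead search over seeded
#' random multi-starts. The answer is the best (lowest-energy) basis state
#' among either `n_shots` multinomial samples from the optimized state or,
#' in the default statevector mode, the most probable basis states.
#'
#' Statevector simulation requires `2^N` amplitudes, so instances above
#' `qubit_limit` are rejected; route those to [solve_qubo_annealing()].
#'
#' @param q a [qubo_problem()].
#' @param depth number of alternating cost/mixer layers (QAOA p).
#' @param n_param_restarts random parameter initializations.
#' @param n_shots if `NULL` (default), the best of the 64 most probable basis
#'   states is returned; otherwise that many measurement samples are drawn.
#' @param seed integer seed.
#' @param qubit_limit maximum N for statevector simulation (default 16).
#' @param maxit Nelder-Mead iteration cap per restart.
#' @return A `qubo_solution`; `diagnostics` holds the optimized expected
#'   energy, parameters, and probability of the returned state.
#' @export
solve_qubo_vqa <- function(q, depth = 3L, n_param_restarts = 5L, n_shots = NULL,
                           seed = 1L, qubit_limit = 16L, maxit = 200L) {
  stopifnot(inherits(q, "qubo_problem"))
  n <- q$n
  if (n > qubit_limit) {
    stop(
      sprintf(
        "statevector VQA limited to %d qubits (got %d); use solve_qubo_annealing()",
        qubit_limit, n
      ),
      call. = FALSE
    )
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  spectrum <- qubo_energy_spectrum(q)
  scale <- max(abs(spectrum), 1e-12)
  sp <- spectrum / scale

  expected_energy <- function(par) {
    psi <- qaoa_state(sp, par[seq_len(depth)], par[depth + seq_len(depth)], n)
    sum(abs(psi)^2 * sp)
  }

  best_val <- Inf
  best_par <- NULL
  converged <- FALSE
  for (r in seq_len(n_param_restarts)) {
    par0 <- c(stats::runif(depth, 0, pi), stats::runif(depth, 0, pi / 2))
    fit <- tryCatch(
      stats::optim(par0, expected_energy,
        method = "Nelder-Mead",
        control = list(maxit = maxit)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    converged <- converged || fit$convergence == 0
    if (fit$value < best_val) {
      best_val <- fit$value
      best_par <- fit$par
    }
  }
  if (is.null(best_par)) {
    warning("VQA parameter optimization failed; returning best uniform-state sample")
    best_par <- rep(0, 2 * depth)
  }

  psi <- qaoa_state(sp, best_par[seq_len(depth)], best_par[depth + seq_len(depth)], n)
  prob <- abs(psi)^2
  prob <- prob / sum(prob)
  if (is.null(n_shots)) {
    cand <- order(prob, decreasing = TRUE)[seq_len(min(64L, length(prob)))]
  } else {
    cand <- unique(sample.int(length(prob), size = n_shots, replace = TRUE, prob = prob))
  }
  k_best <- cand[which.min(spectrum[cand])]
  s <- drop(decode_bits(as.integer(k_best - 1), n))
  new_qubo_solution(
    s, q, "vqa",
    diagnostics = list(
      expected_energy = best_val * scale,
      parameters = best_par,
      depth = depth,
      state_probability = prob[k_best],
      optimizer_converged = converged,
      seed = seed
    )
  )
}

#' Solve a QUBO with a chosen backend
#'
#' Dispatches to the exact, annealing, or variational solver. Instances too
#' large for the requested backend's state space fall back to annealing with
#' a message, mirroring how clinical-scale layer counts (50-80) are handled.
#'
#' @param q a [qubo_problem()].
#' @param method one of `"exact"`, `"anneal"`, `"vqa"`.
#' @param seed integer seed for the stochastic backends.
#' @param ... passed to the backend solver.
#' @return A `qubo_solution`.
#' @export
solve_qubo <- function(q, method = c("exact", "anneal", "vqa"), seed = 1L, ...) {
  method <- match.arg(method)
  limit <- switch(method, exact = 24L, vqa = 16L, Inf)
  if (q$n > limit) {
    message(sprintf(
      "%d-variable instance exceeds the %s backend bound; using annealing",
      q$n, method
    ))
    method <- "anneal"
  }
  switch(method,
    exact = solve_qubo_exact(q),
    anneal = solve_qubo_annealing(q, seed = seed, ...),
    vqa = solve_qubo_vqa(q, seed = seed, ...)
  )
}

# Save/restore the global RNG state so seeded solvers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
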