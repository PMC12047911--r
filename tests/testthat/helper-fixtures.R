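# Shared fixtures: small phantoms and random QUBO instances, all seeded.

tiny_case <- local({
  memo <- new.env(parent = emptyenv())
  function(seed = 3L, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(memo[[key]])) {
      memo[[key]] <- generate_case(case_config(
        grid_shape = c(14, 14, 14), beam_angles_deg = c(0, 90),
        ctv_radius_mm = 9, seed = seed, ...
      ))
    }
    memo[[key]]
  }
})

fast_admm <- function(seed = 1L, ...) {
  admm_config(icr_outer_iter = 8, admm_max_iter = 4, seed = seed, ...)
}

random_qubo <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n, n)
  qubo_problem((M + t(M)) / 2, rnorm(n))
}

# Independent brute-force QUBO oracle: plain double loop over all
# configurations via expand.grid, no shared code with solve_qubo_exact().
brute_force_qubo <- function(q) {
  grid <- as.matrix(expand.grid(rep(list(0:1), q$n)))
  energies <- apply(grid, 1, function(s) {
    drop(t(s) %*% q$Q %*% s - 2 * sum(q$c * s))
  })
  list(energy = min(energies), s = grid[which.min(energies), ])
}
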