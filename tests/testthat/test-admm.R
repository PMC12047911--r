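test_that("MMU projection maps onto {0} U [g_min, Inf) with the documented tie rule", {
  g <- 5
  expect_equal(project_mmu(0, g), 0)
  expect_equal(project_mmu(2, g), 0)
  expect_equal(project_mmu(3, g), 5)
  expect_equal(project_mmu(7, g), 7)
  expect_equal(project_mmu(2.5, g), 5) # tie at g_min/2 resolves upward
  expect_equal(project_mmu(c(-1, 2, 3, 5, 9), g), c(0, 0, 5, 5, 9))
  expect_error(project_mmu(1, 0), "> 0")
})

test_that("MMU projection agrees with dense grid minimization of the distance", {
  set.seed(99)
  for (i in 1:50) {
    g <- runif(1, 0.5, 10)
    v <- runif(1, -2, 3 * g)
    zgrid <- c(0, seq(g, 4 * g, length.out = 4000))
    z_best <- zgrid[which.min((v - zgrid)^2)]
    expect_equal(project_mmu(v, g), z_best, tolerance = 2 * g / 4000)
  }
})

test_that("CG x-step solves the regularized normal equations", {
  set.seed(4)
  A <- matrix(rnorm(12 * 8), 12, 8)
  b <- rnorm(12)
  z <- rnorm(8)
  l1 <- rnorm(8)
  mu1 <- 0.7
  x <- solve_x(A, b, z, l1, mu1, cg_tol = 1e-12, cg_max_iter = 500)
  x_ref <- solve(crossprod(A) + mu1 * diag(8), crossprod(A, b) + mu1 * (z - l1))
  expect_equal(as.numeric(x), as.numeric(x_ref), tolerance = 1e-8)
  expect_true(attr(x, "converged"))

  # A = 0: pure penalty, x = z - lambda1 exactly
  x0 <- solve_x(matrix(0, 5, 8), rep(0, 5), z, l1, mu1)
  expect_equal(as.numeric(x0), z - l1, tolerance = 1e-12)

  # A = I, b given, z = l1 = 0, mu1 = 1: (I + I) x = b
  bI <- rnorm(8)
  xI <- solve_x(diag(8), bI, rep(0, 8), rep(0, 8), 1, cg_tol = 1e-12)
  expect_equal(as.numeric(xI), bI / 2, tolerance = 1e-10)
})

test_that("CG warns and flags non-convergence when starved of iterations", {
  set.seed(8)
  A <- matrix(rnorm(400), 20, 20) + 10 * diag(20)
  expect_warning(
    x <- solve_x(A, rnorm(20), rep(0, 20), rep(0, 20), 1e-6,
      cg_tol = 1e-14, cg_max_iter = 2
    ),
    "CG did not reach"
  )
  expect_false(attr(x, "converged"))
})

test_that("dual updates follow their closed forms", {
  du <- update_duals(c(0, 0), x = c(1, 0), z = c(0, 1), lambda2 = 0.5, s = c(1, 1, 1), ne = 5)
  expect_equal(du$lambda1, c(1, -1))
  expect_equal(du$lambda2, -1.5)
  # feasible point leaves duals unchanged
  du2 <- update_duals(c(2, 3), x = c(1, 1), z = c(1, 1), lambda2 = 4, s = c(1, 0), ne = 1)
  expect_equal(du2$lambda1, c(2, 3))
  expect_equal(du2$lambda2, 4)
})

test_that("assembled matrix rows carry sqrt(weight/|active|) scaling", {
  case <- tiny_case()
  terms <- list(objective_term("L2", "ctv", weight = 4, dose_level = 100))
  active <- list(update_active_sets(
    rep(0, prod(case$grid$shape)), terms, case$structures
  ))
  asm <- assemble_scaled_matrix(list(case$influence), 1, active, terms)
  n_ctv <- length(case$structures$ctv$voxel_indices)
  expect_equal(nrow(asm$A), n_ctv)
  w <- sqrt(4 / n_ctv)
  expect_equal(asm$b, rep(w * 100, n_ctv))
  D <- do.call(cbind, case$influence$blocks)
  expect_equal(
    as.numeric(asm$A[1, ]),
    as.numeric(D[case$structures$ctv$voxel_indices[1], ]) * w
  )
  # s = all zeros wipes every column
  asm0 <- assemble_scaled_matrix(list(case$influence), 1, active, terms,
    s = rep(0, length(case$influence$blocks))
  )
  expect_equal(max(abs(asm0$A)), 0)
  # empty active sets are rejected
  terms_dvh <- list(objective_term("DVH_max", "oar", 1, 1000, volume_fraction = 0))
  active_e <- list(update_active_sets(rep(0, prod(case$grid$shape)), terms_dvh, case$structures))
  expect_error(
    assemble_scaled_matrix(list(case$influence), 1, active_e, terms_dvh),
    "empty"
  )
})

test_that("layer QUBO reproduces the least-squares objective at random s", {
  set.seed(31)
  for (rep in 1:5) {
    m <- 30
    N <- sample(6:12, 1)
    B <- matrix(rnorm(m * N), m, N)
    b <- rnorm(m)
    mu2 <- runif(1, 0.1, 5)
    ne <- sample(1:N, 1)
    l2 <- rnorm(1)
    q <- layer_qubo(B, b, mu2, ne, l2)
    for (k in 1:10) {
      s <- sample(0:1, N, replace = TRUE)
      direct <- sum((B %*% s - b)^2) + mu2 * (sum(s) - ne + l2)^2
      expect_equal(qubo_energy(q, s) + q$constant, direct, tolerance = 1e-9)
    }
    expect_equal(qubo_energy(q, rep(0, N)), 0) # quadratic and linear parts vanish
  }
})

test_that("single-layer QUBO selects the layer whose dose matches the target", {
  b <- c(3, 4)
  q <- layer_qubo(matrix(b, 2, 1), b, mu2 = 0, ne = 1)
  sol <- solve_qubo_exact(q)
  expect_equal(sol$s, 1L)
  expect_equal(sol$energy, -sum(b^2))
})

test_that("build_layer_qubo agrees with dose-level evaluation on a real case", {
  case <- tiny_case()
  terms <- default_objective_terms(case)
  n <- nrow(case$spots)
  set.seed(5)
  x <- runif(n, 0, 3)
  dose <- compute_dose(case$influence, x)
  active <- list(update_active_sets(dose, terms, case$structures))
  q <- build_layer_qubo(list(case$influence), 1, active, terms, x,
    mu2 = 2, ne = 4, lambda2 = 0.3
  )
  asm <- assemble_scaled_matrix(list(case$influence), 1, active, terms)
  N <- length(case$influence$blocks)
  for (k in 1:10) {
    s <- sample(0:1, N, replace = TRUE)
    xs <- x * expand_selection(s, asm$layer_cols, n)
    direct <- sum((as.numeric(asm$A %*% xs) - asm$b)^2) + 2 * (sum(s) - 4 + 0.3)^2
    expect_equal(qubo_energy(q, s) + q$constant, direct, tolerance = 1e-9 * max(1, abs(direct)))
  }
})

test_that("IMPT baseline: monotone outer objective, MMU-feasible output", {
  case <- tiny_case()
  plan <- run_impt(case, config = fast_admm())
  expect_s3_class(plan, "elo_plan")
  expect_true(all(plan$s == 1L))
  g <- plan$config$g_min
  expect_true(all(plan$x == 0 | plan$x >= g))
  expect_true(all(diff(plan$objective_history) <= 1e-8 * plan$objective_history[1]))
  # primal residual shrinks to tolerance on this fixture
  expect_lt(tail(plan$primal_residuals, 1), 0.1 * plan$primal_residuals[1])
})

test_that("layer-constrained solve returns exactly ne layers, zeroed elsewhere", {
  case <- tiny_case()
  for (seed in c(1, 2)) {
    plan <- run_qc(case, ne = 4, config = fast_admm(seed = seed))
    expect_equal(sum(plan$s), 4L)
    lids <- rep(seq_along(case$influence$n_spots_per_layer),
      times = case$influence$n_spots_per_layer
    )
    expect_true(all(plan$x[plan$s[lids] == 0] == 0))
    g <- plan$config$g_min
    expect_true(all(plan$x == 0 | plan$x >= g))
  }
  expect_error(run_qc(case, ne = 0), "between")
  expect_error(run_qc(case, ne = 99), "between")
})

test_that("a feasible prescription is driven near zero objective", {
  # construct a target dose that the spot model can realize exactly:
  # prescribe the dose of a known MMU-feasible plan on the CTV only
  case <- tiny_case()
  n <- nrow(case$spots)
  x_true <- rep(2, n)
  d_true <- compute_dose(case$influence, x_true)
  lvl <- mean(d_true[case$structures$ctv$voxel_indices])
  terms <- list(objective_term("L2", "ctv", 1, dose_level = lvl))
  f_init <- objective_at_dose(rep(0, prod(case$grid$shape)), terms, case$structures)
  plan <- run_impt(case, terms = terms, config = fast_admm())
  expect_lt(plan$f, 1e-3 * f_init)
})

test_that("robust solve with uniform identical scenarios matches nominal", {
  case <- tiny_case()
  scen <- structure(
    list(
      scenarios = rep(list(case$influence), 3),
      weights = rep(1 / 3, 3), nominal_index = 1L,
      descriptions = rep("nominal", 3)
    ),
    class = "elo_scenarios"
  )
  p_nom <- run_impt(case, config = fast_admm())
  p_rob <- run_impt(case, config = fast_admm(), scenarios = scen)
  expect_equal(p_rob$f, p_nom$f, tolerance = 1e-9)
})

test_that("robust objective equals the weighted sum of per-scenario objectives", {
  case <- generate_case(case_config(
    grid_shape = c(10, 10, 10), beam_angles_deg = 0, ctv_radius_mm = 7, seed = 6
  ))
  scen <- generate_scenarios(case, setup_shift_mm = 3, range_uncertainty_fraction = 0.035)
  terms <- default_objective_terms(case)
  plan <- run_impt(case, terms, fast_admm(), scenarios = scen)
  f_direct <- sum(vapply(seq_along(scen$scenarios), function(si) {
    d <- compute_dose(scen$scenarios[[si]], plan$x)
    scen$weights[si] *
      evaluate_objective(d, terms, update_active_sets(d, terms, case$structures))
  }, numeric(1)))
  expect_equal(plan$f, f_direct, tolerance = 1e-12)
})
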