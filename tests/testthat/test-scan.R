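test_that("a global attractor converges at the smallest grid point", {
  fx <- fixture_system("linear-stable")
  sc <- convergence_scan(fx$system, fx$attractors,
                         bases = c("trigonometric", "legendre"),
                         n_grid = c(2, 3, 4), alpha_grid = c(1, 2, 3),
                         tolerance = 0.1, T = 100, seed = 6,
                         dt = 0.01, t_end = 120, settle = 80)
  expect_true(sc$converged)
  expect_identical(sc$n_star, 4L)        # trailing window of 3 needs 3 points
  expect_identical(sc$alpha_star, 3)
  expect_true(all(sc$grid$p_hat == 1))
})

test_that("a tolerance below the noise floor is flagged", {
  fx <- fixture_system("linear-stable")
  expect_warning(
    convergence_scan(fx$system, fx$attractors, bases = "legendre",
                     n_grid = c(2, 3, 4), tolerance = 0.001, T = 50, seed = 1,
                     dt = 0.01, t_end = 120, settle = 80),
    "noise floor")
})

test_that("an over-tight coefficient bound fails the alpha stabilization", {
  sys <- hopfield_system(tau = 2)
  att <- hopfield_attractors(sys)
  sc <- suppressWarnings(
    convergence_scan(sys, att, bases = "trigonometric",
                     n_grid = c(2, 4, 6),
                     alpha_grid = c(0.05, 0.1, 0.2),
                     tolerance = 0.02, T = 400, seed = 12))
  # mass concentrates in the basins adjacent to the origin and keeps
  # shifting as alpha grows: the criterion must reject
  expect_true(is.na(sc$alpha_star) || !sc$converged)
})

test_that("profiles along a parameter are tidy and normalized", {
  fx <- fixture_system("linear-stable", tau = 0.3)
  prof <- bs_vs_parameter(
    function(tau) fixture_system("linear-stable", tau = tau)$system,
    grid = c(0.3, 0.6), attractors = fx$attractors,
    bases = c("legendre", "bernstein"), n = 3, alpha = 2, T = 80, seed = 5,
    dt = 0.01, t_end = 120, settle = 80)
  expect_s3_class(prof, "bs_profile")
  expect_setequal(unique(prof$basis), c("legendre", "bernstein"))
  expect_equal(nrow(prof), 4)          # 2 bases x 2 grid points x 1 attractor
  expect_true(all(prof$p_hat == 1))
  expect_true(all(prof$p_norm == 1))   # flat curve normalizes to 1
  cons <- basis_consensus(prof)
  expect_named(cons, c("attractor", "basis_a", "basis_b", "rho"))
})

test_that("re-running a cell with another seed moves p by sampling error only", {
  sys <- hopfield_system(tau = 2)
  att <- hopfield_attractors(sys)
  T <- 600
  p1 <- estimate_bs(sys, att, sample_plan("legendre", 8, 6, T, seed = 31))
  p2 <- estimate_bs(sys, att, sample_plan("legendre", 8, 6, T, seed = 77))
  for (k in seq_len(4)) {
    a <- p1$table$p_hat[k]; b <- p2$table$p_hat[k]
    expect_lt(abs(a - b), 4 * binom_se_diff(a, b, T))
  }
})
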