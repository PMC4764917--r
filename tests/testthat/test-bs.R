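test_that("sample-size planning follows the binomial closed form", {
  expect_identical(choose_sample_size(0.05), 385L)
  expect_identical(choose_sample_size(0.01), 9604L)
  # halving the half-width quadruples T (up to ceiling effects)
  r <- choose_sample_size(0.02) / choose_sample_size(0.04)
  expect_gt(r, 3.9); expect_lt(r, 4.1)
  expect_error(choose_sample_size(0.7), "half_width")
})

test_that("coefficient draws are uniform, symmetric and reproducible", {
  plan <- sample_plan("trigonometric", n = 3, alpha = 2, T = 1e5, seed = 42)
  a <- sample_coefficients(plan, s = 2)
  expect_identical(a, sample_coefficients(plan, s = 2))
  sd_mean <- (2 * plan$alpha / sqrt(12)) / sqrt(plan$T)
  means <- apply(a, c(1, 2), mean)
  expect_true(all(abs(means) < 3 * sd_mean))
  frac_pos <- mean(a[1, 1, ] > 0)
  expect_lt(abs(frac_pos - 0.5), 3 * 0.5 / sqrt(plan$T))
  expect_true(all(abs(a) <= plan$alpha))
})

test_that("counts are conserved and the estimate is seed-deterministic", {
  fx <- fixture_system("bistable-scalar")
  plan <- sample_plan("legendre", n = 4, alpha = 1.5, T = 300, seed = 11)
  est <- estimate_bs(fx$system, fx$attractors, plan, dt = 0.005,
                     t_end = 150, settle = 100)
  expect_identical(sum(est$table$M) + est$unclassified, est$T)
  est2 <- estimate_bs(fx$system, fx$attractors, plan, dt = 0.005,
                      t_end = 150, settle = 100)
  expect_identical(est$table$M, est2$table$M)
})

test_that("the symmetric bistable fixture has equal basins summing to one", {
  fx <- fixture_system("bistable-scalar")
  plan <- sample_plan("trigonometric", n = 5, alpha = 1.5, T = 1500, seed = 3)
  est <- estimate_bs(fx$system, fx$attractors, plan, dt = 0.005,
                     t_end = 150, settle = 100)
  p <- est$table$p_hat
  expect_gt(sum(p), 0.97)
  expect_lt(abs(p[1] - p[2]), 4 * binom_se_diff(p[1], p[2], est$T))
})

test_that("the half-space fixture matches its analytic hypercube fraction", {
  fx <- fixture_system("halfspace")
  plan <- sample_plan("trigonometric", n = 4, alpha = 2, T = 1000, seed = 21)
  est <- estimate_bs(fx$system, fx$attractors, plan, dt = 0.01,
                     t_end = 60, settle = 40, window = 10)
  frac <- fx$expectations$halfspace_fraction(plan)
  p_up <- est$table$p_hat[est$table$attractor == "upper"]
  se <- sqrt(frac * (1 - frac) / est$T)
  expect_lt(abs(p_up - frac), 4 * se + 0.01)
  expect_identical(sum(est$table$M) + est$unclassified, est$T)
})

test_that("the interpreted and compiled integration paths agree", {
  fx <- fixture_system("bistable-scalar")
  slow_sys <- dde_system(function(t, x, xlag) xlag[1, 1] - x[1]^3,
                         s = 1, delays = 0.5, name = "bistable-R")
  plan <- sample_plan("legendre", n = 3, alpha = 1, T = 40, seed = 8)
  coef <- sample_coefficients(plan, 1)
  fast <- estimate_bs(fx$system, fx$attractors, plan, coefficients = coef,
                      dt = 0.01, t_end = 150, settle = 100,
                      early_exit = FALSE)
  slow <- estimate_bs(slow_sys, fx$attractors, plan, coefficients = coef,
                      dt = 0.01, t_end = 150, settle = 100)
  expect_identical(fast$table$M, slow$table$M)
})

test_that("a run that classifies nothing warns but returns", {
  fx <- fixture_system("bistable-scalar")
  far <- attractor_set(rbind(50), "far", delta = 1e-2)
  plan <- sample_plan("legendre", n = 3, alpha = 1, T = 20, seed = 2)
  expect_warning(
    est <- estimate_bs(fx$system, far, plan, dt = 0.005, t_end = 150,
                       settle = 100),
    "no trajectory")
  expect_identical(est$unclassified, est$T)
})

test_that("tidy and glance expose counts and provenance", {
  fx <- fixture_system("linear-stable")
  plan <- sample_plan("bernstein", n = 3, alpha = 2, T = 100, seed = 4)
  est <- estimate_bs(fx$system, fx$attractors, plan, dt = 0.01,
                     t_end = 120, settle = 80)
  td <- tidy(est)
  expect_setequal(names(td),
                  c("attractor", "M", "T", "p_hat", "ci_lo", "ci_hi",
                    "model", "basis", "n", "alpha", "tau", "seed"))
  gl <- glance(est)
  expect_identical(gl$classified + gl$unclassified, gl$T)
  # single global attractor: every draw lands on it
  expect_equal(td$p_hat, 1)
})
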