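test_that("method of steps reproduces the piecewise closed form", {
  sys <- dde_system(function(t, x, xlag) -xlag[, 1], s = 1, delays = 1)
  dt <- 0.01
  tr <- dde_integrate(sys, constant_history(1, tau = 1), t_end = 2, dt = dt)
  tq <- seq(0, 2, by = 0.05)
  err <- max(abs(trajectory_at(tr, tq)[, 1] - steps_oracle(tq)))
  expect_lt(err, 10 * dt^2)
  expect_equal(trajectory_at(tr, 1)[, 1], 0, tolerance = 1e-10)
  expect_equal(trajectory_at(tr, 2)[, 1], -0.5, tolerance = 1e-8)
})

test_that("zero delay reduces to the ODE and converges at fourth order", {
  sys <- dde_system(function(t, x, xlag) -xlag[, 1], s = 1, delays = 0)
  x_at_1 <- function(dt) {
    tr <- dde_integrate(sys, constant_history(1, tau = 1), t_end = 1, dt = dt)
    tr$state[nrow(tr$state), 1]
  }
  e1 <- abs(x_at_1(0.1) - exp(-1))
  e2 <- abs(x_at_1(0.05) - exp(-1))
  expect_lt(e2, 1e-6)
  expect_gt(e1 / e2, 8)   # nominal order 4 would give 16
})

test_that("past evaluation splices history and interpolant exactly", {
  sys <- dde_system(function(t, x, xlag) rep(1, 1), s = 1, delays = 0.5)
  h <- history_fun(basis_spec("legendre", 2), c(0.3, 0.2), tau = 0.5)
  tr <- dde_integrate(sys, h, t_end = 1, dt = 0.1)
  expect_identical(trajectory_at(tr, 0)[, 1], eval_history(h, 0)[, 1])
  expect_identical(trajectory_at(tr, -0.5)[, 1], eval_history(h, -0.5)[, 1])
  # x(t) = x(0) + t is linear: the cubic Hermite interpolant is exact
  x0 <- eval_history(h, 0)[, 1]
  expect_equal(trajectory_at(tr, 0.537)[, 1], x0 + 0.537, tolerance = 1e-12)
  expect_error(trajectory_at(tr, -0.6), "history start")
  expect_error(trajectory_at(tr, 1.2), "beyond the end")
})

test_that("divergence sets a flag instead of raising", {
  sys <- dde_system(function(t, x, xlag) x^2, s = 1, delays = numeric(0))
  tr <- dde_integrate(sys, constant_history(2, tau = 1), t_end = 2, dt = 0.01)
  expect_true(tr$diverged)
  expect_lt(tr$t_last, 2)
  # non-finite rhs output is also a divergence, not an exception
  sysn <- dde_system(function(t, x, xlag) if (t > 0.1) NaN else -x, s = 1,
                     delays = numeric(0))
  trn <- dde_integrate(sysn, constant_history(1, tau = 1), t_end = 1, dt = 0.01)
  expect_true(trn$diverged)
})

test_that("the step is snapped so delays are grid multiples", {
  sys <- dde_system(function(t, x, xlag) -xlag[, 1], s = 1, delays = 1)
  tr <- dde_integrate(sys, constant_history(1, tau = 1), t_end = 1, dt = 0.3)
  expect_equal(tr$dt, 0.25)
  expect_equal((1 / tr$dt) %% 1, 0)
  # dt larger than the delay is clamped down to it
  tr2 <- dde_integrate(sys, constant_history(1, tau = 1), t_end = 1, dt = 2)
  expect_lte(tr2$dt, 1)
})

test_that("a too-short history is rejected", {
  sys <- dde_system(function(t, x, xlag) -xlag[, 1], s = 1, delays = 2)
  expect_error(
    dde_integrate(sys, constant_history(1, tau = 1), t_end = 1, dt = 0.1),
    "largest delay")
})

test_that("trajectories export to CSV with t, x1..xs columns", {
  tr <- dde_integrate(rossler_system(), constant_history(c(1, 1, 1), tau = 1),
                      t_end = 1, dt = 0.01, keep_every = 10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  got <- utils::read.csv(path)
  expect_named(got, c("t", "x1", "x2", "x3"))
  expect_equal(nrow(got), length(tr$time))
})
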