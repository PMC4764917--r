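test_that("Hopfield right-hand side has the documented structure", {
  sys <- hopfield_system()
  g <- delaybasin:::rhs_frozen(sys)
  expect_equal(g(c(0, 0)), c(0, 0))           # origin is an equilibrium
  withr::with_seed(2, {
    for (i in 1:5) {
      u <- runif(2, -3, 3)
      expect_equal(g(-u), -g(u), tolerance = 1e-12)   # odd symmetry
    }
  })
  expect_error(hopfield_system(a = -1), "a > 0")
})

test_that("the equilibrium census finds exactly four stable states", {
  eq <- find_equilibria(hopfield_system(), c(-4, -4), c(4, 4), grid_n = 41)
  expect_equal(sum(eq$stable), 4)
  expect_true(all(eq$residual < 1e-8))
  # stable equilibria come in symmetric pairs under u -> -u
  st <- as.matrix(eq[eq$stable, c("x1", "x2")])
  for (i in seq_len(nrow(st))) {
    d <- apply(abs(st - matrix(-st[i, ], nrow(st), 2, byrow = TRUE)), 1, max)
    expect_lt(min(d), 1e-6)
  }
})

test_that("census coordinates match the 1-D bisection oracle on symmetry lines", {
  # on u1 = u2:  u = (a + a12) tanh(u); on u1 = -u2:  u = (a - a12) tanh(u)
  bisect_root <- function(f, lo, hi, tol = 1e-12) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  u_diag <- bisect_root(function(u) u - 2.55 * tanh(u), 1, 4)
  u_anti <- bisect_root(function(u) u - 1.45 * tanh(u), 0.5, 4)
  att <- hopfield_attractors()
  st <- delaybasin:::attractor_states(att)
  expect_equal(st[att$label == "E3", ], c(u_diag, u_diag), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(st[att$label == "E1", ], c(u_anti, -u_anti), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("Rossler field divergence equals the analytic Jacobian trace", {
  sys <- rossler_system()
  g <- delaybasin:::rhs_frozen(sys)
  withr::with_seed(3, {
    for (i in 1:4) {
      x <- runif(3, -5, 5)
      J <- pracma::jacobian(g, x)
      expect_equal(sum(diag(J)), 0.2 + (x[1] - 7), tolerance = 1e-6)
    }
  })
})

test_that("the Rossler attractor is bounded and chaotic", {
  sys <- rossler_system()
  tr <- dde_integrate(sys, constant_history(c(1, 1, 1), tau = 1),
                      t_end = 500, dt = 0.01, keep_every = 100L)
  expect_false(tr$diverged)
  expect_lt(max(abs(tr$state)), 1e3)
  lle <- lle_two_traj(sys, c(1, 1, 1))
  expect_gt(lle, 0.02)
})

test_that("trajectories classify to the attractor they start on", {
  sys <- hopfield_system(tau = 2)
  att <- hopfield_attractors(sys)
  st <- delaybasin:::attractor_states(att)
  tr <- dde_integrate(sys, constant_history(st[3, ], tau = 2),
                      t_end = 250, dt = 0.05)
  expect_identical(classify_trajectory(tr, att), "E3")
})

test_that("classification is stable under trajectory extension", {
  sys <- hopfield_system(tau = 2)
  att <- hopfield_attractors(sys)
  h <- history_fun(basis_spec("trigonometric", 5),
                   withr::with_seed(9, matrix(runif(10, -3, 3), 2, 5)),
                   tau = 2)
  lab1 <- classify_trajectory(dde_integrate(sys, h, 300, dt = 0.05), att)
  lab2 <- classify_trajectory(dde_integrate(sys, h, 400, dt = 0.05), att)
  expect_true(lab1 %in% att$label)
  expect_identical(lab1, lab2)
})

test_that("divergent and unsettled trajectories are unclassified", {
  sys <- dde_system(function(t, x, xlag) x^2, s = 1, delays = numeric(0))
  att <- attractor_set(rbind(0), "zero")
  tr <- dde_integrate(sys, constant_history(2, tau = 1), t_end = 300, dt = 0.01,
                      keep_every = 1L)
  expect_identical(classify_trajectory(tr, att, settle = 0.1, window = 0.05),
                   "unclassified")
  expect_error(classify_trajectory(tr, att), "settle")
})

test_that("attractor sets enforce the separation invariant", {
  expect_error(attractor_set(rbind(0, 0.02), delta = 1e-2), "separated")
  expect_silent(attractor_set(rbind(0, 0.05), delta = 1e-2))
})

test_that("delay-stability revalidation keeps the Hopfield equilibria", {
  sys <- hopfield_system(tau = 2)
  att <- hopfield_attractors(sys)
  att2 <- revalidate_attractors(sys, att, n_checks = 2)
  expect_equal(att2$label, att$label)
  expect_length(attr(att2, "destabilized"), 0)
})
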