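test_that("orthonormal families have identity Gram matrices", {
  for (fam in c("trigonometric", "legendre")) {
    b <- basis_spec(fam, 8)
    G <- gram_matrix(b)
    expect_lt(max(abs(G - diag(8))), 1e-8)
  }
})

test_that("Bernstein functions form a partition of unity", {
  b <- basis_spec("bernstein", 3)
  th <- seq(0, 1, by = 0.1)
  B <- basis_functions(b, th)
  expect_equal(rowSums(B), rep(1, length(th)), tolerance = 1e-12)
  # B_{0,2}, B_{1,2}, B_{2,2} at theta = 0.25
  expect_equal(as.numeric(basis_functions(b, 0.25)),
               c(0.75^2, 2 * 0.25 * 0.75, 0.25^2))
})

test_that("basis ordering and normalization follow the documented choices", {
  # trigonometric: constant term is 1/sqrt(2*pi), then cos/sin pairs
  bt <- basis_spec("trigonometric", 5)
  th <- c(-1, 0.4, 2)
  B <- basis_functions(bt, th)
  expect_equal(B[, 1], rep(1 / sqrt(2 * pi), 3))
  expect_equal(B[, 2], cos(th) / sqrt(pi))
  expect_equal(B[, 3], sin(th) / sqrt(pi))
  expect_equal(B[, 4], cos(2 * th) / sqrt(pi))
  expect_equal(B[, 5], sin(2 * th) / sqrt(pi))
  # legendre: sqrt((2k+1)/2) * P_k for degrees 0, 1, 2
  bl <- basis_spec("legendre", 3)
  L <- basis_functions(bl, th <- c(-0.7, 0, 0.9))
  expect_equal(L[, 1], rep(sqrt(1 / 2), 3))
  expect_equal(L[, 2], sqrt(3 / 2) * th)
  expect_equal(L[, 3], sqrt(5 / 2) * (3 * th^2 - 1) / 2)
})

test_that("projection picks out basis members and constants", {
  for (fam in c("trigonometric", "legendre")) {
    b <- basis_spec(fam, 6)
    for (k in c(1, 4)) {
      ek <- function(th) basis_functions(b, th)[, k]
      cf <- project_function(ek, b)
      expect_lt(max(abs(cf - replace(numeric(6), k, 1))), 1e-10)
    }
  }
  bt <- basis_spec("trigonometric", 4)
  cf <- project_function(function(th) rep(1, length(th)), bt)
  expect_equal(cf[1], sqrt(2 * pi), tolerance = 1e-10)
  expect_lt(max(abs(cf[-1])), 1e-10)
})

test_that("a projected basis member is reconstructed exactly", {
  b <- basis_spec("trigonometric", 6)
  cf <- project_function(sin, b)
  th <- seq(-pi, pi, length.out = 11)
  expect_lt(max(abs(basis_functions(b, th) %*% cf - sin(th))), 1e-10)
})

test_that("Legendre projection of t^3 matches a dense least-squares oracle", {
  f <- function(th) th^3
  # n = 4: degree-3 polynomial lies in the span, residual 0
  b4 <- basis_spec("legendre", 4)
  cf4 <- project_function(f, b4)
  th <- seq(-1, 1, length.out = 2001)
  expect_lt(max(abs(basis_functions(b4, th) %*% cf4 - f(th))), 1e-10)
  # n = 3: compare against brute-force least squares on a fine grid
  b3 <- basis_spec("legendre", 3)
  cf3 <- project_function(f, b3)
  B <- basis_functions(b3, th)
  cf_ls <- qr.solve(B, f(th))
  # the grid least squares approximates the continuous projection to the
  # grid resolution
  expect_equal(cf3, cf_ls, tolerance = 2e-3)
  res <- sqrt(mean((B %*% cf3 - f(th))^2))
  res_ls <- sqrt(mean((B %*% cf_ls - f(th))^2))
  expect_equal(res, res_ls, tolerance = 1e-4)
})

test_that("project-then-reconstruct is the identity on the span", {
  withr::with_seed(5, {
    for (fam in c("trigonometric", "legendre", "bernstein")) {
      b <- basis_spec(fam, 5)
      cf <- runif(5, -2, 2)
      f <- function(th) as.numeric(basis_functions(b, th) %*% cf)
      expect_lt(max(abs(project_function(f, b) - cf)), 1e-8)
    }
  })
})

test_that("L2 reconstruction error is non-increasing in n (orthogonal families)", {
  f <- function(th) exp(th / 2) * sin(2 * th)
  for (fam in c("trigonometric", "legendre")) {
    errs <- vapply(2:9, function(n) {
      b <- basis_spec(fam, n)
      q <- pracma::gaussLegendre(301, b$domain[1], b$domain[2])
      cf <- project_function(f, b)
      sqrt(sum(q$w * (basis_functions(b, q$x) %*% cf - f(q$x))^2))
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-10))
  }
})

test_that("the affine domain map hits the documented endpoints", {
  b <- basis_spec("bernstein", 4)
  cf <- matrix(c(0.5, -1, 2, 0.3), 1)
  tau <- 1.7
  h <- history_fun(b, cf, tau = tau)
  got <- eval_history(h, c(-tau, -tau / 2, 0))[, 1]
  want <- as.numeric(basis_functions(b, c(0, 0.5, 1)) %*% t(cf))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(eval_history(h, -2), "\\[-tau, 0\\]")
  expect_error(eval_history(h, 0.1), "\\[-tau, 0\\]")
})

test_that("zero coefficients give the zero function; offsets shift it", {
  b <- basis_spec("legendre", 3)
  h0 <- history_fun(b, matrix(0, 2, 3), tau = 1)
  expect_equal(eval_history(h0, c(-1, -0.3, 0)),
               matrix(0, 3, 2))
  hoff <- history_fun(b, matrix(0, 2, 3), tau = 1, offset = c(1.5, -2))
  expect_equal(eval_history(hoff, c(-0.5, 0)),
               matrix(c(1.5, 1.5, -2, -2), 2, 2))
})
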