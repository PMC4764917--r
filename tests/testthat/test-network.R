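test_that("the p = 0 lattice is the circulant ring with known spectrum", {
  net <- watts_strogatz_net(100, 6, 0, seed = 1)
  expect_true(all(igraph::degree(net$graph) == 6))
  expect_lt(max(abs(net$eigenvalues - ring_laplacian_spectrum(100, 6))), 1e-8)
  expect_lt(abs(net$eigenvalues[1]), 1e-10)
  expect_lt(max(abs(rowSums(net$laplacian))), 1e-12)
})

test_that("the complete graph has R = 1 and eigenvalues N", {
  fx <- fixture_system("complete-graph", N = 10)
  net <- fx$network
  expect_equal(synchronizability(net), 1, tolerance = 1e-12)
  expect_equal(net$eigenvalues[-1], rep(10, 9), tolerance = 1e-10)
})

test_that("disconnected networks are rejected by synchronizability", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "2 3", "3 1", "4 5", "5 6", "6 4"), path)
  net <- read_edge_list(path)
  expect_error(synchronizability(net), "disconnected")
})

test_that("edge lists round-trip through files", {
  net <- watts_strogatz_net(20, 4, 0.2, seed = 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(sort(back$eigenvalues), sort(net$eigenvalues), tolerance = 1e-10)
})

test_that("median synchronizability improves with rewiring (N = 100)", {
  meds <- vapply(c(0.01, 0.1, 1), function(p) {
    stats::median(vapply(1:20, function(r)
      synchronizability(watts_strogatz_net(100, 6, p, seed = 100 * r + 7)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("sigma ranges follow the monotone-scaling closed forms", {
  msf_fake <- structure(list(
    stable_intervals = tibble::tibble(lo = 1, hi = 4,
                                      lo_censored = FALSE,
                                      hi_censored = FALSE)),
    class = "msf_result")
  # complete graph: all gammas equal N, so sigma in (lo, hi) / N
  fx <- fixture_system("complete-graph", N = 8)
  rng <- stable_sigma_range(msf_fake, fx$network)
  expect_equal(unlist(rng), c(lo = 1 / 8, hi = 4 / 8), tolerance = 1e-10)
  # general single interval: (lo / gamma_2, hi / gamma_max) iff non-empty
  net <- watts_strogatz_net(30, 6, 0.1, seed = 4)
  g2 <- net$eigenvalues[2]; gm <- max(net$eigenvalues)
  rng2 <- stable_sigma_range(msf_fake, net)
  if (4 / gm > 1 / g2) {
    expect_equal(unlist(rng2), c(lo = 1 / g2, hi = 4 / gm), tolerance = 1e-10)
  } else {
    expect_equal(nrow(rng2), 0)
  }
  # R > hi/lo is exactly the empty-range condition
  expect_identical(nrow(rng2) == 0, synchronizability(net) > 4 / 1)
  # every sigma in the range keeps every mode inside the stable set
  if (nrow(rng2)) {
    for (sig in seq(rng2$lo[1], rng2$hi[1], length.out = 5)) {
      eps_k <- sig * net$eigenvalues[-1]
      expect_true(all(eps_k > 1 & eps_k < 4))
    }
  }
})

test_that("the linear-node exponent matches the characteristic-root oracle", {
  for (cfg in list(c(0.5, 1), c(2, 0.3), c(5, 0.24), c(8, 0.24))) {
    lam <- msf_lambda(cfg[1], tau = cfg[2], node = "linear",
                      t_average = 2000, dt = 0.005)$lambda
    expect_equal(lam, linear_msf_oracle(cfg[1], cfg[2]), tolerance = 0.02,
                 ignore_attr = TRUE)
  }
})

test_that("at zero coupling the exponent is the node's Lyapunov exponent", {
  lam0 <- msf_lambda(0, tau = 0.4, t_average = 3000)$lambda
  expect_gt(lam0, 0.02)
  lle <- lle_two_traj(rossler_system(), c(1, 1, 1))
  expect_equal(lam0, lle, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("scan boundaries are bisection-refined sign changes", {
  tau <- 1
  sc <- msf_scan(seq(1, 3.5, by = 0.5), tau = tau, node = "linear",
                 t_average = 1500, dt = 0.005, refine_tol = 0.01)
  expect_equal(nrow(sc$stable_intervals), 1)
  b <- sc$stable_intervals$hi[1]
  # the oracle must change sign across the reported boundary
  expect_lt(linear_msf_oracle(b - 0.05, tau), 0)
  expect_gt(linear_msf_oracle(b + 0.05, tau), 0)
  expect_true(sc$stable_intervals$lo_censored[1])
})

test_that("histories on the synchronization manifold always synchronize", {
  msf <- msf_tau04()
  net <- watts_strogatz_net(30, 6, 0.1, seed = 101)
  mb <- mean_basin_stability(net, msf = msf, tau = 0.4, n_sigma = 2, T = 15,
                             alpha = 1e-9, seed = 3)
  expect_false(mb$empty_range)
  expect_equal(mb$mean_bs, 1)
})

test_that("an empty sigma range yields a flagged zero, not an error", {
  msf <- msf_tau04()
  net <- watts_strogatz_net(30, 6, 0, seed = 1)   # ring: R too large
  mb <- mean_basin_stability(net, msf = msf, tau = 0.4, T = 10, seed = 1)
  expect_true(mb$empty_range)
  expect_equal(mb$mean_bs, 0)
})

test_that("widening the perturbation box shrinks the basin fraction", {
  msf <- msf_tau04()
  net <- watts_strogatz_net(10, 4, 0.3, seed = 21)
  bs <- vapply(c(0.3, 3), function(alpha) {
    mean_basin_stability(net, msf = msf, tau = 0.4, n_sigma = 3, T = 60,
                         alpha = alpha, seed = 5)$mean_bs
  }, numeric(1))
  expect_gte(bs[1], bs[2])
  expect_gt(bs[1], 0)
})
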