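# shared oracles and small utilities for the suite

# closed form for x'(t) = -x(t-1) with constant history 1 (method of steps)
steps_oracle <- function(t) {
  ifelse(t <= 0, 1,
         ifelse(t <= 1, 1 - t,
                1 - t + (t - 1)^2 / 2))
}

# binomial standard error of a difference of two proportions from one run
binom_se_diff <- function(p1, p2, T) sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / T)

# largest Lyapunov exponent by two-trajectory renormalization (independent
# of the variational-equation machinery)
lle_two_traj <- function(system, x0, d0 = 1e-8, t_seg = 1, n_seg = 400,
                         t_burn = 100, dt = 0.01) {
  tr <- dde_integrate(system, constant_history(x0, tau = 1),
                      t_end = t_burn, dt = dt, keep_every = 10000L)
  a <- as.numeric(tr$state[nrow(tr$state), ])
  b <- a + c(d0, rep(0, length(a) - 1))
  logs <- numeric(n_seg)
  for (i in seq_len(n_seg)) {
    ta <- dde_integrate(system, constant_history(a, tau = 1), t_end = t_seg,
                        dt = dt, keep_every = 10000L)
    tb <- dde_integrate(system, constant_history(b, tau = 1), t_end = t_seg,
                        dt = dt, keep_every = 10000L)
    a <- as.numeric(ta$state[nrow(ta$state), ])
    bn <- as.numeric(tb$state[nrow(tb$state), ])
    dv <- bn - a
    nrm <- sqrt(sum(dv^2))
    logs[i] <- log(nrm / d0)
    b <- a + dv / nrm * d0
  }
  mean(logs) / t_seg
}

# dominant characteristic root of lambda = -1 - eps * exp(-lambda * tau)
linear_msf_oracle <- function(eps, tau) {
  fixture_system("linear-msf-oracle", tau = tau)$expectations$lambda_oracle(eps, tau)
}

# master-stability scan at tau = 0.4 shared by the network tests
# (computed once per test run)
msf_tau04 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- msf_scan(seq(0, 4.5, by = 0.5), tau = 0.4, t_average = 1000)
    }
    cache
  }
})
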