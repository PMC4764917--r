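#' Two-neuron delayed Hopfield model
#'
#' The multistable two-neuron Hopfield network with delayed self-feedback
#' and delayed cross-coupling,
#' \deqn{\dot u_i = -b\,u_i(t) + a\,f(u_i(t-\tau_s)) +
#'       a_{ij}\,f(u_j(t-\tau_{ij})) + I_i, \quad j \ne i,}
#' with activation \eqn{f = \tanh}.  At the default parameters
#' (\eqn{a = 2}, \eqn{b = 1}, \eqn{a_{12} = a_{21} = 0.55}, zero inputs) the
#' system has four asymptotically stable equilibria arranged symmetrically
#' around the unstable origin: an anti-diagonal pair
#' \eqn{\pm(u_m, -u_m)} and a diagonal pair \eqn{\pm(u_d, u_d)}; see
#' [hopfield_attractors()].  In the associative-memory reading each
#' equilibrium is a stored pattern and its basin volume the probability
#' that a random initial history recalls it.
#'
#' @param a self-feedback gain (> 0).
#' @param b decay rate (> 0, 1/time).
#' @param a12,a21 cross-coupling weights (>= 0).
#' @param I1,I2 external inputs.
#' @param tau common transmission delay; `tau_s`, `tau12`, `tau21` override
#'   the self- and cross-coupling delays individually.
#' @param tau_s,tau12,tau21 individual delays (default all equal `tau`).
#' @return a [dde_system()] with a compiled right-hand side.
#' @export
hopfield_system <- function(a = 2, b = 1, a12 = 0.55, a21 = 0.55,
                            I1 = 0, I2 = 0, tau = 2,
                            tau_s = tau, tau12 = tau, tau21 = tau) {
  if (a <= 0 || b <= 0 || a12 < 0 || a21 < 0) {
    abort("need a > 0, b > 0, a12 >= 0, a21 >= 0.")
  }
  pars <- c(a = a, b = b, a12 = a12, a21 = a21, I1 = I1, I2 = I2)
  rhs <- function(t, x, xlag) {
    c(-b * x[1] + a * tanh(xlag[1, 1]) + a12 * tanh(xlag[2, 2]) + I1,
      -b * x[2] + a * tanh(xlag[2, 1]) + a21 * tanh(xlag[1, 3]) + I2)
  }
  new_dde_system(rhs = rhs, s = 2, delays = c(tau_s, tau12, tau21),
                 pars = pars, name = "hopfield", model = 1L)
}

#' Stable equilibria of the delayed Hopfield model as an attractor set
#'
#' Runs the equilibrium census ([find_equilibria()]) on the
#' zero-delay reduction (delays do not move equilibria) and labels the four
#' stable states: `E1`, `E2` are the anti-diagonal pair
#' \eqn{\pm(u_m, -u_m)} (whose basins shrink as the delay grows) and `E3`,
#' `E4` the diagonal pair \eqn{\pm(u_d, u_d)} (dominant at large delay),
#' each pair ordered with the positive first component first.
#'
#' @param system a [hopfield_system()].
#' @param delta classification tolerance passed to [attractor_set()].
#' @param ... passed to [find_equilibria()].
#' @return an [attractor_set()] with labels `E1..E4`.
#' @export
hopfield_attractors <- function(system = hopfield_system(), delta = 1e-2, ...) {
  eq <- find_equilibria(system, lower = c(-4, -4), upper = c(4, 4), ...)
  st <- eq[eq$stable, , drop = FALSE]
  states <- as.matrix(st[, c("x1", "x2")])
  anti <- which(states[, 1] * states[, 2] < 0)
  diag_ <- which(states[, 1] * states[, 2] > 0)
  if (length(anti) != 2 || length(diag_) != 2) {
    abort(sprintf("expected 2 + 2 symmetric stable equilibria, found %d.",
                  nrow(states)))
  }
  anti <- anti[order(-states[anti, 1])]
  diag_ <- diag_[order(-states[diag_, 1])]
  attractor_set(states[c(anti, diag_), , drop = FALSE],
                labels = c("E1", "E2", "E3", "E4"), delta = delta)
}

#' Rossler oscillator
#'
#' The chaotic Rossler system
#' \eqn{\dot x = -y - z}, \eqn{\dot y = x + a y},
#' \eqn{\dot z = b + z (x - c)}, used here as the node dynamics of
#' delay-coupled networks.  The defaults \eqn{(a, b, c) = (0.2, 0.2, 7)}
#' are the standard choice of the (non-delayed) basin-stability literature
#' for synchronization studies, for which the x-coupled
#' master stability function has the classic stable interval
#' \eqn{\varepsilon \in (0.186, 4.614)} at zero coupling delay.
#'
#' @param a,b,c Rossler parameters.
#' @return a [dde_system()] without delays.
#' @export
rossler_system <- function(a = 0.2, b = 0.2, c = 7) {
  pars <- c(a = a, b = b, c = c)
  rhs <- function(t, x, xlag) {
    c(-x[2] - x[3], x[1] + a * x[2], b + x[3] * (x[1] - c))
  }
  new_dde_system(rhs = rhs, s = 3, delays = numeric(0), pars = pars,
                 name = "rossler", model = 2L)
}

#' Analytically tractable fixture systems
#'
#' Small systems with known attractors and basins, used throughout the test
#' suite as independent oracles for the Monte-Carlo machinery:
#'
#' * `"bistable-scalar"`: \eqn{\dot x = x(t-\tau) - x(t)^3}; stable
#'   equilibria at \eqn{\pm 1}, unstable at 0.  Odd symmetry forces the two
#'   basin volumes to be equal for any sign-symmetric sampling plan.
#' * `"linear-stable"`: \eqn{\dot x = -x(t-\tau) + d}; single globally
#'   attracting equilibrium \eqn{x^* = d} (for \eqn{\tau < \pi/2}), so the
#'   basin-stability estimate is 1 for every basis, order and bound.
#' * `"halfspace"`: the shifted double well \eqn{\dot x = (x - m) -
#'   (x - m)^3} (no delay); trajectories converge to \eqn{m + 1} exactly
#'   when \eqn{x(0) > m}, and \eqn{x(0)} is a linear functional of the
#'   history coefficients, so the basin in coefficient space is an explicit
#'   half-space whose hypercube fraction can be computed without
#'   integrating the system (`expectations$halfspace_fraction`).
#' * `"linear-msf-oracle"`: scalar node \eqn{F(x) = -x} with delayed
#'   coupling; the master-stability exponent \eqn{\Lambda(\varepsilon)}
#'   equals the real part of the dominant root of
#'   \eqn{\lambda = -1 - \varepsilon e^{-\lambda\tau}}
#'   (`expectations$lambda_oracle`, solved by damped complex Newton
#'   iteration from a grid of starting points).
#' * `"complete-graph"`: the complete graph on `N` nodes as a
#'   [watts_strogatz_net()]; all non-zero Laplacian eigenvalues equal `N`, so the
#'   synchronizability ratio is exactly 1.
#'
#' @param name fixture name (see above).
#' @param tau delay used by the delayed fixtures.
#' @param d drift of the linear fixture (equilibrium location).
#' @param m well midpoint of the half-space fixture.
#' @param N node count of the complete-graph fixture.
#' @param delta classification tolerance for the fixture's attractor set.
#' @return a list with components `system`, `attractors` (where relevant)
#'   and `expectations` (named list of machine-checkable facts).
#' @export
fixture_system <- function(name = c("bistable-scalar", "linear-stable",
                                    "halfspace", "linear-msf-oracle",
                                    "complete-graph"),
                           tau = 0.5, d = 0.5, m = 0.3, N = 10,
                           delta = 1e-2) {
  name <- match.arg(name)
  switch(name,
    "bistable-scalar" = {
      sys <- new_dde_system(
        rhs = function(t, x, xlag) xlag[1, 1] - x[1]^3,
        s = 1, delays = tau, pars = c(tau = tau),
        name = "bistable-scalar", model = 3L)
      list(system = sys,
           attractors = attractor_set(rbind(1, -1), c("plus", "minus"),
                                      delta = delta),
           expectations = list(equal_basins = c("plus", "minus"),
                               basin_sum = 1))
    },
    "linear-stable" = {
      sys <- new_dde_system(
        rhs = function(t, x, xlag) -xlag[1, 1] + d,
        s = 1, delays = tau, pars = c(d = d, tau = tau),
        name = "linear-stable", model = 4L)
      if (tau >= pi / 2) abort("linear fixture needs tau < pi/2 for stability.")
      list(system = sys,
           attractors = attractor_set(rbind(d), "star", delta = delta),
           expectations = list(p_hat = 1))
    },
    "halfspace" = {
      sys <- new_dde_system(
        rhs = function(t, x, xlag) (x[1] - m) - (x[1] - m)^3,
        s = 1, delays = numeric(0), pars = c(m = m),
        name = "halfspace", model = 5L)
      frac <- function(plan) {
        # P( sum_i w_i a_i > m ) with a_i iid U[-alpha, alpha] and
        # w_i = e_i(theta(0)): Monte-Carlo on the linear functional alone
        basis <- plan$basis
        w <- as.numeric(basis_functions(basis, basis$domain[2]))
        nsim <- 1e6
        withr::with_seed(derive_seed(plan$seed, 999), {
          a <- matrix(runif(nsim * basis$n, -plan$alpha, plan$alpha),
                      nsim, basis$n)
          mean(a %*% w > m)
        })
      }
      list(system = sys,
           attractors = attractor_set(rbind(m + 1, m - 1), c("upper", "lower"),
                                      delta = delta),
           expectations = list(halfspace_fraction = frac))
    },
    "linear-msf-oracle" = {
      oracle <- function(eps, tau_ = tau) {
        g <- function(l) l + 1 + eps * exp(-l * tau_)
        gp <- function(l) 1 - eps * tau_ * exp(-l * tau_)
        best <- -Inf
        for (x0 in seq(-4, 3, by = 0.7)) for (y0 in seq(0, 40, by = 1.7)) {
          l <- complex(real = x0, imaginary = y0)
          for (it in 1:60) {
            step <- g(l) / gp(l)
            l <- l - step
            if (Mod(step) < 1e-13) break
          }
          if (Mod(g(l)) < 1e-9) best <- max(best, Re(l))
        }
        best
      }
      list(system = NULL, tau = tau,
           expectations = list(lambda_oracle = oracle))
    },
    "complete-graph" = {
      net <- complete_graph_net(N)
      list(system = NULL, network = net,
           expectations = list(R = 1, nonzero_eigenvalue = N))
    })
}
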