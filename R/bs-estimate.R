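#' Sampling plan for the coefficient hypercube
#'
#' A basin-stability run samples `T` coefficient matrices uniformly from
#' the hypercube \eqn{C_{(n,\alpha)} = [-\alpha, \alpha]^{s\,n}} (each of
#' the `s` state components gets an independent coefficient row), maps each
#' to a history function through the basis expansion, integrates, and
#' classifies.  The plan records everything needed to reproduce the draw.
#'
#' @param basis a [basis_spec()] or a family name (combined with `n`).
#' @param n expansion order (number of basis functions).
#' @param alpha coefficient bound (> 0).
#' @param T sample count (>= 1).
#' @param seed RNG seed (required: all randomness flows from it).
#' @return an object of class `sample_plan`.
#' @export
sample_plan <- function(basis = "trigonometric", n = 20, alpha = 6,
                        T = 1000, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible plan.")
  if (!inherits(basis, "basis_spec")) basis <- basis_spec(basis, n)
  if (!is.numeric(alpha) || alpha <= 0) abort("`alpha` must be > 0.")
  T <- as.integer(T)
  if (is.na(T) || T < 1) abort("`T` must be a positive integer.")
  structure(list(basis = basis, n = basis$n, alpha = alpha, T = T,
                 seed = as.integer(seed)),
            class = "sample_plan")
}

#' @export
print.sample_plan <- function(x, ...) {
  cat(sprintf("<sample_plan: %s, n = %d, alpha = %g, T = %d, seed = %d>\n",
              x$basis$family, x$n, x$alpha, x$T, x$seed))
  invisible(x)
}

#' Draw coefficient matrices from the hypercube
#'
#' @param plan a [sample_plan()].
#' @param s number of state components.
#' @return an `s x n x T` array of i.i.d. uniform draws on
#'   \eqn{[-\alpha, \alpha]}; identical for identical plans.
#' @export
sample_coefficients <- function(plan, s) {
  stopifnot(inherits(plan, "sample_plan"))
  withr::with_seed(plan$seed, {
    array(runif(s * plan$n * plan$T, -plan$alpha, plan$alpha),
          dim = c(s, plan$n, plan$T))
  })
}

#' Sample size for a target confidence half-width
#'
#' Standard binomial/normal planning: the smallest `T` whose
#' normal-approximation half-width \eqn{z\sqrt{p(1-p)/T}} does not exceed
#' `half_width` at the worst-case proportion.
#'
#' @param half_width target half-width (in (0, 1/2)).
#' @param level confidence level.
#' @param p planning proportion (worst case 1/2 by default).
#' @return integer sample count.
#' @examples
#' choose_sample_size(0.05)   # 385
#' choose_sample_size(0.01)   # 9604
#' @export
choose_sample_size <- function(half_width, level = 0.95, p = 0.5) {
  if (half_width <= 0 || half_width >= 0.5) abort("`half_width` must be in (0, 0.5).")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  z <- stats::qnorm(1 - (1 - level) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / half_width^2))
}

#' Monte-Carlo estimate of generalized basin stability
#'
#' For each sampled coefficient matrix, builds the history function,
#' integrates the system and classifies the endpoint behaviour
#' ([classify_trajectory()] semantics); the basin stability of attractor
#' \eqn{k} is estimated as \eqn{\hat p_k = M_k / T}, i.e. the fraction of
#' the coefficient hypercube (normalized by its volume
#' \eqn{(2\alpha)^{sn}}) whose histories end up on that attractor, making
#' estimates directly comparable across orders and bounds.  Trajectories
#' that settle on no attractor (divergent or still transient) are counted
#' separately and never assigned; \eqn{\sum_k M_k + M_{uncl} = T} always.
#'
#' Systems with a compiled right-hand side run the whole loop in C++; by
#' default a trajectory is classified early once it has stayed within
#' `delta / 2` of one attractor for a full window, which does not change
#' labels for trajectories that truly settle (set `early_exit = FALSE` for
#' the literal final-window rule).
#'
#' @param system a [dde_system()].
#' @param attractors an [attractor_set()] of equilibria.
#' @param plan a [sample_plan()].
#' @param tau history span (defaults to the largest system delay; must be
#'   positive for a meaningful expansion).
#' @param dt,t_end,settle,window integration/classification settings.
#' @param early_exit classify settled trajectories early (compiled path).
#' @param level confidence level of the Wilson score intervals.
#' @param coefficients optional pre-drawn `s x n x T` array overriding the
#'   plan's draw (used by [convergence_scan()] for common random numbers).
#' @param div_bound divergence bound.
#' @return an object of class `bs_estimate`; see [tidy.bs_estimate()].
#' @examples
#' fx <- fixture_system("bistable-scalar")
#' plan <- sample_plan("legendre", n = 4, alpha = 2, T = 200, seed = 1)
#' estimate_bs(fx$system, fx$attractors, plan, t_end = 100, settle = 50)
#' @export
estimate_bs <- function(system, attractors, plan, tau = NULL,
                        dt = 0.05, t_end = 300, settle = 200, window = 20,
                        early_exit = TRUE, level = 0.95,
                        coefficients = NULL, div_bound = 1e6) {
  stopifnot(inherits(system, "dde_system"),
            inherits(attractors, "attractor_set"),
            inherits(plan, "sample_plan"))
  tau <- tau %||% tau_max(system)
  if (tau <= 0) tau <- 1  # history span for delay-free systems
  if (t_end < settle + window) abort("`t_end` must exceed settle + window.")
  delta <- attr(attractors, "delta")
  states <- attractor_states(attractors)
  s <- system$s
  coef <- coefficients %||% sample_coefficients(plan, s)
  stopifnot(length(dim(coef)) == 3, dim(coef)[1] == s, dim(coef)[2] == plan$n)
  T <- dim(coef)[3]
  dt <- snap_dt(dt, system$delays)

  if (system$model > 0L) {
    coef_all <- matrix(coef, nrow = s * plan$n, ncol = T)
    ca <- cpp_args(system)
    res <- cpp_bs_batch(ca$model, ca$pars, ca$lap, s, system$delays,
                        plan$basis$id, plan$n, coef_all, tau,
                        t_end, dt, states, delta, window,
                        early_exit, div_bound)
    labels <- res$label
    n_div <- sum(res$diverged)
  } else {
    labels <- integer(T)
    n_div <- 0L
    for (i in seq_len(T)) {
      h <- history_fun(plan$basis, coef[, , i, drop = FALSE][, , 1], tau)
      tr <- dde_integrate(system, h, t_end = t_end, dt = dt,
                          div_bound = div_bound)
      if (tr$diverged) { n_div <- n_div + 1L; next }
      lab <- classify_trajectory(tr, attractors, settle = settle,
                                 window = window, delta = delta)
      labels[i] <- match(lab, attractors$label, nomatch = 0L)
    }
  }

  M <- tabulate(labels, nbins = nrow(attractors))
  unclassified <- T - sum(M)
  ci <- t(vapply(M, wilson_ci, numeric(2), T = T, level = level))
  table <- tibble::tibble(
    attractor = attractors$label, M = M, T = T, p_hat = M / T,
    ci_lo = ci[, 1], ci_hi = ci[, 2])
  if (unclassified > 0 && unclassified == T) {
    warning("no trajectory was classified: t_end may be too small or the attractor set incomplete.")
  }
  structure(list(table = table, unclassified = unclassified,
                 n_diverged = n_div, T = T, plan = plan,
                 system = system$name, tau = tau, level = level,
                 settings = list(dt = dt, t_end = t_end, settle = settle,
                                 window = window, early_exit = early_exit)),
            class = "bs_estimate")
}

#' @export
print.bs_estimate <- function(x, ...) {
  cat(sprintf("<bs_estimate: %s | %s basis, n = %d, alpha = %g, T = %d, tau = %g>\n",
              x$system, x$plan$basis$family, x$plan$n, x$plan$alpha, x$T, x$tau))
  print(x$table)
  cat(sprintf("unclassified: %d (%.3g%%), diverged: %d\n",
              x$unclassified, 100 * x$unclassified / x$T, x$n_diverged))
  invisible(x)
}

#' Tidy a basin-stability estimate
#'
#' @param x a [estimate_bs()] result.
#' @param ... unused.
#' @return a tibble with one row per attractor: counts `M`, totals `T`,
#'   estimate `p_hat`, Wilson interval `ci_lo`/`ci_hi`, plus provenance
#'   columns (model, basis, n, alpha, tau, seed).
#' @method tidy bs_estimate
#' @export
tidy.bs_estimate <- function(x, ...) {
  dplyr::mutate(x$table,
                model = x$system, basis = x$plan$basis$family,
                n = x$plan$n, alpha = x$plan$alpha, tau = x$tau,
                seed = x$plan$seed)
}

#' @rdname tidy.bs_estimate
#' @return for `glance()`: a one-row tibble with the classified fraction,
#'   unclassified count and sampling provenance.
#' @method glance bs_estimate
#' @export
glance.bs_estimate <- function(x, ...) {
  tibble::tibble(model = x$system, basis = x$plan$basis$family,
                 n = x$plan$n, alpha = x$plan$alpha, tau = x$tau,
                 T = x$T, classified = sum(x$table$M),
                 unclassified = x$unclassified, diverged = x$n_diverged,
                 coverage = sum(x$table$p_hat), seed = x$plan$seed)
}
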