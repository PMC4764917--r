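#' Master stability function for delay-coupled networks
#'
#' For an undirected network of identical units
#' \eqn{\dot x_i = F(x_i) - \sigma \sum_j g_{ij} E\, x_j(t-\tau)} with
#' Laplacian \eqn{G = (g_{ij})}, the synchronization manifold obeys
#' \eqn{\dot s = F(s)} (zero row sums cancel the coupling) and each
#' transverse mode satisfies the delayed variational equation
#' \deqn{\dot\xi = DF(s(t))\,\xi - \varepsilon\, E\, \xi(t-\tau),
#'       \qquad \varepsilon = \sigma\gamma_k,}
#' one equation per non-zero Laplacian eigenvalue \eqn{\gamma_k}.
#' `msf_lambda()` computes the largest Lyapunov exponent \eqn{\Lambda} of
#' that equation by long integration with Benettin-style renormalization of
#' the full discretized variational history segment (the state of a delayed
#' variational equation is the history, not a point); the synchronous state
#' is stable exactly when \eqn{\Lambda(\sigma\gamma_k) < 0} for all
#' \eqn{k \ge 2}.
#'
#' `E` selects the coupled components: `"x"` (default; the x-to-x coupling
#' used for the Rossler network study), `"y"`, `"z"`, or `"all"` (identity
#' coupling function).  `c_inst` optionally adds an instantaneous
#' self-coupling term \eqn{-c_{inst} E\, \xi(t)} and `c_orbit` a delayed
#' feedback \eqn{c_{orbit} E (s(t-\tau) - s(t))} on the synchronous orbit,
#' which together cover transmission-delay conventions in which the self
#' term is not delayed; both default to zero (fully delayed coupling).
#'
#' @param eps normalized coupling \eqn{\varepsilon = \sigma\gamma_k} (the
#'   coefficient of the delayed term).
#' @param tau coupling delay (>= 0).
#' @param node node dynamics: a [rossler_system()] or the string
#'   `"linear"` for the scalar test node \eqn{F(x) = -x} (whose exponent
#'   has a characteristic-root closed form, see
#'   [fixture_system()]`("linear-msf-oracle")`).
#' @param component coupled component, see above.
#' @param c_inst,c_orbit optional instantaneous/orbit coupling
#'   coefficients (see above).
#' @param t_average averaging time for the exponent.
#' @param t_transient node transient discarded before coupling the
#'   variational equation.
#' @param t_discard variational transient discarded from the average.
#' @param dt integration step (snapped so `tau` is a multiple).
#' @param renorm_dt renormalization interval.
#' @param s0,xi0 initial node state and variational direction
#'   (deterministic defaults).
#' @return for `msf_lambda()`: a one-row tibble with `eps`, `lambda`,
#'   `fluct` (running-average fluctuation over the last half; an estimate
#'   is flagged `converged = FALSE` when it exceeds `0.05 + 5%` of
#'   `|lambda|`) and `ok`.
#' @export
msf_lambda <- function(eps, tau, node = rossler_system(), component = "x",
                       c_inst = 0, c_orbit = 0,
                       t_average = 2000, t_transient = 200, t_discard = 200,
                       dt = 0.01, renorm_dt = 1,
                       s0 = c(1, 1, 1), xi0 = c(1, 0.7, 0.3)) {
  comp <- match.arg(component, c("x", "y", "z", "all"))
  comp_id <- match(comp, c("x", "y", "z", "all")) - 1L
  if (tau > 0) dt <- snap_dt(dt, tau)
  if (identical(node, "linear")) {
    node_id <- 1L; pars <- numeric(0); xi0 <- xi0[1]
  } else {
    stopifnot(inherits(node, "dde_system"))
    if (node$model != 2L) abort("`node` must be rossler_system() or \"linear\".")
    node_id <- 2L; pars <- as.numeric(node$pars)
  }
  res <- cpp_msf_lyap(node_id, pars, c_inst, eps, c_orbit, tau, comp_id,
                      dt, t_transient, t_discard, t_average, renorm_dt,
                      as.numeric(s0), as.numeric(xi0))
  fluct <- res$fluct
  tibble::tibble(eps = eps, lambda = res$lambda, fluct = fluct,
                 ok = isTRUE(res$ok),
                 converged = isTRUE(res$ok) &&
                   is.finite(fluct) && fluct < 0.05 + 0.05 * abs(res$lambda))
}

#' @rdname msf_lambda
#'
#' @param eps_grid grid of \eqn{\varepsilon} values to scan.
#' @param refine_tol width to which each sign-change boundary is refined by
#'   bisection.
#' @param ... passed on to `msf_lambda()`.
#' @return for `msf_scan()`: an object of class `msf_result` with the
#'   \eqn{\Lambda(\varepsilon)} table and the extracted stable intervals
#'   \eqn{\{\varepsilon : \Lambda < 0\}} (disjoint, sorted, boundaries
#'   refined by bisection; intervals reaching the grid ends are flagged
#'   censored).
#' @export
msf_scan <- function(eps_grid, tau, ..., refine_tol = 0.01) {
  eps_grid <- sort(unique(as.numeric(eps_grid)))
  tab <- dplyr::bind_rows(lapply(eps_grid, function(e)
    msf_lambda(e, tau = tau, ...)))
  lam <- tab$lambda
  if (any(!is.finite(lam))) abort("non-finite Lyapunov estimates in the scan.")

  bisect <- function(lo, hi, f_lo) {
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      f_mid <- msf_lambda(mid, tau = tau, ...)$lambda
      if (sign(f_mid) == sign(f_lo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  boundaries <- list()
  for (i in seq_len(length(eps_grid) - 1)) {
    if (sign(lam[i]) != sign(lam[i + 1]) && lam[i] != 0) {
      b <- bisect(eps_grid[i], eps_grid[i + 1], lam[i])
      boundaries[[length(boundaries) + 1]] <-
        list(eps = b, direction = if (lam[i] > 0) "down" else "up")
    }
  }
  # assemble stable intervals from the sign pattern
  stable <- list()
  open_lo <- if (lam[1] < 0) eps_grid[1] else NA_real_
  lo_censored <- lam[1] < 0
  for (b in boundaries) {
    if (b$direction == "down") {
      open_lo <- b$eps; lo_censored <- FALSE
    } else if (!is.na(open_lo)) {
      stable[[length(stable) + 1]] <-
        tibble::tibble(lo = open_lo, hi = b$eps,
                       lo_censored = lo_censored, hi_censored = FALSE)
      open_lo <- NA_real_
    }
  }
  if (!is.na(open_lo)) {
    stable[[length(stable) + 1]] <-
      tibble::tibble(lo = open_lo, hi = eps_grid[length(eps_grid)],
                     lo_censored = lo_censored, hi_censored = TRUE)
  }
  stable <- if (length(stable)) dplyr::bind_rows(stable) else
    tibble::tibble(lo = numeric(0), hi = numeric(0),
                   lo_censored = logical(0), hi_censored = logical(0))
  structure(list(table = tab, stable_intervals = stable, tau = tau,
                 eps_grid = eps_grid, refine_tol = refine_tol),
            class = "msf_result")
}

#' @export
print.msf_result <- function(x, ...) {
  cat(sprintf("<msf_result: tau = %g, %d grid points on [%g, %g]>\n",
              x$tau, length(x$eps_grid), min(x$eps_grid), max(x$eps_grid)))
  if (nrow(x$stable_intervals)) {
    cat("stable intervals (Lambda < 0):\n")
    print(as.data.frame(round(x$stable_intervals[, c("lo", "hi")], 4)),
          row.names = FALSE)
  } else {
    cat("no stable interval on the scanned grid\n")
  }
  invisible(x)
}

#' @method tidy msf_result
#' @export
tidy.msf_result <- function(x, ...) x$table

#' @method glance msf_result
#' @export
glance.msf_result <- function(x, ...) {
  tibble::tibble(tau = x$tau, n_grid = length(x$eps_grid),
                 n_stable_intervals = nrow(x$stable_intervals),
                 lambda_min = min(x$table$lambda),
                 lambda_max = max(x$table$lambda))
}

#' Coupling strengths that synchronize a given network
#'
#' Intersects, over every transverse mode \eqn{k \ge 2}, the set
#' \eqn{\{\sigma > 0 : \sigma\gamma_k \in \text{stable } \varepsilon
#' \text{-set}\}}.  An empty result is a valid outcome: the network cannot
#' be stably synchronized at any coupling strength (this happens exactly
#' when the synchronizability `R` exceeds `hi/lo` for a single stable
#' interval).
#'
#' @param msf an [msf_scan()] result.
#' @param net a network spec ([watts_strogatz_net()]).
#' @return a tibble of disjoint `lo`/`hi` sigma intervals (possibly empty).
#' @export
stable_sigma_range <- function(msf, net) {
  stopifnot(inherits(msf, "msf_result"), inherits(net, "network_spec"))
  if (net$eigenvalues[2] <= 1e-9) abort("network is disconnected.")
  eps_set <- as.matrix(msf$stable_intervals[, c("lo", "hi")])
  if (nrow(eps_set) == 0) {
    return(tibble::tibble(lo = numeric(0), hi = numeric(0)))
  }
  gammas <- net$eigenvalues[-1]
  acc <- scale_intervals(eps_set, 1 / gammas[1])
  for (g in gammas[-1]) {
    acc <- intersect_intervals(acc, scale_intervals(eps_set, 1 / g))
    if (nrow(acc) == 0) break
  }
  tibble::tibble(lo = acc[, 1], hi = acc[, 2])
}
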