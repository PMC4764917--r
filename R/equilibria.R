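#' Find equilibria of a DDE system
#'
#' Equilibria of a system with discrete delays coincide with the roots of
#' the right-hand side evaluated with every delayed argument equal to the
#' instantaneous state, so the search runs on that frozen map: Newton
#' iterations (numeric Jacobian) are started from a regular grid over a
#' search box, converged roots are deduplicated, and each root is flagged
#' stable or unstable from the eigenvalues of the zero-delay Jacobian (all
#' real parts negative).  This flag is the zero-delay assessment;
#' delay-induced instability at a working delay can be checked empirically
#' with [revalidate_attractors()].  Seeds whose Newton iteration fails to
#' converge are discarded silently.
#'
#' @param system a [dde_system()].
#' @param lower,upper numeric vectors delimiting the search box.
#' @param grid_n grid points per dimension (grid size is `grid_n^s`).
#' @param tol residual tolerance for an accepted root.
#' @param dedup_tol sup-norm distance under which two roots are merged.
#' @param max_iter Newton iterations per seed.
#' @return a tibble of class `equilibrium_set` with columns `x1..xs`,
#'   `stable`, `residual` and `max_re` (largest eigenvalue real part).
#' @examples
#' find_equilibria(hopfield_system(), c(-4, -4), c(4, 4), grid_n = 21)
#' @export
find_equilibria <- function(system, lower, upper, grid_n = 41,
                            tol = 1e-8, dedup_tol = 1e-4, max_iter = 50) {
  stopifnot(inherits(system, "dde_system"))
  s <- system$s
  if (length(lower) != s || length(upper) != s || any(upper <= lower)) {
    abort("`lower` and `upper` must be length-s with upper > lower.")
  }
  g <- rhs_frozen(system)
  axes <- lapply(seq_len(s), function(j) seq(lower[j], upper[j], length.out = grid_n))
  seeds <- as.matrix(expand.grid(axes))
  span <- max(upper - lower)

  roots <- matrix(numeric(0), 0, s)
  for (i in seq_len(nrow(seeds))) {
    x <- seeds[i, ]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      fx <- g(x)
      if (any(!is.finite(fx))) break
      if (max(abs(fx)) < tol) { ok <- TRUE; break }
      J <- pracma::jacobian(g, x)
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      x <- x - step
      if (max(abs(x)) > 10 * span + max(abs(upper))) break
    }
    if (!ok) next
    if (nrow(roots) == 0 ||
        min(apply(abs(roots - matrix(x, nrow(roots), s, byrow = TRUE)), 1, max)) > dedup_tol) {
      roots <- rbind(roots, x)
    }
  }
  if (nrow(roots) == 0) {
    out <- tibble::as_tibble(matrix(numeric(0), 0, s,
                                    dimnames = list(NULL, paste0("x", 1:s))))
    out$stable <- logical(0); out$residual <- numeric(0); out$max_re <- numeric(0)
    return(structure(out, class = c("equilibrium_set", class(out))))
  }
  roots <- roots[order(-roots[, 1], if (s > 1) -roots[, 2] else NULL), ,
                 drop = FALSE]
  max_re <- apply(roots, 1, function(x) {
    J <- pracma::jacobian(g, x)
    max(Re(eigen(J, only.values = TRUE)$values))
  })
  residual <- apply(roots, 1, function(x) max(abs(g(x))))
  out <- tibble::as_tibble(as.data.frame(roots))
  names(out) <- paste0("x", seq_len(s))
  out$stable <- max_re < 0
  out$residual <- residual
  out$max_re <- max_re
  structure(out, class = c("equilibrium_set", class(out)))
}

#' Empirically re-validate attractor stability at a working delay
#'
#' The zero-delay Jacobian flag from [find_equilibria()] can miss
#' delay-induced instability, so this check integrates a few small random
#' history perturbations around each attractor at the working delay and
#' keeps the attractors to which all perturbed trajectories return.
#'
#' @param system a [dde_system()].
#' @param attractors an [attractor_set()].
#' @param tau history span (defaults to the largest system delay).
#' @param amplitude perturbation coefficient amplitude.
#' @param n_checks perturbed histories per attractor.
#' @param t_end,dt,settle,window integration and classification settings
#'   (see [classify_trajectory()]).
#' @param seed RNG seed for the perturbations.
#' @return the attractor set restricted to the empirically stable rows,
#'   with an attribute `"destabilized"` naming the dropped labels.
#' @export
revalidate_attractors <- function(system, attractors, tau = tau_max(system),
                                  amplitude = 0.05, n_checks = 3,
                                  t_end = 300, dt = 0.05, settle = 200,
                                  window = 20, seed = 1L) {
  states <- attractor_states(attractors)
  labels <- attractors$label
  basis <- basis_spec("trigonometric", 3)
  keep <- logical(nrow(states))
  for (k in seq_len(nrow(states))) {
    ok <- TRUE
    for (j in seq_len(n_checks)) {
      coef <- withr::with_seed(derive_seed(seed, 100 * k + j), {
        matrix(runif(system$s * basis$n, -amplitude, amplitude),
               system$s, basis$n)
      })
      h <- history_fun(basis, coef, tau, offset = states[k, ])
      tr <- dde_integrate(system, h, t_end = t_end, dt = dt)
      lab <- classify_trajectory(tr, attractors, settle = settle,
                                 window = window)
      if (!identical(lab, labels[k])) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  dropped <- labels[!keep]
  out <- attractor_set(states[keep, , drop = FALSE], labels[keep],
                       delta = attr(attractors, "delta"))
  attr(out, "destabilized") <- dropped
  out
}
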