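#' Convergence scan of the basin-stability estimate in n and alpha
#'
#' The generalized basin stability depends on the expansion order `n` and
#' the coefficient bound `alpha`; before trusting an estimate both must be
#' large enough that the estimates have stopped moving, simultaneously for
#' all requested bases (the cross-validation procedure).  The scan computes
#' \eqn{\hat p} on the full `(basis, n, alpha)` grid and, for each cell, a
#' fluctuation statistic: the largest absolute spread of \eqn{\hat p}
#' (over attractors) across a trailing window of 3 consecutive grid points.
#' The chosen `n*` is the smallest order at which the statistic is below
#' `tolerance` for every basis and every `alpha`; `alpha*` is then the
#' smallest bound that passes the same test along the `alpha` axis at
#' `n*`.  If no grid point qualifies the scan fails explicitly
#' (`converged = FALSE`).
#'
#' Sampling uses common random numbers: for each basis one `s x max(n) x T`
#' uniform draw on \eqn{[-1,1]} is made and every cell reuses its leading
#' `n` columns scaled by `alpha`.  Histories at neighbouring grid points
#' then differ only through the extra terms, so the trailing-difference
#' statistic measures systematic order-dependence rather than independent
#' binomial noise.
#'
#' @param system a [dde_system()].
#' @param attractors an [attractor_set()].
#' @param bases character vector of basis families to cross-validate.
#' @param n_grid increasing grid of expansion orders (>= 2 points).
#' @param alpha_grid increasing grid of coefficient bounds.
#' @param tolerance allowable fluctuation, specified a priori.  A warning
#'   is recorded when it is below the Monte-Carlo noise floor
#'   \eqn{\sqrt{0.25/T}}.
#' @param T samples per grid cell.
#' @param seed master seed.
#' @param ... integration settings passed to [estimate_bs()].
#' @return an object of class `bs_convergence` with the grid tibble, the
#'   fluctuation tibble, `n_star`, `alpha_star` and a `converged` flag.
#' @export
convergence_scan <- function(system, attractors,
                             bases = c("trigonometric", "legendre", "bernstein"),
                             n_grid = seq(2, 24, by = 2), alpha_grid = 6,
                             tolerance = 0.02, T = 2000, seed, ...) {
  if (missing(seed)) abort("`seed` is required.")
  n_grid <- sort(unique(as.integer(n_grid)))
  alpha_grid <- sort(unique(as.numeric(alpha_grid)))
  if (length(n_grid) < 2) abort("`n_grid` needs at least 2 points.")
  noise_floor <- sqrt(0.25 / T)
  noisy <- tolerance < noise_floor
  if (noisy) {
    warning(sprintf(
      "tolerance %.4g is below the Monte-Carlo noise floor %.4g at T = %d.",
      tolerance, noise_floor, T))
  }
  s <- system$s
  n_max <- max(n_grid)
  rows <- list()
  for (bi in seq_along(bases)) {
    u <- withr::with_seed(derive_seed(seed, bi), {
      array(runif(s * n_max * T, -1, 1), dim = c(s, n_max, T))
    })
    for (alpha in alpha_grid) for (n in n_grid) {
      plan <- sample_plan(bases[bi], n = n, alpha = alpha, T = T,
                          seed = derive_seed(seed, bi))
      est <- estimate_bs(system, attractors, plan,
                         coefficients = alpha * u[, seq_len(n), , drop = FALSE],
                         ...)
      rows[[length(rows) + 1]] <- tidy(est)
    }
  }
  grid <- dplyr::bind_rows(rows)

  trail_spread <- function(p, j, w = 3) {
    idx <- max(1, j - w + 1):j
    max(p[idx]) - min(p[idx])
  }
  fl <- grid |>
    dplyr::group_by(.data$basis, .data$alpha, .data$attractor) |>
    dplyr::arrange(.data$n, .by_group = TRUE) |>
    dplyr::mutate(fluct_n = vapply(seq_along(.data$p_hat), function(j)
      trail_spread(.data$p_hat, j), numeric(1))) |>
    dplyr::ungroup()
  fluct_n <- fl |>
    dplyr::group_by(.data$basis, .data$alpha, .data$n) |>
    dplyr::summarise(fluct = max(.data$fluct_n), .groups = "drop")

  # smallest n whose trailing window passes for every basis and alpha
  by_n <- fluct_n |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(worst = max(.data$fluct), .groups = "drop") |>
    dplyr::arrange(.data$n)
  eligible <- by_n$n[seq_along(by_n$n) >= min(3, length(n_grid)) &
                       by_n$worst < tolerance]
  n_star <- if (length(eligible)) min(eligible) else NA_integer_

  alpha_star <- NA_real_
  fluct_a <- NULL
  if (!is.na(n_star) && length(alpha_grid) > 1) {
    fa <- grid |>
      dplyr::filter(.data$n == n_star) |>
      dplyr::group_by(.data$basis, .data$attractor) |>
      dplyr::arrange(.data$alpha, .by_group = TRUE) |>
      dplyr::mutate(fluct_a = vapply(seq_along(.data$p_hat), function(j)
        trail_spread(.data$p_hat, j, w = min(3, length(alpha_grid))),
        numeric(1))) |>
      dplyr::ungroup()
    fluct_a <- fa |>
      dplyr::group_by(.data$basis, .data$alpha) |>
      dplyr::summarise(fluct = max(.data$fluct_a), .groups = "drop")
    by_a <- fluct_a |>
      dplyr::group_by(.data$alpha) |>
      dplyr::summarise(worst = max(.data$fluct), .groups = "drop") |>
      dplyr::arrange(.data$alpha)
    elig_a <- by_a$alpha[seq_along(by_a$alpha) >= min(3, length(alpha_grid)) &
                           by_a$worst < tolerance]
    alpha_star <- if (length(elig_a)) min(elig_a) else NA_real_
  } else if (!is.na(n_star)) {
    alpha_star <- alpha_grid[1]
  }

  structure(list(grid = grid, fluct_n = fluct_n, fluct_alpha = fluct_a,
                 n_star = n_star, alpha_star = alpha_star,
                 tolerance = tolerance, T = T,
                 converged = !is.na(n_star) && !is.na(alpha_star),
                 noise_warning = noisy, bases = bases,
                 n_grid = n_grid, alpha_grid = alpha_grid, seed = seed),
            class = "bs_convergence")
}

#' @export
print.bs_convergence <- function(x, ...) {
  cat(sprintf("<bs_convergence: %s | n in {%s}, alpha in {%s}, T = %d>\n",
              paste(x$bases, collapse = "/"),
              paste(x$n_grid, collapse = ","),
              paste(x$alpha_grid, collapse = ","), x$T))
  if (x$converged) {
    cat(sprintf("converged: n* = %d, alpha* = %g (tolerance %g)\n",
                x$n_star, x$alpha_star, x$tolerance))
  } else {
    cat(sprintf("NOT converged at tolerance %g on this grid\n", x$tolerance))
  }
  if (x$noise_warning) cat("warning: tolerance below Monte-Carlo noise floor\n")
  invisible(x)
}

#' Basin stability along a delay (or parameter) grid
#'
#' Re-estimates the basin stability of every attractor at each value of a
#' model parameter -- typically the transmission delay -- for one or more
#' bases.  The attractor set is re-validated at each grid point
#' ([revalidate_attractors()]); an attractor destabilized at some value is
#' recorded with \eqn{\hat p = 0} and flagged rather than dropped.
#'
#' @param system_factory `function(value) -> dde_system`.
#' @param grid numeric parameter grid (e.g. delays).
#' @param attractors_for `function(system, value) -> attractor_set`
#'   (defaults to reusing `attractors`).
#' @param attractors fixed attractor set (alternative to `attractors_for`).
#' @param bases basis families to run.
#' @param n,alpha,T sampling-plan settings shared across the grid.
#' @param seed master seed; each (basis, value) cell gets a derived seed.
#' @param revalidate empirically re-check attractor stability per value.
#' @param normalize add a per-(basis, attractor) min-max normalized column
#'   `p_norm` for cross-basis shape comparison.
#' @param parameter name of the grid column in the result.
#' @param ... passed to [estimate_bs()].
#' @return a tibble of class `bs_profile` with columns `basis`, the
#'   parameter, `attractor`, `M`, `T`, `p_hat`, `ci_lo`, `ci_hi`,
#'   `destabilized` and (optionally) `p_norm`.
#' @export
bs_vs_parameter <- function(system_factory, grid, attractors = NULL,
                            attractors_for = NULL,
                            bases = c("trigonometric", "legendre", "bernstein"),
                            n = 20, alpha = 6, T = 1000, seed,
                            revalidate = FALSE, normalize = TRUE,
                            parameter = "tau", ...) {
  if (missing(seed)) abort("`seed` is required.")
  if (is.null(attractors) && is.null(attractors_for)) {
    abort("provide `attractors` or `attractors_for`.")
  }
  attractors_for <- attractors_for %||% function(system, value) attractors
  rows <- list()
  for (bi in seq_along(bases)) for (gi in seq_along(grid)) {
    value <- grid[gi]
    sys <- system_factory(value)
    att <- attractors_for(sys, value)
    full_labels <- att$label
    dest <- character(0)
    if (revalidate) {
      att <- revalidate_attractors(sys, att, seed = derive_seed(seed, 9000 + gi))
      dest <- attr(att, "destabilized")
    }
    plan <- sample_plan(bases[bi], n = n, alpha = alpha, T = T,
                        seed = derive_seed(seed, 100 * bi + gi))
    est <- estimate_bs(sys, att, plan, ...)
    tb <- tidy(est)
    if (length(dest)) {
      zero <- tb[rep(1, length(dest)), ]
      zero$attractor <- dest
      zero$M <- 0L; zero$p_hat <- 0; zero$ci_lo <- 0; zero$ci_hi <- 0
      tb <- dplyr::bind_rows(tb, zero)
    }
    tb$destabilized <- tb$attractor %in% dest
    tb[[parameter]] <- value
    rows[[length(rows) + 1]] <- tb[match(full_labels, tb$attractor), ]
  }
  out <- dplyr::bind_rows(rows)
  if (normalize) {
    out <- out |>
      dplyr::group_by(.data$basis, .data$attractor) |>
      dplyr::mutate(p_norm = if (diff(range(.data$p_hat)) > 0) {
        (.data$p_hat - min(.data$p_hat)) / diff(range(.data$p_hat))
      } else rep(1, dplyr::n())) |>
      dplyr::ungroup()
  }
  class(out) <- c("bs_profile", class(out))
  attr(out, "parameter") <- parameter
  out
}

#' @rdname bs_vs_parameter
#' @param tau_grid delay grid for the Hopfield convenience wrapper.
#' @export
hopfield_bs_vs_tau <- function(tau_grid = seq(0.5, 4, by = 0.5),
                               bases = c("trigonometric", "legendre", "bernstein"),
                               n = 20, alpha = 6, T = 1000, seed, ...) {
  att <- hopfield_attractors()
  bs_vs_parameter(function(tau) hopfield_system(tau = tau), tau_grid,
                  attractors = att, bases = bases, n = n, alpha = alpha,
                  T = T, seed = seed, parameter = "tau", ...)
}

#' Cross-basis consensus of normalized basin-stability curves
#'
#' Spearman rank correlation between the (normalized) \eqn{\hat p} curves
#' of every pair of bases, per attractor: the exact basin-stability values
#' differ between bases, but their variation with the parameter should
#' agree.
#'
#' @param profile a [bs_vs_parameter()] result with `p_norm` column.
#' @param attractor attractor label(s) to compare (default: all).
#' @return a tibble with columns `attractor`, `basis_a`, `basis_b`, `rho`.
#' @export
basis_consensus <- function(profile, attractor = NULL) {
  stopifnot(inherits(profile, "bs_profile"))
  par <- attr(profile, "parameter")
  labs <- attractor %||% unique(profile$attractor)
  bases <- unique(profile$basis)
  out <- list()
  for (a in labs) {
    sub <- profile[profile$attractor == a, ]
    wide <- tidyr::pivot_wider(sub[, c(par, "basis", "p_norm")],
                               names_from = "basis", values_from = "p_norm")
    for (i in seq_along(bases)[-length(bases)]) {
      for (j in (i + 1):length(bases)) {
        out[[length(out) + 1]] <- tibble::tibble(
          attractor = a, basis_a = bases[i], basis_b = bases[j],
          rho = suppressWarnings(
            stats::cor(wide[[bases[i]]], wide[[bases[j]]],
                       method = "spearman")))
      }
    }
  }
  dplyr::bind_rows(out)
}
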