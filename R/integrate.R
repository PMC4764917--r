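#' Integrate a delay differential equation
#'
#' Fixed-step explicit Runge-Kutta 4 with the method of steps: delayed state
#' values come from the history function for \eqn{t - \tau < 0} and from
#' cubic Hermite interpolation of the stored solution afterwards.  The step
#' is snapped down so that the smallest positive delay is an integer
#' multiple of `dt` (delayed lookups then fall on stored grid points); `dt`
#' may not exceed the smallest positive delay.  The first point uses
#' `x(0) = history(0)`; derivative jumps at multiples of the delay are not
#' smoothed (they cost a bounded, local order reduction that is immaterial
#' at the classification tolerances used downstream).
#'
#' If any state component leaves `[-div_bound, div_bound]` (or becomes
#' non-finite) the integration stops and the trajectory is flagged
#' divergent rather than raising an error.
#'
#' @param system a [dde_system()].
#' @param history a [history_fun()] defined on at least the largest delay.
#' @param t_end end time (> 0).
#' @param dt requested time step; the effective step (after snapping) is
#'   stored in the result.
#' @param keep_every keep every k-th grid point in the returned trajectory.
#' @param div_bound sup-norm divergence bound.
#' @return an object of class `dde_trajectory`: a list with fields `time`,
#'   `state` (matrix, one row per kept time), `deriv`, `diverged`, `dt`,
#'   `t_last`, plus the system and history used.  Convert with
#'   [tibble::as_tibble()]; query between grid points with
#'   [trajectory_at()].
#' @examples
#' sys <- dde_system(function(t, x, xlag) -xlag[, 1], s = 1, delays = 1)
#' tr <- dde_integrate(sys, constant_history(1, tau = 1), t_end = 2, dt = 0.01)
#' tail(as_tibble(tr))   # x(t) = 1 - t on [0, 1], then 1 - t + (t-1)^2/2
#' @export
dde_integrate <- function(system, history, t_end, dt = 0.01, keep_every = 1L,
                          div_bound = 1e6) {
  stopifnot(inherits(system, "dde_system"), inherits(history, "history_fun"))
  if (!is.numeric(t_end) || t_end <= 0) abort("`t_end` must be > 0.")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be > 0.")
  tmax <- tau_max(system)
  if (history$tau + 1e-12 < tmax) {
    abort(sprintf("history spans [-%g, 0] but the largest delay is %g.",
                  history$tau, tmax))
  }
  dt <- snap_dt(dt, system$delays)
  ca <- cpp_args(system)
  ha <- history_cpp_args(history, system$s)
  res <- cpp_integrate(ca$model, ca$pars, ca$lap, system$s, system$delays,
                       ha$type, ha$const, ha$fam, ha$coef, ha$tau, ha$rfun,
                       system$rhs %||% null_fun,
                       t_end, dt, div_bound, as.integer(keep_every))
  structure(list(time = res$t, state = res$x, deriv = res$f,
                 diverged = res$diverged, t_last = res$t_last, dt = dt,
                 keep_every = as.integer(keep_every),
                 system = system, history = history),
            class = "dde_trajectory")
}

#' @export
print.dde_trajectory <- function(x, ...) {
  cat(sprintf("<dde_trajectory: %s, %d points on [0, %g], dt = %g%s>\n",
              x$system$name, length(x$time), x$t_last, x$dt,
              if (x$diverged) ", DIVERGED" else ""))
  invisible(x)
}

#' @method as_tibble dde_trajectory
#' @export
as_tibble.dde_trajectory <- function(x, ...) {
  st <- as.data.frame(x$state)
  names(st) <- paste0("x", seq_len(ncol(st)))
  tibble::as_tibble(cbind(data.frame(t = x$time), st))
}

#' @export
as.data.frame.dde_trajectory <- function(x, ...) {
  as.data.frame(as_tibble(x))
}

#' Evaluate a trajectory (or its history) at arbitrary times
#'
#' Returns the history value for `t` in \eqn{[-\tau, 0]} and the cubic
#' Hermite interpolant of the stored solution for `t` in `(0, t_last]`
#' (exact at grid points; one order below the integrator in between).
#'
#' @param trajectory a [dde_integrate()] result kept at full resolution
#'   (`keep_every = 1`).
#' @param t numeric vector of query times in \eqn{[-\tau, t_{last}]}.
#' @return a `length(t) x s` matrix of states.
#' @export
trajectory_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "dde_trajectory"))
  if (trajectory$keep_every != 1L) {
    abort("`trajectory_at()` needs a trajectory stored at full resolution.")
  }
  tau <- trajectory$history$tau
  t <- as.numeric(t)
  if (any(t < -tau - 1e-12)) {
    abort(sprintf("query before the history start -%g.", tau))
  }
  if (any(t > trajectory$t_last + 1e-12)) {
    abort("query beyond the end of the trajectory.")
  }
  s <- ncol(trajectory$state)
  out <- matrix(NA_real_, length(t), s)
  past <- t <= 0
  if (any(past)) out[past, ] <- eval_history(trajectory$history, t[past])
  if (any(!past)) {
    dt <- trajectory$dt
    for (i in which(!past)) {
      u <- t[i] / dt
      k <- floor(u)
      if (abs(u - round(u)) < 1e-9) {
        out[i, ] <- trajectory$state[round(u) + 1, ]
      } else {
        a <- u - k
        h00 <- 2 * a^3 - 3 * a^2 + 1; h10 <- a^3 - 2 * a^2 + a
        h01 <- -2 * a^3 + 3 * a^2;    h11 <- a^3 - a^2
        out[i, ] <- h00 * trajectory$state[k + 1, ] +
          h10 * dt * trajectory$deriv[k + 1, ] +
          h01 * trajectory$state[k + 2, ] +
          h11 * dt * trajectory$deriv[k + 2, ]
      }
    }
  }
  out
}

#' Write a trajectory to CSV
#'
#' Columns `t, x1..xs`, one row per kept grid point.
#'
#' @inheritParams trajectory_at
#' @param path output file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
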