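#' Define a delay differential equation system
#'
#' A `dde_system` bundles a right-hand side with its discrete delays,
#' dimension and parameters.  The right-hand side receives the current time,
#' the current state and one delayed state per delay, and must return the
#' state derivative:
#' `rhs(t, x, xlag)` with `x` a length-`s` vector and `xlag` an `s x d`
#' matrix whose column `j` is the state at `t - delays[j]`.  With all delays
#' equal to zero the system is an ordinary differential equation and `xlag`
#' simply repeats the current state.
#'
#' Built-in model constructors ([hopfield_system()], [rossler_system()],
#' [fixture_system()]) attach a compiled right-hand side so that integration
#' and Monte-Carlo sampling run in C++; systems defined directly through
#' `dde_system()` use the R function (identical results, slower).
#'
#' @param rhs right-hand side function `function(t, x, xlag)` returning a
#'   numeric vector of length `s`.
#' @param s state dimension (positive integer).
#' @param delays numeric vector of non-negative discrete delays (time units
#'   of the model); may be empty for an ODE.
#' @param pars named numeric vector of parameters (kept for provenance).
#' @param name display name.
#' @return an object of class `dde_system`.
#' @examples
#' sys <- dde_system(function(t, x, xlag) -xlag[, 1], s = 1, delays = 1)
#' traj <- dde_integrate(sys, constant_history(1, tau = 1), t_end = 2, dt = 0.01)
#' @export
dde_system <- function(rhs, s, delays = numeric(0), pars = numeric(0),
                       name = "custom") {
  stopifnot(is.function(rhs))
  new_dde_system(rhs = rhs, s = s, delays = delays, pars = pars, name = name,
                 model = 0L)
}

# internal constructor shared with the built-in models
new_dde_system <- function(rhs, s, delays, pars, name, model,
                           lap = NULL, extra = list()) {
  s <- as.integer(s)
  if (length(s) != 1 || is.na(s) || s < 1) {
    abort("`s` must be a single positive integer.")
  }
  delays <- as.numeric(delays)
  if (any(!is.finite(delays)) || any(delays < 0)) {
    abort("all `delays` must be finite and >= 0.")
  }
  if (!is.null(rhs)) {
    probe <- rhs(0, rep(0, s), matrix(0, s, max(length(delays), 1L)))
    if (length(probe) != s || !is.numeric(probe)) {
      abort(sprintf("`rhs` must return a numeric vector of length s = %d.", s))
    }
  }
  structure(
    c(list(rhs = rhs, s = s, delays = delays, pars = pars, name = name,
           model = as.integer(model), lap = lap), extra),
    class = "dde_system")
}

#' @export
print.dde_system <- function(x, ...) {
  cat(sprintf("<dde_system: %s>\n", x$name))
  cat(sprintf("  dimension: %d\n", x$s))
  if (length(x$delays)) {
    cat(sprintf("  delays: %s\n", paste(format(x$delays), collapse = ", ")))
  } else {
    cat("  delays: none (ODE)\n")
  }
  if (length(x$pars)) {
    cat(sprintf("  parameters: %s\n",
                paste(names(x$pars), format(x$pars), sep = " = ",
                      collapse = ", ")))
  }
  invisible(x)
}

# largest delay (0 for an ODE)
tau_max <- function(system) if (length(system$delays)) max(system$delays) else 0

# right-hand side with every delayed argument set to the instantaneous
# state: equilibria of the DDE are the roots of this map
rhs_frozen <- function(system) {
  d <- max(length(system$delays), 1L)
  function(x) system$rhs(0, x, matrix(rep(x, d), system$s, d))
}

# pars/lap in the layout the C++ engine expects
cpp_args <- function(system) {
  list(model = system$model,
       pars = as.numeric(system$pars),
       lap = if (is.null(system$lap)) matrix(0, 0, 0) else system$lap)
}

# snap the step down so the smallest positive delay is an integer multiple:
# delayed lookups then hit stored grid points exactly
snap_dt <- function(dt, delays) {
  pos <- delays[delays > 0]
  if (!length(pos)) return(dt)
  tmin <- min(pos)
  if (dt > tmin) dt <- tmin
  tmin / ceiling(tmin / dt - 1e-9)
}
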