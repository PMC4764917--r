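#' Attractor sets for trajectory classification
#'
#' Bundles the attractors of a system with a classification tolerance.
#' Equilibrium attractors are constant states; a periodic attractor is
#' described by reference orbit samples (distance to the attractor is then
#' the minimum over samples).  Attractors must be pairwise separated by
#' more than `3 * delta` in sup norm, which guarantees a trajectory can
#' never be classified to two attractors at once.
#'
#' @param states a `K x s` matrix of equilibrium states (one row per
#'   attractor), or a list of sample matrices for periodic attractors.
#' @param labels character labels, one per attractor.
#' @param delta classification tolerance (sup norm).
#' @param kind `"equilibrium"` or `"periodic"`.
#' @return a tibble of class `attractor_set` with columns `label` and
#'   `kind`, state coordinates as attribute.
#' @export
attractor_set <- function(states, labels = NULL, delta = 1e-2,
                          kind = "equilibrium") {
  kind <- match.arg(kind, c("equilibrium", "periodic"))
  if (kind == "equilibrium") {
    states <- as.matrix(states)
    K <- nrow(states)
  } else {
    stopifnot(is.list(states))
    K <- length(states)
  }
  labels <- labels %||% paste0("A", seq_len(K))
  if (length(labels) != K || anyDuplicated(labels)) {
    abort("`labels` must be unique, one per attractor.")
  }
  # pairwise separation check (for periodic: between closest samples)
  rep_pts <- if (kind == "equilibrium") states else
    do.call(rbind, lapply(states, function(m) m[1, , drop = FALSE]))
  if (K > 1) {
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      di <- if (kind == "equilibrium") {
        max(abs(states[i, ] - states[j, ]))
      } else {
        min(apply(states[[j]], 1, function(p)
          min(apply(abs(states[[i]] - matrix(p, nrow(states[[i]]),
                                             length(p), byrow = TRUE)), 1, max))))
      }
      if (di <= 3 * delta) {
        abort(sprintf(
          "attractors '%s' and '%s' are separated by %.3g <= 3 * delta = %.3g.",
          labels[i], labels[j], di, 3 * delta))
      }
    }
  }
  out <- tibble::tibble(label = labels, kind = kind)
  structure(out, states = states, delta = delta,
            class = c("attractor_set", class(out)))
}

# K x s matrix of equilibrium states (error for periodic sets)
attractor_states <- function(attractors) {
  st <- attr(attractors, "states")
  if (!is.matrix(st)) abort("attractor set is not purely of equilibria.")
  st
}

#' @export
print.attractor_set <- function(x, ...) {
  st <- attr(x, "states")
  cat(sprintf("<attractor_set: %d %s attractor(s), delta = %g>\n",
              nrow(x), x$kind[1], attr(x, "delta")))
  if (is.matrix(st)) {
    m <- cbind(label = x$label, as.data.frame(round(st, 6)))
    print(m, row.names = FALSE)
  }
  invisible(x)
}

#' Classify a trajectory to an attractor
#'
#' Returns the label of the unique attractor whose sup-norm distance to the
#' trajectory stays below `delta` throughout the final window
#' `[t_end - window, t_end]`, or `"unclassified"` if the trajectory
#' diverged, is still transient, or no (unique) attractor qualifies.
#' Classification is stable under trajectory extension: once a trajectory
#' has truly settled into an attractor, integrating longer never changes
#' the label.
#'
#' @param trajectory a [dde_integrate()] result.
#' @param attractors an [attractor_set()].
#' @param settle minimum settle time: the trajectory must extend beyond
#'   `settle + window`.
#' @param window length of the final window over which the distance must
#'   stay below `delta`.
#' @param delta classification tolerance (defaults to the attractor set's).
#' @return a single character label.
#' @export
classify_trajectory <- function(trajectory, attractors, settle = 200,
                                window = 20,
                                delta = attr(attractors, "delta")) {
  stopifnot(inherits(trajectory, "dde_trajectory"),
            inherits(attractors, "attractor_set"))
  if (trajectory$t_last < settle + window - 1e-9) {
    abort(sprintf("trajectory ends at %g but settle + window = %g.",
                  trajectory$t_last, settle + window))
  }
  if (trajectory$diverged) return("unclassified")
  sel <- trajectory$time >= trajectory$t_last - window - 1e-9
  X <- trajectory$state[sel, , drop = FALSE]
  st <- attr(attractors, "states")
  K <- nrow(attractors)
  dmax <- numeric(K)
  for (k in seq_len(K)) {
    if (attractors$kind[k] == "equilibrium") {
      ref <- matrix(st[k, ], nrow(X), ncol(X), byrow = TRUE)
      dmax[k] <- max(abs(X - ref))
    } else {
      orbit <- st[[k]]
      dmax[k] <- max(apply(X, 1, function(p)
        min(apply(abs(orbit - matrix(p, nrow(orbit), length(p),
                                     byrow = TRUE)), 1, max))))
    }
  }
  hit <- which(dmax < delta)
  if (length(hit) == 1) attractors$label[hit] else "unclassified"
}
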