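#' Basis families for history-function expansion
#'
#' Constructs the first `n` functions of one of three basis families used to
#' expand initial history functions of a DDE:
#'
#' * `"trigonometric"`: the orthonormal Fourier system on \eqn{[-\pi, \pi]},
#'   ordered as the constant \eqn{1/\sqrt{2\pi}}, then
#'   \eqn{\cos(k\theta)/\sqrt\pi, \sin(k\theta)/\sqrt\pi} pairs of
#'   increasing frequency \eqn{k = 1, 2, \dots}.
#' * `"legendre"`: Legendre polynomials of degrees \eqn{0..n-1} on
#'   \eqn{[-1, 1]}, normalized to unit \eqn{L^2} norm
#'   (\eqn{P_k \sqrt{(2k+1)/2}}).
#' * `"bernstein"`: the Bernstein polynomials \eqn{B_{0,n-1}..B_{n-1,n-1}}
#'   of degree \eqn{n-1} on \eqn{[0, 1]}.  Not orthogonal; the functions of
#'   each degree form a partition of unity.
#'
#' The two orthonormal families make the coefficient hypercube directly
#' comparable across families; the Bernstein family is kept non-normalized
#' and serves as the third, non-orthogonal generating family of the
#' cross-validation procedure.
#'
#' @param family one of `"trigonometric"`, `"legendre"`, `"bernstein"`
#'   (abbreviations allowed).
#' @param n number of basis functions taken (positive integer).
#' @return an object of class `basis_spec` with fields `family`, `n`,
#'   `domain` and `orthonormal`.
#' @examples
#' b <- basis_spec("legendre", 3)
#' basis_functions(b, c(-1, 0, 1))
#' @export
basis_spec <- function(family = c("trigonometric", "legendre", "bernstein"),
                       n) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || n < 1) {
    abort("`n` must be a single positive integer.")
  }
  info <- switch(family,
    trigonometric = list(id = 1L, domain = c(-pi, pi), orthonormal = TRUE),
    legendre      = list(id = 2L, domain = c(-1, 1),  orthonormal = TRUE),
    bernstein     = list(id = 3L, domain = c(0, 1),   orthonormal = FALSE))
  structure(list(family = family, n = n, domain = info$domain,
                 orthonormal = info$orthonormal, id = info$id),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec: %s, n = %d, domain [%g, %g]%s>\n",
              x$family, x$n, x$domain[1], x$domain[2],
              if (x$orthonormal) ", orthonormal" else ""))
  invisible(x)
}

#' Evaluate basis functions on their natural domain
#'
#' @param basis a [basis_spec()].
#' @param theta numeric vector of evaluation points inside the basis's
#'   natural domain.
#' @return a `length(theta) x n` matrix; column `i` is the i-th basis
#'   function.
#' @export
basis_functions <- function(basis, theta) {
  stopifnot(inherits(basis, "basis_spec"))
  theta <- as.numeric(theta)
  eps <- 1e-12
  if (any(theta < basis$domain[1] - eps) || any(theta > basis$domain[2] + eps)) {
    abort(sprintf("`theta` must lie in the basis domain [%g, %g].",
                  basis$domain[1], basis$domain[2]))
  }
  cpp_basis_matrix(basis$id, basis$n, theta)
}

#' Gram matrix of a basis on its natural domain
#'
#' Computed by Gauss-Legendre quadrature.  For the trigonometric and
#' Legendre families the result is the identity up to quadrature error.
#'
#' @inheritParams basis_functions
#' @param n_nodes number of quadrature nodes.
#' @return an `n x n` matrix of pairwise inner products.
#' @export
gram_matrix <- function(basis, n_nodes = 256) {
  q <- pracma::gaussLegendre(n_nodes, basis$domain[1], basis$domain[2])
  B <- basis_functions(basis, q$x)
  t(B) %*% (q$w * B)
}

#' Project a function onto a basis
#'
#' For the orthonormal families the coefficients are the inner products
#' \eqn{\langle f, e_i\rangle} computed by Gauss-Legendre quadrature.  For
#' the (non-orthogonal) Bernstein family projection is defined as the least
#' squares fit on a fine uniform grid.
#'
#' @param f a vectorized function on the basis's natural domain.
#' @param basis a [basis_spec()].
#' @param n_nodes quadrature nodes (orthonormal families) or grid points
#'   (Bernstein least squares).
#' @return numeric coefficient vector of length `basis$n`.
#' @examples
#' b <- basis_spec("trigonometric", 5)
#' project_function(function(th) sin(th), b)   # picks out the sin(theta) slot
#' @export
project_function <- function(f, basis, n_nodes = if (basis$orthonormal) 256 else 512) {
  stopifnot(inherits(basis, "basis_spec"), is.function(f))
  if (basis$orthonormal) {
    q <- pracma::gaussLegendre(n_nodes, basis$domain[1], basis$domain[2])
    fx <- f(q$x)
    if (any(!is.finite(fx))) abort("`f` returned non-finite values on the domain.")
    B <- basis_functions(basis, q$x)
    as.numeric(t(B) %*% (q$w * fx))
  } else {
    th <- seq(basis$domain[1], basis$domain[2], length.out = n_nodes)
    fx <- f(th)
    if (any(!is.finite(fx))) abort("`f` returned non-finite values on the domain.")
    B <- basis_functions(basis, th)
    as.numeric(qr.solve(B, fx))
  }
}

#' History functions on a delay interval
#'
#' A history function is the initial condition of a DDE: a vector-valued
#' function on \eqn{[-\tau, 0]}.  `history_fun()` represents it as a basis
#' expansion with one coefficient row per state component; the affine map
#' \eqn{\theta(t)} carries \eqn{[-\tau, 0]} onto the basis's natural domain
#' (orientation preserving, \eqn{t = -\tau} to the left endpoint).
#' Coefficients are interpreted in the natural domain; no Jacobian rescaling
#' is applied, so the coefficient hypercube itself is the object whose
#' volume fractions basin stability measures.
#'
#' `constant_history()` is the special case of a constant vector (used e.g.
#' to start a trajectory exactly on an equilibrium).
#'
#' @param basis a [basis_spec()].
#' @param coefficients an `s x n` matrix (a vector is taken as `s = 1`).
#' @param tau length of the history interval (must cover the largest delay
#'   of the system it is used with).
#' @param offset optional constant state vector added to the expansion
#'   (used to perturb around a reference state such as an equilibrium or a
#'   synchronous orbit point).
#' @return an object of class `history_fun`.
#' @examples
#' h <- history_fun(basis_spec("legendre", 3), c(1, 0.5, 0), tau = 2)
#' eval_history(h, c(-2, -1, 0))
#' @export
history_fun <- function(basis, coefficients, tau, offset = NULL) {
  stopifnot(inherits(basis, "basis_spec"))
  if (is.vector(coefficients)) coefficients <- matrix(coefficients, nrow = 1)
  coefficients <- as.matrix(coefficients)
  if (ncol(coefficients) != basis$n) {
    abort(sprintf("`coefficients` must have %d columns (one per basis function).",
                  basis$n))
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    abort("`tau` must be a single non-negative number.")
  }
  if (!is.null(offset) && length(offset) != nrow(coefficients)) {
    abort("`offset` must have one entry per state component.")
  }
  structure(list(type = "basis", basis = basis, coefficients = coefficients,
                 s = nrow(coefficients), tau = tau, offset = offset),
            class = "history_fun")
}

#' @param x constant state vector.
#' @rdname history_fun
#' @export
constant_history <- function(x, tau) {
  x <- as.numeric(x)
  structure(list(type = "constant", value = x, s = length(x), tau = tau),
            class = "history_fun")
}

#' Evaluate a history function
#'
#' @param history a [history_fun()].
#' @param t numeric vector of times in \eqn{[-\tau, 0]}.
#' @return a `length(t) x s` matrix of states.
#' @export
eval_history <- function(history, t) {
  stopifnot(inherits(history, "history_fun"))
  t <- as.numeric(t)
  if (any(t < -history$tau - 1e-12) || any(t > 1e-12)) {
    abort(sprintf("`t` must lie in [-tau, 0] = [%g, 0].", -history$tau))
  }
  if (history$type == "constant") {
    return(matrix(history$value, nrow = length(t), ncol = history$s,
                  byrow = TRUE))
  }
  b <- history$basis
  theta <- if (history$tau > 0) {
    b$domain[1] + (t + history$tau) * diff(b$domain) / history$tau
  } else {
    rep(b$domain[2], length(t))
  }
  theta <- pmin(pmax(theta, b$domain[1]), b$domain[2])
  out <- basis_functions(b, theta) %*% t(history$coefficients)
  if (!is.null(history$offset)) out <- sweep(out, 2, history$offset, "+")
  out
}

#' @export
print.history_fun <- function(x, ...) {
  if (x$type == "constant") {
    cat(sprintf("<history_fun: constant (%s) on [-%g, 0]>\n",
                paste(format(x$value), collapse = ", "), x$tau))
  } else {
    cat(sprintf("<history_fun: %s expansion, s = %d, n = %d, on [-%g, 0]>\n",
                x$basis$family, x$s, x$basis$n, x$tau))
  }
  invisible(x)
}

# arguments describing a history in the layout cpp_integrate expects
history_cpp_args <- function(history, s) {
  if (history$s != s) {
    abort(sprintf("history has %d components but the system needs %d.",
                  history$s, s))
  }
  if (history$type == "constant") {
    list(type = 0L, const = history$value, fam = 1L,
         coef = matrix(0, 1, 1), tau = history$tau, rfun = null_fun)
  } else {
    # for basis histories the `const` slot carries the constant offset
    list(type = 1L, const = history$offset %||% numeric(s),
         fam = history$basis$id,
         coef = history$coefficients, tau = history$tau, rfun = null_fun)
  }
}
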