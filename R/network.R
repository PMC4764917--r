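#' Watts-Strogatz network for delay-coupled oscillator studies
#'
#' Generates a connected Watts-Strogatz small-world graph (ring lattice
#' with mean degree `k`, edges rewired with probability `p`; `p = 0` gives
#' the regular lattice, `p = 1` an Erdos-Renyi-like random graph) and
#' precomputes its Laplacian \eqn{G = D - A} and spectrum
#' \eqn{0 = \gamma_1 < \gamma_2 \le \dots \le \gamma_N}.  Disconnected
#' draws are rejected and regenerated.
#'
#' @param N node count.
#' @param k mean degree (even, < N).
#' @param p rewiring probability in \eqn{[0, 1]}.
#' @param seed RNG seed.
#' @param max_tries regeneration attempts before giving up.
#' @return an object of class `network_spec` with fields `graph`
#'   (igraph), `adjacency`, `laplacian`, `eigenvalues` (increasing), `N`,
#'   `k`, `p`, `seed`.
#' @export
watts_strogatz_net <- function(N, k, p, seed = 1L, max_tries = 100) {
  if (k %% 2 != 0) abort("`k` must be even.")
  if (k >= N) abort("`k` must be smaller than `N`.")
  if (p < 0 || p > 1) abort("`p` must be in [0, 1].")
  g <- withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_tries)) {
      gg <- igraph::sample_smallworld(dim = 1, size = N, nei = k / 2, p = p,
                                      loops = FALSE, multiple = FALSE)
      gg <- igraph::simplify(gg)
      if (igraph::is_connected(gg)) break
      gg <- NULL
    }
    gg
  })
  if (is.null(g)) abort("could not generate a connected network.")
  new_network_spec(g, N = N, k = k, p = p, seed = as.integer(seed))
}

#' @rdname watts_strogatz_net
#' @export
complete_graph_net <- function(N) {
  g <- igraph::make_full_graph(N)
  new_network_spec(g, N = N, k = N - 1, p = NA_real_, seed = NA_integer_)
}

new_network_spec <- function(g, N, k, p, seed) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(graph = g, adjacency = A, laplacian = L, eigenvalues = ev,
                 N = N, k = k, p = p, seed = seed),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec: N = %d, k = %g, p = %s, gamma_2 = %.4g, gamma_max = %.4g>\n",
              x$N, x$k, format(x$p), x$eigenvalues[2], max(x$eigenvalues)))
  invisible(x)
}

#' Synchronizability ratio of a network
#'
#' \eqn{R = \gamma_{max}/\gamma_{min}}, the ratio of the largest to the
#' smallest non-zero Laplacian eigenvalue.  The smaller `R`, the wider the
#' window of coupling strengths for which every transverse mode falls in a
#' stable region of the master stability function.
#'
#' @param net a network spec ([watts_strogatz_net()]).
#' @param tol zero-eigenvalue tolerance (connectivity check).
#' @return a single number `>= 1`.
#' @export
synchronizability <- function(net, tol = 1e-9) {
  stopifnot(inherits(net, "network_spec"))
  ev <- net$eigenvalues
  if (ev[2] <= tol) abort("network is disconnected (gamma_2 = 0).")
  max(ev) / ev[2]
}

#' Closed-form Laplacian spectrum of the ring lattice
#'
#' For the circulant `p = 0` Watts-Strogatz lattice (each node joined to
#' its `k/2` nearest neighbours on both sides) the Laplacian eigenvalues
#' are \eqn{\gamma_j = k - 2\sum_{m=1}^{k/2}\cos(2\pi j m / N)},
#' \eqn{j = 0..N-1}.
#'
#' @param N node count.
#' @param k even degree.
#' @return numeric vector of the `N` eigenvalues, increasing.
#' @export
ring_laplacian_spectrum <- function(N, k) {
  if (k %% 2 != 0) abort("`k` must be even.")
  j <- 0:(N - 1)
  m <- seq_len(k / 2)
  gam <- vapply(j, function(jj) k - 2 * sum(cos(2 * pi * jj * m / N)),
                numeric(1))
  sort(gam)
}

#' Write or read a network as a plain edge list
#'
#' @param net a network spec ([watts_strogatz_net()]).
#' @param path file path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  utils::write.table(el, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  el <- as.matrix(utils::read.table(path))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  N <- igraph::vcount(g)
  new_network_spec(g, N = N, k = mean(igraph::degree(g)), p = NA_real_,
                   seed = NA_integer_)
}
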