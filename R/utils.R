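# internal helpers: seeding, binomial intervals, interval algebra

# deterministic child seed, kept well inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 7919) %% 2147483629) + 1L
}

# Wilson score interval for a binomial proportion; well-behaved near 0 and 1
wilson_ci <- function(M, T, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- M / T
  den <- 1 + z^2 / T
  centre <- (p + z^2 / (2 * T)) / den
  half <- z * sqrt(p * (1 - p) / T + z^2 / (4 * T^2)) / den
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

# interval unions are (k x 2) matrices of disjoint, sorted [lo, hi] rows
normalize_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(numeric(0), 0, 2))
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0) return(matrix(numeric(0), 0, 2))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

intersect_intervals <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) out <- rbind(out, c(lo, hi))
  }
  normalize_intervals(out)
}

scale_intervals <- function(m, f) {
  if (nrow(m) == 0) return(m)
  out <- m * f
  if (f < 0) out <- out[, 2:1, drop = FALSE]
  normalize_intervals(out)
}

# dummy closure handed to C++ where an R callback slot is unused
null_fun <- function(...) stop("internal: callback should never be invoked")
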