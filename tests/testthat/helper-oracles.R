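# Independent oracles used by the tests; deliberately brute-force and
# separate from the package's own numerics.

# logseries tail T(a) = alpha * sum_{k >= a} x^k / k for a = 1..K by direct
# (truncated) summation; only usable when x is far enough from 1 that the
# terms decay within K
brute_tail_vector <- function(alpha, x, K = 2e5) {
  k <- seq_len(K)
  terms <- alpha * exp(k * log(x) - log(k))
  stopifnot(terms[K] < 1e-12) # truncation must be negligible
  rev(cumsum(rev(terms)))
}

# rank inversion (largest a with T(a) >= r - 0.5) + remainder rule,
# written independently with whole-vector scans
brute_ranked_logseries <- function(N, S) {
  alpha <- fishers_alpha(N, S)
  x <- N / (N + alpha)
  Tvec <- brute_tail_vector(alpha, x)
  abund <- vapply(seq_len(S), function(r) {
    ok <- which(Tvec >= r - 0.5)
    if (length(ok) == 0) 1 else max(ok)
  }, numeric(1))
  diff <- N - sum(abund)
  if (diff > 0) abund[1] <- abund[1] + diff
  while (diff < 0) {
    for (r in seq_len(S)) {
      floor_r <- if (r < S) abund[r + 1] else 1
      take <- min(-diff, abund[r] - floor_r)
      abund[r] <- abund[r] - take
      diff <- diff + take
      if (diff == 0) break
    }
  }
  abund
}

# Chinese-restaurant-process sample of an Ewens(theta) abundance vector
crp_sample <- function(theta, N) {
  lab <- integer(N)
  lab[1] <- 1
  K <- 1
  for (i in 2:N) {
    if (stats::runif(1) < theta / (theta + i - 1)) {
      K <- K + 1
      lab[i] <- K
    } else {
      lab[i] <- lab[sample.int(i - 1, 1)]
    }
  }
  tabulate(lab)
}

# all integer partitions of n (list of decreasing vectors)
all_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq(min(n, max_part), 1)) {
    for (rest in all_partitions(n - k, k)) out <- c(out, list(c(k, rest)))
  }
  out
}

# all compositions of n into s non-negative parts
all_compositions <- function(n, s) {
  if (s == 1) return(list(n))
  out <- list()
  for (k in 0:n) {
    for (rest in all_compositions(n - k, s - 1)) out <- c(out, list(c(k, rest)))
  }
  out
}

# Gaussian-kernel escape probability via the separable closed form
# (displacement components are independent normals) — an independent route
# from the package's polar-coordinate integration
gaussian_escape_separable <- function(w, d) {
  sigma <- d * sqrt(2 / pi)
  q <- stats::integrate(function(x)
    stats::pnorm((w - x) / sigma) - stats::pnorm(-x / sigma),
    0, w, rel.tol = 1e-10)$value / w
  1 - q^2
}
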