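#' Solve Fisher's alpha from individuals and species
#'
#' Inverts the Fisher logseries relationship `S = alpha * log(1 + N/alpha)`
#' for the diversity parameter alpha, given the total number of individuals
#' `N` and species `S` in a sample.
#'
#' @param N total number of individuals (scalar, `N >= S`).
#' @param S total number of species (scalar, `S >= 2`).
#' @return The unique positive root alpha.
#' @examples
#' fishers_alpha(37446, 1042)   # Guiana-Shield-scale sample, approx 198
#' @export
fishers_alpha <- function(N, S) {
  stopifnot(length(N) == 1, length(S) == 1, is.finite(N), is.finite(S))
  if (S < 2) stop("S must be >= 2")
  if (N < S) stop("logseries undefined for N < S")
  # S(alpha) = alpha*log1p(N/alpha) is strictly increasing in alpha,
  # with limits 0 (alpha -> 0) and N (alpha -> Inf); root-find on log(alpha)
  f <- function(la) {
    a <- exp(la)
    a * log1p(N / a) - S
  }
  r <- stats::uniroot(f, lower = log(1e-12), upper = log(N * 2),
                      extendInt = "upX", tol = 1e-12)
  alpha <- exp(r$root)
  if (abs(alpha * log1p(N / alpha) - S) > 1e-6 * S)
    stop("alpha solver did not converge on bracket [",
         exp(r$root) / 2, ", ", exp(r$root) * 2, "]")
  alpha
}

#' Expected number of species in a logseries sample
#'
#' @param n sample size (individuals).
#' @param alpha Fisher's alpha.
#' @return Expected distinct-species count `alpha * log(1 + n/alpha)`.
#' @export
expected_species <- function(n, alpha) alpha * log1p(n / alpha)

#' Expected number of singletons in a logseries sample
#'
#' Under Fisher's logseries the expected number of species observed with
#' exactly one individual in a sample of `n` is `alpha * x` with
#' `x = n/(n + alpha)`.
#'
#' @param n sample size (individuals), `n >= 1`.
#' @param alpha Fisher's alpha (> 0).
#' @return Expected singleton count `alpha * n / (n + alpha)`.
#' @export
expected_singletons <- function(n, alpha) {
  stopifnot(all(n >= 1), all(alpha >= 0))
  alpha * n / (n + alpha)
}

# Expected number of species with abundance >= a under the logseries,
# T(a) = alpha * sum_{k >= a} x^k / k.  The first `nexact` terms are summed
# directly; the remainder is an Euler-Maclaurin corrected exponential-integral
# tail, accurate far beyond the 0.5-species resolution the rank inversion
# needs.  Works for x arbitrarily close to 1 (eps = -log(x) down to ~1e-11).
logseries_tail <- function(a, alpha, x, nexact = 500L) {
  eps <- -log(x)
  vapply(a, function(a1) {
    k <- a1 + seq_len(nexact) - 1
    head_sum <- sum(exp(-eps * k) / k)
    b <- a1 + nexact
    lb <- -eps * b
    tail_sum <- if (lb < -745) 0 else {
      xb <- exp(lb)
      pracma::expint_E1(eps * b) + xb / (2 * b) +
        xb * (eps / b + 1 / b^2) / 12
    }
    alpha * (head_sum + tail_sum)
  }, numeric(1))
}

#' Construct a ranked Fisher-logseries metacommunity
#'
#' Builds the regional species pool as a deterministic rank-abundance vector
#' following Fisher's logseries, starting from the most dominant species.
#' The abundance at rank r is the largest integer a for which the expected
#' number of species with abundance at least a, `T(a) = sum_{k>=a}
#' alpha*x^k/k`, still satisfies `T(a) >= r - 0.5` (midpoint inversion).
#' Any deficit or surplus of individuals relative to `N` is then absorbed
#' starting at rank 1, preserving monotonicity, so that the abundances sum
#' to `N` exactly.
#'
#' @param N metacommunity size (total individuals).
#' @param S number of species; exactly one of `S` and `alpha` must be given.
#' @param alpha Fisher's alpha; if supplied, `S` is derived as
#'   `round(alpha * log(1 + N/alpha))`.
#' @return An object of class `logseries_meta`: a list with elements `N`,
#'   `S`, `alpha`, `x`, `abundance` (non-increasing integer vector of length
#'   `S` summing to `N`) and `species` (identifiers `"sp000001"`, ...).
#' @examples
#' mc <- logseries_metacommunity(1e4, S = 50)
#' sum(mc$abundance) == 1e4
#' @export
logseries_metacommunity <- function(N, S = NULL, alpha = NULL) {
  stopifnot(xor(is.null(S), is.null(alpha)))
  if (is.null(S)) {
    stopifnot(alpha > 0)
    S <- round(expected_species(N, alpha))
    if (S < 2) stop("alpha implies fewer than 2 species at this N")
  } else {
    alpha <- fishers_alpha(N, S)
  }
  if (N < S) stop("logseries undefined for N < S")
  x <- N / (N + alpha)

  abund <- numeric(S)
  hi <- N # T is non-increasing; shrink the bracket as rank grows
  T1 <- logseries_tail(1, alpha, x)
  for (r in seq_len(S)) {
    target <- r - 0.5
    lo <- 1
    if (T1 < target) {
      abund[r] <- 1 # even a = 1 falls short of the midpoint; minimal species
      hi <- 1
      next
    }
    # largest integer a with T(a) >= target, binary search on [lo, hi]
    while (hi - lo > 0) {
      mid <- ceiling((lo + hi) / 2)
      if (logseries_tail(mid, alpha, x) >= target) lo <- mid else hi <- mid - 1
    }
    abund[r] <- lo
    hi <- lo
  }

  # remainder rule: absorb the deficit/surplus starting at rank 1
  diff <- N - sum(abund)
  if (diff > 0) {
    abund[1] <- abund[1] + diff
  } else if (diff < 0) {
    need <- -diff
    while (need > 0) {
      for (r in seq_len(S)) {
        floor_r <- if (r < S) abund[r + 1] else 1
        take <- min(need, abund[r] - floor_r)
        abund[r] <- abund[r] - take
        need <- need - take
        if (need == 0) break
      }
      if (need > 0 && all(abund == 1))
        stop("cannot distribute individuals: N < S after inversion")
    }
  }
  stopifnot(sum(abund) == N, !is.unsorted(rev(abund)))
  structure(list(N = N, S = as.integer(S), alpha = alpha, x = x,
                 abundance = abund,
                 species = sprintf("sp%06d", seq_len(S))),
            class = "logseries_meta")
}

#' @export
print.logseries_meta <- function(x, ...) {
  cat("Fisher-logseries metacommunity\n")
  cat(sprintf("  N = %s individuals, S = %d species\n",
              format(x$N, big.mark = ","), x$S))
  cat(sprintf("  alpha = %.4g, x = %.10g\n", x$alpha, x$x))
  cat(sprintf("  dominance: rank 1 = %s, rank S = %s\n",
              format(x$abundance[1], big.mark = ","),
              format(x$abundance[x$S], big.mark = ",")))
  invisible(x)
}

#' Sample a local community from a metacommunity
#'
#' Draws `size` individuals in proportion to the metacommunity relative
#' abundances. The default is multinomial sampling (with replacement),
#' appropriate when the pool exceeds the sample by orders of magnitude; a
#' without-replacement (multivariate hypergeometric) option is available for
#' small pools.
#'
#' @param meta a `logseries_meta` object.
#' @param size number of individuals to draw (`>= 0`).
#' @param replace logical; multinomial (`TRUE`, default) or hypergeometric.
#' @return Integer vector of species counts, length `meta$S`.
#' @export
sample_community <- function(meta, size, replace = TRUE) {
  stopifnot(inherits(meta, "logseries_meta"), size >= 0)
  if (size == 0) return(integer(meta$S))
  if (replace) {
    as.integer(stats::rmultinom(1, size, prob = meta$abundance))
  } else {
    if (meta$N > 5e6)
      stop("without-replacement sampling only supported for small pools")
    if (size > meta$N) stop("size exceeds metacommunity N")
    ids <- sample.int(meta$N, size)
    breaks <- c(0, cumsum(meta$abundance))
    as.integer(tabulate(findInterval(ids, breaks, left.open = TRUE),
                        nbins = meta$S))
  }
}
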