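#' Unbiased within-sample probability of conspecific identity
#'
#' The probability that two individuals drawn without replacement from the
#' sample are the same species: `F = sum(n_i (n_i - 1)) / (J (J - 1))`.
#' This is the unbiased (Simpson-type) identity used by the Gst estimator.
#'
#' @param counts non-negative integer abundance vector with total `J >= 2`.
#' @return Identity probability in `[0, 1]`.
#' @export
simpson_identity <- function(counts) {
  J <- sum(counts)
  if (J < 2) stop("need at least 2 individuals")
  sum(counts * (counts - 1)) / (J * (J - 1))
}

migration_estimate <- function(method, m_hat, m_raw = m_hat, I_hat = NULL,
                               theta_hat = NULL, flags = NULL) {
  structure(list(method = method,
                 m_hat = m_hat, m_raw = m_raw,
                 I_hat = I_hat, theta_hat = theta_hat,
                 mean = mean(m_hat), sd = stats::sd(m_hat),
                 mean_raw = mean(m_raw),
                 flags = flags),
            class = "migration_estimate")
}

#' @export
print.migration_estimate <- function(x, ...) {
  cat(sprintf("migration estimate [%s]: mean m = %.4f (sd %.4f, %d plots)\n",
              x$method, x$mean, x$sd, length(x$m_hat)))
  if (!is.null(x$flags) && any(x$flags != ""))
    cat("  flagged plots:", sum(x$flags != ""), "\n")
  invisible(x)
}

#' Gst-based migration estimator
#'
#' Population-genetics-style differentiation estimator. For each plot k the
#' unbiased within-plot identity `F_k` is compared with the pooled identity
#' `F_T` (computed on summed counts). Under the equilibrium
#' Dirichlet-multinomial local community, `E[F_k] = (I F_T + 1)/(I + 1)`,
#' which inverts to the immigration number `I_k = (1 - F_k)/(F_k - F_T)`
#' and the migration probability `m_k = I_k / (I_k + J_k - 1)`.
#'
#' Plots with `F_k <= F_T` (no detectable differentiation) are flagged and
#' their `m_hat` capped at 1; the raw transform is preserved in `m_raw`.
#'
#' @param mat plots x species count matrix (>= 2 plots, each with J >= 2).
#' @return A `migration_estimate` with per-plot values, mean and sd.
#' @export
gst_migration <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 plots to compute pooled identity")
  FT <- simpson_identity(colSums(mat))
  J <- rowSums(mat)
  Fk <- apply(mat, 1, simpson_identity)
  I <- (1 - Fk) / (Fk - FT)
  m_raw <- I / (I + J - 1)
  flags <- ifelse(Fk <= FT, "undifferentiated", "")
  m_hat <- ifelse(Fk <= FT, 1, pmin(pmax(m_raw, 0), 1))
  migration_estimate("gst", m_hat, m_raw, I_hat = I, flags = flags)
}

#' Dirichlet-multinomial local-community log-likelihood
#'
#' Log-likelihood of a plot's abundance vector under the equilibrium
#' compound-multinomial (Dirichlet-multinomial) local community with
#' concentration `I * p`: the stationary distribution of a zero-sum local
#' community of size `J` receiving immigrants from a fixed regional pool
#' with relative abundances `p` at immigration number `I`.
#'
#' @param counts non-negative integer abundance vector (length of `p`).
#' @param I immigration number (> 0).
#' @param p regional relative abundances (sums to 1).
#' @return Log-likelihood (scalar). `-Inf` if a species with `p = 0` has
#'   positive count.
#' @export
dm_loglik <- function(counts, I, p) {
  stopifnot(I > 0, length(counts) == length(p),
            abs(sum(p) - 1) < 1e-8, all(counts >= 0))
  J <- sum(counts)
  obs <- which(counts > 0)
  if (any(p[obs] == 0)) return(-Inf)
  lfactorial(J) - sum(lfactorial(counts[obs])) +
    lgamma(I) - lgamma(I + J) +
    sum(lgamma(I * p[obs] + counts[obs]) - lgamma(I * p[obs]))
}

# Scalar minimization with explicit ridge handling: when the likelihood is
# monotone (or flat) toward an interval endpoint, golden-section can settle
# anywhere on the plateau, so an endpoint whose objective ties the interior
# optimum wins and is flagged.
scalar_mle <- function(nll, interval, tie = 1e-6) {
  opt <- stats::optimize(nll, interval = interval, tol = 1e-8)
  flag <- ""
  if (nll(interval[2]) <= opt$objective + tie) {
    opt$minimum <- interval[2]
    flag <- "upper-bound"
  } else if (nll(interval[1]) <= opt$objective + tie) {
    opt$minimum <- interval[1]
    flag <- "lower-bound"
  }
  list(minimum = opt$minimum, objective = min(opt$objective, nll(opt$minimum)),
       flag = flag)
}

#' Migration by per-plot likelihood under a pooled regional estimate
#'
#' The "Inference"-style estimator: the regional relative abundances are
#' estimated from the pooled sample (optionally leave-one-plot-out), then the
#' immigration number `I` of each plot is fit by maximizing [dm_loglik()]
#' over `log I`, and converted to `m = I/(I + J - 1)`.
#'
#' @param mat plots x species count matrix (>= 2 plots).
#' @param pool `"all"` (default) or `"loo"` (leave the focal plot out of the
#'   regional estimate).
#' @param interval search interval for `log I`.
#' @return A `migration_estimate`; plots whose optimum sits at either bound
#'   of the search interval are flagged.
#' @export
inference_migration <- function(mat, pool = c("all", "loo"),
                                interval = log(c(1e-3, 1e8))) {
  pool <- match.arg(pool)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 plots")
  tot <- colSums(mat)
  n_plots <- nrow(mat)
  m_hat <- I_hat <- numeric(n_plots)
  flags <- character(n_plots)
  for (k in seq_len(n_plots)) {
    pk <- if (pool == "loo") tot - mat[k, ] else tot
    pk <- pk / sum(pk)
    nll <- function(logI) -dm_loglik(mat[k, ], exp(logI), pk)
    opt <- scalar_mle(nll, interval)
    I_hat[k] <- exp(opt$minimum)
    J <- sum(mat[k, ])
    m_hat[k] <- I_hat[k] / (I_hat[k] + J - 1)
    flags[k] <- opt$flag
  }
  migration_estimate("inference", m_hat, I_hat = I_hat, flags = flags)
}

#' Etienne sampling-formula log-likelihood
#'
#' Log-likelihood of an (unlabeled) species abundance distribution under
#' Etienne's (2005) sampling formula for a local community of size `J`
#' receiving immigrants at immigration number `I` from a metacommunity with
#' fundamental biodiversity number `theta`:
#' \deqn{P[D | \theta, I] = \frac{J!}{\prod_i n_i \prod_j \Phi_j!}
#'   \frac{\theta^S}{(I)_J} \sum_{A=S}^{J} K(D, A) \frac{I^A}{(\theta)_A}}
#' The ancestry coefficients `K(D, A)` combine unsigned Stirling numbers of
#' the first kind per species and are computed once per abundance vector in
#' log space (stable up to J in the thousands).
#'
#' @param counts abundance vector (zeros allowed, dropped).
#' @param theta fundamental biodiversity number (> 0).
#' @param I immigration number (> 0).
#' @param log_kda optional precomputed coefficient vector from a previous
#'   call (attribute `"log_kda"` of the result), reused across likelihood
#'   evaluations on the same data during optimization.
#' @return Log-likelihood with attribute `"log_kda"`.
#' @export
etienne_loglik <- function(counts, theta, I, log_kda = NULL) {
  stopifnot(theta > 0, I > 0)
  n <- counts[counts > 0]
  if (length(n) == 0) stop("empty sample")
  J <- sum(n)
  S <- length(n)
  if (is.null(log_kda)) log_kda <- .log_kda(as.integer(n))
  A <- S:J
  terms <- log_kda + A * log(I) - (lgamma(theta + A) - lgamma(theta))
  mx <- max(terms)
  lsum <- mx + log(sum(exp(terms - mx)))
  ll <- lfactorial(J) - sum(log(n)) - sum(lfactorial(tabulate(n))) +
    S * log(theta) - (lgamma(I + J) - lgamma(I)) + lsum
  attr(ll, "log_kda") <- log_kda
  ll
}

#' Ewens sampling-formula log-likelihood
#'
#' The `I -> Inf` limit of [etienne_loglik()]: the probability of an
#' unlabeled abundance configuration when the local sample is drawn directly
#' from the metacommunity.
#'
#' @inheritParams etienne_loglik
#' @return Log-likelihood (scalar).
#' @export
ewens_loglik <- function(counts, theta) {
  n <- counts[counts > 0]
  J <- sum(n)
  S <- length(n)
  lfactorial(J) - sum(log(n)) - sum(lfactorial(tabulate(n))) +
    S * log(theta) - (lgamma(theta + J) - lgamma(theta))
}

#' Ewens estimator of the fundamental biodiversity number
#'
#' Solves `S = sum_{j=0}^{N-1} theta/(theta + j)`, i.e.
#' `S = theta * (digamma(theta + N) - digamma(theta))`, for `theta`.
#'
#' @param S observed species count.
#' @param N sample size.
#' @return `theta_hat`; `Inf` (with a warning) when `S == N`, `0` when
#'   `S == 1` is approached.
#' @export
ewens_theta <- function(S, N) {
  stopifnot(N >= S, S >= 1)
  if (S == N) {
    warning("S == N: theta is unbounded")
    return(Inf)
  }
  if (S == 1) return(0)
  f <- function(lt) {
    t <- exp(lt)
    t * (digamma(t + N) - digamma(t)) - S
  }
  r <- stats::uniroot(f, lower = -30, upper = 30, extendInt = "upX",
                      tol = 1e-12)
  theta <- exp(r$root)
  if (abs(theta * (digamma(theta + N) - digamma(theta)) - S) > 1e-8 * S)
    stop("theta solver did not converge")
  theta
}

#' One-stage joint estimation of theta, I and m from a single sample
#'
#' Joint maximum-likelihood fit of Etienne's sampling formula over
#' `(log theta, log I)` by Nelder-Mead, with the ancestry coefficients
#' computed once. `m = I/(I + J - 1)`. Near `m -> 1` the likelihood ridge
#' flattens (the formula degenerates as all `J` individuals become potential
#' immigrant ancestors); such fits are flagged.
#'
#' @param counts abundance vector of one sample (`J >= 2`, `S >= 2`).
#' @return List with `theta_hat`, `I_hat`, `m_hat`, `loglik` and `flag`
#'   (`""`, `"flat-ridge"` or `"boundary"`).
#' @export
etienne_onestage <- function(counts) {
  n <- counts[counts > 0]
  J <- sum(n)
  S <- length(n)
  if (J < 2) stop("need J >= 2")
  if (S < 2) {
    # monoculture: likelihood increases as theta -> 0, m -> 0 boundary
    return(list(theta_hat = 0, I_hat = 0, m_hat = 0,
                loglik = 0, flag = "boundary"))
  }
  kda <- .log_kda(as.integer(n))
  nll <- function(par) {
    th <- exp(par[1]); II <- exp(par[2])
    if (!is.finite(th) || !is.finite(II) || th <= 0 || II <= 0) return(1e10)
    -as.numeric(etienne_loglik(n, th, II, log_kda = kda))
  }
  init <- c(log(ewens_theta(S, J)), log(J - 1)) # m = 0.5 start
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  theta_hat <- exp(opt$par[1])
  I_hat <- exp(opt$par[2])
  m_hat <- I_hat / (I_hat + J - 1)
  # flatness diagnostic: if pushing I to 1e8 barely changes the likelihood,
  # the ridge toward m = 1 is unresolved
  flag <- ""
  ll_inf <- -nll(c(opt$par[1], log(1e8)))
  if (m_hat > 0.8 && (-opt$value) - ll_inf < 2) flag <- "flat-ridge"
  if (I_hat > 1e7) flag <- "boundary"
  list(theta_hat = theta_hat, I_hat = I_hat, m_hat = min(m_hat, 1),
       loglik = -opt$value, flag = flag)
}

#' One-stage Etienne estimation applied plot-wise
#'
#' @param mat plots x species count matrix.
#' @return A `migration_estimate` with per-plot `theta_hat` and `I_hat`.
#' @export
onestage_migration <- function(mat) {
  mat <- as.matrix(mat)
  fits <- apply(mat, 1, etienne_onestage)
  migration_estimate("etienne1",
                     m_hat = vapply(fits, `[[`, numeric(1), "m_hat"),
                     I_hat = vapply(fits, `[[`, numeric(1), "I_hat"),
                     theta_hat = vapply(fits, `[[`, numeric(1), "theta_hat"),
                     flags = vapply(fits, `[[`, character(1), "flag"))
}

#' Two-stage Etienne estimation of migration
#'
#' Stage 1 estimates the fundamental biodiversity number from the pooled
#' sample with [ewens_theta()]; stage 2 fixes theta and fits the immigration
#' number of each plot by maximizing [etienne_loglik()] over `log I`.
#'
#' @param mat plots x species count matrix (>= 2 plots).
#' @param interval search interval for `log I`.
#' @return A `migration_estimate` with the pooled `theta_hat` attached.
#' @export
twostage_migration <- function(mat, interval = log(c(1e-3, 1e8))) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 plots")
  tot <- colSums(mat)
  theta <- ewens_theta(sum(tot > 0), sum(tot))
  n_plots <- nrow(mat)
  m_hat <- I_hat <- numeric(n_plots)
  flags <- character(n_plots)
  for (k in seq_len(n_plots)) {
    n <- mat[k, ][mat[k, ] > 0]
    J <- sum(n)
    kda <- .log_kda(as.integer(n))
    nll <- function(logI)
      -as.numeric(etienne_loglik(n, theta, exp(logI), log_kda = kda))
    opt <- scalar_mle(nll, interval)
    I_hat[k] <- exp(opt$minimum)
    m_hat[k] <- I_hat[k] / (I_hat[k] + J - 1)
    flags[k] <- opt$flag
  }
  migration_estimate("etienne2", m_hat, I_hat = I_hat,
                     theta_hat = rep(theta, n_plots), flags = flags)
}

#' Observed versus expected singletons
#'
#' Diagnostic for mixing: the pooled observed number of singletons divided
#' by the logseries expectation `alpha_hat * N/(N + alpha_hat)`, with
#' `alpha_hat` solved from the pooled `(N, S)`. Values near 1 indicate a
#' well-mixed system; values below 1 indicate clumping (plots weakly
#' connected over larger distances).
#'
#' @param mat plots x species count matrix (or a single pooled count vector).
#' @return Ratio observed/expected (scalar).
#' @export
singleton_ratio <- function(mat) {
  tot <- if (is.matrix(mat)) colSums(mat) else mat
  N <- sum(tot)
  S <- sum(tot > 0)
  if (N < 2) stop("need pooled J >= 2")
  alpha <- fishers_alpha(N, S)
  sum(tot == 1) / expected_singletons(N, alpha)
}
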