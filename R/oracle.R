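# Brute-force reference implementation: sums over all 2^(N-1)
# configurations of the change indicators. Independent of the recursions
# it validates -- each configuration's weight is computed directly as
# prior(configuration) x product of Beta-binomial segment marginals.

#' Exact posterior by enumeration of change configurations
#'
#' Enumerates every assignment of the change indicators I_2..I_N (I_1 = 1),
#' weighting each by its Bernoulli prior times the product of conjugate
#' Beta-binomial marginal likelihoods of its segments (binomial
#' coefficients omitted, as in [forward_recursion()]). Exact posterior
#' means and change probabilities follow by conditioning. Intended as an
#' independent oracle for small N.
#'
#' @param counts A `site_counts` with at most 14 sites.
#' @param hyper A `bar_hyperparams`.
#' @return List with `theta_mean`, `change_prob` and `log_marginal`.
#' @export
enumerate_posterior_oracle <- function(counts, hyper) {
  stopifnot(inherits(counts, "site_counts"))
  N <- length(counts$x)
  if (N > 14) stop("enumeration oracle limited to N <= 14")
  a0 <- hyper$mu0 * hyper$nu0
  b0 <- (1 - hyper$mu0) * hyper$nu0
  lB0 <- lbeta(a0, b0)
  p <- hyper$p
  n <- counts$n
  x <- counts$x

  n_cfg <- 2L^(N - 1L)
  logw <- numeric(n_cfg)
  mu_cfg <- matrix(0, n_cfg, N)
  I_cfg <- matrix(0L, n_cfg, N)
  for (b in seq_len(n_cfg) - 1L) {
    I <- c(1L, as.integer(intToBits(b))[seq_len(max(N - 1L, 0L))])
    I <- I[seq_len(N)]
    lprior <- 0
    if (N > 1L) {
      for (t in 2:N) {
        lprior <- lprior +
          if (I[t] == 1L) log(p[t]) else log1p(-p[t])
      }
    }
    starts <- which(I == 1L)
    ends <- c(starts[-1L] - 1L, N)
    llik <- 0
    for (s in seq_along(starts)) {
      idx <- starts[s]:ends[s]
      Xs <- sum(x[idx])
      m <- length(idx)
      llik <- llik + lbeta(a0 + Xs, b0 + m * n - Xs) - lB0
      mu_cfg[b + 1L, idx] <- (a0 + Xs) / (a0 + b0 + m * n)
    }
    logw[b + 1L] <- lprior + llik
    I_cfg[b + 1L, ] <- I
  }
  logZ <- .logsumexp(logw)
  w <- exp(logw - logZ)
  list(theta_mean = as.numeric(crossprod(w, mu_cfg)),
       change_prob = as.numeric(crossprod(w, I_cfg)),
       log_marginal = logZ)
}
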