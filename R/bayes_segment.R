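# Continuous-state Bayesian multiple change-point model.
#
# Sites tau_1..tau_N carry binomial counts x_t ~ Binomial(theta_t, n) with
# theta piecewise constant; latent indicators I_t ~ Bernoulli(p_t) mark
# where theta changes (I_1 = 1 by convention), and each new theta is drawn
# from Beta(mu0, nu0) in mean/sample-size form. Exact posteriors follow from
# Beta-binomial conjugacy via forward/backward recursions over "most recent
# change" / "last point before the next change" variables. All recursions
# run in log space; Beta-function ratios go through lgamma, so real-valued
# (scaled) counts are accepted throughout.

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Hyperparameters of the segmentation model
#'
#' The per-site prior change probabilities come from a Poisson boundary
#' process with rate `lambda` per bp: p_1 = 1 and
#' p_t = 1 - exp(-lambda * (tau_t - tau_(t-1))) for t > 1, so wider gaps
#' between informative sites carry more prior change mass.
#'
#' @param mu0 Prior mean accessibility, in (0, 1).
#' @param nu0 Prior sample size, > 0.
#' @param lambda Poisson change rate per bp, > 0.
#' @param positions Informative-site coordinates tau_1..tau_N.
#' @param n Binomial size (weighted molecule count).
#' @param p Optional explicit per-site change probabilities overriding the
#'   Poisson form (p[1] must be 1); used for limit checks.
#' @return An object of class `bar_hyperparams`.
#' @export
bar_hyperparams <- function(mu0, nu0, lambda, positions, n, p = NULL) {
  if (mu0 <= 0 || mu0 >= 1) stop("mu0 must be in (0, 1)")
  if (nu0 <= 0) stop("nu0 must be positive")
  if (is.null(p)) {
    if (lambda < 0) stop("lambda must be nonnegative")
    p <- c(1, 1 - exp(-lambda * diff(positions)))
  } else {
    if (length(p) != length(positions)) stop("p must have one entry per site")
    if (p[1] != 1) stop("p[1] must be 1 (a change at the first site is certain)")
    if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  }
  structure(list(mu0 = mu0, nu0 = nu0, lambda = lambda, p = p,
                 n = n, positions = as.numeric(positions)),
            class = "bar_hyperparams")
}

#' Empirical-Bayes prior estimates
#'
#' The prior sample size is set to the binomial size (the prior stands for
#' one data point) and the prior mean to the sample mean of the per-site
#' frequencies, clamped away from 0 and 1 to keep the Beta parameters
#' positive.
#'
#' @param counts A `site_counts` object.
#' @param eps Clamp width for degenerate all-zero / all-converted data.
#' @return A list with `mu0` and `nu0`.
#' @export
estimate_mu0_nu0 <- function(counts, eps = 1e-6) {
  stopifnot(inherits(counts, "site_counts"))
  mu0 <- sum(counts$x) / (length(counts$x) * counts$n)
  mu0 <- min(max(mu0, eps), 1 - eps)
  list(mu0 = mu0, nu0 = counts$n)
}

# Segment-level conjugate quantities for all 1 <= i <= j <= N:
#   lc[i, j] = log c_{i,j} = -log Beta(a0 + X_ij, b0 + m*n - X_ij)
#   mu[i, j] = posterior mean of the segment's Beta
# and lc0 for the prior. Entries with i > j are NA.
.segment_tables <- function(counts, hyper) {
  N <- length(counts$x)
  a0 <- hyper$mu0 * hyper$nu0
  b0 <- (1 - hyper$mu0) * hyper$nu0
  cs <- c(0, cumsum(counts$x))
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  X <- matrix(NA_real_, N, N)
  ok <- i <= j
  X[ok] <- cs[j[ok] + 1L] - cs[i[ok]]
  m <- j - i + 1
  a <- a0 + X
  b <- b0 + m * counts$n - X
  lc <- -lbeta(a, b)
  mu <- a / (a + b)
  list(lc = lc, mu = mu, nu = a + b, X = X, lc0 = -lbeta(a0, b0), N = N)
}

#' Conjugate posterior of a single candidate segment
#'
#' For sites i..j sharing one accessibility value, the Beta prior updates to
#' mean (nu0*mu0 + X_ij) / (nu0 + m*n) and sample size nu0 + m*n, where
#' X_ij is the summed count over the segment and m = j - i + 1.
#'
#' @param counts A `site_counts`.
#' @param i,j Inclusive site indices, 1 <= i <= j <= N.
#' @param hyper A `bar_hyperparams`.
#' @return List with `i`, `j`, `X`, `mu`, `nu`, `log_c` (log reciprocal Beta
#'   function of the posterior) and `log_c0` (same for the prior).
#' @export
segment_posterior <- function(counts, i, j, hyper) {
  stopifnot(inherits(counts, "site_counts"))
  N <- length(counts$x)
  if (i < 1 || j > N || i > j) stop("need 1 <= i <= j <= N")
  tb <- .segment_tables(counts, hyper)
  list(i = i, j = j, X = tb$X[i, j], mu = tb$mu[i, j], nu = tb$nu[i, j],
       log_c = tb$lc[i, j], log_c0 = tb$lc0)
}

#' Forward recursion: distribution of the most recent change
#'
#' Computes p_{i,t} = Pr(the most recent change at or before site t is at
#' site i | x_1..x_t) for all i <= t, together with the per-t log
#' normalizers whose sum is the log marginal likelihood of the sequence
#' (used for the lambda grid search). Binomial coefficients, constant in
#' the segmentation, are omitted throughout (also in the enumeration
#' oracle, so the two marginals agree).
#'
#' @param counts A `site_counts`.
#' @param hyper A `bar_hyperparams`.
#' @param tables Precomputed segment tables (internal reuse).
#' @return List with `lp` (N x N matrix, `lp[i, t]` = log p_{i,t} for
#'   i <= t), `log_norms` and `log_marginal`.
#' @export
forward_recursion <- function(counts, hyper, tables = NULL) {
  tb <- if (is.null(tables)) .segment_tables(counts, hyper) else tables
  N <- tb$N
  p <- hyper$p
  lp <- matrix(-Inf, N, N)
  log_norms <- numeric(N)
  for (t in seq_len(N)) {
    lpstar <- rep(-Inf, t)
    lpstar[t] <- log(p[t]) + tb$lc0 - tb$lc[t, t]
    if (t > 1L && p[t] < 1) {
      i <- seq_len(t - 1L)
      lpstar[i] <- log1p(-p[t]) + lp[i, t - 1L] + tb$lc[i, t - 1L] - tb$lc[i, t]
    }
    log_norms[t] <- .logsumexp(lpstar)
    lp[seq_len(t), t] <- lpstar - log_norms[t]
  }
  if (anyNA(lp[lower.tri(lp, diag = TRUE)]) || any(is.nan(lp))) {
    stop("NaN in forward recursion")
  }
  list(lp = lp, log_norms = log_norms, log_marginal = sum(log_norms))
}

#' Backward recursion: distribution of the last site before the next change
#'
#' Computes q_{j,t+1} = Pr(site j >= t is the last data point before a new
#' change | x_(t+1)..x_N). The boundary case q_{t,t+1} = p_{t+1} (a change
#' immediately after t) is exact because the future data are uninformative
#' about whether a fresh prior draw occurred; the remaining mass 1 - p_{t+1}
#' is distributed over j >= t+1 by the recursion. Convention p_{N+1} = 1.
#'
#' @inheritParams forward_recursion
#' @return List with `lq` (N x N matrix, `lq[j, t]` = log q_{j,t+1} for
#'   j >= t).
#' @export
backward_recursion <- function(counts, hyper, tables = NULL) {
  tb <- if (is.null(tables)) .segment_tables(counts, hyper) else tables
  N <- tb$N
  p_ext <- c(hyper$p, 1)  # p_{N+1} = 1
  lq <- matrix(-Inf, N, N)
  lq[N, N] <- log(p_ext[N + 1L])  # = 0
  if (N == 1L) return(list(lq = lq))
  for (t in seq(N - 1L, 1L)) {
    ptp1 <- p_ext[t + 1L]
    lqstar <- rep(-Inf, N)
    lqstar[t + 1L] <- log(p_ext[t + 2L]) + tb$lc0 - tb$lc[t + 1L, t + 1L]
    if (t + 2L <= N) {
      j <- seq(t + 2L, N)
      lqstar[j] <- lq[j, t + 1L] + tb$lc[t + 2L, j] - tb$lc[t + 1L, j]
    }
    tail_idx <- seq(t + 1L, N)
    Z <- .logsumexp(lqstar[tail_idx])
    lq[tail_idx, t] <- log1p(-ptp1) + lqstar[tail_idx] - Z
    lq[t, t] <- log(ptp1)
  }
  if (any(is.nan(lq))) stop("NaN in backward recursion")
  list(lq = lq)
}

# Log segment weights lw[i, jcol] at site t (jcol indexes j = t..N):
#   j = t:  lp[i,t] + lq[t,t]
#   j > t:  lp[i,t] + lq[j,t] + lc[i,t] + lc[t+1,j] - lc[i,j] - lc0
# Returned unnormalized together with the normalizer logZ.
.log_weights_at <- function(t, lp, lq, tb) {
  N <- tb$N
  lw <- matrix(-Inf, t, N - t + 1L)
  lw[, 1L] <- lp[seq_len(t), t] + lq[t, t]
  if (t < N) {
    j <- seq(t + 1L, N)
    left <- lp[seq_len(t), t] + tb$lc[seq_len(t), t]
    right <- lq[j, t] + tb$lc[t + 1L, j]
    lw[, -1L] <- outer(left, right, `+`) -
      tb$lc[seq_len(t), j, drop = FALSE] - tb$lc0
  }
  list(lw = lw, logZ = .logsumexp(lw))
}

#' Combine forward and backward passes into posterior summaries
#'
#' For every site t, the posterior over the segment (i, j) containing t has
#' weights w_{i,j,t} proportional to p_{i,t} q_{j,t+1} corrected by the
#' Beta-function ratio c_{i,t} c_{t+1,j} / (c_{i,j} c_0) that rejoins the
#' two half-segments. The posterior accessibility mean is the w-weighted
#' mixture of segment posterior means, and the posterior change probability
#' at t+1 is the total weight on segments ending at t.
#'
#' @inheritParams forward_recursion
#' @param fwd,bwd Results of [forward_recursion()] and
#'   [backward_recursion()].
#' @return List with `theta_mean` (E(theta_t | X), length N), `change_prob`
#'   (Pr(I_t = 1 | X), length N, first entry 1), and `log_norm_w` (per-t log
#'   normalizers of the unnormalized weights).
#' @export
combine_weights <- function(fwd, bwd, counts, hyper, tables = NULL) {
  tb <- if (is.null(tables)) .segment_tables(counts, hyper) else tables
  N <- tb$N
  theta_mean <- numeric(N)
  change_prob <- numeric(N)
  change_prob[1L] <- 1
  log_norm_w <- numeric(N)
  for (t in seq_len(N)) {
    lwz <- .log_weights_at(t, fwd$lp, bwd$lq, tb)
    if (!is.finite(lwz$logZ)) stop("zero normalizer in combined weights")
    w <- exp(lwz$lw - lwz$logZ)
    theta_mean[t] <- sum(w * tb$mu[seq_len(t), seq(t, N), drop = FALSE])
    if (t < N) change_prob[t + 1L] <- sum(w[, 1L])
    log_norm_w[t] <- lwz$logZ
  }
  list(theta_mean = theta_mean, change_prob = change_prob,
       log_norm_w = log_norm_w)
}

#' Posterior probability of change per site
#'
#' Convenience accessor: Pr(I_t = 1 | X) for every site, with the first
#' site fixed at 1 by convention.
#'
#' @param result A `bar_segmentation` from [segment_sites()].
#' @return Numeric vector of per-site change probabilities.
#' @export
change_probability <- function(result) {
  stopifnot(inherits(result, "bar_segmentation"))
  result$change_prob
}

#' Fit the Poisson change rate by marginal-likelihood grid search
#'
#' For each candidate lambda the per-site prior change probabilities are
#' recomputed from the site spacings and the forward recursion's log
#' marginal is evaluated; the smallest lambda attaining the maximum is
#' returned. Default grid: 40 log-spaced values in [1e-4, 1] per bp.
#'
#' @param counts A `site_counts`.
#' @param grid Ascending positive lambda values.
#' @param mu0,nu0 Prior parameters; estimated from the data when `NULL`.
#' @return List with `lambda` (selected), `grid` and `log_marginal` (curve).
#' @export
fit_lambda <- function(counts, grid = NULL, mu0 = NULL, nu0 = NULL) {
  stopifnot(inherits(counts, "site_counts"))
  if (is.null(grid)) grid <- exp(seq(log(1e-4), log(1), length.out = 40))
  if (length(grid) == 0) stop("empty lambda grid")
  if (is.null(mu0) || is.null(nu0)) {
    est <- estimate_mu0_nu0(counts)
    if (is.null(mu0)) mu0 <- est$mu0
    if (is.null(nu0)) nu0 <- est$nu0
  }
  curve <- vapply(grid, function(lam) {
    hy <- bar_hyperparams(mu0, nu0, lam, counts$positions, counts$n)
    forward_recursion(counts, hy)$log_marginal
  }, numeric(1))
  list(lambda = grid[which.max(curve)], grid = grid, log_marginal = curve)
}

#' Rescale counts to a common binomial size
#'
#' Clusters of different sizes n have different posterior concentration;
#' dividing x and n by a common factor leaves every segment posterior mean
#' unchanged but restores a comparable posterior variance
#' (mu0 + X/n)(1 - mu0 - X/n)/(1 + n) across clusters. Scaled counts are
#' real-valued; all downstream computations use gamma functions and accept
#' them.
#'
#' @param counts A `site_counts`.
#' @param target_n New binomial size, > 0.
#' @return A `site_counts` with `x * target_n / n` and `n = target_n`.
#' @export
scale_counts <- function(counts, target_n) {
  stopifnot(inherits(counts, "site_counts"))
  if (target_n <= 0) stop("target_n must be positive")
  site_counts(counts$positions, counts$x * target_n / counts$n, target_n)
}

#' Segment a cluster's site counts
#'
#' Main entry point of the model: estimates (or accepts) the prior, fits
#' lambda by grid search when requested, runs the forward/backward/combine
#' recursions and returns per-site posterior accessibility means and change
#' probabilities.
#'
#' @param counts A `site_counts` (typically [to_site_counts()] of one
#'   cluster's matrix).
#' @param lambda `"auto"` (grid search) or a positive value.
#' @param grid Lambda grid for `"auto"` (default 40 log-spaced points in
#'   [1e-4, 1] per bp).
#' @param mu0,nu0 Prior parameters; empirical-Bayes estimates when `NULL`.
#' @param scale_n Optional common binomial size to rescale to before
#'   fitting.
#' @param p Optional explicit prior change probabilities (overrides
#'   `lambda`).
#' @return An object of class `bar_segmentation` with elements `positions`,
#'   `n`, `x`, `obs_freq`, `theta_mean`, `change_prob`, `log_marginal`,
#'   `hyper`, and the internal state needed by
#'   [posterior_segment_weights()].
#' @export
segment_sites <- function(counts, lambda = "auto", grid = NULL,
                          mu0 = NULL, nu0 = NULL, scale_n = NULL, p = NULL) {
  stopifnot(inherits(counts, "site_counts"))
  if (!is.null(scale_n)) counts <- scale_counts(counts, scale_n)
  est <- estimate_mu0_nu0(counts)
  if (is.null(mu0)) mu0 <- est$mu0
  if (is.null(nu0)) nu0 <- est$nu0
  if (is.null(p) && identical(lambda, "auto")) {
    fit <- fit_lambda(counts, grid = grid, mu0 = mu0, nu0 = nu0)
    lambda <- fit$lambda
  } else if (!is.null(p)) {
    lambda <- NA_real_
  }
  hyper <- bar_hyperparams(mu0, nu0, lambda, counts$positions, counts$n,
                           p = p)
  tb <- .segment_tables(counts, hyper)
  fwd <- forward_recursion(counts, hyper, tables = tb)
  bwd <- backward_recursion(counts, hyper, tables = tb)
  comb <- combine_weights(fwd, bwd, counts, hyper, tables = tb)
  structure(
    list(positions = counts$positions, n = counts$n, x = counts$x,
         obs_freq = counts$x / counts$n,
         theta_mean = comb$theta_mean, change_prob = comb$change_prob,
         log_marginal = fwd$log_marginal, hyper = hyper,
         lp = fwd$lp, lq = bwd$lq, tables = tb),
    class = "bar_segmentation"
  )
}

#' @export
print.bar_segmentation <- function(x, ...) {
  cat("Bayesian segmentation: ", length(x$positions), " sites, n = ", x$n,
      "\n  mu0 = ", signif(x$hyper$mu0, 4), ", nu0 = ",
      signif(x$hyper$nu0, 4), ", lambda = ", signif(x$hyper$lambda, 4),
      "\n  log marginal = ", signif(x$log_marginal, 6), "\n", sep = "")
  invisible(x)
}

#' Posterior segment-weight distribution at one site
#'
#' Returns the full distribution {w_{i,j,t}} over segments (i, j) containing
#' site t -- the patch-size distribution anchored at t.
#'
#' @param result A `bar_segmentation`.
#' @param t Site index in 1..N.
#' @return A data.frame with columns `i`, `j` (site indices) and `w`
#'   (posterior weight, summing to 1), sorted by decreasing weight.
#' @export
posterior_segment_weights <- function(result, t) {
  stopifnot(inherits(result, "bar_segmentation"))
  N <- length(result$positions)
  if (t < 1 || t > N) stop("t out of range")
  lwz <- .log_weights_at(t, result$lp, result$lq, result$tables)
  w <- exp(lwz$lw - lwz$logZ)
  df <- data.frame(i = rep(seq_len(t), times = N - t + 1L),
                   j = rep(seq(t, N), each = t),
                   w = as.numeric(w))
  df <- df[df$w > 0, , drop = FALSE]
  df[order(-df$w, df$i, df$j), , drop = FALSE]
}
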