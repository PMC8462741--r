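test_that("segment posterior follows the conjugate update formulas", {
  cnt <- site_counts(c(3, 8), c(0, 5), 10)
  hy <- bar_hyperparams(0.1, 10, 0.05, cnt$positions, cnt$n)
  sp <- segment_posterior(cnt, 1, 1, hy)
  expect_equal(sp$mu, (10 * 0.1 + 0) / 20)
  expect_equal(sp$nu, 20)

  # under the empirical mu0 rule the full-segment mean equals mu0
  cnt2 <- site_counts(c(3, 8), c(3, 1), 10)
  hy2 <- eb_hyper(cnt2, 0.05)
  expect_equal(hy2$mu0, 0.2)
  sp2 <- segment_posterior(cnt2, 1, 2, hy2)
  expect_equal(sp2$mu, (10 * 0.2 + 4) / 30)
  expect_equal(sp2$mu, hy2$mu0)

  expect_error(segment_posterior(cnt, 2, 1, hy), "i <= j")
})

test_that("posterior means are invariant to dividing x and n by a constant", {
  set.seed(21)
  cnt <- random_counts(6, 40)
  for (g in c(2, 5, 8)) {
    scaled <- scale_counts(cnt, cnt$n / g)
    hy <- eb_hyper(cnt, 0.1)
    hys <- eb_hyper(scaled, 0.1)
    for (i in 1:3) for (j in i:6) {
      expect_equal(segment_posterior(cnt, i, j, hy)$mu,
                   segment_posterior(scaled, i, j, hys)$mu,
                   tolerance = 1e-12)
    }
  }
})

test_that("empirical-Bayes prior estimates match the stated rules", {
  expect_equal(estimate_mu0_nu0(site_counts(c(1, 5), c(2, 2), 10)),
               list(mu0 = 0.2, nu0 = 10))
  expect_equal(estimate_mu0_nu0(site_counts(c(1, 5), c(0, 0), 10))$mu0, 1e-6)
  expect_equal(estimate_mu0_nu0(site_counts(c(1, 5), c(10, 10), 10))$mu0,
               1 - 1e-6)
})

test_that("forward recursion handles the degenerate conventions", {
  cnt <- site_counts(7, 3, 10)
  hy <- bar_hyperparams(0.2, 10, 0.1, cnt$positions, cnt$n)
  fwd <- forward_recursion(cnt, hy)
  expect_equal(exp(fwd$lp[1, 1]), 1)

  # p_t = 1 everywhere forces every site to be its own segment
  cnt3 <- site_counts(c(2, 4, 9), c(1, 5, 2), 10)
  hy3 <- bar_hyperparams(0.2, 10, NA, cnt3$positions, cnt3$n, p = c(1, 1, 1))
  fwd3 <- forward_recursion(cnt3, hy3)
  expect_equal(exp(diag(fwd3$lp)), rep(1, 3))
})

test_that("backward distributions are normalized and respect the boundary", {
  set.seed(14)
  cnt <- random_counts(6, 20)
  hy <- eb_hyper(cnt, 0.08)
  bwd <- backward_recursion(cnt, hy)
  for (t in 1:6) {
    expect_equal(sum(exp(bwd$lq[t:6, t])), 1, tolerance = 1e-10)
  }
  expect_equal(exp(bwd$lq[6, 6]), 1)              # q_{N,N+1} = 1
  expect_equal(exp(bwd$lq[3, 3]), hy$p[4])        # q_{t,t+1} = p_{t+1}
})

test_that("single-site model reduces to its closed form", {
  cnt <- site_counts(5, 4, 12)
  hy <- bar_hyperparams(0.3, 12, 0.1, cnt$positions, cnt$n)
  fit <- segment_sites(cnt, mu0 = 0.3, nu0 = 12, lambda = 0.1)
  a0 <- 0.3 * 12; b0 <- 0.7 * 12
  expect_equal(fit$theta_mean, (a0 + 4) / (a0 + b0 + 12))
  expect_equal(fit$change_prob, 1)
  ora <- enumerate_posterior_oracle(cnt, hy)
  expect_equal(ora$log_marginal, lbeta(a0 + 4, b0 + 8) - lbeta(a0, b0))
  expect_equal(fit$log_marginal, ora$log_marginal)
})

test_that("limits: lambda -> 0 gives one segment, p == 1 gives independence", {
  set.seed(8)
  cnt <- random_counts(5, 25)
  one <- segment_sites(cnt, lambda = 0)
  hy <- eb_hyper(cnt, 0)
  mu_full <- segment_posterior(cnt, 1, 5, hy)$mu
  expect_equal(one$theta_mean, rep(mu_full, 5))
  expect_equal(one$change_prob, c(1, rep(0, 4)))

  indep <- segment_sites(cnt, p = rep(1, 5))
  hy1 <- bar_hyperparams(indep$hyper$mu0, indep$hyper$nu0, NA,
                         cnt$positions, cnt$n, p = rep(1, 5))
  mu_site <- vapply(1:5, function(t) segment_posterior(cnt, t, t, hy1)$mu,
                    numeric(1))
  expect_equal(indep$theta_mean, mu_site)
  expect_equal(indep$change_prob, rep(1, 5))
})

test_that("posteriors match the enumeration oracle on random instances", {
  set.seed(77)
  for (rep in 1:25) {
    N <- sample(2:9, 1)
    cnt <- random_counts(N, sample(5:30, 1))
    hy <- eb_hyper(cnt, runif(1, 0.005, 0.5))
    fit <- segment_sites(cnt, mu0 = hy$mu0, nu0 = hy$nu0, lambda = hy$lambda)
    ora <- enumerate_posterior_oracle(cnt, hy)
    expect_lt(max(abs(fit$theta_mean - ora$theta_mean)), 1e-8)
    expect_lt(max(abs(fit$change_prob - ora$change_prob)), 1e-8)
    expect_lt(abs(fit$log_marginal - ora$log_marginal), 1e-8)
  }
})

test_that("oracle change probability is symmetric under site-order swap", {
  cnt <- site_counts(c(10, 14), c(3, 3), 12)
  hy <- bar_hyperparams(0.2, 12, 0.1, cnt$positions, cnt$n)
  ora <- enumerate_posterior_oracle(cnt, hy)
  cnt_r <- site_counts(c(10, 14), rev(cnt$x), 12)
  ora_r <- enumerate_posterior_oracle(cnt_r, hy)
  expect_equal(ora$change_prob[2], ora_r$change_prob[2])
})

test_that("posterior means stay within the segment-mean envelope", {
  set.seed(30)
  for (rep in 1:10) {
    N <- sample(3:8, 1)
    cnt <- random_counts(N, 20)
    hy <- eb_hyper(cnt, 0.1)
    fit <- segment_sites(cnt, mu0 = hy$mu0, nu0 = hy$nu0, lambda = 0.1)
    tb <- barseg:::.segment_tables(cnt, hy)
    for (t in seq_len(N)) {
      mus <- tb$mu[seq_len(t), seq(t, N)]
      expect_gte(fit$theta_mean[t], min(mus, na.rm = TRUE) - 1e-12)
      expect_lte(fit$theta_mean[t], max(mus, na.rm = TRUE) + 1e-12)
    }
  }
})

test_that("all outputs are invariant to shifting the coordinate origin", {
  set.seed(41)
  cnt <- random_counts(6, 15)
  shifted <- site_counts(cnt$positions + 137, cnt$x, cnt$n)
  f1 <- segment_sites(cnt, lambda = 0.07)
  f2 <- segment_sites(shifted, lambda = 0.07)
  expect_equal(f2$theta_mean, f1$theta_mean)
  expect_equal(f2$change_prob, f1$change_prob)
  expect_equal(f2$log_marginal, f1$log_marginal)
})

test_that("lambda grid search returns the argmax, smallest on ties", {
  set.seed(2)
  cnt <- random_counts(8, 20)
  single <- fit_lambda(cnt, grid = 0.05)
  expect_equal(single$lambda, 0.05)

  fit <- fit_lambda(cnt)
  expect_equal(fit$log_marginal[match(fit$lambda, fit$grid)],
               max(fit$log_marginal))
})

test_that("fitted lambda is larger for densely changing data", {
  set.seed(19)
  wins <- 0
  for (rep in 1:20) {
    N <- 30; n <- 100
    pos <- cumsum(sample(2:5, N, replace = TRUE))
    theta_dense <- rep(c(0.05, 0.4), length.out = N)  # change at every site
    dense <- site_counts(pos, rbinom(N, n, theta_dense), n)
    flat <- site_counts(pos, rbinom(N, n, 0.2), n)
    wins <- wins + (fit_lambda(dense)$lambda > fit_lambda(flat)$lambda)
  }
  expect_gte(wins, 18)
})

test_that("scaling halves counts and shrinks the printed posterior variance", {
  cnt <- site_counts(c(1, 4, 9), c(10, 40, 20), 100)
  half <- scale_counts(cnt, 50)
  expect_equal(half$x, c(5, 20, 10))
  expect_equal(half$n, 50)

  # Var_{1:1} = (mu0 + X/n)(1 - mu0 - X/n)/(1 + n) decreases in n
  mu0 <- 0.2; Xfrac <- 0.25
  v <- function(n) (mu0 + Xfrac) * (1 - mu0 - Xfrac) / (1 + n)
  expect_true(all(diff(v(c(10, 50, 200, 1000))) < 0))
})

test_that("recursions reject invalid hyperparameters", {
  expect_error(bar_hyperparams(0, 10, 0.1, c(1, 2), 5), "mu0")
  expect_error(bar_hyperparams(0.2, 10, 0.1, c(1, 2), 5, p = c(0.5, 0.5)),
               "p\\[1\\]")
  expect_error(enumerate_posterior_oracle(
    site_counts(1:15, rep(1, 15), 5),
    bar_hyperparams(0.2, 5, 0.1, 1:15, 5)), "N <= 14")
})
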