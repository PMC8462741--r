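# Shared fixtures and independent mini-oracles for the test suite.

# Random binomial site counts.
random_counts <- function(N, n, spread = 60) {
  pos <- sort(sample.int(spread, N))
  x <- rbinom(N, n, runif(1, 0.05, 0.5))
  site_counts(pos, x, n)
}

# Hyperparameters with empirical-Bayes prior and a given lambda.
eb_hyper <- function(counts, lambda) {
  est <- estimate_mu0_nu0(counts)
  bar_hyperparams(est$mu0, est$nu0, lambda, counts$positions, counts$n)
}

# Write a small FASTA file; returns its path.
write_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# Naive agglomerative complete-linkage: returns the multiset of merge
# heights, computed by exhaustive max-pairwise-distance search.
naive_complete_linkage_heights <- function(rows) {
  clusters <- lapply(seq_len(nrow(rows)), identity)
  d <- as.matrix(dist(rows, method = "manhattan"))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best) { best <- h; bi <- a; bj <- b }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Simple two-segment synthetic counts: elevated theta_in over sites
# seg[1]:seg[2], baseline theta_out elsewhere, direct binomial sampling.
segment_counts <- function(N, n, seg, theta_in = 0.3, theta_out = 0.01,
                           positions = NULL) {
  if (is.null(positions)) positions <- cumsum(sample(1:6, N, replace = TRUE))
  theta <- rep(theta_out, N)
  theta[seg[1]:seg[2]] <- theta_in
  site_counts(positions, rbinom(N, n, theta), n)
}
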