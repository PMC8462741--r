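#' Hamming distance between two binary vectors
#'
#' @param x,y Equal-length binary vectors.
#' @return Number of disagreeing coordinates.
#' @export
hamming_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  sum(x != y)
}

# Deduplicate rows of a call matrix; returns distinct rows in canonical
# (lexicographic) order with summed multiplicity weights and the mapping
# from original rows to distinct rows. Complete-linkage heights depend only
# on the set of distinct rows, so clustering the deduplicated matrix with
# multiplicities is exactly equivalent to clustering the expanded matrix.
.dedup_rows <- function(calls, weights) {
  keys <- apply(calls, 1L, paste0, collapse = "")
  lev <- sort(unique(keys))
  idx <- match(keys, lev)
  distinct <- calls[match(lev, keys), , drop = FALSE]
  w <- as.numeric(tapply(weights, idx, sum))
  list(distinct = distinct, weights = w, map = idx)
}

#' Complete-linkage clustering under Hamming distance
#'
#' Groups molecules by their binary accessibility pattern. Distinct rows are
#' clustered once (complete linkage is unaffected by row multiplicity) and
#' assignments are re-expanded; cluster sizes are duplicate-count weighted.
#' Rows are put in canonical lexicographic order before linkage so the
#' result is invariant to input row order.
#'
#' @param matrix A `mutation_matrix`.
#' @param k Number of clusters (1..number of distinct rows).
#' @return An object of class `cluster_assignment`: `labels` (per-sequence
#'   cluster index, 1 = largest cluster), `k`, `sizes` (weighted), `names`
#'   (strand-prefixed, e.g. `"C_1909"`), `seq_ids`, and attribute `heights`
#'   (complete-linkage merge heights over distinct rows).
#' @export
complete_linkage_cluster <- function(matrix, k) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (k < 1) stop("k must be >= 1")
  dd <- .dedup_rows(matrix$calls, matrix$weights)
  n_distinct <- nrow(dd$distinct)
  if (k > n_distinct) {
    stop("k = ", k, " exceeds the number of distinct rows (", n_distinct, ")")
  }
  if (n_distinct == 1L) {
    lab_distinct <- 1L
    heights <- numeric(0)
  } else {
    d <- stats::dist(dd$distinct, method = "manhattan")
    hc <- stats::hclust(d, method = "complete")
    lab_distinct <- stats::cutree(hc, k = k)
    heights <- hc$height
  }
  labels <- lab_distinct[dd$map]
  sizes <- vapply(seq_len(k), function(g) {
    sum(matrix$weights[labels == g])
  }, numeric(1))
  ord <- order(-sizes, seq_len(k))
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  labels <- relab[labels]
  sizes <- sizes[ord]
  prefix <- if (matrix$strand == "top") "C" else "G"
  structure(
    list(labels = labels, k = as.integer(k), sizes = sizes,
         names = paste0(prefix, "_", round(sizes)),
         seq_ids = matrix$seq_ids),
    heights = heights,
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: k =", x$k, "\n")
  print(stats::setNames(x$sizes, x$names))
  invisible(x)
}

# Weighted within-cluster dispersion W_k = sum_r D_r / (2 n_r), with
# D_r the (ordered) weighted pairwise Hamming distance sum in cluster r.
.within_dispersion <- function(distinct, weights, labels) {
  W <- 0
  for (g in unique(labels)) {
    rows <- which(labels == g)
    n_r <- sum(weights[rows])
    if (length(rows) < 2L || n_r <= 0) next
    d <- as.matrix(stats::dist(distinct[rows, , drop = FALSE],
                               method = "manhattan"))
    w <- weights[rows]
    D_r <- as.numeric(t(w) %*% d %*% w)  # ordered pairs; diagonal is 0
    W <- W + D_r / (2 * n_r)
  }
  W
}

.cluster_distinct <- function(distinct, k) {
  if (nrow(distinct) == 1L) return(rep(1L, 1L))
  d <- stats::dist(distinct, method = "manhattan")
  stats::cutree(stats::hclust(d, method = "complete"), k = k)
}

#' Gap statistic for selecting the number of clusters
#'
#' Compares the log within-cluster Hamming dispersion of the data against B
#' reference datasets in which each column is resampled as an independent
#' Bernoulli with that column's empirical frequency (the uniform-box
#' reference of the original gap statistic is degenerate for binary data;
#' the Bernoulli reference preserves marginal site accessibility). The
#' selected k is the smallest k with gap(k) >= gap(k+1) - se(k+1).
#'
#' @param matrix A `mutation_matrix`.
#' @param k_max Largest k considered (>= 2).
#' @param B Number of reference datasets (>= 10, default 50).
#' @param seed Integer seed for the reference draws.
#' @return A list with `k` (selected), `gap`, `se`, `log_W`, `log_W_ref_mean`
#'   per k in 1..k_max.
#' @export
gap_statistic <- function(matrix, k_max = 10, B = 50, seed = 1) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (k_max < 2) stop("k_max must be >= 2")
  if (B < 10) stop("B must be >= 10")
  dd <- .dedup_rows(matrix$calls, matrix$weights)
  if (nrow(dd$distinct) == 1L) {
    warning("all rows identical; returning k = 1")
    return(list(k = 1L, gap = NA_real_, se = NA_real_,
                log_W = NA_real_, log_W_ref_mean = NA_real_))
  }
  k_max <- min(k_max, nrow(dd$distinct))
  ks <- seq_len(k_max)
  logW <- function(distinct, weights) {
    vapply(ks, function(k) {
      W <- .within_dispersion(distinct, weights,
                              .cluster_distinct(distinct, k))
      log(max(W, .Machine$double.xmin))
    }, numeric(1))
  }
  lW <- logW(dd$distinct, dd$weights)

  n_rows <- nrow(matrix$calls)
  col_freq <- as.numeric(crossprod(matrix$weights, matrix$calls)) /
    sum(matrix$weights)
  set.seed(seed)
  lW_ref <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    ref <- vapply(col_freq, function(p) stats::rbinom(n_rows, 1L, p),
                  integer(n_rows))
    ref <- matrix(as.integer(ref), nrow = n_rows)
    rdd <- .dedup_rows(ref, rep(1, n_rows))
    lw <- rep(log(.Machine$double.xmin), k_max)
    kk <- min(k_max, nrow(rdd$distinct))
    lw[seq_len(kk)] <- vapply(seq_len(kk), function(k) {
      W <- .within_dispersion(rdd$distinct, rdd$weights,
                              .cluster_distinct(rdd$distinct, k))
      log(max(W, .Machine$double.xmin))
    }, numeric(1))
    lW_ref[b, ] <- lw
  }
  gap <- colMeans(lW_ref) - lW
  se <- apply(lW_ref, 2L, stats::sd) * sqrt(1 + 1 / B)
  k_sel <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) { k_sel <- k; break }
  }
  list(k = as.integer(k_sel), gap = gap, se = se, log_W = lW,
       log_W_ref_mean = colMeans(lW_ref))
}
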