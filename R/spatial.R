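# Downstream correlation machinery: hotspot selection, cross-strand
# smoothing, posterior-weighted distances from SHM hotspots to BARs, window
# score aggregation for external tracks and the strand-fraction test.

#' Per-position signal track over the amplicon
#'
#' @param values Per-position values, one per amplicon base 1..L.
#' @param strand Optional strand label.
#' @return An object of class `site_track`.
#' @export
site_track <- function(values, strand = NA_character_) {
  if (any(!is.finite(values))) stop("track values must be finite")
  structure(list(positions = seq_along(values),
                 values = as.numeric(values), strand = strand),
            class = "site_track")
}

#' Embed per-site values into a full-length track
#'
#' Places values observed at informative sites onto the 1..L bp grid with
#' zeros elsewhere, the gridding used before cross-strand smoothing.
#'
#' @param positions Site coordinates.
#' @param values Values at those sites.
#' @param L Amplicon length.
#' @param strand Optional strand label.
#' @return A `site_track` of length L.
#' @export
track_from_sites <- function(positions, values, L, strand = NA_character_) {
  v <- numeric(L)
  v[positions] <- values
  site_track(v, strand)
}

#' Top-k most mutated sites
#'
#' Sorts sites by descending mutation frequency (ties broken by ascending
#' position) and keeps the first k per strand; multiple strands are
#' concatenated in the order given.
#'
#' @param counts A `site_counts` or list of them (one per strand).
#' @param k Number of sites per strand (>= 1).
#' @return A data.frame with `position`, `freq`, `rank`, `strand`.
#' @export
top_k_sites <- function(counts, k) {
  if (k < 1) stop("k must be >= 1")
  if (inherits(counts, "site_counts")) counts <- list(counts)
  out <- lapply(seq_along(counts), function(s) {
    cc <- counts[[s]]
    if (k > length(cc$positions)) stop("k exceeds number of sites")
    freq <- cc$x / cc$n
    ord <- order(-freq, cc$positions)[seq_len(k)]
    data.frame(position = cc$positions[ord], freq = freq[ord],
               rank = seq_len(k),
               strand = if (!is.null(names(counts))) names(counts)[s]
                        else as.character(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation between paired site values
#'
#' @param a,b Equal-length numeric vectors (>= 3 paired values).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r` and `p` (two-sided).
#' @export
site_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need at least 3 paired values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in one of the vectors")
  }
  ct <- stats::cor.test(a, b, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Gaussian kernel smoothing of a track
#'
#' Discrete Gaussian kernel over bp positions, truncated at 4 sigma and
#' renormalized (also at the track edges), so total mass on
#' interior-supported tracks is conserved.
#'
#' @param track A `site_track`.
#' @param sigma Kernel standard deviation in bp (> 0, default 1).
#' @return A smoothed `site_track`.
#' @export
gaussian_smooth <- function(track, sigma = 1) {
  stopifnot(inherits(track, "site_track"))
  if (sigma <= 0) stop("sigma must be positive")
  r <- max(1L, ceiling(4 * sigma))
  offs <- seq(-r, r)
  kern <- exp(-offs^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  L <- length(track$values)
  out <- numeric(L)
  wsum <- numeric(L)
  for (d in seq_along(offs)) {
    src <- seq_len(L) - offs[d]
    ok <- src >= 1L & src <= L
    out[ok] <- out[ok] + kern[d] * track$values[src[ok]]
    wsum[ok] <- wsum[ok] + kern[d]
  }
  site_track(out / wsum, track$strand)
}

#' Posterior-weighted signed distance from a site to a BAR
#'
#' Averages the signed bp distances from the query site to every site of
#' the BAR, weighted by each BAR site's posterior accessibility mean (its
#' "posterior response probability to bisulfite"). Positive values mean the
#' query site lies 3' of the BAR's posterior-weighted centroid.
#'
#' @param site Query position (bp).
#' @param bar A single BAR call (element of a `bar_calls` list).
#' @return Signed distance in bp.
#' @export
weighted_distance_to_bar <- function(site, bar) {
  tau <- bar$site_positions
  th <- bar$theta_mean
  sum((site - tau) * th) / sum(th)
}

#' Nearest-BAR distance table for hotspot sites
#'
#' For each query site, computes the posterior-weighted signed distance to
#' every BAR (both strands pooled), identifies the nearest and second
#' nearest by absolute distance, and reports two correlations of SHM
#' frequency against distance: over nearest-BAR pairs within `window` bp,
#' and over all second-nearest distances.
#'
#' @param sites A data.frame from [top_k_sites()] (columns `position`,
#'   `freq`).
#' @param bars Named list of `bar_calls` (all clusters, both strands).
#' @param window Distance threshold in bp for the nearest-BAR correlation
#'   (default 15; `Inf` uses all sites).
#' @return List with `table` (one row per site: nearest/second-nearest BAR
#'   and distances, `within_window`), `cor_nearest` and `cor_second` (each
#'   `r`/`p`, or NULL when fewer than 3 usable pairs).
#' @export
nearest_bar_analysis <- function(sites, bars, window = 15) {
  flat <- list()
  for (cl in names(bars)) {
    for (b in bars[[cl]]) {
      b$cluster <- cl
      flat[[length(flat) + 1L]] <- b
    }
  }
  if (length(flat) == 0L) stop("no BARs supplied")
  rows <- lapply(seq_len(nrow(sites)), function(r) {
    d <- vapply(flat, function(b) weighted_distance_to_bar(sites$position[r], b),
                numeric(1))
    ord <- order(abs(d))
    second <- if (length(d) >= 2L) ord[2L] else NA_integer_
    data.frame(
      site = sites$position[r], shm_freq = sites$freq[r],
      nearest_bar = flat[[ord[1L]]]$cluster,
      signed_distance_bp = d[ord[1L]],
      second_bar = if (is.na(second)) NA_character_
                   else flat[[second]]$cluster,
      second_distance_bp = if (is.na(second)) NA_real_ else d[second],
      within_window = abs(d[ord[1L]]) <= window,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  safe_cor <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NULL)
    site_correlation(a, b)
  }
  near <- tab[tab$within_window, , drop = FALSE]
  list(
    table = tab,
    cor_nearest = safe_cor(near$shm_freq, abs(near$signed_distance_bp)),
    cor_second = if (all(is.na(tab$second_distance_bp))) NULL
                 else safe_cor(tab$shm_freq[!is.na(tab$second_distance_bp)],
                               abs(tab$second_distance_bp[
                                 !is.na(tab$second_distance_bp)]))
  )
}

#' Aggregate sliding-window score arrays onto the amplicon
#'
#' External per-window per-site scores (e.g. attribution scores computed on
#' overlapping sequence windows) are combined by summing the scores falling
#' on each amplicon position and dividing by the number of windows covering
#' it. Positions covered by no window get 0 and are flagged.
#'
#' @param window_scores List of windows, each a list with `offset` (1-based
#'   start on the amplicon) and `scores` (per-site numeric array).
#' @param L Amplicon length.
#' @return A `site_track` of length L with attribute `coverage` (number of
#'   windows per position).
#' @export
aggregate_window_scores <- function(window_scores, L) {
  total <- numeric(L)
  cover <- integer(L)
  for (w in window_scores) {
    lw <- length(w$scores)
    if (w$offset < 1 || w$offset + lw - 1L > L) {
      stop("window at offset ", w$offset, " exceeds [1, ", L, "]")
    }
    idx <- seq(w$offset, w$offset + lw - 1L)
    total[idx] <- total[idx] + w$scores
    cover[idx] <- cover[idx] + 1L
  }
  v <- ifelse(cover > 0L, total / pmax(cover, 1L), 0)
  tr <- site_track(v)
  attr(tr, "coverage") <- cover
  tr
}

#' Chi-squared comparison of strand accessibility fractions
#'
#' 2x2 test of independence, without continuity correction, of the fraction
#' of molecules carrying a BAR between the two strands.
#'
#' @param n_bar_top,n_total_top Counts for the top strand.
#' @param n_bar_bottom,n_total_bottom Counts for the bottom strand.
#' @return List with `statistic`, `p`, and the two `fractions`.
#' @export
strand_fraction_test <- function(n_bar_top, n_total_top,
                                 n_bar_bottom, n_total_bottom) {
  if (n_total_top <= 0 || n_total_bottom <= 0) stop("totals must be > 0")
  tab <- rbind(top = c(bar = n_bar_top, no_bar = n_total_top - n_bar_top),
               bottom = c(n_bar_bottom, n_total_bottom - n_bar_bottom))
  if (any(colSums(tab) == 0)) stop("zero margin in the 2x2 table")
  if (n_bar_top / n_total_top == n_bar_bottom / n_total_bottom) {
    return(list(statistic = 0, p = 1,
                fractions = c(top = n_bar_top / n_total_top,
                              bottom = n_bar_bottom / n_total_bottom)))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       fractions = c(top = n_bar_top / n_total_top,
                     bottom = n_bar_bottom / n_total_bottom))
}
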