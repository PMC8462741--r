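# Calling accessible regions from segmentation posteriors and measuring
# patch sizes under four boundary definitions:
#   previous      -- per-sequence runs of >= 2 converted Cs, last-C ends
#   previous-MP   -- same runs, ends extended to flanking midpoints
#   model (new)   -- expectation over the posterior segment distribution
#                    {w_{i,j,t}} at the cluster's peak site, last-C ends
#   model-MP      -- same expectation with midpoint ends
# "Size" is the inclusive bp length tau_j - tau_i + 1 under last-C ends;
# midpoint ends replace each end by the midpoint to the nearest flanking
# informative site (falling back to last-C at the sequence ends), which can
# only widen a patch.

# Boundary coordinates of segment (i, j) in site-index space.
.patch_bounds <- function(i, j, positions, mode) {
  N <- length(positions)
  if (mode == "last_c") {
    left <- positions[i] - 0.5
    right <- positions[j] + 0.5
  } else {
    left <- ifelse(i > 1, (positions[pmax(i - 1, 1)] + positions[i]) / 2,
                   positions[i] - 0.5)
    right <- ifelse(j < N, (positions[j] + positions[pmin(j + 1, N)]) / 2,
                    positions[j] + 0.5)
  }
  cbind(left = left, right = right)
}

#' Patch-size distribution and expectation from segment weights
#'
#' Given the posterior distribution over segments (i, j) anchored at a peak
#' site, computes the size of every candidate segment under the chosen
#' boundary definition and the posterior expectation of the size.
#'
#' @param w A data.frame with columns `i`, `j`, `w` as returned by
#'   [posterior_segment_weights()]; weights must sum to 1.
#' @param positions Site coordinates tau_1..tau_N.
#' @param mode `"last_c"` (inclusive bp span of the terminal converted Cs)
#'   or `"midpoint"` (boundaries at midpoints to the flanking informative
#'   sites; sequence-end segments fall back to last-C on that side).
#' @return List with `expectation` (bp) and `sizes` (the input data.frame
#'   with a `size` column).
#' @export
model_patch_size <- function(w, positions, mode = c("last_c", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(w), all(c("i", "j", "w") %in% names(w)))
  if (abs(sum(w$w) - 1) > 1e-6) stop("weights must sum to 1")
  b <- .patch_bounds(w$i, w$j, positions, mode)
  sizes <- b[, "right"] - b[, "left"]
  w$size <- sizes
  list(expectation = sum(w$w * sizes), sizes = w)
}

#' Call BARs from a segmentation posterior
#'
#' A cluster contains a nontrivial BAR when at least `min_consecutive`
#' consecutive informative sites have posterior accessibility mean at or
#' above `threshold_factor` times the prior mean mu0. Each maximal such run
#' yields one BAR, anchored at its peak site (maximal observed conversion
#' frequency; ties to the lower position) and extended to the
#' maximum-a-posteriori segment around that peak. Expected sizes are
#' reported under last-C and midpoint boundary definitions.
#'
#' @param result A `bar_segmentation`.
#' @param threshold_factor Multiple of mu0 a site must reach (default 3).
#' @param min_consecutive Minimum run length of elevated sites (default 2).
#' @param cluster,strand Optional labels carried into the calls.
#' @return An object of class `bar_calls`: a list of BAR calls, each with
#'   `peak_site`, `site_span` (positions), `span_index`, `size_new`,
#'   `size_new_mp`, `size_distribution`, `theta_mean`; attribute `has_bar`
#'   is FALSE for clusters with no typical patch.
#' @export
call_bars <- function(result, threshold_factor = 3, min_consecutive = 2,
                      cluster = NA_character_, strand = NA_character_) {
  stopifnot(inherits(result, "bar_segmentation"))
  thr <- threshold_factor * result$hyper$mu0
  above <- result$theta_mean >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_consecutive
  calls <- list()
  for (k in which(keep)) {
    run <- starts[k]:ends[k]
    peak <- run[which.max(result$obs_freq[run])]
    w <- posterior_segment_weights(result, peak)
    map <- w[1L, ]  # maximum a posteriori segment around the peak
    lo <- min(starts[k], map$i)
    hi <- max(ends[k], map$j)
    calls[[length(calls) + 1L]] <- list(
      cluster = cluster, strand = strand,
      peak_site = result$positions[peak], peak_index = peak,
      site_span = result$positions[c(lo, hi)],
      span_index = c(lo, hi),
      size_new = model_patch_size(w, result$positions, "last_c")$expectation,
      size_new_mp = model_patch_size(w, result$positions,
                                     "midpoint")$expectation,
      size_distribution = w,
      site_positions = result$positions[lo:hi],
      theta_mean = result$theta_mean[lo:hi]
    )
  }
  structure(calls, has_bar = length(calls) > 0L, class = "bar_calls")
}

#' @export
print.bar_calls <- function(x, ...) {
  if (!attr(x, "has_bar")) {
    cat("No typical patch.\n")
    return(invisible(x))
  }
  for (b in x) {
    cat(sprintf("BAR %s [%d, %d] peak %d: size %.2f bp (last-C), %.2f bp (midpoint)\n",
                ifelse(is.na(b$cluster), "", b$cluster),
                b$site_span[1], b$site_span[2], b$peak_site,
                b$size_new, b$size_new_mp))
  }
  invisible(x)
}

#' Per-sequence patch calling (previous definition)
#'
#' The definition used before model-based segmentation: within each
#' individual molecule, a patch is a maximal run of at least `min_run`
#' consecutive converted informative sites, with the patch ending at the
#' last converted C on either end (`size_prev`, inclusive bp length) or
#' extended to the flanking midpoints (`size_prev_mp`). Independent of any
#' cluster assignment.
#'
#' @param matrix A `mutation_matrix`.
#' @param min_run Minimum number of consecutive converted sites (default 2).
#' @return A data.frame with one row per patch: `seq_id`, `weight`,
#'   `first_converted`, `last_converted`, `run_length`, `size_prev`,
#'   `size_prev_mp`.
#' @export
previous_patch_caller <- function(matrix, min_run = 2) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  pos <- matrix$positions
  out <- vector("list", nrow(matrix$calls))
  for (s in seq_len(nrow(matrix$calls))) {
    r <- rle(matrix$calls[s, ] == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_run)
    if (length(keep) == 0L) next
    b_last <- .patch_bounds(starts[keep], ends[keep], pos, "last_c")
    b_mp <- .patch_bounds(starts[keep], ends[keep], pos, "midpoint")
    out[[s]] <- data.frame(
      seq_id = matrix$seq_ids[s], weight = matrix$weights[s],
      first_converted = pos[starts[keep]], last_converted = pos[ends[keep]],
      run_length = r$lengths[keep],
      size_prev = b_last[, "right"] - b_last[, "left"],
      size_prev_mp = b_mp[, "right"] - b_mp[, "left"],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(), weight = numeric(),
                      first_converted = numeric(), last_converted = numeric(),
                      run_length = integer(), size_prev = numeric(),
                      size_prev_mp = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Mean patch size under the four definitions
#'
#' Summarizes called BARs and per-sequence patches per cluster and overall.
#' Grand means average the cluster-level means unweighted (both strands may
#' be pooled by passing their clusters together); the weighted alternative
#' averages cluster means weighted by cluster size.
#'
#' @param bar_calls Named list (one entry per cluster) of `bar_calls`.
#' @param sequence_patches Named list (same clusters) of data.frames from
#'   [previous_patch_caller()], run on each cluster's matrix.
#' @param weight_by_size Weight cluster means by weighted patch/sequence
#'   counts instead of unweighted averaging (default FALSE).
#' @return A data.frame with rows Previous, New, Previous-MP, New-MP and
#'   columns `mean`, `sem`, `n_clusters`; attribute `single_cluster` flags
#'   an undefined SEM (reported as 0).
#' @export
patch_summary_table <- function(bar_calls, sequence_patches,
                                weight_by_size = FALSE) {
  if (length(bar_calls) == 0L) stop("no clusters supplied")
  has <- vapply(bar_calls, function(b) isTRUE(attr(b, "has_bar")), logical(1))
  if (!any(has)) stop("no cluster contains a BAR")
  clusters <- names(bar_calls)[has]

  per_cluster <- lapply(clusters, function(cl) {
    bc <- bar_calls[[cl]]
    sp <- sequence_patches[[cl]]
    wmean <- function(v, w) if (length(v)) sum(v * w) / sum(w) else NA_real_
    c(prev = wmean(sp$size_prev, sp$weight),
      prev_mp = wmean(sp$size_prev_mp, sp$weight),
      new = mean(vapply(bc, `[[`, numeric(1), "size_new")),
      new_mp = mean(vapply(bc, `[[`, numeric(1), "size_new_mp")),
      size = if (!is.null(sp) && nrow(sp)) sum(sp$weight) else 1)
  })
  m <- do.call(rbind, per_cluster)
  rownames(m) <- clusters
  wts <- if (weight_by_size) m[, "size"] else rep(1, nrow(m))
  grand <- function(col) {
    v <- m[, col]
    ok <- !is.na(v)
    sum(v[ok] * wts[ok]) / sum(wts[ok])
  }
  sem <- function(col) {
    v <- m[!is.na(m[, col]), col]
    if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  }
  defs <- c(prev = "Previous", new = "New",
            prev_mp = "Previous-MP", new_mp = "New-MP")
  out <- data.frame(
    definition = unname(defs),
    mean = vapply(names(defs), grand, numeric(1)),
    sem = vapply(names(defs), sem, numeric(1)),
    n_clusters = length(clusters),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "single_cluster") <- length(clusters) < 2L
  attr(out, "per_cluster") <- m
  out
}

#' Export BAR calls as a BED-like table
#'
#' Coordinates in the BED output are 0-based half-open (converted from the
#' package's internal 1-based inclusive coordinates; stated in the header).
#'
#' @param bar_calls Named list of `bar_calls` per cluster.
#' @param path Output path.
#' @param chrom Chromosome/amplicon name for the first column.
#' @export
write_bars_bed <- function(bar_calls, path, chrom = "amplicon") {
  rows <- list()
  for (cl in names(bar_calls)) {
    for (b in bar_calls[[cl]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = b$site_span[1] - 1L, end = b$site_span[2],
        name = cl, score = signif(max(b$theta_mean), 6),
        strand = ifelse(identical(b$strand, "bottom"), "-", "+"),
        stringsAsFactors = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# BED intervals: 0-based half-open, converted from ",
                    "1-based inclusive amplicon coordinates"), con)
  if (length(rows)) {
    utils::write.table(do.call(rbind, rows), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
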