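# End-to-end pipeline: matrix -> clustering -> per-cluster segmentation ->
# BAR calls -> patch-size summary (-> spatial analysis when an SHM matrix
# is supplied), with all randomness flowing from one root seed.

#' Run the full BAR analysis pipeline
#'
#' Stages: load (or simulate) a mutation matrix, cluster molecules, segment
#' each cluster's site counts, call BARs, summarize patch sizes, and --
#' when an SHM matrix is supplied -- run the hotspot-to-BAR distance
#' analysis. Writes per-stage TSV/BED/JSON outputs when `outdir` is given
#' and returns the full result bundle invisibly.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `matrix` (path to a matrix TSV) or `simulate = TRUE` (uses
#'   [default_synthetic_spec()]); optional `weights`, `shm_matrix`,
#'   `n_sequences`, `k` (clusters, default 6), `lambda` (`"auto"` or
#'   value), `min_cluster` (smallest cluster segmented, default 20),
#'   `threshold_factor` (default 3), `min_run` (default 2), `top_k`
#'   (default 25), `window_bp` (default 15), `seed` (default 1), `outdir`.
#' @return (Invisibly) a list with `matrix`, `clusters`, `segmentation`
#'   (per cluster), `bars`, `patch_summary`, `spatial` (or NULL) and
#'   `summary` (the machine-readable stage summary).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(simulate = FALSE, k = 6L, lambda = "auto", min_cluster = 20,
         threshold_factor = 3, min_run = 2, top_k = 25, window_bp = 15,
         seed = 1L, outdir = NULL, n_sequences = 2000), config)
  for (key in c("matrix", "weights", "shm_matrix")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("stage validate: input path does not exist: ", cfg[[key]])
    }
  }
  if (!isTRUE(cfg$simulate) && is.null(cfg$matrix)) {
    stop("stage validate: need either 'matrix' or 'simulate: true'")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  m <- stage("load", {
    if (isTRUE(cfg$simulate)) {
      simulate_matrix(default_synthetic_spec(cfg$n_sequences), cfg$seed)$matrix
    } else {
      read_matrix(cfg$matrix, weights = cfg$weights)
    }
  })

  cl <- stage("cluster", complete_linkage_cluster(m, k = cfg$k))

  seg <- stage("segment", {
    out <- list()
    for (g in seq_len(cl$k)) {
      rows <- cl$labels == g
      if (sum(m$weights[rows]) < cfg$min_cluster) next
      sub <- mutation_matrix(m$calls[rows, , drop = FALSE], m$positions,
                             m$strand, seq_ids = m$seq_ids[rows],
                             weights = m$weights[rows])
      out[[cl$names[g]]] <- segment_sites(to_site_counts(sub),
                                          lambda = cfg$lambda)
    }
    out
  })

  bars <- stage("bars", {
    out <- list()
    for (nm in names(seg)) {
      out[[nm]] <- call_bars(seg[[nm]],
                             threshold_factor = cfg$threshold_factor,
                             min_consecutive = cfg$min_run,
                             cluster = nm, strand = m$strand)
    }
    out
  })

  patches <- stage("patches", {
    out <- list()
    for (g in seq_len(cl$k)) {
      rows <- cl$labels == g
      sub <- mutation_matrix(m$calls[rows, , drop = FALSE], m$positions,
                             m$strand, seq_ids = m$seq_ids[rows],
                             weights = m$weights[rows])
      out[[cl$names[g]]] <- previous_patch_caller(sub, min_run = cfg$min_run)
    }
    out
  })

  has_bar <- vapply(bars, function(b) isTRUE(attr(b, "has_bar")), logical(1))
  summary_tab <- if (any(has_bar)) {
    stage("patch_summary", patch_summary_table(bars, patches))
  } else NULL

  spatial_res <- NULL
  if (!is.null(cfg$shm_matrix)) {
    spatial_res <- stage("spatial", {
      shm <- read_matrix(cfg$shm_matrix)
      sites <- top_k_sites(to_site_counts(shm), k = cfg$top_k)
      nearest_bar_analysis(sites, bars[has_bar], window = cfg$window_bp)
    })
  }

  bar_fraction <- sum(cl$sizes[has_bar]) / sum(cl$sizes)
  summary <- list(
    parameters = cfg[c("k", "lambda", "threshold_factor", "min_run",
                       "top_k", "window_bp", "seed")],
    n_sequences = sum(m$weights),
    n_sites = length(m$positions),
    cluster_fractions = stats::setNames(cl$sizes / sum(cl$sizes), cl$names),
    bar_fraction = bar_fraction,
    n_bars = sum(vapply(bars, length, integer(1))),
    bar_table = lapply(bars[has_bar], function(b) lapply(b, function(x) {
      x[c("cluster", "peak_site", "site_span", "size_new", "size_new_mp")]
    })),
    patch_size_means = if (!is.null(summary_tab)) {
      stats::setNames(summary_tab$mean, summary_tab$definition)
    } else NULL,
    correlations = if (!is.null(spatial_res)) {
      list(nearest = spatial_res$cor_nearest,
           second = spatial_res$cor_second)
    } else NULL
  )

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(seq_id = cl$seq_ids, cluster = cl$labels,
                 cluster_name = cl$names[cl$labels]),
      file.path(cfg$outdir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    seg_json <- lapply(seg, function(s) list(
      positions = s$positions, obs_freq = s$obs_freq,
      theta_mean = s$theta_mean, change_prob = s$change_prob,
      mu0 = s$hyper$mu0, nu0 = s$hyper$nu0, lambda = s$hyper$lambda,
      log_marginal = s$log_marginal))
    jsonlite::write_json(seg_json, file.path(cfg$outdir, "segmentation.json"),
                         auto_unbox = TRUE, digits = NA)
    write_bars_bed(bars[has_bar], file.path(cfg$outdir, "bars.bed"))
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  invisible(list(matrix = m, clusters = cl, segmentation = seg, bars = bars,
                 patches = patches, patch_summary = summary_tab,
                 spatial = spatial_res, summary = summary))
}
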