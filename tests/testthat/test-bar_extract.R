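test_that("model_patch_size reproduces the worked boundary arithmetic", {
  pos <- c(10, 14, 20, 26)
  w <- data.frame(i = 2, j = 3, w = 1)
  expect_equal(model_patch_size(w, pos, "last_c")$expectation, 7)   # 20-14+1
  expect_equal(model_patch_size(w, pos, "midpoint")$expectation, 11)

  # point segment under last-C has size 1
  wp <- data.frame(i = 2, j = 2, w = 1)
  expect_equal(model_patch_size(wp, pos, "last_c")$expectation, 1)

  # uniform weight over two segments averages their sizes
  w2 <- data.frame(i = c(1, 2), j = c(2, 3), w = c(0.5, 0.5))
  s1 <- model_patch_size(data.frame(i = 1, j = 2, w = 1), pos,
                         "last_c")$expectation
  s2 <- model_patch_size(data.frame(i = 2, j = 3, w = 1), pos,
                         "last_c")$expectation
  expect_equal(model_patch_size(w2, pos, "last_c")$expectation,
               mean(c(s1, s2)))

  expect_error(model_patch_size(data.frame(i = 1, j = 1, w = 0.5), pos),
               "sum to 1")
})

test_that("midpoint sizes dominate last-C sizes for every segment", {
  set.seed(12)
  for (rep in 1:20) {
    N <- sample(3:10, 1)
    pos <- cumsum(sample(1:9, N, replace = TRUE))
    i <- sample(N, 1); j <- sample(i:N, 1)
    w <- data.frame(i = i, j = j, w = 1)
    expect_gte(model_patch_size(w, pos, "midpoint")$expectation,
               model_patch_size(w, pos, "last_c")$expectation)
  }
})

test_that("previous_patch_caller finds per-sequence runs with both sizes", {
  m <- mutation_matrix(rbind(c(0, 1, 1, 0)), c(3, 5, 6, 9), "top")
  p <- previous_patch_caller(m)
  expect_equal(nrow(p), 1L)
  expect_equal(p$size_prev, 2)         # 6 - 5 + 1
  expect_equal(p$size_prev_mp, 3.5)    # (6+9)/2 - (3+5)/2
  expect_equal(p$run_length, 2L)

  # single isolated converted C is below min_run
  lone <- mutation_matrix(rbind(c(0, 1, 0, 0)), c(3, 5, 6, 9), "top")
  expect_equal(nrow(previous_patch_caller(lone)), 0L)

  full <- mutation_matrix(rbind(c(1, 1, 1, 1)), c(3, 5, 6, 9), "top")
  pf <- previous_patch_caller(full)
  expect_equal(pf$size_prev, 9 - 3 + 1)
  expect_equal(pf$first_converted, 3)
  expect_equal(pf$last_converted, 9)
})

test_that("previous patches are independent of cluster structure and ordered", {
  set.seed(33)
  m <- mutation_matrix(matrix(rbinom(200, 1, 0.3), 20, 10),
                       cumsum(sample(1:4, 10, replace = TRUE)), "top")
  p <- previous_patch_caller(m)
  expect_true(all(p$size_prev_mp >= p$size_prev))
  perm <- sample(20)
  mp <- mutation_matrix(m$calls[perm, ], m$positions, "top",
                        seq_ids = m$seq_ids[perm])
  pp <- previous_patch_caller(mp)
  expect_equal(sort(pp$size_prev), sort(p$size_prev))
})

test_that("call_bars returns nothing on a flat posterior", {
  set.seed(50)
  cnt <- site_counts(cumsum(sample(2:5, 20, replace = TRUE)),
                     rbinom(20, 200, 0.02), 200)
  fit <- segment_sites(cnt, lambda = "auto")
  bars <- call_bars(fit)
  expect_false(attr(bars, "has_bar"))
  expect_length(bars, 0L)
})

test_that("call_bars recovers one or two planted elevated segments", {
  set.seed(60)
  # one segment
  cnt <- segment_counts(30, 500, c(12, 17))
  fit <- segment_sites(cnt)
  bars <- call_bars(fit)
  expect_length(bars, 1L)
  expect_lte(abs(bars[[1]]$span_index[1] - 12), 1)
  expect_lte(abs(bars[[1]]$span_index[2] - 17), 1)

  # two segments separated by >= 3 baseline sites
  pos <- cumsum(sample(2:5, 40, replace = TRUE))
  theta <- rep(0.01, 40); theta[8:12] <- 0.3; theta[25:29] <- 0.3
  cnt2 <- site_counts(pos, rbinom(40, 500, theta), 500)
  fit2 <- segment_sites(cnt2)
  bars2 <- call_bars(fit2)
  expect_length(bars2, 2L)
})

test_that("patch summary table averages clusters and flags single clusters", {
  mk_bar <- function(new, new_mp) {
    structure(list(list(size_new = new, size_new_mp = new_mp,
                        site_positions = c(1, 2), theta_mean = c(0.3, 0.3),
                        site_span = c(1, 2), span_index = c(1, 2),
                        peak_site = 1)),
              has_bar = TRUE, class = "bar_calls")
  }
  sp <- data.frame(size_prev = c(4, 6), size_prev_mp = c(5, 8),
                   weight = c(1, 1))
  one <- patch_summary_table(list(A = mk_bar(5, 8)), list(A = sp))
  expect_true(attr(one, "single_cluster"))
  expect_equal(one$sem, rep(0, 4))
  expect_equal(one$mean[one$definition == "Previous"], 5)

  two <- patch_summary_table(list(A = mk_bar(5, 8), B = mk_bar(15, 18)),
                             list(A = sp, B = sp))
  expect_false(attr(two, "single_cluster"))
  expect_equal(two$mean[two$definition == "New"], 10)
  expect_gte(two$mean[two$definition == "New-MP"],
             two$mean[two$definition == "New"])

  expect_error(patch_summary_table(list(), list()), "no clusters")
})

test_that("model size expectation approaches the true span as n grows", {
  set.seed(71)
  pos <- seq(2, 120, by = 2)                       # dense, regular spacing
  true_span <- pos[35] - pos[26] + 2               # midpoint-true size in bp
  err <- sapply(c(50, 500), function(n) {
    sizes <- replicate(5, {
      cnt <- segment_counts(60, n, c(26, 35), positions = pos)
      fit <- segment_sites(cnt)
      bars <- call_bars(fit)
      if (length(bars) == 0) return(NA_real_)
      bars[[which.max(vapply(bars, function(b) diff(b$span_index),
                             numeric(1)))]]$size_new_mp
    })
    mean(abs(sizes - true_span), na.rm = TRUE)
  })
  expect_lt(err[2], err[1] + 1e-9)
  expect_lt(err[2], 4)
})

test_that("BED export converts to 0-based half-open coordinates", {
  mk <- structure(list(list(cluster = "C_10", strand = "top",
                            site_span = c(21, 40), span_index = c(3, 7),
                            peak_site = 30, site_positions = 21:40,
                            theta_mean = rep(0.4, 20),
                            size_new = 20, size_new_mp = 22)),
                  has_bar = TRUE, class = "bar_calls")
  path <- tempfile(fileext = ".bed")
  write_bars_bed(list(C_10 = mk), path)
  lines <- readLines(path)
  expect_match(lines[1], "0-based half-open")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(20L, 40L))
})
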