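test_that("white-line rule matches hand-computed masks", {
  # median 10, MAD 1, threshold 7 -> only the 0 is below
  expect_equal(detect_white_lines(c(0, 8, 9, 10, 11, 12, 10, 10)), 1L)
  # constant coverage: MAD 0, nothing strictly below the median
  expect_warning(wl <- detect_white_lines(rep(7, 5)), "MAD")
  expect_length(wl, 0)
  # degenerate MAD = 0 with an outlier: threshold is '< median'
  expect_warning(wl2 <- detect_white_lines(c(10, 10, 10, 10, 0)), "MAD")
  expect_equal(wl2, 5L)
})

test_that("downsampling conserves the requested total and is seeded", {
  map <- random_counts_map(10, lambda = 40, seed = 2)
  total <- sum(map$matrix[upper.tri(map$matrix, diag = TRUE)])
  down <- downsample_map(map, 500, seed = 7)
  expect_equal(sum(down$matrix[upper.tri(down$matrix, diag = TRUE)]), 500)
  expect_equal(down$matrix, t(down$matrix))
  expect_equal(downsample_map(map, 500, seed = 7)$matrix, down$matrix)
  expect_equal(downsample_map(map, total, seed = 1)$matrix, map$matrix)
  expect_error(downsample_map(map, total + 1, seed = 1), "exceeds")
})

test_that("downsampling preserves expected proportions", {
  map <- random_counts_map(10, lambda = 40, seed = 4)
  up <- upper.tri(map$matrix, diag = TRUE)
  cnt <- map$matrix[up]
  total <- sum(cnt)
  n_draw <- 600
  acc <- 0
  for (s in 1:200) acc <- acc + downsample_map(map, n_draw, seed = s)$matrix[up]
  mean_obs <- acc / 200
  p <- cnt / total
  expected <- n_draw * p
  se <- sqrt(n_draw * p * (1 - p) / 200)
  ok <- abs(mean_obs - expected) <= 3 * pmax(se, 1e-9)
  expect_gt(mean(ok), 0.98)
})

test_that("log2 ratio follows its closed forms", {
  a <- random_counts_map(8, seed = 1)
  expect_true(all(log2_ratio(a, a) == 0))
  b <- a; b$matrix <- 2 * a$matrix
  expect_equal(log2_ratio(b, a, pseudocount = 0)[a$matrix > 0],
               rep(1, sum(a$matrix > 0)))
  m4 <- contact_map(matrix(4, 1, 1), 1000)
  m1 <- contact_map(matrix(1, 1, 1), 1000)
  expect_equal(log2_ratio(m4, m1, pseudocount = 0), matrix(2, 1, 1))
  expect_error(log2_ratio(a, random_counts_map(9)), "shape")
})

test_that("distance decay averages by circular separation and interpolates masks", {
  lin <- contact_map(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3), 1000,
                     circular = FALSE)
  expect_equal(distance_decay(lin)$value, c(0, 1, 2))
  circ <- decay_map(4, function(s) ifelse(s == 0, 0, 1))
  dd <- distance_decay(circ)
  expect_equal(dd$value[dd$separation %in% 1:2], c(1, 1))
  # exact recovery of a planted decay law
  f <- function(s) 100 / (s + 2)
  expect_equal(distance_decay(decay_map(21, f))$value, f(0:10))
  # a fully masked separation cannot occur for contiguous masks; mask a bin
  # and check values remain finite everywhere
  dd2 <- distance_decay(mask_bins(decay_map(20, f), 5L))
  expect_true(all(is.finite(dd2$value)))
})

test_that("rebinning aggregates blocks, conserves totals and masks majorities", {
  map <- random_counts_map(8, seed = 6)
  expect_identical(rebin_map(map, 1), map)
  ones <- contact_map(matrix(1, 4, 4), 1000)
  expect_equal(rebin_map(ones, 2)$matrix, matrix(4, 2, 2))
  reb <- rebin_map(map, 2)
  expect_equal(sum(reb$matrix), sum(map$matrix))
  expect_equal(reb$bin_size, 2000)
  # 2 of 3 fine bins masked -> coarse bin masked; 1 of 3 -> kept
  m9 <- mask_bins(random_counts_map(9, seed = 8), c(1L, 2L, 4L))
  expect_equal(rebin_map(m9, 3)$mask, 1L)
})

test_that("correlation matrix is a proper correlation with block structure", {
  map <- random_counts_map(10, seed = 9)
  cm <- correlation_matrix(map)
  expect_equal(diag(cm), rep(1, 10))
  expect_true(all(cm >= -1 & cm <= 1))
  # checkerboard two-block map: within-block positive, cross-block negative
  blk <- outer(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5))
  m <- blk + outer(rep(c(0, 1), each = 5), rep(c(0, 1), each = 5))
  set.seed(10)
  m <- m * 10 + matrix(stats::runif(100, 0, 0.5), 10)
  m <- (m + t(m)) / 2
  cmb <- correlation_matrix(contact_map(m, 1000))
  expect_gt(min(cmb[1:5, 1:5]), 0)
  expect_lt(max(cmb[1:5, 6:10]), 0)
  # oracle: plain Pearson between two rows
  expect_equal(cmb[1, 3], stats::cor(m[1, ], m[3, ]), tolerance = 1e-12)
})
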