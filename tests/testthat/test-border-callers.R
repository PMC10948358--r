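test_that("directionality index matches a brute-force paired t-test", {
  map <- ice_balance(random_counts_map(60, lambda = 25, seed = 13))
  w <- 8L
  tt <- directionality_index(map, w)
  cm <- correlation_matrix(map)
  n <- n_bins(map)
  for (i in seq(1, n, by = 3)) {
    L <- cm[i, tidmapper:::.wrap(i - 1:w, n)]
    R <- cm[i, tidmapper:::.wrap(i + 1:w, n)]
    oracle <- stats::t.test(R, L, paired = TRUE)$statistic
    expect_lt(abs(tt[i] - oracle), 1e-10)
  }
})

test_that("mirror-symmetric maps give zero directionality", {
  # entries depend only on separation -> every row is mirror symmetric
  map <- decay_map(30, function(s) 10 / (s + 1), balanced = TRUE)
  tt <- suppressWarnings(directionality_index(map, 5, use_correlation = FALSE))
  expect_true(all(abs(tt) < 1e-8))
})

test_that("DI borders are negative-to-positive transitions only", {
  b <- call_di_borders(c(-3, -3, 0, 3, 3), max_gap_bins = 1, circular = FALSE)
  expect_equal(b$bin, 4L)
  expect_equal(b$statistic, 3)
  expect_equal(nrow(call_di_borders(c(-1.5, 0.3, 1.9, -1, 0))), 0L)
  # positive run before negative run is not a border
  expect_equal(nrow(call_di_borders(c(3, 3, 0, -3, -3), circular = FALSE)), 0L)
  # a gap longer than max_gap_bins breaks the transition
  expect_equal(nrow(call_di_borders(c(-3, 0, 0, 0, 3), max_gap_bins = 2,
                                    circular = FALSE)), 0L)
})

test_that("relative insulation is bounded, flat on uniform maps, maximal at block junctions", {
  uni <- contact_map(matrix(1, 60, 60) + diag(60), 1000, balanced = TRUE)
  ins <- insulation_multiscale(uni, windows_bp = c(5e3, 8e3))
  expect_equal(nrow(call_insulation_borders(ins)), 0L)
  # two perfect blocks joined with zero cross contacts
  blk <- matrix(0, 40, 40)
  blk[1:20, 1:20] <- 1
  blk[21:40, 21:40] <- 1
  diag(blk) <- 2
  bm <- contact_map(blk, 1000, circular = FALSE, balanced = TRUE)
  sep_bins <- 5L
  ri_raw <- sapply(seq(6, 35), function(i) {
    up <- (i - sep_bins):(i - 1); dn <- i:(i + sep_bins - 1)
    a <- (sum(blk[up, up]) - sum(diag(blk)[up])) / 2
    b2 <- (sum(blk[dn, dn]) - sum(diag(blk)[dn])) / 2
    cc <- sum(blk[up, dn])
    (a + b2 - cc) / (a + b2 + cc)
  })
  expect_equal(max(ri_raw), 1)               # junction: C = 0
  expect_equal(seq(6, 35)[which.max(ri_raw)], 21L)
  ins2 <- insulation_multiscale(bm, windows_bp = 5e3)
  expect_equal(which.max(ins2), 21L)
  # RI bounded for any nonnegative map
  rmap <- ice_balance(random_counts_map(40, seed = 20))
  insr <- insulation_multiscale(rmap, windows_bp = c(5e3, 10e3))
  expect_true(all(abs(insr[is.finite(insr)]) <= 2))  # corrected = RI - envelope
})

test_that("insulation borders are monotone in the z cutoff", {
  sc <- make_scenario(seed = 41, n_domains = 8, domain_kappa = 1,
                      plaid_kappa = 0, epsilon_true = 0.01, white_line_bins = 5)
  bal <- ice_balance(simulate_map(sc))
  ins <- insulation_multiscale(bal)
  b1 <- call_insulation_borders(ins, z_cutoff = 1)
  b2 <- call_insulation_borders(ins, z_cutoff = 2)
  expect_true(all(b2$bin %in% b1$bin))
  expect_equal(nrow(call_insulation_borders(ins, z_cutoff = Inf)), 0L)
})

test_that("border sets are matched greedily and one-to-one", {
  full <- compare_border_sets(c(3, 10, 50), c(3, 10, 50), 2)
  expect_equal(full$matched, 3)
  expect_length(full$a_only, 0)
  one <- compare_border_sets(10, 12, 2)
  expect_equal(one$matched, 1)
  dup <- compare_border_sets(c(10, 11), 10, 2)
  expect_equal(dup$matched, 1)
  expect_equal(dup$a_only, 11)
})

test_that("interval overlap measures unioned kb", {
  a <- data.frame(start = 0, end = 10000)
  b <- data.frame(start = 5000, end = 15000)
  ov <- interval_overlap_kb(a, b)
  expect_equal(ov$a_kb, 10)
  expect_equal(ov$b_kb, 10)
  expect_equal(ov$intersection_kb, 5)
  expect_equal(interval_overlap_kb(a, data.frame(start = 2e4, end = 3e4))$intersection_kb, 0)
  # nested intervals are unioned before measuring
  nested <- data.frame(start = c(0, 2000), end = c(10000, 4000))
  expect_equal(interval_overlap_kb(nested, b)$a_kb, 10)
})
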