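test_that("scenarios are reproducible and respect their layout contracts", {
  s1 <- make_scenario(seed = 5)
  s2 <- make_scenario(seed = 5)
  expect_identical(s1, s2)
  g <- s1$genes
  expect_true(all(g$end > g$start))
  expect_true(all(g$end - g$start >= 1000 & g$end - g$start <= 20000))
  expect_true(all(g$end <= s1$genome_length))
  # non-overlapping layout
  ord <- g[order(g$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-nrow(ord)]))
  expect_equal(sum(g$active), 10L)
  expect_error(make_scenario(n_genes = 500), "infeasible")
})

test_that("rifampicin silences every native gene", {
  sr <- make_scenario(seed = 6, rifampicin = TRUE)
  expect_true(all(sr$genes$expression == 0))
  expect_false(any(sr$genes$active))
  occ <- simulate_occupancy(sr)
  expect_true(all(occ$values == 0))
  # with a T7 unit the polymerase track survives and peaks at the promoter
  st <- make_scenario(seed = 6, rifampicin = TRUE, t7_unit = TRUE,
                      epsilon_true = 0.25)
  occ_t7 <- simulate_occupancy(st)
  expect_equal(max(occ_t7$values), 0.25)
  prom_bin <- floor(st$t7_unit$position_bp / st$bin_size) + 1
  expect_equal(which.max(occ_t7$values), prom_bin)
})

test_that("occupancy support is confined to transcribed regions", {
  sc <- make_scenario(seed = 7, t7_unit = TRUE)
  occ <- simulate_occupancy(sc)
  expect_equal(max(occ$values), sc$epsilon_true)
  n <- length(occ$values)
  covered <- logical(n)
  for (k in seq_len(nrow(sc$genes))) {
    b1 <- floor(sc$genes$start[k] / 1000) + 1
    b2 <- ceiling(sc$genes$end[k] / 1000)
    covered[b1:b2] <- TRUE
  }
  iv <- tidmapper:::.t7_interval(sc)
  covered[(floor(iv[1] / 1000) + 1):ceiling(iv[2] / 1000)] <- TRUE
  expect_true(all(occ$values[!covered] == 0))
})

test_that("simulated maps hit the requested depth and are seeded", {
  sc <- make_scenario(seed = 8, white_line_bins = 0)
  m1 <- simulate_map(sc)
  m2 <- simulate_map(sc)
  expect_identical(m1$matrix, m2$matrix)
  total <- sum(m1$matrix[upper.tri(m1$matrix, diag = TRUE)])
  expect_lt(abs(total - sc$sequencing_depth), 3 * sqrt(sc$sequencing_depth))
  expect_equal(m1$matrix, t(m1$matrix))
  # white lines are zeroed and masked
  scw <- make_scenario(seed = 8, white_line_bins = 12)
  mw <- simulate_map(scw)
  expect_length(mw$mask, 12L)
  expect_true(all(is.na(mw$matrix[mw$mask, ])))
})

test_that("silent scenarios produce a pure power-law decay", {
  sc <- make_scenario(seed = 9, rifampicin = TRUE, plaid_kappa = 0,
                      white_line_bins = 0)
  map <- simulate_map(sc)
  dd <- distance_decay(ice_balance(map))
  s <- dd$separation[-1]
  expect_gt(stats::cor(log(dd$value[-1]), log(1 / (s + 1))), 0.99)
})

test_that("truth tables record merged active TUs and the T7 track", {
  sc <- make_scenario(seed = 10, active_fraction = 0.2)
  truth <- attr(simulate_map(sc), "truth")
  act <- sc$genes[sc$genes$active, ]
  # every active gene is inside exactly one truth TID
  for (k in seq_len(nrow(act)))
    expect_true(any(truth$tids_bp$start <= act$start[k] &
                    truth$tids_bp$end >= act$end[k]))
  # truth TIDs are separated by more than the merge gap
  tt <- truth$tids_bp[order(truth$tids_bp$start), ]
  if (nrow(tt) > 1)
    expect_true(all(tt$start[-1] - tt$end[-nrow(tt)] > 2 * sc$bin_size))
})

test_that("fixtures round-trip through the readers byte-identically", {
  sc <- make_scenario(seed = 11, genome_length = 2e5, n_genes = 20,
                      sequencing_depth = 2e5)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sc, dir)
  map <- simulate_map(sc)
  back <- read_map(paths[["map"]])
  expect_equal(back$matrix, map$matrix)
  expect_equal(back$mask, map$mask)
  genes <- read_genes(paths[["genes"]])
  expect_equal(genes$start, sc$genes$start)
  expect_equal(genes$expression, sc$genes$expression)
  occ <- read_bedgraph(paths[["occupancy"]], units = "occupancy")
  truth <- attr(map, "truth")
  expect_equal(which(occ$values > 0), which(truth$occupancy > 0))
  # regeneration is byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture(make_scenario(seed = 11, genome_length = 2e5,
                                        n_genes = 20, sequencing_depth = 2e5),
                          dir2)
  for (f in names(paths))
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]),
                     info = f)
})
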