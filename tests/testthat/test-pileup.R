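toy_genes <- function() {
  data.frame(id = sprintf("g%d", 1:10),
             start = seq(0, 90000, by = 10000),
             end = seq(0, 90000, by = 10000) + 4000,
             strand = rep(c("+", "-"), 5),
             expression = c(5, 50, 3, 40, 8, 30, 1, 20, 2, 10))
}

test_that("active gene selection takes the top fraction with coordinate ties", {
  g <- toy_genes()
  top2 <- select_active_genes(g, 0.2)
  expect_equal(sort(top2$expression), c(40, 50))
  expect_equal(select_active_genes(g, 1)$id, g$id)
  tie <- g; tie$expression <- 7
  sel <- select_active_genes(tie, 0.3)
  expect_equal(sel$start, g$start[1:3])   # first ceil(f*n) in genomic order
  expect_equal(nrow(select_active_genes(g[0, ], 0.5)), 0L)
})

test_that("TU-start filtering is strand-aware and wraps", {
  act <- data.frame(id = c("a", "b"), start = c(5000, 8500),
                    end = c(8000, 9500), strand = "+",
                    expression = c(10, 10))
  keep <- select_tu_starts(act, genome_length = 1e5)
  expect_equal(keep$id, "a")      # b has a within its 3-kb upstream window
  single <- select_tu_starts(act[1, ], genome_length = 1e5)
  expect_equal(nrow(single), 1L)
  # reverse gene: upstream is after its end
  rev <- data.frame(id = c("r", "x"), start = c(5000, 8500),
                    end = c(8000, 9500), strand = c("-", "+"),
                    expression = 10)
  # r's upstream [8000, 11000) contains x, and x's upstream [5500, 8500)
  # overlaps r: both are disqualified
  keepr <- select_tu_starts(rev, genome_length = 1e5)
  expect_equal(nrow(keepr), 0L)
  # subset invariant
  sc <- make_scenario(seed = 3)
  act2 <- select_active_genes(sc$genes, 0.1)
  tu <- select_tu_starts(act2, genome_length = sc$genome_length)
  expect_true(all(tu$id %in% act2$id))
})

test_that("window extraction is centered, oriented and involutive", {
  map <- random_counts_map(50, seed = 21)
  w <- extract_window(map, anchor_bp = 25500, strand = "+", width_bp = 9000)
  expect_equal(dim(w), c(9, 9))
  expect_equal(w[5, 5], map$matrix[26, 26])
  wr <- extract_window(map, 25500, "-", 9000)
  expect_equal(wr, w[9:1, 9:1])
  expect_equal(wr[9:1, 9:1], w)   # flipping twice is the identity
  # a marker 2 bins downstream of a reverse gene appears 2 bins upstream
  # after the flip: window position 7 maps to position 3
  m <- matrix(0, 50, 50); m[28, 28] <- 100
  mm <- contact_map(m + 1, 1000)
  wf <- extract_window(mm, 25500, "-", 9000)
  expect_equal(unname(which(wf == max(wf))), (3 - 1) * 9 + 3)
  # linear genome edge windows are excluded with a warning
  lin <- contact_map(matrix(1, 20, 20), 1000, circular = FALSE)
  expect_warning(out <- extract_window(lin, 500, "+", 9000), "excluded")
  expect_null(out)
})

test_that("pileups average per cell over unmasked contributors", {
  w1 <- matrix(2, 3, 3); w2 <- matrix(4, 3, 3)
  pl <- pileup_windows(list(w1, w2))
  expect_equal(pl$matrix, matrix(3, 3, 3))
  expect_equal(pl$n_windows, 2L)
  expect_equal(pileup_windows(list(w1))$matrix, w1)
  w2na <- w2; w2na[1, 1] <- NA
  mixed <- pileup_windows(list(w1, w2na))
  expect_equal(mixed$matrix[1, 1], 2)
  expect_equal(mixed$counts[1, 1], 1L)
  expect_equal(mixed$matrix[2, 2], 3)
  # K copies of one window equal the window
  expect_equal(pileup_windows(rep(list(w1), 5))$matrix, w1)
  expect_error(pileup_windows(list()), "no windows")
})

test_that("pileup ratio is 1 at zero jitter and deterministic by seed", {
  map <- random_counts_map(60, seed = 22)
  anchors <- c(10500, 30500, 50500)
  wins <- lapply(anchors, function(a) extract_window(map, a, "+", 9000))
  pl <- pileup_windows(wins)
  r0 <- pileup_ratio(pl, map, anchors, jitter_bp = 0, seed = 5)
  expect_true(all(abs(r0$ratio - 1) < 1e-12, na.rm = TRUE))
  ra <- pileup_ratio(pl, map, anchors, jitter_bp = 2e4, seed = 9)
  rb <- pileup_ratio(pl, map, anchors, jitter_bp = 2e4, seed = 9)
  expect_equal(ra$ratio, rb$ratio)
})

test_that("track pileup reverses minus-strand windows before averaging", {
  expect_equal(pileup_track(list(c(0, 1, 2))), c(0, 1, 2))
  expect_equal(pileup_track(list(c(0, 1, 2), c(2, 1, 0)), c("+", "-")),
               c(0, 1, 2))
  expect_equal(pileup_track(rep(list(rep(4, 5)), 3)), rep(4, 5))
})

test_that("TSS pileups correlate strongly with averaged transcription", {
  sc <- make_scenario(seed = 1, active_fraction = 0.2)
  mp <- simulate_map(sc)
  bal <- ice_balance(mask_bins(mp, detect_white_lines(map_coverage(mp))))
  tu <- select_tu_starts(select_active_genes(sc$genes, 0.2),
                         genome_length = sc$genome_length)
  anch <- ifelse(tu$strand == "+", tu$start, tu$end)
  pl <- pileup_windows(lapply(seq_len(nrow(tu)), function(k)
    extract_window(bal, anch[k], tu$strand[k], 5e4)), "TSS")
  rna <- simulate_rna_track(sc)
  tw <- lapply(seq_len(nrow(tu)), function(k) {
    ctr <- floor(anch[k] / sc$bin_size) + 1
    rna$values[tidmapper:::.wrap(ctr + (-25):24, n_bins(mp))]
  })
  tr <- pileup_track(tw, tu$strand)
  expect_gt(pileup_transcription_correlation(pl, tr), 0.8)
})

test_that("pileup-transcription correlation uses the adjacent-bin profile", {
  # symmetric window whose adjacent-bin diagonal varies along the window
  m <- matrix(1, 9, 9)
  for (k in 1:8) { m[k, k + 1] <- k + 2; m[k + 1, k] <- k + 2 }
  pl <- pileup_windows(list(m))
  prof <- m[cbind(1:8, 2:9)]
  expect_equal(prof, (1:8) + 2)
  expect_equal(pileup_transcription_correlation(pl, prof), 1)
  expect_equal(pileup_transcription_correlation(pl, -2 * prof + 7), -1)
  expect_warning(
    out <- pileup_transcription_correlation(
      pileup_windows(list(matrix(1, 9, 9))), prof),
    "constant")
  expect_true(is.na(out))
})
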