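test_that("chip normalization scales the maximum to epsilon", {
  occ <- normalize_chip(c(200, 100, 0, 50), 0.15)
  expect_equal(occ$values, c(0.15, 0.075, 0, 0.0375))
  expect_equal(occ$epsilon, 0.15)
  inunit <- normalize_chip(c(0.2, 1, 0.5), 1)
  expect_equal(inunit$values, c(0.2, 1, 0.5))
  set.seed(1)
  x <- stats::runif(20)
  expect_equal(max(normalize_chip(x, 0.37)$values), 0.37)
  expect_warning(z <- normalize_chip(rep(0, 5), 0.5), "zero")
  expect_equal(z$values, rep(0, 5))
  expect_error(normalize_chip(c(1, 2), 1.5), "epsilon")
})

test_that("model weights follow the printed formulas", {
  # variant 1: a fully occupied bin against an unoccupied one contributes 0
  w1 <- tidmapper:::.model_weight(c(1, 0, 0.5), 1, circular = FALSE)
  expect_equal(w1[1, 2], 0)
  expect_equal(w1[1, 3], 0.5)          # 1*0.5 + 0*0.5
  # variant 2, linear 3 bins, C = 0.5 everywhere, as in the worked example
  w2 <- tidmapper:::.model_weight(rep(0.5, 3), 2, circular = FALSE)
  expect_equal(w2[1, 3], 0.375)        # m = 0.5 -> 0.5*0.25 + 0.25
  expect_equal(w2[1, 2], 0.25)         # empty sum -> m = 0
})

test_that("variant weights match a brute-force double loop on random cases", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    Cv <- stats::runif(n, 0, 0.6) * stats::rbinom(n, 1, 0.4)
    for (circ in c(TRUE, FALSE)) for (variant in 1:2) {
      w <- tidmapper:::.model_weight(Cv, variant, circular = circ)
      oracle <- matrix(0, n, n)
      for (i in 1:n) for (j in 1:n) {
        a <- min(i, j); b <- max(i, j)
        m_in <- if (b - a >= 2) sum(Cv[(a + 1):(b - 1)]) else 0
        m <- m_in
        if (circ && (n - (b - a)) < (b - a)) {
          out_bins <- setdiff(1:n, a:b)
          m <- sum(Cv[out_bins])
        }
        oracle[i, j] <- if (variant == 1) Cv[i] * Cv[j] + (1 - Cv[i]) * (1 - Cv[j])
                        else m * Cv[i] * Cv[j] + (1 - Cv[i]) * (1 - Cv[j])
      }
      expect_lt(max(abs(w - oracle)), 1e-12)
    }
  }
})

test_that("with zero occupancy both variants collapse to the pure p(s) map", {
  n <- 40
  p <- data.frame(separation = 0:(n %/% 2), value = 1 / (0:(n %/% 2) + 1))
  m1 <- model_map(p, rep(0, n), variant = 1)
  m2 <- model_map(p, rep(0, n), variant = 2)
  sep <- tidmapper:::.sep_matrix(n, TRUE)
  pure <- doubly_stochastic(matrix(p$value[sep + 1], n, n))
  expect_equal(m1$matrix, unclass(pure), ignore_attr = TRUE)
  expect_equal(m2$matrix, unclass(pure), ignore_attr = TRUE)
  # model maps are symmetric and doubly stochastic
  occ <- normalize_chip(c(rep(0, 30), 5:1, rep(0, 5)), 0.4)
  mm <- model_map(p, occ, variant = 2)
  expect_equal(mm$matrix, t(mm$matrix))
  expect_lt(max(abs(rowSums(mm$matrix) - 1)), 1e-6)
})

test_that("epsilon fitting recovers a noise-free self-consistent truth", {
  n <- 120
  p <- data.frame(separation = 0:(n %/% 2), value = 1 / (0:(n %/% 2) + 1))
  set.seed(3)
  chip <- c(rep(0, 40), exp(-(0:29) / 10), rep(0, 50))
  obs <- model_map(p, normalize_chip(chip, 0.2), variant = 2,
                   bin_size = 1000)
  fit <- fit_epsilon(obs, chip, p = p, variant = 2,
                     grid = seq(0.1, 0.3, 0.01), max_sep_bp = 60e3)
  expect_equal(fit$best_epsilon, 0.2)
  expect_gt(fit$best_spearman, 0.999)
  expect_equal(fit$best_spearman, max(fit$spearman_per_epsilon))
  # degenerate grid of length 1
  f1 <- fit_epsilon(obs, chip, p = p, grid = 0.4)
  expect_equal(f1$best_epsilon, 0.4)
  # a pure p(s) observation prefers the smallest epsilon under variant 1
  pure <- model_map(p, rep(0, n), variant = 1)
  fp <- fit_epsilon(pure, chip, p = p, variant = 1,
                    grid = seq(0.05, 0.95, 0.05), max_sep_bp = 60e3)
  expect_equal(fp$best_epsilon, 0.05)
})

test_that("compare_variants ties exactly when occupancy is zero", {
  n <- 60
  p <- data.frame(separation = 0:30, value = 1 / (0:30 + 1))
  sep <- tidmapper:::.sep_matrix(n, TRUE)
  set.seed(9)
  m <- matrix(p$value[sep + 1], n, n) * 1e4
  m[upper.tri(m)] <- m[upper.tri(m)] + stats::runif(sum(upper.tri(m)))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  obs <- contact_map(m, 1000, balanced = TRUE)
  fits <- suppressWarnings(
    compare_variants(obs, rep(0, n), p = p, grid = c(0.1, 0.5, 1)))
  expect_equal(fits$variant1$best_spearman, fits$variant2$best_spearman)
})
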