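#' Normalize a ChIP track into a polymerase occupancy track
#'
#' Scales a non-negative ChIP signal (e.g. RNA-polymerase ChIP CPM) so its
#' maximum equals `epsilon`, the maximum occupancy parameter of the contact
#' model: `C = chip * epsilon / max(chip)`. `C[i]` is then read as the
#' proportion of contacts at bin `i` mediated by polymerases.
#'
#' @param chip non-negative per-bin signal.
#' @param epsilon maximum occupancy, in (0, 1].
#' @return an `OccupancyTrack` (list with `values` and `epsilon`).
#' @export
normalize_chip <- function(chip, epsilon) {
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must be in (0, 1]")
  if (any(chip < 0, na.rm = TRUE)) stop("chip signal must be non-negative")
  mx <- max(chip, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) {
    warning("all-zero chip signal; occupancy is all zero")
    values <- rep(0, length(chip))
  } else values <- chip * epsilon / mx
  structure(list(values = values, epsilon = epsilon), class = "OccupancyTrack")
}

.occ_values <- function(C) if (inherits(C, "OccupancyTrack")) C$values else as.numeric(C)

# insulation factor m[i, j] = sum of C over bins strictly between i and j,
# taken along the shorter arc on circular genomes (m = 0 on and next to the
# diagonal). Scales linearly in C, which fit_epsilon exploits.
.insulation_m <- function(C, circular) {
  n <- length(C)
  cs <- cumsum(C)
  total <- cs[n]
  I <- row(diag(n)); J <- col(diag(n))
  a <- pmin(I, J); b <- pmax(I, J)
  inner <- cs[pmax(b - 1L, 1L)] - cs[a]
  inner[b - a <= 1L] <- 0
  dim(inner) <- c(n, n)
  if (circular) {
    d <- b - a
    outer_sum <- total - inner - C[a] - C[b]
    dim(outer_sum) <- c(n, n)
    use_outer <- (n - d) < d
    inner[use_outer] <- outer_sum[use_outer]
  }
  inner
}

# pre-normalization model weight for a given occupancy vector
.model_weight <- function(Cv, variant, circular,
                          insulation_form = c("printed", "reciprocal"),
                          m_mat = NULL) {
  insulation_form <- match.arg(insulation_form)
  pol <- outer(Cv, Cv)
  bg <- outer(1 - Cv, 1 - Cv)
  if (variant == 1) return(pol + bg)
  if (is.null(m_mat)) m_mat <- .insulation_m(Cv, circular)
  if (insulation_form == "printed") m_mat * pol + bg
  else pol / (1 + m_mat) + bg
}

#' Model contact map from distance decay and polymerase occupancy
#'
#' Builds the expected contact map under the two polymerase-contact
#' hypotheses and normalizes it to a doubly stochastic matrix (every row and
#' column sums to 1, so entries are contact probabilities). With `s` the
#' (circular) bin separation and `C` the occupancy track:
#' \itemize{
#' \item variant 1 (preferential polymerase-polymerase contacts):
#'   `p(s) * (C_i C_j + (1 - C_i)(1 - C_j))`
#' \item variant 2 (contacts between consecutive polymerases, modulated by
#'   the insulation factor `m = sum(C)` over bins strictly between `i` and
#'   `j`): `p(s) * (m * C_i C_j + (1 - C_i)(1 - C_j))`
#' }
#' `insulation_form = "reciprocal"` replaces the `m` factor by `1/(1 + m)`,
#' the form in which intervening polymerases *reduce* the pair contact.
#' Diagonal pairs use `m = 0`.
#'
#' @param p a `DistanceDecay` (or numeric `p(s)` vector indexed by
#'   separation 0..S) covering all separations of the map.
#' @param C an `OccupancyTrack` or numeric occupancy vector in `[0, 1]`.
#' @param variant 1 or 2 (default 2).
#' @param bin_size bin size in bp of the output map (default 1000).
#' @param circular circular genome (default `TRUE`).
#' @param insulation_form `"printed"` (default) or `"reciprocal"`.
#' @param normalize doubly-stochastic normalize the result (default `TRUE`).
#' @return a balanced `ContactMap` of model contact probabilities.
#' @export
model_map <- function(p, C, variant = 2, bin_size = 1000, circular = TRUE,
                      insulation_form = c("printed", "reciprocal"),
                      normalize = TRUE) {
  insulation_form <- match.arg(insulation_form)
  Cv <- .occ_values(C)
  n <- length(Cv)
  pv <- if (inherits(p, "data.frame")) p$value else as.numeric(p)
  sep <- .sep_matrix(n, circular)
  if (max(sep) + 1L > length(pv)) stop("p(s) does not cover all separations")
  P <- matrix(pv[sep + 1L], n, n)
  W <- .model_weight(Cv, variant, circular, insulation_form)
  M <- P * W
  if (normalize) M <- doubly_stochastic(M)
  contact_map(unname(M), bin_size, genome_length = n * bin_size,
              circular = circular, balanced = TRUE)
}

# stabilized argmax of a correlation-vs-epsilon curve: vertex of a
# tricube-weighted local quadratic around the raw maximum, snapped to the
# nearest grid value. Flat noisy curve tops make the raw argmax jitter by a
# few grid steps; the local fit centers the estimate on the underlying peak
# while leaving sharp peaks untouched.
.refine_argmax <- function(rho, grid, half = 5L) {
  i0 <- which.max(rho)
  # an extremum on the grid boundary is a trend, not a peak to center
  if (length(grid) < 2 * half + 1 || i0 == 1L || i0 == length(grid))
    return(grid[i0])
  win <- max(1L, i0 - half):min(length(grid), i0 + half)
  step <- grid[2] - grid[1]
  u <- abs(grid[win] - grid[i0]) / (step * (half + 1))
  wts <- (1 - pmin(u, 1)^3)^3
  co <- tryCatch(
    stats::coef(stats::lm(rho[win] ~ stats::poly(grid[win], 2, raw = TRUE),
                          weights = wts)),
    error = function(e) rep(NA_real_, 3))
  if (anyNA(co) || co[3] >= 0) return(grid[i0])
  peak <- min(max(-co[2] / (2 * co[3]), grid[min(win)]), grid[max(win)])
  grid[which.min(abs(grid - peak))]
}

# upper-triangle band pairs (1 <= sep <= max_sep_bins) excluding masked bins
.band_index <- function(n, circular, max_sep_bins, mask = integer()) {
  sep <- .sep_matrix(n, circular)
  sel <- upper.tri(sep) & sep >= 1L & sep <= max_sep_bins
  if (length(mask)) { sel[mask, ] <- FALSE; sel[, mask] <- FALSE }
  which(sel)
}

#' Fit the maximum occupancy parameter of the contact model
#'
#' Grid search over `epsilon`: for each value the ChIP track is scaled to
#' maximum `epsilon`, the model map is built ([model_map()]), and the
#' Spearman rank correlation with the observed map is computed over
#' unmasked upper-triangle pairs within `max_sep_bp`. The fitted `epsilon`
#' maximizes that correlation. Self-pairs (the diagonal) are excluded.
#'
#' Whether the two maps are normalized before ranking is controlled by
#' `normalize`. With a balanced observed map (`"both"`) the model is made
#' doubly stochastic so the two sides are comparable — but note that
#' balancing absorbs the separable part of the polymerase weight
#' (`(1-C_i)(1-C_j)` scales rows), so only the insulation structure then
#' identifies `epsilon`, which requires deep maps. With a raw count map
#' (`"none"`) the raw counts are ranked against the unnormalized model
#' expectation, retaining the full occupancy signal — the preferred mode
#' when raw counts are available. `"auto"` (default) picks by the observed
#' map's `balanced` flag.
#'
#' @param observed a `ContactMap` (raw counts or balanced, see `normalize`).
#' @param chip non-negative per-bin ChIP signal (only its shape matters).
#' @param p `DistanceDecay` to use; default: [distance_decay()] of
#'   `observed`.
#' @param variant model variant, 1 or 2 (default 2).
#' @param grid epsilon grid (default `seq(0.01, 1, by = 0.01)`, the full
#'   0-100% search range).
#' @param max_sep_bp maximum pair separation entering the correlation
#'   (default 200 kb; the modeled signal is local).
#' @param insulation_form see [model_map()].
#' @param normalize `"auto"`, `"both"` or `"none"` (see Details).
#' @param refine stabilize the argmax with a local weighted quadratic fit of
#'   the Spearman curve around its maximum (default `TRUE`); the reported
#'   `best_epsilon` is still a grid value and `best_spearman` is the curve's
#'   maximum.
#' @param balance_tol,balance_max_iter normalization tolerance/iterations
#'   used during the grid search in `"both"` mode.
#' @return a `ModelFit` list: `variant`, `epsilon_grid`,
#'   `spearman_per_epsilon`, `best_epsilon`, `best_spearman`,
#'   `insulation_form`, `max_sep_bp`.
#' @export
fit_epsilon <- function(observed, chip, p = NULL, variant = 2,
                        grid = seq(0.01, 1, by = 0.01), max_sep_bp = 2e5,
                        insulation_form = c("printed", "reciprocal"),
                        normalize = c("auto", "both", "none"),
                        refine = TRUE,
                        balance_tol = 1e-6, balance_max_iter = 300L) {
  insulation_form <- match.arg(insulation_form)
  normalize <- match.arg(normalize)
  if (normalize == "auto") normalize <- if (observed$balanced) "both" else "none"
  if (any(grid <= 0 | grid > 1)) stop("grid values must be in (0, 1]")
  n <- n_bins(observed)
  if (length(chip) != n) stop("chip track length does not match the map")
  if (is.null(p)) p <- distance_decay(observed)
  pv <- if (inherits(p, "data.frame")) p$value else as.numeric(p)
  sep <- .sep_matrix(n, observed$circular)
  P <- matrix(pv[sep + 1L], n, n)
  max_sep_bins <- max(1L, floor(max_sep_bp / observed$bin_size))
  band <- .band_index(n, observed$circular, max_sep_bins, observed$mask)
  obs_band <- observed$matrix[band]
  ok <- is.finite(obs_band)
  band <- band[ok]
  obs_rank <- rank(obs_band[ok])
  if (length(unique(obs_rank)) < 2 || stats::sd(obs_rank) == 0)
    stop("observed map is degenerate over the fitting band")
  mx <- max(chip, na.rm = TRUE)
  if (mx == 0) {
    warning("all-zero chip signal: every epsilon gives the same map")
    c0 <- rep(0, n)
  } else c0 <- chip / mx
  m0 <- if (variant == 2) .insulation_m(c0, observed$circular) else NULL

  rho <- numeric(length(grid))
  b <- NULL   # Sinkhorn bias, warm-started across the grid
  for (g in seq_along(grid)) {
    eps <- grid[g]
    Cv <- eps * c0
    W <- if (variant == 1) {
      outer(Cv, Cv) + outer(1 - Cv, 1 - Cv)
    } else if (insulation_form == "printed") {
      (eps * m0) * outer(Cv, Cv) + outer(1 - Cv, 1 - Cv)
    } else {
      outer(Cv, Cv) / (1 + eps * m0) + outer(1 - Cv, 1 - Cv)
    }
    M <- P * W
    if (normalize == "both") {
      fit <- .balance_core(M, tol = balance_tol, max_iter = balance_max_iter,
                           target = "one", b0 = b)
      b <- fit$bias
      bi <- b[(band - 1L) %% n + 1L]
      bj <- b[(band - 1L) %/% n + 1L]
      model_band <- M[band] / (bi * bj)
    } else {
      model_band <- M[band]
    }
    rho[g] <- stats::cor(rank(model_band), obs_rank)
  }
  best_eps <- if (refine) .refine_argmax(rho, grid) else grid[which.max(rho)]
  structure(list(variant = variant, epsilon_grid = grid,
                 spearman_per_epsilon = rho,
                 best_epsilon = best_eps, best_spearman = max(rho),
                 insulation_form = insulation_form, max_sep_bp = max_sep_bp),
            class = "ModelFit")
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf(
    "ModelFit (variant %d, %s form): best epsilon = %.3g (Spearman %.4f) over %d grid points\n",
    x$variant, x$insulation_form, x$best_epsilon, x$best_spearman,
    length(x$epsilon_grid)))
  invisible(x)
}

#' Fit both model variants for model selection
#'
#' Runs [fit_epsilon()] under variant 1 (plain polymerase-polymerase
#' preference) and variant 2 (consecutive-polymerase / insulation model) on
#' the same inputs, returning both fits so their Spearman curves can be
#' compared.
#'
#' @inheritParams fit_epsilon
#' @param ... further arguments passed to [fit_epsilon()].
#' @return list with elements `variant1` and `variant2` (each a `ModelFit`).
#' @export
compare_variants <- function(observed, chip, p = NULL,
                             grid = seq(0.01, 1, by = 0.01), ...) {
  list(variant1 = fit_epsilon(observed, chip, p, variant = 1, grid = grid, ...),
       variant2 = fit_epsilon(observed, chip, p, variant = 2, grid = grid, ...))
}
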