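# circular-aware separation matrix: sep[i, j] = genomic distance in bins
.sep_matrix <- function(n, circular) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (circular) d <- pmin(d, n - d)
  d
}

.wrap <- function(i, n) ((i - 1L) %% n) + 1L

#' Per-bin coverage of a contact map
#'
#' Row sums of the contact matrix, the usual input to [detect_white_lines()].
#'
#' @param map a `ContactMap`.
#' @return numeric vector of length `n_bins(map)` (`NA` on masked bins).
#' @export
map_coverage <- function(map) rowSums(map$matrix, na.rm = FALSE)

#' Detect low-coverage ("white line") bins
#'
#' A bin is a white line when its coverage falls below
#' `median - 3 * MAD`, with the MAD taken unscaled
#' (`MAD = median(|x - median(x)|)`). White lines typically arise from
#' unmappable regions (e.g. rDNA operons) and are masked from all downstream
#' computations.
#'
#' When the MAD is zero (near-constant coverage) the threshold degenerates to
#' "strictly below the median"; a warning is emitted because the rule then
#' flags any bin below the majority value.
#'
#' @param coverage numeric per-bin coverage (e.g. [map_coverage()]); `NA`
#'   entries are ignored for the threshold and never flagged.
#' @return integer vector of white-line bin indices (1-based).
#' @export
detect_white_lines <- function(coverage) {
  x <- coverage[is.finite(coverage)]
  if (!length(x)) return(integer())
  med <- stats::median(x)
  mad <- stats::median(abs(x - med))
  if (mad == 0)
    warning("MAD of coverage is 0; white-line threshold degenerates to '< median'")
  which(is.finite(coverage) & coverage < med - 3 * mad)
}

#' Downsample a raw contact map to a fixed number of contacts
#'
#' Draws `n_contacts` contacts without replacement from the observed ones
#' (multivariate hypergeometric over the upper-triangle cells, diagonal
#' counted once), so maps of different depths can be compared on equal
#' footing. The result is symmetric and sums (upper triangle) to exactly
#' `n_contacts`.
#'
#' @param map a raw integer-count `ContactMap`.
#' @param n_contacts target total; must not exceed the current total.
#' @param seed integer seed (the operation is deterministic given the seed).
#' @return the downsampled `ContactMap`.
#' @export
downsample_map <- function(map, n_contacts, seed) {
  m <- map$matrix
  up <- upper.tri(m, diag = TRUE)
  cnt <- m[up]
  cnt[!is.finite(cnt)] <- 0
  cnt <- round(cnt)
  total <- sum(cnt)
  if (n_contacts > total) stop("n_contacts exceeds the total contact count")
  set.seed(seed)
  new <- numeric(length(cnt))
  remaining <- total
  need <- n_contacts
  nz <- which(cnt > 0)
  for (k in nz) {
    if (need == 0) break
    # draw this cell's share from the remaining pool without replacement
    x <- stats::rhyper(1, cnt[k], remaining - cnt[k], need)
    new[k] <- x
    need <- need - x
    remaining <- remaining - cnt[k]
  }
  out <- matrix(0, nrow(m), ncol(m))
  out[up] <- new
  out <- out + t(out)
  diag(out) <- diag(out) / 2
  res <- contact_map(out, map$bin_size, map$genome_length, map$circular,
                     balanced = FALSE)
  if (length(map$mask)) res <- mask_bins(res, map$mask)
  res
}

#' Elementwise log2 ratio of two contact maps
#'
#' Standard comparison of two maps previously downsampled to the same number
#' of contacts: `log2((a + pseudocount) / (b + pseudocount))`. Masked bins in
#' either map propagate as `NA`.
#'
#' @param map_a,map_b `ContactMap`s of identical shape and bin size.
#' @param pseudocount added to both maps before the ratio (default 1).
#' @return numeric matrix of log2 ratios.
#' @export
log2_ratio <- function(map_a, map_b, pseudocount = 1) {
  if (n_bins(map_a) != n_bins(map_b) || map_a$bin_size != map_b$bin_size)
    stop("maps must have the same shape and bin size")
  log2((map_a$matrix + pseudocount) / (map_b$matrix + pseudocount))
}

#' Contact probability as a function of genomic separation, p(s)
#'
#' Mean contact frequency over all unmasked bin pairs at each separation
#' `s` (in bins), with `s = min(|i-j|, N - |i-j|)` on circular genomes.
#' Separations at which every pair is masked are filled by linear
#' interpolation between defined neighbors.
#'
#' @param map a (typically balanced) `ContactMap`.
#' @return a `DistanceDecay` data frame with columns `separation` (bins) and
#'   `value`; `attr(, "bin_size")` carries the bin size in bp.
#' @export
distance_decay <- function(map) {
  n <- n_bins(map)
  sep <- .sep_matrix(n, map$circular)
  smax <- if (map$circular) floor(n / 2) else n - 1L
  ok <- is.finite(map$matrix)
  vals <- rep(NA_real_, smax + 1L)
  means <- tapply(map$matrix[ok], sep[ok], mean)
  vals[as.integer(names(means)) + 1L] <- means
  if (anyNA(vals) && sum(!is.na(vals)) >= 2) {
    idx <- which(is.na(vals))
    vals[idx] <- stats::approx(x = which(!is.na(vals)), y = vals[!is.na(vals)],
                               xout = idx, rule = 2)$y
  }
  out <- data.frame(separation = 0:smax, value = vals)
  class(out) <- c("DistanceDecay", "data.frame")
  attr(out, "bin_size") <- map$bin_size
  out
}

#' Rebin a contact map to a coarser resolution
#'
#' Aggregates `factor x factor` blocks of bins by summation (total contacts
#' are conserved). A coarse bin is masked when more than half of its
#' constituent fine bins are masked.
#'
#' @param map a `ContactMap`.
#' @param factor integer aggregation factor (>= 1).
#' @return the rebinned `ContactMap`.
#' @export
rebin_map <- function(map, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(map)
  n <- n_bins(map)
  g <- (seq_len(n) - 1L) %/% factor + 1L
  m <- map$matrix
  m[!is.finite(m)] <- 0
  agg <- rowsum(t(rowsum(m, g)), g)      # block sums
  agg <- (agg + t(agg)) / 2              # exact symmetry against fp noise
  masked_per <- tabulate(g[map$mask], nbins = max(g))
  size_per <- tabulate(g, nbins = max(g))
  coarse_mask <- which(masked_per > size_per / 2)
  res <- contact_map(unname(agg), map$bin_size * factor, map$genome_length,
                     map$circular, balanced = FALSE)
  if (length(coarse_mask)) res <- mask_bins(res, coarse_mask)
  res
}

#' Bin-by-bin Pearson correlation matrix of a contact map
#'
#' Correlates the contact profiles (rows) of every pair of unmasked bins, the
#' input to directionality-index analysis. Optionally the map can be
#' log-transformed (`log2(x + 1)`) or detrended by the distance decay before
#' correlating.
#'
#' @param map a balanced `ContactMap`.
#' @param log log2-transform contacts first (default `FALSE`).
#' @param detrend divide by the expected `p(s)` at each separation first
#'   (default `FALSE`).
#' @return `N x N` correlation matrix in `[-1, 1]` with unit diagonal; masked
#'   bins are `NA`; constant rows yield 0 off-diagonal (with a warning).
#' @export
correlation_matrix <- function(map, log = FALSE, detrend = FALSE) {
  n <- n_bins(map)
  valid <- setdiff(seq_len(n), map$mask)
  sub <- map$matrix[valid, valid, drop = FALSE]
  if (detrend) {
    dd <- distance_decay(map)
    expected <- dd$value[.sep_matrix(n, map$circular)[valid, valid] + 1L]
    sub <- sub / ifelse(expected > 0, expected, NA_real_)
  }
  if (log) sub <- log2(sub + 1)
  const <- apply(sub, 1, stats::sd, na.rm = TRUE) == 0
  cm <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
  if (any(const, na.rm = TRUE)) {
    warning("constant contact row(s); their correlations set to 0")
    cm[which(const), ] <- 0
    cm[, which(const)] <- 0
  }
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm <- pmin(pmax(cm, -1), 1)
  out <- matrix(NA_real_, n, n)
  out[valid, valid] <- cm
  out
}
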