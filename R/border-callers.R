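#' Directionality index by paired t-test
#'
#' For each bin `i`, the vectors of correlation-matrix values between that
#' bin and its `window_bins` left neighbors (`L_k = corr(i, i-k)`) and right
#' neighbors (`R_k = corr(i, i+k)`), `k = 1..w`, are compared by a paired
#' t-test on `d = R - L` (sample sd):
#' `t = mean(d) / (sd(d) / sqrt(w))`. Positive `t` means a downstream
#' contact bias; domain borders appear as negative-to-positive transitions.
#'
#' Masked neighbors are dropped pairwise; a bin with fewer than 2 usable
#' pairs (or a masked bin) is `NA`. Zero-variance differences give `t = 0`
#' with a warning.
#'
#' @param map a balanced `ContactMap`.
#' @param window_bins window half-width in bins (>= 2).
#' @param use_correlation compare correlation-matrix rows (default, as in
#'   classic CID analysis) or raw contact rows (`FALSE`).
#' @return numeric t-value per bin.
#' @export
directionality_index <- function(map, window_bins, use_correlation = TRUE) {
  w <- as.integer(window_bins)
  if (w < 2L) stop("window_bins must be >= 2")
  n <- n_bins(map)
  cm <- if (use_correlation) correlation_matrix(map) else map$matrix
  t_track <- rep(NA_real_, n)
  zero_sd <- FALSE
  for (i in setdiff(seq_len(n), map$mask)) {
    ks <- seq_len(w)
    li <- i - ks; ri <- i + ks
    if (map$circular) {
      li <- .wrap(li, n); ri <- .wrap(ri, n)
    } else {
      bad <- li < 1L | ri > n
      li <- li[!bad]; ri <- ri[!bad]
    }
    if (!length(li)) next
    d <- cm[i, ri] - cm[i, li]
    d <- d[is.finite(d)]
    if (length(d) < 2L) next
    s <- stats::sd(d)
    if (s == 0) { zero_sd <- TRUE; t_track[i] <- 0; next }
    t_track[i] <- mean(d) / (s / sqrt(length(d)))
  }
  if (zero_sd) warning("zero-variance left/right differences; t set to 0 there")
  t_track
}

#' Call domain borders from a directionality-index track
#'
#' A border is the first bin of a significant positive run
#' (`t >= t_threshold`) that follows a significant negative run
#' (`t <= -t_threshold`) with at most `max_gap_bins` non-significant bins in
#' between — the negative-to-positive DI transition characteristic of a
#' domain boundary. The default threshold `|t| = 2` corresponds to P ~ 0.05.
#'
#' @param t_track per-bin t values ([directionality_index()]).
#' @param t_threshold significance threshold (default 2).
#' @param max_gap_bins maximum non-significant gap between the runs
#'   (default 2).
#' @param circular consider the wrap-around transition (default `TRUE`).
#' @param window_bp window size in bp, recorded in the output.
#' @return data frame with `bin`, `method`, `statistic`, `window_bp`.
#' @export
call_di_borders <- function(t_track, t_threshold = 2, max_gap_bins = 2L,
                            circular = TRUE, window_bp = NA_real_) {
  sgn <- ifelse(!is.finite(t_track), 0,
                ifelse(t_track >= t_threshold, 1L,
                       ifelse(t_track <= -t_threshold, -1L, 0L)))
  n <- length(sgn)
  sig <- which(sgn != 0L)
  empty <- data.frame(bin = integer(), method = character(),
                      statistic = numeric(), window_bp = numeric())
  if (length(sig) < 2) return(empty)
  prev <- sig[-length(sig)]
  cur <- sig[-1]
  gaps <- cur - prev - 1L
  hits <- cur[sgn[prev] == -1L & sgn[cur] == 1L & gaps <= max_gap_bins]
  if (circular) {
    wrap_gap <- (n - sig[length(sig)]) + (sig[1] - 1L)
    if (sgn[sig[length(sig)]] == -1L && sgn[sig[1]] == 1L &&
        wrap_gap <= max_gap_bins)
      hits <- c(hits, sig[1])
  }
  hits <- sort(unique(hits))
  if (!length(hits)) return(empty)
  data.frame(bin = hits, method = "DI", statistic = t_track[hits],
             window_bp = window_bp)
}

#' Multi-window relative insulation track
#'
#' For each bin `i` and window `w` (converted from bp by the bin size), with
#' upstream block `U = [i-w, i)`, downstream block `D = [i, i+w)` and
#' within/between contact sums `A` (within `U`), `B` (within `D`), `C`
#' (between), the relative insulation is
#' `RI_w(i) = (A + B - C) / (A + B + C)` (diagonal entries excluded).
#' `RI` is bounded in `[-1, 1]`, scale-free, and maximal at contact-depleted
#' junctions. The tracks are averaged over the window set and the second
#' envelope is removed ([remove_second_envelope()]); borders are local maxima
#' of the returned corrected track.
#'
#' @param map a balanced `ContactMap` (1-kb bins in the reference analysis).
#' @param windows_bp window sizes in bp (default 10, 15, 20, 25, 30 kb).
#' @return corrected insulation track (one value per bin, `NA` where both
#'   blocks are fully masked); `attr(, "windows_bp")` records the windows.
#' @export
insulation_multiscale <- function(map, windows_bp = c(10, 15, 20, 25, 30) * 1e3) {
  n <- n_bins(map)
  ws <- unique(as.integer(round(windows_bp / map$bin_size)))
  if (any(ws < 1)) stop("window smaller than one bin")
  m <- map$matrix
  ri <- matrix(NA_real_, n, length(ws))
  for (wi in seq_along(ws)) {
    w <- ws[wi]
    for (i in seq_len(n)) {
      up <- i - w:1; dn <- i + 0:(w - 1)
      if (map$circular) {
        up <- .wrap(up, n); dn <- .wrap(dn, n)
      } else {
        up <- up[up >= 1]; dn <- dn[dn <= n]
        if (length(up) < 2 || length(dn) < 2) next
      }
      mu <- m[up, up]; md <- m[dn, dn]
      a <- (sum(mu, na.rm = TRUE) - sum(diag(mu), na.rm = TRUE)) / 2
      b <- (sum(md, na.rm = TRUE) - sum(diag(md), na.rm = TRUE)) / 2
      cc <- sum(m[up, dn], na.rm = TRUE)
      tot <- a + b + cc
      if (!is.finite(tot) || tot == 0) next
      ri[i, wi] <- (a + b - cc) / tot
    }
  }
  avg <- rowMeans(ri, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  out <- remove_second_envelope(avg, circular = map$circular)
  attr(out, "windows_bp") <- windows_bp
  out
}

#' Call borders from a corrected insulation track
#'
#' Borders are local maxima of the corrected track whose value is at least
#' `mean + z_cutoff * sd` of the (defined) track.
#'
#' @param corrected corrected insulation track ([insulation_multiscale()]).
#' @param z_cutoff number of standard deviations above the mean (default 1).
#' @param circular wrap at the ends (default `TRUE`).
#' @return data frame with `bin`, `method`, `statistic`.
#' @export
call_insulation_borders <- function(corrected, z_cutoff = 1, circular = TRUE) {
  x <- as.numeric(corrected)
  n <- length(x)
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  empty <- data.frame(bin = integer(), method = character(), statistic = numeric())
  if (!is.finite(s) || s == 0) return(empty)
  thr <- mu + z_cutoff * s
  xb <- ifelse(is.na(x), -Inf, x)
  left <- if (circular) xb[.wrap(seq_len(n) - 1L, n)] else c(-Inf, xb[-n])
  right <- if (circular) xb[.wrap(seq_len(n) + 1L, n)] else c(xb[-1], -Inf)
  hits <- which(is.finite(xb) & xb >= thr & xb > left & xb >= right)
  if (!length(hits)) return(empty)
  data.frame(bin = hits, method = "insulation", statistic = x[hits])
}

#' Match two border sets within a bin tolerance
#'
#' Greedy nearest matching: candidate pairs within `tol_bins` are matched in
#' order of increasing distance, each border at most once.
#'
#' @param a,b integer vectors of border bins (or data frames with a `bin`
#'   column).
#' @param tol_bins matching tolerance in bins.
#' @return list with `matched` (count), `a_only`, `b_only` (unmatched bins)
#'   and `pairs` (data frame of matched `a`/`b` bins).
#' @export
compare_border_sets <- function(a, b, tol_bins) {
  if (is.data.frame(a)) a <- a$bin
  if (is.data.frame(b)) b <- b$bin
  a <- sort(a); b <- sort(b)
  pairs <- expand.grid(ia = seq_along(a), ib = seq_along(b))
  pairs$d <- abs(a[pairs$ia] - b[pairs$ib])
  pairs <- pairs[pairs$d <= tol_bins, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_a <- logical(length(a)); used_b <- logical(length(b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ia <- pairs$ia[k]; ib <- pairs$ib[k]
    if (!used_a[ia] && !used_b[ib]) {
      keep[k] <- TRUE; used_a[ia] <- TRUE; used_b[ib] <- TRUE
    }
  }
  matched <- pairs[keep, , drop = FALSE]
  list(matched = sum(keep),
       a_only = a[!used_a], b_only = b[!used_b],
       pairs = data.frame(a = a[matched$ia], b = b[matched$ib]))
}

# union of half-open bp intervals given as a data.frame(start, end)
.interval_union <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, c("start", "end"), drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv$start[k] <= out$end[last]) {
      out$end[last] <- max(out$end[last], iv$end[k])
    } else out <- rbind(out, iv[k, c("start", "end")])
  }
  out
}

#' Total covered kb of two interval sets and their intersection
#'
#' Each set is unioned first; the intersection is measured on the unions.
#' Intervals are bp, 0-based half-open.
#'
#' @param a,b data frames with `start` and `end` columns in bp.
#' @return list with `a_kb`, `b_kb`, `intersection_kb`.
#' @export
interval_overlap_kb <- function(a, b) {
  ua <- .interval_union(a); ub <- .interval_union(b)
  kb <- function(iv) sum(iv$end - iv$start) / 1e3
  inter <- 0
  for (i in seq_len(nrow(ua))) for (j in seq_len(nrow(ub))) {
    lo <- max(ua$start[i], ub$start[j]); hi <- min(ua$end[i], ub$end[j])
    if (hi > lo) inter <- inter + (hi - lo)
  }
  list(a_kb = kb(ua), b_kb = kb(ub), intersection_kb = inter / 1e3)
}
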