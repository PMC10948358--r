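# shared fixture builders and evaluation helpers (everything is generated
# in code; no stored fixtures)

# symmetric map whose entries are an exact function of circular separation
decay_map <- function(n, f = function(s) 1 / (s + 1), bin_size = 1000,
                      circular = TRUE, balanced = FALSE) {
  sep <- tidmapper:::.sep_matrix(n, circular)
  contact_map(matrix(f(sep), n, n), bin_size, circular = circular,
              balanced = balanced)
}

# random symmetric Poisson count map around a flat expectation
random_counts_map <- function(n, lambda = 20, seed = 1, bin_size = 1000) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  m[up] <- stats::rpois(sum(up), lambda)
  m <- m + t(m); diag(m) <- diag(m) / 2
  contact_map(m, bin_size)
}

# recall / precision of called bundles against truth intervals, matched at
# >= 50% reciprocal overlap in bins
bundle_prf <- function(bundles, tids_bp, bin_size, n) {
  tr <- cbind(floor(tids_bp$start / bin_size) + 1, ceiling(tids_bp$end / bin_size))
  called <- lapply(seq_len(nrow(bundles)), function(k) {
    s <- bundles$start_bin[k]; e <- bundles$end_bin[k]
    if (e > s) s:(e - 1) else c(s:n, seq_len(max(e - 1, 0)))
  })
  tp_t <- logical(nrow(tr)); tp_c <- logical(length(called))
  for (i in seq_len(nrow(tr))) for (j in seq_along(called)) {
    tb <- tr[i, 1]:tr[i, 2]
    ov <- length(intersect(tb, called[[j]]))
    if (ov >= 0.5 * length(tb) && ov >= 0.5 * length(called[[j]])) {
      tp_t[i] <- TRUE; tp_c[j] <- TRUE
    }
  }
  list(recall = mean(tp_t),
       precision = if (length(called)) mean(tp_c) else NA_real_,
       n_called = length(called))
}

# F1 of called border bins against true border bins at a bin tolerance
border_f1 <- function(called_bins, true_bins, tol_bins) {
  cmp <- compare_border_sets(called_bins, true_bins, tol_bins)
  n_called <- cmp$matched + length(cmp$a_only)
  n_true <- cmp$matched + length(cmp$b_only)
  if (n_called == 0 || n_true == 0) return(0)
  prec <- cmp$matched / n_called
  rec <- cmp$matched / n_true
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
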