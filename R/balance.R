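# Symmetric iterative proportional fitting shared by ICE balancing and the
# model map's doubly-stochastic normalization. Works on the bias vector only
# (one mat-vec per iteration); the scaled matrix is materialized at the end.
#
# target "mean": row sums equalized to their running mean (ICE; overall scale
#   preserved, convergence measured as CV of row sums).
# target "one": row and column sums driven to exactly 1 (doubly stochastic;
#   convergence measured as max |row sum - 1|).
.balance_core <- function(m, tol, max_iter, target = c("mean", "one"),
                          b0 = NULL) {
  target <- match.arg(target)
  k <- nrow(m)
  b <- if (is.null(b0)) rep(1, k) else b0
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    r <- drop(m %*% (1 / b)) / b
    if (target == "mean") {
      mu <- mean(r)
      dev <- if (mu > 0) stats::sd(r) / mu else Inf
      if (dev < tol) { converged <- TRUE; break }
      b <- b * sqrt(r / mu)
    } else {
      if (max(abs(r - 1)) < tol) { converged <- TRUE; break }
      b <- b * sqrt(r)
    }
  }
  list(bias = b, row_sums = r, converged = converged, iters = iters)
}

#' ICE-balance a contact map
#'
#' Iterative correction equalizes the visibility of every valid bin: the
#' matrix is symmetrically scaled (`m[i,j] / (b[i] * b[j])`) until all
#' unmasked row sums agree, removing per-bin coverage biases. Rows whose
#' coefficient of variation falls below `tol` are considered converged.
#' All-zero rows that are not yet masked cannot be balanced and are added to
#' the mask with a warning.
#'
#' @param map a raw-count `ContactMap` (mask already applied).
#' @param tol convergence tolerance on the coefficient of variation of the
#'   unmasked row sums (default 1e-6).
#' @param max_iter maximum number of iterations (default 1000).
#' @return the balanced `ContactMap` (`balanced = TRUE`); if the iteration
#'   did not converge the partial result carries `attr(, "converged") = FALSE`
#'   and a warning is emitted.
#' @export
ice_balance <- function(map, tol = 1e-6, max_iter = 1000L) {
  n <- n_bins(map)
  valid <- setdiff(seq_len(n), map$mask)
  zero <- valid[rowSums(map$matrix[valid, valid, drop = FALSE], na.rm = TRUE) == 0]
  if (length(zero)) {
    warning(sprintf("%d all-zero unmasked row(s) added to mask", length(zero)))
    map <- mask_bins(map, zero)
    valid <- setdiff(seq_len(n), map$mask)
  }
  sub <- map$matrix[valid, valid, drop = FALSE]
  fit <- .balance_core(sub, tol = tol, max_iter = max_iter, target = "mean")
  if (!fit$converged)
    warning(sprintf("ICE did not converge in %d iterations (CV = %.3g)",
                    max_iter, stats::sd(fit$row_sums) / mean(fit$row_sums)))
  out <- matrix(NA_real_, n, n)
  out[valid, valid] <- sub / tcrossprod(fit$bias)
  res <- contact_map(out, map$bin_size, map$genome_length, map$circular,
                     mask = integer(), balanced = TRUE)
  res$mask <- map$mask
  attr(res, "converged") <- fit$converged
  res
}

#' Doubly-stochastic normalization of a non-negative matrix
#'
#' Symmetric Sinkhorn scaling: divide iteratively by the square root of the
#' row-sum products until every row and column sums to 1 (so entries can be
#' read as contact probabilities).
#'
#' @param m non-negative square matrix with no zero rows.
#' @param tol tolerance on `|row sum - 1|` (default 1e-8).
#' @param max_iter maximum iterations (default 5000).
#' @return the scaled matrix; `attr(, "converged")` is `FALSE` (with a
#'   warning) if `max_iter` was exhausted.
#' @export
doubly_stochastic <- function(m, tol = 1e-8, max_iter = 5000L) {
  if (any(m < 0)) stop("matrix must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("matrix has an all-zero row or column")
  sym <- isSymmetric(unname(m), tol = 1e-12)
  if (sym) {
    fit <- .balance_core(m, tol = tol, max_iter = max_iter, target = "one")
    out <- m / tcrossprod(fit$bias)
    converged <- fit$converged
  } else {
    # general case: alternate row and column scaling (classic Sinkhorn-Knopp)
    out <- m
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      out <- out / rowSums(out)
      out <- sweep(out, 2, colSums(out), "/")
      if (max(abs(rowSums(out) - 1)) < tol &&
          max(abs(colSums(out) - 1)) < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) warning("doubly_stochastic did not converge")
  attr(out, "converged") <- converged
  out
}
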