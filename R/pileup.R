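#' Select the most transcribed genes
#'
#' Keeps the top `ceil(fraction * n)` genes by expression (RPKM); ties are
#' broken by genomic order.
#'
#' @param genes data frame with at least `id`, `start`, `end`, `strand`,
#'   `expression` columns (bp, 0-based half-open).
#' @param fraction fraction of genes to keep, in (0, 1].
#' @return the selected genes, in genomic order.
#' @export
select_active_genes <- function(genes, fraction) {
  if (!nrow(genes)) return(genes)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * nrow(genes))
  ord <- order(-genes$expression, genes$start)
  sel <- genes[ord[seq_len(k)], , drop = FALSE]
  sel[order(sel$start), , drop = FALSE]
}

#' Keep only transcription-unit starts
#'
#' Filters an active-gene list down to genes with no other active gene in
#' the `upstream_gap_bp` interval upstream of their start codon
#' (strand-aware: upstream of a reverse gene lies after its end coordinate).
#' Any overlap of another active gene with that interval disqualifies the
#' gene. The interval wraps on circular genomes.
#'
#' @param active active genes ([select_active_genes()]).
#' @param upstream_gap_bp upstream exclusion window in bp (default 3000).
#' @param genome_length genome length in bp (needed for wrapping).
#' @param circular wrap the upstream interval (default `TRUE`).
#' @return the subset of `active` that are first transcribed genes.
#' @export
select_tu_starts <- function(active, upstream_gap_bp = 3000,
                             genome_length, circular = TRUE) {
  if (!nrow(active)) return(active)
  # upstream interval [us, ue) in bp, possibly wrapped
  keep <- vapply(seq_len(nrow(active)), function(k) {
    g <- active[k, ]
    if (g$strand == "+") { us <- g$start - upstream_gap_bp; ue <- g$start }
    else { us <- g$end; ue <- g$end + upstream_gap_bp }
    others <- active[-k, , drop = FALSE]
    if (!nrow(others)) return(TRUE)
    segs <- if (circular) {
      us2 <- us %% genome_length; ue2 <- ue %% genome_length
      if (us2 < ue2) list(c(us2, ue2))
      else list(c(us2, genome_length), c(0, ue2))
    } else list(c(max(us, 0), min(ue, genome_length)))
    for (sg in segs) {
      hit <- others$start < sg[2] & others$end > sg[1]
      if (any(hit)) return(FALSE)
    }
    TRUE
  }, logical(1))
  active[keep, , drop = FALSE]
}

#' Extract an oriented contact-map window around an anchor
#'
#' Returns the `W x W` submatrix centered on the bin containing `anchor_bp`
#' (`W = width_bp / bin_size`, forced odd by centering). For reverse-strand
#' anchors the window is rotated 180 degrees (both axes reversed) so that
#' the anchored gene always points in the same direction. Masked bins appear
#' as `NA`. Windows falling off the end of a linear genome return `NULL`
#' with a warning.
#'
#' @param map a `ContactMap`.
#' @param anchor_bp anchor position in bp (e.g. a start codon).
#' @param strand `"+"` or `"-"`.
#' @param width_bp window width in bp (multiple of the bin size).
#' @return `W x W` matrix, or `NULL` if the window is unavailable.
#' @export
extract_window <- function(map, anchor_bp, strand = "+", width_bp) {
  n <- n_bins(map)
  wbins <- round(width_bp / map$bin_size)
  h <- wbins %/% 2L
  center <- floor(anchor_bp / map$bin_size) + 1L
  idx <- center + (-h):(h - (1L - wbins %% 2L))
  if (!map$circular && (min(idx) < 1L || max(idx) > n)) {
    warning("window extends past the end of a linear genome; excluded")
    return(NULL)
  }
  idx <- .wrap(idx, n)
  win <- map$matrix[idx, idx, drop = FALSE]
  if (strand == "-") win <- win[rev(seq_len(nrow(win))), rev(seq_len(ncol(win)))]
  unname(win)
}

#' Average a list of contact windows into a pileup
#'
#' Per-cell mean over the windows in which that cell is defined (white lines
#' are `NA` and simply do not contribute). Cells defined in no window are
#' `NA`.
#'
#' @param windows list of equally sized matrices ([extract_window()]).
#' @param anchor_kind label recorded in the result (`"TSS"`, `"ATG"`,
#'   `"random"`, ...).
#' @return a `Pileup` list: `matrix` (per-cell mean), `n_windows`, `counts`
#'   (per-cell contributing windows), `anchor_kind`.
#' @export
pileup_windows <- function(windows, anchor_kind = "TSS") {
  windows <- Filter(Negate(is.null), windows)
  if (!length(windows)) stop("no windows to pile up")
  dm <- dim(windows[[1]])
  acc <- matrix(0, dm[1], dm[2])
  cnt <- matrix(0L, dm[1], dm[2])
  for (w in windows) {
    if (!identical(dim(w), dm)) stop("windows differ in size")
    def <- is.finite(w)
    acc[def] <- acc[def] + w[def]
    cnt <- cnt + def
  }
  avg <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(list(matrix = avg, n_windows = length(windows), counts = cnt,
                 anchor_kind = anchor_kind),
            class = "Pileup")
}

#' @export
print.Pileup <- function(x, ...) {
  cat(sprintf("Pileup of %d %s-anchored windows (%d x %d)\n",
              x$n_windows, x$anchor_kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Ratio of an observed pileup to a random-anchor pileup
#'
#' Controls for the regional contact background: for every observed anchor a
#' random anchor is drawn uniformly within `+/- jitter_bp`, the random
#' windows are piled up with the same orientation rules, and the elementwise
#' `observed / random` ratio is returned (`NA` where the random pileup is 0
#' or undefined).
#'
#' @param observed observed `Pileup`.
#' @param map the `ContactMap` the windows came from.
#' @param anchors_bp observed anchor positions in bp.
#' @param strands anchor strands (recycled; default all `"+"`).
#' @param jitter_bp half-width of the jitter interval (default 100 kb).
#' @param seed integer seed.
#' @return list with `ratio` (matrix), `random` (the random `Pileup`).
#' @export
pileup_ratio <- function(observed, map, anchors_bp, strands = "+",
                         jitter_bp = 1e5, seed = 1L) {
  strands <- rep_len(strands, length(anchors_bp))
  set.seed(seed)
  offs <- stats::runif(length(anchors_bp), -jitter_bp, jitter_bp)
  rnd <- (anchors_bp + offs) %% map$genome_length
  w <- nrow(observed$matrix) * map$bin_size
  wins <- lapply(seq_along(rnd), function(k)
    extract_window(map, rnd[k], strands[k], w))
  rp <- pileup_windows(wins, anchor_kind = "random")
  ratio <- observed$matrix / rp$matrix
  ratio[!is.finite(ratio)] <- NA_real_
  list(ratio = ratio, random = rp)
}

#' Average strand-oriented 1D signal windows
#'
#' Companion of the contact pileup for genomics tracks: reverse-strand
#' windows are reversed before the per-position mean, so all genes point the
#' same way.
#'
#' @param tracks list of equal-length numeric vectors.
#' @param strands one strand per track (`"+"`/`"-"`).
#' @return numeric averaged track.
#' @export
pileup_track <- function(tracks, strands = "+") {
  strands <- rep_len(strands, length(tracks))
  if (!length(tracks)) stop("no tracks to pile up")
  m <- vapply(seq_along(tracks), function(k) {
    v <- tracks[[k]]
    if (strands[k] == "-") rev(v) else v
  }, numeric(length(tracks[[1]])))
  rowMeans(m, na.rm = TRUE)
}

#' Correlate a pileup's short-range diagonal with an averaged track
#'
#' The pileup's adjacent-bin diagonal profile (`matrix[k, k+1]` for each
#' position `k`) quantifies short-range contacts across the window; it is
#' correlated (Pearson) with the averaged transcription track resampled to
#' the same inter-bin positions (mean of adjacent track bins).
#'
#' @param pileup a `Pileup`.
#' @param track averaged 1D signal over the same window, one value per bin.
#' @return Pearson r, or `NA` with a warning when a profile is constant.
#' @export
pileup_transcription_correlation <- function(pileup, track) {
  m <- pileup$matrix
  w <- nrow(m)
  prof <- m[cbind(seq_len(w - 1L), seq_len(w - 1L) + 1L)]
  tr <- if (length(track) == w) (track[-1] + track[-w]) / 2
        else if (length(track) == w - 1L) track
        else stop("track length does not match the pileup window")
  ok <- is.finite(prof) & is.finite(tr)
  if (sum(ok) < 3 || stats::sd(prof[ok]) == 0 || stats::sd(tr[ok]) == 0) {
    warning("constant or undersized profile; correlation undefined")
    return(NA_real_)
  }
  stats::cor(prof[ok], tr[ok])
}
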