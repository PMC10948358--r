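#' Construct a binned genomics track
#'
#' A `GenomicTrack` holds one value per genomic bin (RNA-seq CPM, ChIP CPM,
#' z-scores, occupancy, short-range contacts...) plus the binning metadata.
#'
#' @param values numeric per-bin values (`NA` = masked bin).
#' @param bin_size bin width in bp.
#' @param genome_length genome length in bp (default `length(values) *
#'   bin_size`).
#' @param circular circular genome (default `TRUE`).
#' @param units unit label: `"CPM"`, `"z"`, `"contacts"`, `"occupancy"`.
#' @return an object of class `GenomicTrack`.
#' @export
genomic_track <- function(values, bin_size, genome_length = NULL,
                          circular = TRUE, units = "CPM") {
  if (is.null(genome_length)) genome_length <- length(values) * bin_size
  if (length(values) != ceiling(genome_length / bin_size))
    stop("track length does not match ceiling(genome_length / bin_size)")
  structure(list(values = as.numeric(values), bin_size = as.numeric(bin_size),
                 genome_length = as.numeric(genome_length),
                 circular = isTRUE(circular), units = units),
            class = "GenomicTrack")
}

#' @export
print.GenomicTrack <- function(x, ...) {
  cat(sprintf("GenomicTrack: %d bins of %g bp (%s), units: %s\n",
              length(x$values), x$bin_size,
              if (x$circular) "circular" else "linear", x$units))
  invisible(x)
}

.track_values <- function(x) if (inherits(x, "GenomicTrack")) x$values else as.numeric(x)

#' Aggregate a signal into coarser bins
#'
#' Block aggregation by mean or sum; a trailing partial block is aggregated
#' over its actual length.
#'
#' @param values numeric fine-scale signal or a `GenomicTrack`.
#' @param factor integer aggregation factor (>= 1).
#' @param aggregator `"mean"` (default) or `"sum"`.
#' @return a `GenomicTrack` when the input is one (bin size multiplied),
#'   otherwise a numeric vector.
#' @export
bin_track <- function(values, factor, aggregator = c("mean", "sum")) {
  aggregator <- match.arg(aggregator)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  v <- .track_values(values)
  if (factor == 1L) out <- v
  else {
    g <- (seq_along(v) - 1L) %/% factor + 1L
    f <- if (aggregator == "mean") function(z) mean(z) else function(z) sum(z)
    out <- as.numeric(tapply(v, g, f))
  }
  if (inherits(values, "GenomicTrack"))
    genomic_track(out, values$bin_size * factor, values$genome_length,
                  values$circular, values$units)
  else out
}

#' z-transform a track
#'
#' Subtracts the mean and divides by the sample standard deviation over
#' unmasked bins; standard preprocessing before comparing tracks of
#' different units. Masked (`NA`) bins stay masked.
#'
#' @param track numeric vector or `GenomicTrack` with at least 2 unmasked,
#'   non-identical values.
#' @param population use the population (n) instead of the sample (n-1)
#'   standard deviation (default `FALSE`).
#' @return the z-scored track (same type as the input; units become `"z"`).
#' @export
z_transform <- function(track, population = FALSE) {
  v <- .track_values(track)
  x <- v[is.finite(v)]
  if (length(x) < 2) stop("need at least 2 unmasked bins")
  s <- stats::sd(x)
  if (population) s <- s * sqrt((length(x) - 1) / length(x))
  if (s == 0) stop("constant track cannot be z-transformed")
  out <- (v - mean(x)) / s
  if (inherits(track, "GenomicTrack")) {
    track$values <- out; track$units <- "z"; track
  } else out
}

#' Short-range Hi-C signal (adjacent-bin contacts)
#'
#' The contacts between each bin and the next one (`map[i, i+1]`, wrapping
#' at the end on circular genomes) — the classic adjacent-5-kb-bin signal
#' used to compare Hi-C with transcription tracks. Pairs touching a masked
#' bin are masked.
#'
#' @param map a balanced `ContactMap` (conventionally at 5-kb bins).
#' @return a `GenomicTrack` of per-bin short-range contacts.
#' @export
short_range_signal <- function(map) {
  n <- n_bins(map)
  nxt <- .wrap(seq_len(n) + 1L, n)
  v <- map$matrix[cbind(seq_len(n), nxt)]
  if (!map$circular) v[n] <- NA_real_
  genomic_track(v, map$bin_size, map$genome_length, map$circular,
                units = "contacts")
}

#' Circular Gaussian blur of a track
#'
#' Wrapped Gaussian smoothing (e.g. of GapR ChIP signal, for which
#' `sigma_bp = 2500` is the reference value). The kernel is truncated at 4
#' standard deviations and renormalized, so the total signal is conserved.
#'
#' @param track numeric vector or `GenomicTrack`.
#' @param sigma_bp standard deviation in bp (default 2500).
#' @param bin_size bin size in bp when `track` is a plain vector (default 1,
#'   i.e. sigma interpreted in elements).
#' @return the blurred track (same type as the input).
#' @export
gaussian_blur_circular <- function(track, sigma_bp = 2500, bin_size = 1) {
  v <- .track_values(track)
  if (inherits(track, "GenomicTrack")) bin_size <- track$bin_size
  sigma <- sigma_bp / bin_size
  if (sigma <= 0) stop("sigma must be positive")
  n <- length(v)
  h <- min(n %/% 2, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k <- k / sum(k)
  out <- numeric(n)
  idx <- seq_len(n)
  for (o in -h:h)
    out <- out + k[o + h + 1L] * v[.wrap(idx + o, n)]
  if (inherits(track, "GenomicTrack")) { track$values <- out; track }
  else out
}

#' Spearman correlation between two tracks
#'
#' Rank correlation over the bins where both tracks are defined (average
#' ranks on ties) — the statistic used to compare z-transformed ChIP /
#' RNA-seq tracks with the short-range Hi-C signal.
#'
#' @param a,b numeric vectors or `GenomicTrack`s on the same binning.
#' @return Spearman rho, or `NA` with a warning when either track is
#'   constant or fewer than 3 bins are shared.
#' @export
track_spearman <- function(a, b) {
  va <- .track_values(a); vb <- .track_values(b)
  if (length(va) != length(vb)) stop("tracks differ in length")
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3) { warning("fewer than 3 shared bins"); return(NA_real_) }
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    warning("constant track; Spearman undefined")
    return(NA_real_)
  }
  stats::cor(va[ok], vb[ok], method = "spearman")
}

#' Read a bedgraph file as a binned track
#'
#' Expects uniform fixed-width intervals on a single sequence (the usual
#' layout for binned bacterial tracks); `track` header lines are skipped.
#'
#' @param path bedgraph path (chrom, start, end, value).
#' @param circular circular genome flag for the resulting track.
#' @param units unit label.
#' @return a `GenomicTrack`.
#' @export
read_bedgraph <- function(path, circular = TRUE, units = "CPM") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") & nzchar(lines)]
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  df <- df[order(df$start), ]
  bin <- stats::median(df$end - df$start)
  n <- ceiling(max(df$end) / bin)
  v <- rep(NA_real_, n)
  v[df$start %/% bin + 1L] <- df$value
  genomic_track(v, bin, max(df$end), circular, units)
}

#' Write a track as a bedgraph file
#'
#' @param track a `GenomicTrack`.
#' @param path output path.
#' @param chrom sequence name (default `"genome"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = "genome") {
  n <- length(track$values)
  start <- (seq_len(n) - 1L) * track$bin_size
  end <- pmin(start + track$bin_size, track$genome_length)
  keep <- is.finite(track$values)
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(start[keep]),
                     as.integer(end[keep]),
                     sprintf("%.17g", track$values[keep])),
             path)
  invisible(path)
}
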