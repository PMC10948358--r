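#' Construct a binned Hi-C contact map
#'
#' A `ContactMap` is a symmetric, non-negative `N x N` matrix of contact
#' counts (or balanced frequencies) between genomic bins, together with the
#' binning metadata needed to interpret it: bin size, genome length, whether
#' the genome is circular (bacterial chromosomes are), and a set of invalid
#' ("white line") bins that are excluded from every computation.
#'
#' Bins are indexed 1..N in R convention, with bin `i` covering the 0-based,
#' half-open genomic interval `[(i-1)*bin_size, i*bin_size)`, and
#' `N = ceiling(genome_length / bin_size)`.
#'
#' @param matrix numeric `N x N` matrix; must be symmetric within a relative
#'   tolerance of 1e-9 and have no negative finite entries.
#' @param bin_size bin width in bp.
#' @param genome_length genome length in bp; defaults to `N * bin_size`.
#' @param circular logical; whether genomic distance and window extraction
#'   wrap around the origin (default `TRUE`).
#' @param mask integer vector of invalid (white-line) bin indices (1-based).
#' @param balanced logical; whether the matrix has been ICE-balanced.
#' @return an object of class `ContactMap`.
#' @seealso [read_map()], [ice_balance()], [distance_decay()]
#' @export
contact_map <- function(matrix, bin_size, genome_length = NULL,
                        circular = TRUE, mask = integer(), balanced = FALSE) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("contact map must be a square matrix")
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  if (is.null(genome_length)) genome_length <- n * bin_size
  if (n != ceiling(genome_length / bin_size))
    stop("matrix dimension does not match ceiling(genome_length / bin_size)")
  fin <- is.finite(matrix)
  if (any(matrix[fin] < 0))
    stop("contact map entries must be non-negative")
  d <- abs(matrix - t(matrix))
  scale <- max(abs(matrix[fin]), 1)
  if (any(d[fin & t(fin)] > 1e-9 * scale))
    stop("contact map is not symmetric within tolerance")
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1 || max(mask) > n))
    stop("mask indices out of range")
  structure(
    list(matrix = matrix, bin_size = as.numeric(bin_size),
         genome_length = as.numeric(genome_length),
         circular = isTRUE(circular), mask = mask,
         balanced = isTRUE(balanced)),
    class = "ContactMap"
  )
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf(
    "ContactMap: %d bins of %g bp (%s genome, %g bp)\n",
    n_bins(x), x$bin_size, if (x$circular) "circular" else "linear",
    x$genome_length))
  cat(sprintf("  balanced: %s; masked bins: %d; total contacts: %.4g\n",
              x$balanced, length(x$mask), sum(x$matrix, na.rm = TRUE)))
  invisible(x)
}

#' Number of bins in a ContactMap
#' @param map a `ContactMap`.
#' @return integer bin count.
#' @export
n_bins <- function(map) nrow(map$matrix)

#' Mark bins as invalid in a ContactMap
#'
#' Adds `bins` to the map's mask and sets the corresponding rows/columns to
#' `NA` so they cannot leak into downstream statistics.
#'
#' @param map a `ContactMap`.
#' @param bins integer bin indices (1-based).
#' @return the masked `ContactMap`.
#' @export
mask_bins <- function(map, bins) {
  bins <- sort(unique(as.integer(bins)))
  if (!length(bins)) return(map)
  if (min(bins) < 1 || max(bins) > n_bins(map)) stop("mask indices out of range")
  m <- map$matrix
  m[bins, ] <- NA_real_
  m[, bins] <- NA_real_
  map$matrix <- m
  map$mask <- sort(unique(c(map$mask, bins)))
  map
}

#' Read a contact map from a dense or triplet text file
#'
#' Two plain-text layouts are supported. Both start with header lines
#' `#bin_size <bp>`, `#genome_length <bp>`, `#circular <0|1>` (and optionally
#' `#balanced <0|1>`, `#mask i,j,...` with 0-based bin indices).
#' A *dense* file then holds the full `N x N` tab-separated matrix; a
#' *triplet* file holds `bin1<TAB>bin2<TAB>value` records with 0-based bin
#' indices, which are mirrored into both triangles.
#'
#' @param path file path.
#' @param format `"auto"` (default; sniffed from the content), `"dense"` or
#'   `"triplet"`.
#' @return a `ContactMap`.
#' @export
read_map <- function(path, format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  get_hdr <- function(key, default = NULL) {
    hit <- grep(paste0("^#", key, "\\b"), hdr, value = TRUE)
    if (!length(hit)) {
      if (is.null(default)) stop(sprintf("header line #%s missing in %s", key, path))
      return(default)
    }
    sub(paste0("^#", key, "\\s+"), "", hit[1])
  }
  bin_size <- as.numeric(get_hdr("bin_size"))
  genome_length <- as.numeric(get_hdr("genome_length"))
  circular <- as.numeric(get_hdr("circular")) != 0
  balanced <- as.numeric(get_hdr("balanced", "0")) != 0
  mask_s <- get_hdr("mask", "")
  mask <- if (nzchar(mask_s)) as.integer(strsplit(mask_s, ",")[[1]]) + 1L else integer()
  n <- ceiling(genome_length / bin_size)

  if (format == "auto") {
    ncol1 <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
    format <- if (ncol1 == n && length(body) == n) "dense" else "triplet"
  }
  if (format == "dense") {
    m <- as.matrix(utils::read.table(text = body, sep = "\t"))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != n) stop("dense matrix dimensions disagree with header")
  } else {
    tr <- utils::read.table(text = body, sep = "\t",
                            col.names = c("bin1", "bin2", "value"))
    if (any(tr$value < 0)) stop("negative values in triplet file")
    i <- tr$bin1 + 1L; j <- tr$bin2 + 1L
    if (any(i < 1 | i > n | j < 1 | j > n)) stop("triplet bin index out of range")
    m <- matrix(0, n, n)
    m[cbind(i, j)] <- tr$value
    m[cbind(j, i)] <- tr$value
  }
  map <- contact_map(m, bin_size, genome_length, circular,
                     mask = integer(), balanced = balanced)
  if (length(mask)) map <- mask_bins(map, mask)
  map
}

#' Write a contact map to a dense or triplet text file
#'
#' Inverse of [read_map()]; the round trip reproduces the map exactly.
#' Triplet output stores the upper triangle (including the diagonal) of
#' non-zero entries with 0-based bin indices.
#'
#' @param map a `ContactMap`.
#' @param path output path.
#' @param format `"triplet"` (default) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  hdr <- c(sprintf("#bin_size\t%g", map$bin_size),
           sprintf("#genome_length\t%g", map$genome_length),
           sprintf("#circular\t%d", as.integer(map$circular)),
           sprintf("#balanced\t%d", as.integer(map$balanced)))
  if (length(map$mask))
    hdr <- c(hdr, paste0("#mask\t", paste(map$mask - 1L, collapse = ",")))
  if (format == "dense") {
    body <- apply(map$matrix, 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
  } else {
    m <- map$matrix
    keep <- which(upper.tri(m, diag = TRUE) & is.finite(m) & m != 0, arr.ind = TRUE)
    body <- sprintf("%d\t%d\t%s", keep[, 1] - 1L, keep[, 2] - 1L,
                    sprintf("%.17g", m[keep]))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
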