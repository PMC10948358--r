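#' Define a synthetic bacterial Hi-C scenario
#'
#' Samples a seeded, fully reproducible synthetic study condition: a
#' circular genome with a non-overlapping gene/operon layout (lengths
#' log-uniform on 1-20 kb), log-normal expression levels, a power-law
#' contact decay `p(s) = (s + s0)^-alpha`, polymerase occupancy scaled to a
#' true maximum `epsilon_true`, optional plaid enrichment between active
#' regions, optional large self-interacting domains, an optional strong
#' T7-like transcription unit, Poisson sequencing noise and masked
#' white-line bins.
#'
#' The top `active_fraction` of genes by expression are flagged active;
#' `rifampicin = TRUE` silences every native gene (only a T7 unit, driven by
#' a rifampicin-insensitive polymerase, keeps transcribing).
#'
#' @param genome_length genome length in bp (default 1e6).
#' @param bin_size bin width in bp (default 1000).
#' @param n_genes number of genes (default 100).
#' @param active_fraction fraction of genes flagged active (default 0.10).
#' @param expression_meanlog,expression_sdlog log-normal RPKM parameters
#'   (defaults 3 and 1.5).
#' @param epsilon_true true maximum polymerase occupancy in (0, 1]
#'   (default 0.15).
#' @param decay_exponent,decay_s0 `p(s) = (s + s0)^-alpha` in bins
#'   (defaults 1 and 1).
#' @param plaid_kappa multiplicative plaid enrichment between active bins
#'   (default 2.5; 0 disables).
#' @param plaid_range_bp maximum separation of the plaid term (default
#'   25 kb).
#' @param sequencing_depth expected total contacts (default 2e6).
#' @param white_line_bins number of randomly masked bins (default 10).
#' @param rifampicin transcription-initiation block (default `FALSE`).
#' @param t7_unit `NULL`, `TRUE` (defaults: promoter at mid-genome, forward,
#'   110-kb track) or a list with `position_bp`, `direction` (+1/-1),
#'   `track_length_bp`.
#' @param n_domains number of large planted self-interacting domains
#'   (default 0).
#' @param domain_kappa multiplicative within-domain enrichment (default 1).
#' @param seed integer seed; scenarios are bit-for-bit reproducible.
#' @return a `SyntheticScenario` list (genes, per-bin layout and all
#'   parameters).
#' @export
make_scenario <- function(genome_length = 1e6, bin_size = 1000,
                          n_genes = 100, active_fraction = 0.10,
                          expression_meanlog = 3, expression_sdlog = 1.5,
                          epsilon_true = 0.15, decay_exponent = 1,
                          decay_s0 = 1, plaid_kappa = 2.5,
                          plaid_range_bp = 25000, sequencing_depth = 2e6,
                          white_line_bins = 10, rifampicin = FALSE,
                          t7_unit = NULL, n_domains = 0, domain_kappa = 1,
                          seed = 1L) {
  if (epsilon_true <= 0 || epsilon_true > 1) stop("epsilon_true must be in (0, 1]")
  set.seed(seed)
  lens <- round(exp(stats::runif(n_genes, log(1e3), log(2e4))))
  if (sum(lens) > 0.85 * genome_length)
    stop("gene layout infeasible: total gene length exceeds 85% of the genome")
  slack <- genome_length - sum(lens)
  cuts <- sort(stats::runif(n_genes, 0, slack))
  gaps <- diff(c(0, cuts))
  starts <- round(cumsum(gaps) + cumsum(c(0, lens[-n_genes])))
  genes <- data.frame(
    id = sprintf("gene%03d", seq_len(n_genes)),
    start = starts, end = starts + lens,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    expression = stats::rlnorm(n_genes, expression_meanlog, expression_sdlog))
  if (rifampicin) genes$expression <- 0
  k_active <- ceiling(active_fraction * n_genes)
  genes$active <- FALSE
  if (!rifampicin)
    genes$active[order(-genes$expression, genes$start)[seq_len(k_active)]] <- TRUE
  if (isTRUE(t7_unit)) t7_unit <- list()
  if (is.list(t7_unit)) {
    t7_unit <- utils::modifyList(
      list(position_bp = genome_length / 2, direction = 1L,
           track_length_bp = 110e3), t7_unit)
  }
  boundaries <- NULL
  if (n_domains > 0) {
    min_dom <- 50e3
    if (n_domains * min_dom > genome_length) stop("too many domains")
    slack_d <- genome_length - n_domains * min_dom
    cuts_d <- sort(stats::runif(n_domains, 0, slack_d))
    sizes <- min_dom + diff(c(0, cuts_d, slack_d))[seq_len(n_domains)]
    sizes <- sizes * genome_length / sum(sizes)
    boundaries <- round(cumsum(sizes))[-n_domains]
    boundaries <- sort(c(0, boundaries))   # n_domains junctions on the circle
  }
  structure(
    list(genome_length = genome_length, bin_size = bin_size,
         circular = TRUE, genes = genes,
         epsilon_true = epsilon_true, decay_exponent = decay_exponent,
         decay_s0 = decay_s0, plaid_kappa = plaid_kappa,
         plaid_range_bp = plaid_range_bp,
         sequencing_depth = sequencing_depth,
         white_line_bins = white_line_bins, rifampicin = rifampicin,
         t7_unit = t7_unit, n_domains = n_domains,
         domain_kappa = domain_kappa, domain_boundaries_bp = boundaries,
         seed = as.integer(seed)),
    class = "SyntheticScenario")
}

#' @export
print.SyntheticScenario <- function(x, ...) {
  cat(sprintf(
    "SyntheticScenario: %g bp circular genome, %g bp bins, %d genes (%d active)%s\n",
    x$genome_length, x$bin_size, nrow(x$genes), sum(x$genes$active),
    if (!is.null(x$t7_unit)) ", T7 unit" else ""))
  cat(sprintf("  epsilon_true %.2f, depth %.3g, seed %d\n",
              x$epsilon_true, x$sequencing_depth, x$seed))
  invisible(x)
}

# per-bin indicator: bin overlaps an active TU (or the T7 track)
.active_bins <- function(scenario) {
  n <- ceiling(scenario$genome_length / scenario$bin_size)
  a <- logical(n)
  act <- scenario$genes[scenario$genes$active, , drop = FALSE]
  for (k in seq_len(nrow(act))) {
    b1 <- floor(act$start[k] / scenario$bin_size) + 1L
    b2 <- ceiling(act$end[k] / scenario$bin_size)
    a[.wrap(b1:b2, n)] <- TRUE
  }
  t7 <- scenario$t7_unit
  if (is.list(t7)) {
    iv <- .t7_interval(scenario)
    b1 <- floor(iv[1] / scenario$bin_size) + 1L
    b2 <- ceiling(iv[2] / scenario$bin_size)
    a[.wrap(b1:b2, n)] <- TRUE
  }
  a
}

.t7_interval <- function(scenario) {
  t7 <- scenario$t7_unit
  if (t7$direction >= 0) c(t7$position_bp, t7$position_bp + t7$track_length_bp)
  else c(t7$position_bp - t7$track_length_bp, t7$position_bp)
}

#' Simulate the polymerase occupancy track of a scenario
#'
#' Occupancy is constant over each gene and proportional to its expression;
#' an optional T7 unit adds an exponentially decaying track (decay length =
#' one-third of the track length) from its promoter in its direction, with
#' twice the amplitude of the strongest native gene. The whole track is
#' scaled so its maximum equals `epsilon_true`.
#'
#' @param scenario a `SyntheticScenario`.
#' @return an `OccupancyTrack` (all-zero if nothing is transcribed).
#' @export
simulate_occupancy <- function(scenario) {
  n <- ceiling(scenario$genome_length / scenario$bin_size)
  raw <- numeric(n)
  g <- scenario$genes
  for (k in seq_len(nrow(g))) {
    if (g$expression[k] <= 0) next
    b1 <- floor(g$start[k] / scenario$bin_size) + 1L
    b2 <- ceiling(g$end[k] / scenario$bin_size)
    idx <- .wrap(b1:b2, n)
    raw[idx] <- raw[idx] + g$expression[k]
  }
  t7 <- scenario$t7_unit
  if (is.list(t7)) {
    amp <- if (any(g$expression > 0)) 2 * max(g$expression) else 1
    len_bins <- max(1L, round(t7$track_length_bp / scenario$bin_size))
    tau <- len_bins / 3
    prom <- floor(t7$position_bp / scenario$bin_size) + 1L
    d <- 0:(len_bins - 1L)
    idx <- .wrap(prom + sign(t7$direction) * d, n)
    raw[idx] <- raw[idx] + amp * exp(-d / tau)
  }
  if (all(raw == 0))
    return(structure(list(values = raw, epsilon = scenario$epsilon_true),
                     class = "OccupancyTrack"))
  normalize_chip(raw, scenario$epsilon_true)
}

#' Simulate a raw Hi-C contact map for a scenario
#'
#' The expected map combines the power-law distance decay with the
#' consecutive-polymerase (variant 2) contact weight of the occupancy
#' track, a multiplicative plaid enrichment between active bins within
#' `plaid_range_bp`, and (when domains are configured) a within-domain
#' enrichment. It is scaled to `sequencing_depth` expected contacts,
#' Poisson-sampled on the upper triangle, symmetrized, and `white_line_bins`
#' random bins are zeroed and masked.
#'
#' @param scenario a `SyntheticScenario`.
#' @return a raw-count `ContactMap`; `attr(, "truth")` records the planted
#'   TID intervals (bp), domain boundaries, occupancy and `epsilon_true`.
#' @export
simulate_map <- function(scenario) {
  n <- ceiling(scenario$genome_length / scenario$bin_size)
  occ <- simulate_occupancy(scenario)
  Cv <- occ$values
  sep <- .sep_matrix(n, TRUE)
  P <- matrix((sep + scenario$decay_s0)^(-scenario$decay_exponent), n, n)
  W <- .model_weight(Cv, variant = 2, circular = TRUE,
                     insulation_form = "printed")
  expected <- P * W
  a <- .active_bins(scenario)
  if (scenario$plaid_kappa > 0 && any(a)) {
    rng <- round(scenario$plaid_range_bp / scenario$bin_size)
    plaid <- 1 + scenario$plaid_kappa * outer(a, a) * (sep <= rng)
    expected <- expected * plaid
  }
  if (scenario$n_domains > 0 && scenario$domain_kappa > 0) {
    dom <- findInterval((seq_len(n) - 0.5) * scenario$bin_size,
                        c(scenario$domain_boundaries_bp, scenario$genome_length))
    dom[dom > scenario$n_domains] <- 1L   # wrap the last stretch onto domain 1
    expected <- expected * (1 + scenario$domain_kappa * outer(dom, dom, "=="))
  }
  up <- upper.tri(expected, diag = TRUE)
  lambda <- expected[up] * (scenario$sequencing_depth / sum(expected[up]))
  set.seed(scenario$seed + 1L)
  counts <- stats::rpois(length(lambda), lambda)
  m <- matrix(0, n, n)
  m[up] <- counts
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  map <- contact_map(m, scenario$bin_size, scenario$genome_length,
                     circular = TRUE)
  if (scenario$white_line_bins > 0) {
    wl <- sample.int(n, scenario$white_line_bins)
    map <- mask_bins(map, wl)
  }
  act <- scenario$genes[scenario$genes$active, , drop = FALSE]
  tids <- act[, c("start", "end")]
  if (is.list(scenario$t7_unit)) {
    iv <- .t7_interval(scenario)
    tids <- rbind(tids, data.frame(start = iv[1], end = iv[2]))
  }
  # active TUs separated by less than ~2 bins are transcribed back-to-back
  # and form a single contiguous domain; record them as one planted TID
  if (nrow(tids) > 1) {
    tids <- tids[order(tids$start), , drop = FALSE]
    gap <- 2 * scenario$bin_size
    grp <- cumsum(c(1, tids$start[-1] > cummax(tids$end[-nrow(tids)]) + gap))
    tids <- data.frame(start = tapply(tids$start, grp, min),
                       end = tapply(tids$end, grp, max))
  }
  attr(map, "truth") <- list(
    tids_bp = tids[order(tids$start), , drop = FALSE],
    domain_boundaries_bp = scenario$domain_boundaries_bp,
    epsilon_true = scenario$epsilon_true,
    occupancy = Cv, active_bins = a)
  map
}

#' Per-bin RNA-seq-like expression track of a scenario
#'
#' Sum of the expression of the genes covering each bin (CPM-like units).
#'
#' @param scenario a `SyntheticScenario`.
#' @return a `GenomicTrack`.
#' @export
simulate_rna_track <- function(scenario) {
  n <- ceiling(scenario$genome_length / scenario$bin_size)
  v <- numeric(n)
  g <- scenario$genes
  for (k in seq_len(nrow(g))) {
    b1 <- floor(g$start[k] / scenario$bin_size) + 1L
    b2 <- ceiling(g$end[k] / scenario$bin_size)
    idx <- .wrap(b1:b2, n)
    v[idx] <- v[idx] + g$expression[k]
  }
  genomic_track(v, scenario$bin_size, scenario$genome_length, TRUE, "CPM")
}

#' Write a scenario's simulated inputs and truth tables to disk
#'
#' Emits everything a pipeline run needs: the raw map (triplet TSV), genes
#' (BED6 + RPKM), RNA and occupancy bedgraphs, and plain-text truth tables
#' (TID intervals, domain boundaries, `epsilon_true`). Regenerating with the
#' same scenario yields byte-identical files.
#'
#' @param scenario a `SyntheticScenario`.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(scenario, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory")
  map <- simulate_map(scenario)
  truth <- attr(map, "truth")
  paths <- c(map = file.path(outdir, "map.tsv"),
             genes = file.path(outdir, "genes.bed"),
             rna = file.path(outdir, "rna_cpm.bedgraph"),
             occupancy = file.path(outdir, "occupancy.bedgraph"),
             tids = file.path(outdir, "truth_tids.tsv"),
             borders = file.path(outdir, "truth_borders.tsv"),
             epsilon = file.path(outdir, "truth_epsilon.txt"))
  write_map(map, paths["map"])
  write_genes(scenario$genes, paths["genes"])
  write_bedgraph(simulate_rna_track(scenario), paths["rna"])
  write_bedgraph(genomic_track(truth$occupancy, scenario$bin_size,
                               scenario$genome_length, TRUE, "occupancy"),
                 paths["occupancy"])
  utils::write.table(truth$tids_bp, paths["tids"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(boundary_bp = truth$domain_boundaries_bp %||% numeric()),
    paths["borders"], sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(sprintf("%.17g", scenario$epsilon_true), paths["epsilon"])
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read genes from a BED6(+RPKM) file
#'
#' @param path BED path: chrom, start, end, name, score, strand and an
#'   optional seventh RPKM column (score is used when absent).
#' @return gene data frame (`id`, `start`, `end`, `strand`, `expression`).
#' @export
read_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("expected at least 6 BED columns")
  data.frame(id = df[[4]], start = df[[2]], end = df[[3]], strand = df[[6]],
             expression = if (ncol(df) >= 7) df[[7]] else df[[5]])
}

#' Write genes as BED6 + RPKM
#'
#' @param genes gene data frame.
#' @param path output path.
#' @param chrom sequence name (default `"genome"`).
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, chrom = "genome") {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s",
                     chrom, as.integer(genes$start), as.integer(genes$end),
                     genes$id, 0L, genes$strand,
                     sprintf("%.17g", genes$expression)),
             path)
  invisible(path)
}
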