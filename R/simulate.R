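#' Configuration for a synthetic two-color tiling-array experiment
#'
#' The simulator emulates the inputs of a two-strain ChIP-chip
#' experiment: a bacterial genome with annotated genes and cryptic
#' prophage intervals, and one co-hybridized array whose wild-type
#' channel has flat expected intensity while the mutant channel is
#' multiplied by a planted fold change inside chosen regions.  Observed
#' intensities carry multiplicative log-normal noise per probe per
#' channel, plus an optional dye bias on the mutant channel.
#'
#' Defaults give a desk-scale experiment with the same probe density as
#' a 60-bp/105-bp tiling array: a 500-kb circular genome, 400 genes and
#' 3 prophages.
#'
#' @param genome_length Genome length in bp (default 5e5).
#' @param n_genes Number of genes to place (default 400).
#' @param n_prophages Number of prophage intervals (default 3).
#' @param planted_effects data.frame with columns `start`, `end`,
#'   `fold` (mutant/wild-type occupancy fold; > 0), or `NULL` for no
#'   differential regions.
#' @param baseline_intensity Expected wild-type fluorescence per probe
#'   (default 100 arbitrary units).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise (default 0.1; 0 disables noise).
#' @param dye_bias Multiplicative bias applied to the mutant (Cy5)
#'   channel (default 1).
#' @param seed RNG seed (default 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e5, n_genes = 400, n_prophages = 3,
                       planted_effects = NULL, baseline_intensity = 100,
                       noise_cv = 0.1, dye_bias = 1, seed = 1L) {
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    if (!all(c("start", "end", "fold") %in% names(planted_effects))) {
      stop("planted_effects needs columns start, end, fold")
    }
    if (any(planted_effects$fold <= 0)) stop("planted folds must be > 0")
    if (any(planted_effects$start < 0 |
            planted_effects$end > genome_length |
            planted_effects$start >= planted_effects$end)) {
      stop("planted regions must lie within the genome")
    }
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (baseline_intensity <= 0) stop("baseline_intensity must be > 0")
  structure(list(genome_length = genome_length, n_genes = n_genes,
                 n_prophages = n_prophages,
                 planted_effects = planted_effects,
                 baseline_intensity = baseline_intensity,
                 noise_cv = noise_cv, dye_bias = dye_bias,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw non-overlapping planted differential regions
#'
#' Convenience generator for simulation studies: places `n` regions of
#' `span_bp` bp uniformly on the genome, rejecting overlaps, and
#' assigns each a fold change cycled from `folds`.
#'
#' @param genome_length Genome length in bp.
#' @param n Number of regions.
#' @param span_bp Region width in bp (default 400, i.e. >= 3 probes of a
#'   60/105 grid).
#' @param folds Fold changes to cycle through.
#' @return data.frame with `start`, `end`, `fold`, usable as
#'   `planted_effects`.
#' @export
random_planted_effects <- function(genome_length, n, span_bp = 400,
                                   folds = c(5, 10, 36)) {
  starts <- numeric(0)
  guard <- 0
  while (length(starts) < n) {
    cand <- floor(stats::runif(1, 0, genome_length - span_bp))
    if (!length(starts) ||
        all(abs(cand - starts) >= span_bp + 210)) { # 2 probe periods apart
      starts <- c(starts, cand)
    }
    guard <- guard + 1
    if (guard > 10000 * n) stop("could not place non-overlapping regions")
  }
  starts <- sort(starts)
  data.frame(start = starts, end = starts + span_bp,
             fold = rep_len(folds, n))
}

#' Simulate a genome annotation
#'
#' Genes of 900 bp are placed on a regular lattice with random strand;
#' prophage intervals of ~20 kb are spaced evenly.  The layout is a
#' schematic stand-in for a real chromosome: coordinates are synthetic,
#' only the containment structure matters.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  genome <- genome_spec(L, circular = TRUE)
  pitch <- floor(L / config$n_genes)
  glen <- min(900, pitch - 10)
  gstart <- (seq_len(config$n_genes) - 1) * pitch
  genes <- data.frame(
    name = sprintf("gene%04d", seq_len(config$n_genes)),
    start = gstart, end = gstart + glen,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE))
  prophages <- if (config$n_prophages > 0) {
    pl <- min(20000, floor(L / (2 * config$n_prophages)))
    ps <- floor((seq_len(config$n_prophages) - 0.5) *
                  L / config$n_prophages)
    data.frame(name = sprintf("PP%d", seq_len(config$n_prophages)),
               start = ps, end = ps + pl)
  } else {
    data.frame(name = character(), start = numeric(), end = numeric())
  }
  genome_annotation(genes, prophages, genome)
}

#' Simulate the two channel tracks of a co-hybridized array
#'
#' Expected wild-type intensity is the baseline everywhere; expected
#' mutant intensity is baseline times the planted fold inside each
#' planted region (a probe is inside a region when its interval overlaps
#' it by at least one bp) and baseline elsewhere.  Observed intensity is
#' the expectation times the channel dye bias times a log-normal
#' multiplicative noise term with the configured coefficient of
#' variation.
#'
#' @param config A [sim_config()].
#' @param grid A [build_probe_grid()] on the config's genome.
#' @return List with `wt` and `mut` channel [occupancy_track()]s and
#'   `truth`, a data.frame recording each planted region, its fold and
#'   the 1-based indices of the probes it covers (`first_probe`,
#'   `last_probe`).
#' @export
simulate_tracks <- function(config, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "probe_grid"))
  if (grid$genome$length != config$genome_length) {
    stop("grid was not built on the configured genome")
  }
  set.seed(config$seed + 1L)
  n <- grid$count
  iv <- probe_intervals(grid)
  fold <- rep(1, n)
  truth <- data.frame(start = numeric(0), end = numeric(0),
                      fold = numeric(0), first_probe = integer(0),
                      last_probe = integer(0))
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    for (i in seq_len(nrow(pe))) {
      hit <- which(iv[, "start"] < pe$end[i] & iv[, "end"] > pe$start[i])
      if (!length(hit)) {
        stop(sprintf("planted region [%s, %s) covers no probe",
                     pe$start[i], pe$end[i]))
      }
      fold[hit] <- pe$fold[i]
      truth <- rbind(truth, data.frame(
        start = pe$start[i], end = pe$end[i], fold = pe$fold[i],
        first_probe = min(hit), last_probe = max(hit)))
    }
  }
  sigma <- sqrt(log(1 + config$noise_cv^2))
  noise <- function() {
    if (sigma == 0) rep(1, n) else stats::rlnorm(n, 0, sigma)
  }
  wt_vals <- config$baseline_intensity * noise()
  mut_vals <- config$baseline_intensity * fold * config$dye_bias * noise()
  list(wt = occupancy_track(wt_vals, grid, "channel"),
       mut = occupancy_track(mut_vals, grid, "channel"),
       truth = truth)
}

#' Configuration for a synthetic qPCR experiment
#'
#' @param genes data.frame with columns `gene` and `fold` (true
#'   mutant/wild-type expression fold change).
#' @param replicates Replicates per (gene, strain) (default 3).
#' @param ct_noise_sd Gaussian Ct noise in cycles (default 0.3).
#' @param reference_gene Normalization gene, planted at fold 1 and
#'   appended if absent (default `"16S"`).
#' @param efficiency Amplification factor per cycle (default 2).
#' @param seed RNG seed.
#' @return Object of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(genes, replicates = 3, ct_noise_sd = 0.3,
                            reference_gene = "16S", efficiency = 2.0,
                            seed = 1L) {
  genes <- as.data.frame(genes)
  if (!all(c("gene", "fold") %in% names(genes))) {
    stop("genes needs columns gene, fold")
  }
  if (any(genes$fold <= 0)) stop("folds must be > 0")
  if (replicates < 2) stop("need at least two replicates")
  if (efficiency <= 1) stop("efficiency must be > 1")
  if (!reference_gene %in% genes$gene) {
    genes <- rbind(genes, data.frame(gene = reference_gene, fold = 1))
  } else if (genes$fold[genes$gene == reference_gene] != 1) {
    stop("the reference gene must have fold 1")
  }
  structure(list(genes = genes, replicates = as.integer(replicates),
                 ct_noise_sd = ct_noise_sd,
                 reference_gene = reference_gene,
                 efficiency = efficiency, seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate a replicated Ct table
#'
#' Each gene gets a baseline threshold cycle; the mutant strain's
#' expression multiplier (the true fold change) shifts its Ct by
#' `-log_efficiency(fold)` cycles, and Gaussian cycle noise is added per
#' replicate.  The reference gene is planted at fold 1, so downstream
#' normalization recovers the planted folds.
#'
#' @param config A [qpcr_sim_config()].
#' @return A [qpcr_table()] with attribute `truth` (the planted folds).
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  set.seed(config$seed)
  g <- config$genes
  base_ct <- stats::setNames(
    ifelse(g$gene == config$reference_gene, 12,
           stats::runif(nrow(g), 18, 26)), g$gene)
  rows <- expand.grid(gene = g$gene,
                      strain = c("wild-type", "mutant"),
                      replicate = seq_len(config$replicates),
                      stringsAsFactors = FALSE)
  mult <- ifelse(rows$strain == "mutant",
                 g$fold[match(rows$gene, g$gene)], 1)
  rows$ct <- base_ct[rows$gene] - log(mult, base = config$efficiency) +
    stats::rnorm(nrow(rows), 0, config$ct_noise_sd)
  tab <- qpcr_table(rows, reference_gene = config$reference_gene)
  attr(tab, "truth") <- g
  tab
}
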