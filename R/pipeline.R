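#' Configure an end-to-end occupancy analysis run
#'
#' A run either simulates its inputs (`sim` is a [sim_config()],
#' optionally with `qpcr_sim` a [qpcr_sim_config()]) or reads them from
#' files (`inputs`, a named list of paths).  File mode accepts either
#' raw inputs (`genes`, `prophages`, `wt_track`, `mut_track`, plus
#' `genome_length`; tracks as [write_track()] TSVs) for the full
#' pipeline, or pre-ranked tables (`ranked_increased`,
#' `ranked_decreased`, `qpcr_ratios` TSVs with `gene`/`level`/`ratio`
#' and `prophage` columns) for the summary stages alone, e.g. to
#' re-analyze published ranked tables.
#'
#' @param sim A [sim_config()], or `NULL` for file mode.
#' @param qpcr_sim A [qpcr_sim_config()], or `NULL`.
#' @param inputs Named list of input paths (file mode), or `NULL`.
#' @param probe_length,period Probe grid geometry in bp (defaults 60 and
#'   105).
#' @param normalization `"median-ratio"` or `"none"`.
#' @param pseudocount Ratio pseudocount (intensity units, default 1).
#' @param cutoff_up,cutoff_down,min_probes,max_gap Peak-calling
#'   parameters, see [call_peaks()].
#' @param method Peak quantification method, see [quantify_peaks()].
#' @param top_n Rows kept in the ranked increased table (default 30).
#' @param top_n_decreased Rows kept in the ranked decreased table
#'   (default 31, mirroring the convention of reporting the strongest
#'   31 losses).
#' @param thresholds qPCR fold-classification thresholds (default
#'   `c(2, 4)`).
#' @param efficiency qPCR amplification factor per cycle (default 2).
#' @param seed Seed recorded in the manifest and used for simulation.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = NULL, qpcr_sim = NULL, inputs = NULL,
                       probe_length = 60, period = 105,
                       normalization = c("median-ratio", "none"),
                       pseudocount = 1, cutoff_up = 5, cutoff_down = 0.2,
                       min_probes = 2, max_gap = 0,
                       method = c("ratio-of-sums", "sum-ratio"),
                       top_n = 30, top_n_decreased = 31,
                       thresholds = c(2, 4), efficiency = 2.0,
                       seed = 1L) {
  if (is.null(sim) == is.null(inputs)) {
    stop("supply exactly one of sim or inputs")
  }
  structure(list(sim = sim, qpcr_sim = qpcr_sim, inputs = inputs,
                 probe_length = probe_length, period = period,
                 normalization = match.arg(normalization),
                 pseudocount = pseudocount, cutoff_up = cutoff_up,
                 cutoff_down = cutoff_down, min_probes = min_probes,
                 max_gap = max_gap, method = match.arg(method),
                 top_n = top_n, top_n_decreased = top_n_decreased,
                 thresholds = thresholds,
                 efficiency = efficiency, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `sim` and
#' `qpcr_sim` are nested maps passed to [sim_config()] /
#' [qpcr_sim_config()] (with `planted_effects` and `genes` given as
#' lists of maps), `inputs` is a map of paths.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$planted_effects)) {
      y$sim$planted_effects <-
        do.call(rbind, lapply(y$sim$planted_effects, as.data.frame))
    }
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$qpcr_sim)) {
    y$qpcr_sim$genes <- do.call(rbind, lapply(y$qpcr_sim$genes,
                                              as.data.frame))
    y$qpcr_sim <- do.call(qpcr_sim_config, y$qpcr_sim)
  }
  do.call(run_config, y)
}

#' Run the full occupancy pipeline
#'
#' Orchestrates simulate/load, channel normalization, ratio computation,
#' peak calling and quantification, gene/prophage annotation, ranked
#' tables, prophage summary and qPCR fold analysis, writing all outputs
#' plus a manifest to `out_dir`.  Re-running the same configuration
#' (same seed) reproduces every output byte-for-byte.
#'
#' Output files: `ranked_increased.tsv`, `ranked_decreased.tsv`,
#' `annotated_peaks.tsv`, `prophage_summary.json`, `qpcr_ratios.tsv`,
#' `summary.json`, `manifest.json`, `log.txt` (those applicable to the
#' input mode).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the in-memory results (`peaks`,
#'   `ranked_increased`, `ranked_decreased`, `prophage_summary`,
#'   `qpcr`, `fold_classes`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  res <- list()

  if (!is.null(config$sim)) {
    say("stage simulate: genome %d bp, seed %d",
        config$sim$genome_length, config$seed)
    sim <- config$sim
    sim$seed <- config$seed
    ann <- stage("simulate", simulate_annotation(sim))
    grid <- build_probe_grid(ann$genome, config$probe_length,
                             config$period)
    tracks <- stage("simulate", simulate_tracks(sim, grid))
    wt <- tracks$wt
    mut <- tracks$mut
    res$truth <- tracks$truth
    ranked_mode <- FALSE
  } else if (!is.null(config$inputs$ranked_increased)) {
    say("stage load: pre-ranked tables")
    ranked_mode <- TRUE
    inc <- stage("load", utils::read.delim(config$inputs$ranked_increased,
                                           stringsAsFactors = FALSE))
    dec <- if (!is.null(config$inputs$ranked_decreased)) {
      stage("load", utils::read.delim(config$inputs$ranked_decreased,
                                      stringsAsFactors = FALSE))
    }
    fix_na <- function(x) {
      if (!is.null(x$prophage)) x$prophage[x$prophage == ""] <- NA
      x
    }
    inc <- fix_na(inc)
    if (!is.null(dec)) dec <- fix_na(dec)
  } else {
    say("stage load: raw inputs")
    ranked_mode <- FALSE
    genome <- genome_spec(config$inputs$genome_length)
    ann <- stage("load", read_annotation(config$inputs$genes,
                                         config$inputs$prophages, genome))
    grid <- build_probe_grid(genome, config$probe_length, config$period)
    wt <- stage("load", read_track(config$inputs$wt_track, grid))
    mut <- stage("load", read_track(config$inputs$mut_track, grid))
  }

  if (!ranked_mode) {
    say("stage normalize: %s", config$normalization)
    norm <- stage("normalize",
                  normalize_channels(wt, mut, config$normalization))
    say("stage ratio: pseudocount %g", config$pseudocount)
    ratio <- stage("ratio",
                   probe_ratio(norm$mut, norm$wt, config$pseudocount))
    say("stage peaks: cutoffs %g / %g, min %d probes", config$cutoff_up,
        config$cutoff_down, config$min_probes)
    peaks <- stage("peaks", call_peaks(ratio, config$cutoff_up,
                                       config$cutoff_down,
                                       config$min_probes, config$max_gap))
    peaks <- stage("quantify",
                   quantify_peaks(peaks, norm$wt, norm$mut, config$method))
    say("stage annotate: %d peaks", nrow(peaks$peaks))
    annotated <- stage("annotate", assign_peaks(peaks, ann))
    annotated$gene[is.na(annotated$gene)] <- annotated$peak_id[
      is.na(annotated$gene)]
    inc <- rank_peaks(annotated, "increased")
    dec <- rank_peaks(annotated, "decreased")
    res$peaks <- peaks
    res$annotated <- annotated
    utils::write.table(
      annotated[c("peak_id", "start", "end", "direction", "n_probes",
                  "level", "gene", "location_class", "prophage")],
      file.path(out_dir, "annotated_peaks.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }

  keep <- function(x, n) utils::head(x, n)
  inc_top <- keep(inc, config$top_n)
  say("stage summarize: top %d of %d increased rows",
      nrow(inc_top), nrow(inc))
  summ <- stage("summarize",
                summarize_prophages(inc_top, top_n = nrow(inc_top)))
  res$ranked_increased <- inc_top
  res$ranked_decreased <- if (!is.null(dec))
    keep(dec, config$top_n_decreased)
  res$prophage_summary <- summ
  write_ranked <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  write_ranked(res$ranked_increased,
               file.path(out_dir, "ranked_increased.tsv"))
  if (!is.null(res$ranked_decreased)) {
    write_ranked(res$ranked_decreased,
                 file.path(out_dir, "ranked_decreased.tsv"))
  }
  jsonlite::write_json(
    list(prophage_fraction = summ$prophage_fraction,
         per_prophage_counts = as.list(summ$per_prophage_counts),
         total_genes = summ$total_genes),
    file.path(out_dir, "prophage_summary.json"), auto_unbox = TRUE,
    digits = NA)

  qpcr_ratios <- NULL
  if (!is.null(config$qpcr_sim)) {
    say("stage qpcr: simulated Ct table")
    qs <- config$qpcr_sim
    qs$seed <- config$seed
    ct <- stage("qpcr", simulate_qpcr(qs))
    fit <- stage("qpcr", delta_delta_ct(ct, config$efficiency))
    qpcr_ratios <- fit$ratios
    res$qpcr <- fit
    write_qpcr_ratios(fit, file.path(out_dir, "qpcr_ratios.tsv"))
  } else if (!is.null(config$inputs$qpcr_ct)) {
    say("stage qpcr: Ct table %s", config$inputs$qpcr_ct)
    ct <- stage("qpcr", read_qpcr(config$inputs$qpcr_ct))
    fit <- stage("qpcr", delta_delta_ct(ct, config$efficiency))
    qpcr_ratios <- fit$ratios
    res$qpcr <- fit
    write_qpcr_ratios(fit, file.path(out_dir, "qpcr_ratios.tsv"))
  } else if (!is.null(config$inputs$qpcr_ratios)) {
    say("stage qpcr: precomputed ratio table")
    qpcr_ratios <- stage("qpcr",
                         utils::read.delim(config$inputs$qpcr_ratios,
                                           stringsAsFactors = FALSE))
  }
  if (!is.null(qpcr_ratios)) {
    res$fold_classes <- classify_folds(qpcr_ratios, config$thresholds)
  }

  summary_json <- list(prophage_fraction = summ$prophage_fraction,
                       per_prophage_counts = as.list(
                         summ$per_prophage_counts),
                       top_increased_level =
                         if (nrow(inc_top)) max(inc_top$level) else NULL,
                       min_decreased_level =
                         if (!is.null(res$ranked_decreased) &&
                             nrow(res$ranked_decreased))
                           min(res$ranked_decreased$level) else NULL,
                       fold_classes = res$fold_classes)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(package = "occutile",
                   version = as.character(utils::packageVersion("occutile")),
                   seed = config$seed,
                   config = config_fingerprint(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(res)
}

## stable hash of the configuration, for the output manifest
config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}
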