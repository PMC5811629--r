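#' Per-probe occupancy track
#'
#' Holds one value per probe of a grid: raw fluorescence for a single
#' channel (`kind = "channel"`, e.g. Cy3 for wild type or Cy5 for the
#' mutant) or a dimensionless mutant/wild-type ratio
#' (`kind = "ratio"`).
#'
#' @param values Numeric vector, one value per probe.
#' @param grid The [build_probe_grid()] the values live on.
#' @param kind `"channel"` or `"ratio"`.
#' @return Object of class `occupancy_track`.
#' @export
occupancy_track <- function(values, grid, kind = c("channel", "ratio")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "probe_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$count) {
    stop(sprintf("track has %d values but the grid has %d probes",
                 length(values), grid$count))
  }
  if (kind == "channel" && any(values < 0, na.rm = TRUE)) {
    stop("channel intensities must be >= 0")
  }
  if (kind == "ratio" && any(values <= 0, na.rm = TRUE)) {
    stop("ratio values must be > 0")
  }
  structure(list(values = values, grid = grid, kind = kind),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("<occupancy_track> %s, %d probes; median %.3g\n",
              x$kind, length(x$values), stats::median(x$values)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$grid$starts, b$grid$starts) &&
    a$grid$probe_length == b$grid$probe_length
}

#' Normalize the two channels of a co-hybridized array
#'
#' `method = "median-ratio"` rescales the mutant channel so that the
#' genome-wide median of the per-probe mutant/wild-type ratio is 1.
#' Because differential regions cover a small minority of probes, the
#' median is a robust estimate of the neutral dye and loading bias.
#' `method = "none"` returns the inputs unchanged (the analysis can be
#' run exactly as scanned).
#'
#' @param wt,mut Channel [occupancy_track()]s on the same grid.
#' @param method `"median-ratio"` (default) or `"none"`.
#' @return List with elements `wt` and `mut` (normalized tracks) and
#'   `scale` (the factor applied to the mutant channel).
#' @export
normalize_channels <- function(wt, mut, method = c("median-ratio", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(wt, "occupancy_track"), inherits(mut, "occupancy_track"))
  if (wt$kind != "channel" || mut$kind != "channel") {
    stop("normalize_channels expects channel tracks")
  }
  if (!same_grid(wt, mut)) stop("tracks are on different grids")
  if (all(wt$values == 0) || all(mut$values == 0)) {
    stop("cannot normalize an all-zero channel")
  }
  if (method == "none") {
    return(list(wt = wt, mut = mut, scale = 1))
  }
  ok <- wt$values > 0 & mut$values > 0
  if (!any(ok)) stop("no probe with positive intensity in both channels")
  m <- stats::median(mut$values[ok] / wt$values[ok])
  scaled <- occupancy_track(mut$values / m, mut$grid, "channel")
  list(wt = wt, mut = scaled, scale = 1 / m)
}

#' Per-probe mutant/wild-type occupancy ratio
#'
#' The ratio track is the quantity plotted along the genome in a
#' two-color ChIP-chip experiment: values above 1 mean the mutant
#' polymerase occupies the probe more than the wild type.  A pseudocount
#' stabilizes ratios at background probes where intensities approach
#' zero.  Ratios are kept on the linear scale because the peak-calling
#' cutoffs (5 and 0.2 by default) are linear.
#'
#' @param mut,wt Channel [occupancy_track()]s on the same grid.
#' @param pseudocount Intensity units added to both channels
#'   (default 1).
#' @return An [occupancy_track()] with `kind = "ratio"`.
#' @examples
#' g <- build_probe_grid(genome_spec(1050))
#' wt <- occupancy_track(rep(2, 10), g)
#' mut <- occupancy_track(rep(10, 10), g)
#' probe_ratio(mut, wt, pseudocount = 0)$values   # all 5
#' @export
probe_ratio <- function(mut, wt, pseudocount = 1) {
  stopifnot(inherits(wt, "occupancy_track"), inherits(mut, "occupancy_track"))
  if (wt$kind != "channel" || mut$kind != "channel") {
    stop("probe_ratio expects channel tracks")
  }
  if (!same_grid(wt, mut)) stop("tracks are on different grids")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  denom <- wt$values + pseudocount
  if (any(denom == 0)) {
    stop("zero wild-type intensity plus pseudocount at probe ",
         which(denom == 0)[1L])
  }
  occupancy_track((mut$values + pseudocount) / denom, wt$grid, "ratio")
}

#' Read or write a probe track as TSV
#'
#' The dialect is `probe_index start end value` with a header line;
#' `probe_index` is 1-based, `start`/`end` are the probe's genomic bp.
#'
#' @param track An [occupancy_track()].
#' @param path Output path.
#' @return `track`, invisibly.
#' @export
write_track <- function(track, path) {
  iv <- probe_intervals(track$grid)
  utils::write.table(
    data.frame(probe_index = seq_along(track$values),
               start = iv[, "start"], end = iv[, "end"],
               value = track$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(track)
}

#' @param path TSV written by [write_track()].
#' @param grid The grid the track belongs to.
#' @param kind `"channel"` or `"ratio"`.
#' @rdname write_track
#' @export
read_track <- function(path, grid, kind = "channel") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_index", "value") %in% names(tab))) {
    stop("malformed track TSV (need probe_index and value columns): ", path)
  }
  occupancy_track(tab$value[order(tab$probe_index)], grid, kind)
}
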