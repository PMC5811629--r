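#' Call increased- and decreased-occupancy peaks from a ratio track
#'
#' A peak is a maximal run of consecutive probes whose mutant/wild-type
#' ratio is at or above `cutoff_up` (increased occupancy) or at or below
#' `cutoff_down` (decreased occupancy).  Because a sonicated ChIP
#' fragment of typical size always hybridizes to at least two probes of
#' the grid, runs with fewer than `min_probes` qualifying probes are
#' discarded as background noise.  `max_gap` sub-threshold probes may be
#' bridged inside a run (default 0: strictly consecutive).  On circular
#' genomes a run crossing the origin is reported as a single wrapped
#' peak.
#'
#' Threshold comparisons are inclusive (`>=` / `<=`).
#'
#' @param ratio An [occupancy_track()] of `kind = "ratio"`.
#' @param cutoff_up Lower bound for increased-occupancy probes
#'   (default 5).
#' @param cutoff_down Upper bound for decreased-occupancy probes
#'   (default 0.2 = 1/5).
#' @param min_probes Minimum qualifying probes per peak (default 2).
#' @param max_gap Sub-threshold probes tolerated inside a run
#'   (default 0).
#' @return Object of class `peak_set`; `as.data.frame()` yields one row
#'   per peak with columns `peak_id`, `first_probe`, `last_probe`
#'   (1-based probe indices; `first_probe > last_probe` for a wrapped
#'   peak), `start`, `end` (genomic bp of the probe span), `direction`,
#'   `n_probes`, `wraps`, `level` (`NA` until quantified).
#' @examples
#' g <- build_probe_grid(genome_spec(1050))
#' r <- occupancy_track(c(1, 6, 7, 1, 1, 0.1, 0.1, 0.1, 1, 1), g, "ratio")
#' call_peaks(r)
#' @export
call_peaks <- function(ratio, cutoff_up = 5, cutoff_down = 0.2,
                       min_probes = 2, max_gap = 0) {
  stopifnot(inherits(ratio, "occupancy_track"))
  if (ratio$kind != "ratio") stop("call_peaks expects a ratio track")
  if (!(cutoff_up > 1 && cutoff_down < 1 && cutoff_down > 0)) {
    stop("need cutoff_up > 1 > cutoff_down > 0")
  }
  up <- find_runs(ratio$values >= cutoff_up, min_probes, max_gap,
                  circular = is_full_circle(ratio$grid))
  dn <- find_runs(ratio$values <= cutoff_down, min_probes, max_gap,
                  circular = is_full_circle(ratio$grid))
  build_peak_set(up, dn, ratio)
}

## does the grid tile the whole circular genome, so probe `count` is
## adjacent to probe 1 across the origin?
is_full_circle <- function(grid) {
  grid$genome$circular && grid$count * grid$period >= grid$genome$length
}

## Maximal gap-tolerant runs over a logical vector.  A run starts and ends
## on a TRUE probe, internal FALSE stretches are <= max_gap long, and it
## contains >= min_true TRUE probes.  Returns a data.frame
## (first, last, n_true, wraps); for wrapped runs first > last.
find_runs <- function(hit, min_true, max_gap, circular = FALSE) {
  idx <- which(hit)
  empty <- data.frame(first = integer(), last = integer(),
                      n_true = integer(), wraps = logical())
  if (!length(idx)) return(empty)
  n <- length(hit)
  brk <- which(diff(idx) > max_gap + 1)
  first <- idx[c(1L, brk + 1L)]
  last <- idx[c(brk, length(idx))]
  runs <- data.frame(first = first, last = last,
                     n_true = vapply(seq_along(first), function(i) {
                       sum(hit[first[i]:last[i]])
                     }, integer(1)),
                     wraps = FALSE)
  if (circular && nrow(runs) >= 1) {
    gap_around <- (n - runs$last[nrow(runs)]) + (runs$first[1L] - 1L)
    if (nrow(runs) > 1 && gap_around <= max_gap) {
      ## the last run continues across the origin into the first
      head <- runs[1L, ]
      tail <- runs[nrow(runs), ]
      merged <- data.frame(first = tail$first, last = head$last,
                           n_true = head$n_true + tail$n_true,
                           wraps = TRUE)
      runs <- rbind(merged, runs[-c(1L, nrow(runs)), ])
    } else if (nrow(runs) == 1 && runs$first == 1L && runs$last == n &&
               gap_around <= max_gap) {
      ## entire genome qualifies: single non-wrapped full-cover run
    }
  }
  runs <- runs[runs$n_true >= min_true, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

build_peak_set <- function(up, dn, ratio) {
  grid <- ratio$grid
  one <- function(runs, direction) {
    if (!nrow(runs)) return(NULL)
    data.frame(first_probe = runs$first, last_probe = runs$last,
               direction = direction, n_probes = NA_integer_,
               wraps = runs$wraps, n_hit = runs$n_true)
  }
  pk <- rbind(one(up, "increased"), one(dn, "decreased"))
  if (is.null(pk)) pk <- data.frame(first_probe = integer(),
                                    last_probe = integer(),
                                    direction = character(),
                                    n_probes = integer(),
                                    wraps = logical(), n_hit = integer())
  probe_sets <- lapply(seq_len(nrow(pk)), function(i) {
    peak_probe_indices(pk$first_probe[i], pk$last_probe[i], pk$wraps[i],
                       grid$count)
  })
  pk$n_probes <- vapply(probe_sets, length, integer(1))
  iv <- probe_intervals(grid)
  if (nrow(pk)) {
    pk$start <- iv[pk$first_probe, "start"]
    pk$end <- pmin(iv[pk$last_probe, "end"], grid$genome$length)
  } else {
    pk$start <- numeric(0)
    pk$end <- numeric(0)
  }
  o <- order(pk$start, pk$end)
  pk <- pk[o, , drop = FALSE]
  probe_sets <- probe_sets[o]
  pk$peak_id <- sprintf("peak_%03d", seq_len(nrow(pk)))
  pk$level <- rep(NA_real_, nrow(pk))
  pk$method <- rep(NA_character_, nrow(pk))
  rownames(pk) <- NULL
  structure(list(peaks = pk[c("peak_id", "first_probe", "last_probe",
                              "start", "end", "direction", "n_probes",
                              "wraps", "level", "method")],
                 probe_sets = probe_sets, grid = grid),
            class = "peak_set")
}

peak_probe_indices <- function(first, last, wraps, count) {
  if (wraps) c(first:count, 1:last) else first:last
}

#' @export
print.peak_set <- function(x, ...) {
  pk <- x$peaks
  cat(sprintf("<peak_set> %d peak(s): %d increased, %d decreased\n",
              nrow(pk), sum(pk$direction == "increased"),
              sum(pk$direction == "decreased")))
  if (nrow(pk)) print(utils::head(pk, 10), ...)
  invisible(x)
}

#' @export
summary.peak_set <- function(object, ...) {
  pk <- object$peaks
  out <- list(n = nrow(pk),
              by_direction = table(pk$direction),
              quantified = !all(is.na(pk$level)),
              level_range = if (!all(is.na(pk$level)))
                range(pk$level, na.rm = TRUE) else NULL)
  class(out) <- "summary.peak_set"
  out
}

#' @export
print.summary.peak_set <- function(x, ...) {
  cat(sprintf("peak set: %d peaks\n", x$n))
  print(x$by_direction)
  if (x$quantified) {
    cat(sprintf("levels in [%.3g, %.3g]\n", x$level_range[1], x$level_range[2]))
  }
  invisible(x)
}

#' @export
as.data.frame.peak_set <- function(x, ...) x$peaks

#' Quantify peaks by combined fluorescence
#'
#' The combined level of a peak summarizes the total polymerase binding
#' over all probes of the peak.  The default `"ratio-of-sums"` divides
#' the summed mutant fluorescence by the summed wild-type fluorescence
#' across the peak's probes; `"sum-ratio"` averages the per-probe
#' ratios.  The two agree when the wild-type signal is flat across the
#' peak and can diverge otherwise, which is why the method used is
#' recorded with the level.
#'
#' @param peaks A [call_peaks()] result.
#' @param wt,mut Channel [occupancy_track()]s on the peak grid.
#' @param method `"ratio-of-sums"` (default) or `"sum-ratio"`.
#' @return The `peak_set` with `level` and `method` filled in.
#' @export
quantify_peaks <- function(peaks, wt, mut,
                           method = c("ratio-of-sums", "sum-ratio")) {
  method <- match.arg(method)
  stopifnot(inherits(peaks, "peak_set"),
            inherits(wt, "occupancy_track"), inherits(mut, "occupancy_track"))
  if (!same_grid(wt, mut)) stop("tracks are on different grids")
  pk <- peaks$peaks
  lv <- vapply(seq_len(nrow(pk)), function(i) {
    ii <- peaks$probe_sets[[i]]
    w <- wt$values[ii]
    m <- mut$values[ii]
    if (method == "ratio-of-sums") {
      if (sum(w) == 0) stop("zero wild-type signal in ", pk$peak_id[i])
      sum(m) / sum(w)
    } else {
      if (any(w == 0)) stop("zero wild-type probe in ", pk$peak_id[i])
      mean(m / w)
    }
  }, numeric(1))
  peaks$peaks$level <- lv
  peaks$peaks$method <- rep(method, nrow(pk))
  peaks
}

#' Rank peaks the way occupancy tables are printed
#'
#' Increased-occupancy peaks are listed in decreasing order of level (the
#' strongest gain first); decreased-occupancy peaks in increasing order
#' (the strongest loss first).  Ties are broken by genomic start.
#'
#' @param peaks A quantified [quantify_peaks()] result, or a data.frame
#'   with `level` and `start` columns.
#' @param direction `"increased"` or `"decreased"`.
#' @return data.frame of the ranked peaks of that direction.
#' @export
rank_peaks <- function(peaks, direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  pk <- if (inherits(peaks, "peak_set")) peaks$peaks else
    as.data.frame(peaks)
  if ("direction" %in% names(pk)) {
    pk <- pk[pk$direction == direction, , drop = FALSE]
  }
  if (any(is.na(pk$level))) stop("peaks must be quantified before ranking")
  if (is.null(pk$start)) pk$start <- seq_len(nrow(pk))
  o <- if (direction == "increased") order(-pk$level, pk$start) else
    order(pk$level, pk$start)
  pk <- pk[o, , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Write a peak table as TSV
#'
#' Dialect: `peak_id start end direction n_probes level method`.
#'
#' @param peaks A `peak_set` or peak data.frame.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  pk <- if (inherits(peaks, "peak_set")) peaks$peaks else as.data.frame(peaks)
  utils::write.table(
    pk[c("peak_id", "start", "end", "direction", "n_probes", "level",
         "method")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(peaks)
}
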