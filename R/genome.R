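#' Describe a (possibly circular) bacterial genome axis
#'
#' All coordinates in the package are 0-based, half-open `[start, end)`
#' base-pair intervals on a single replicon.  GFF3 input/output converts
#' to and from that format's 1-based inclusive convention; BED passes
#' through unchanged.
#'
#' @param length Genome length in base pairs (positive integer).
#' @param circular Logical; is the replicon circular?  Bacterial
#'   chromosomes usually are.
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(4641652)            # an E. coli K-12 sized chromosome
#' genome_spec(5e5, circular = TRUE)
#' @export
genome_spec <- function(length, circular = TRUE) {
  length <- as.numeric(length)
  if (length(length) != 1L || !is.finite(length) || length < 1 ||
      length != floor(length)) {
    stop("genome length must be a single positive integer")
  }
  structure(list(length = length, circular = isTRUE(circular)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %s bp, %s\n", format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

## Check that a set of intervals lies within the genome; intervals are
## 0-based half-open.  Returns invisibly or stops with `what` in the message.
check_intervals <- function(start, end, genome, what = "interval") {
  bad <- which(!(start >= 0 & start < end & end <= genome$length))
  if (length(bad)) {
    stop(sprintf("%s %d out of genome bounds: [%s, %s) on a %s bp genome",
                 what, bad[1L], start[bad[1L]], end[bad[1L]], genome$length))
  }
  invisible(TRUE)
}

## Split a possibly wrap-around interval on a circular genome into one or two
## records with 0 <= start < end <= length.
normalize_interval <- function(start, end, genome) {
  L <- genome$length
  if (start < end && end <= L) {
    return(data.frame(start = start, end = end))
  }
  if (!genome$circular) {
    stop("interval exceeds the bounds of a linear genome")
  }
  start <- start %% L
  end <- end %% L
  if (end == 0) end <- L
  if (start < end) {
    data.frame(start = start, end = end)
  } else {
    data.frame(start = c(start, 0), end = c(L, end))
  }
}

#' Build a regular tiling-array probe grid
#'
#' Models arrays whose probes of fixed length start every `period` base
#' pairs along the genome, such as a 43,450-feature array of 60-bp probes
#' spaced 105 bp apart on the E. coli chromosome.
#'
#' @param genome A [genome_spec()].
#' @param probe_length Probe length in bp (default 60).
#' @param period Distance between consecutive probe starts in bp
#'   (default 105).
#' @return An object of class `probe_grid` with fields `starts` (0-based
#'   probe start positions), `probe_length`, `period`, `count`, `genome`.
#' @examples
#' g <- genome_spec(1050)
#' build_probe_grid(g)$count     # 10 probes at 0, 105, ..., 945
#' @export
build_probe_grid <- function(genome, probe_length = 60, period = 105) {
  stopifnot(inherits(genome, "genome_spec"))
  probe_length <- as.integer(probe_length)
  period <- as.integer(period)
  if (probe_length < 1L || period < 1L) {
    stop("probe_length and period must be positive")
  }
  if (probe_length > genome$length) {
    stop("probe_length exceeds genome length")
  }
  if (genome$circular) {
    count <- floor(genome$length / period)
  } else {
    ## last probe must fit entirely on the axis
    count <- floor((genome$length - probe_length) / period) + 1
  }
  starts <- (seq_len(count) - 1) * period
  structure(list(starts = starts, probe_length = probe_length,
                 period = period, count = count, genome = genome),
            class = "probe_grid")
}

#' @export
print.probe_grid <- function(x, ...) {
  cat(sprintf("<probe_grid> %d probes of %d bp every %d bp (coverage %.1f%%)\n",
              x$count, x$probe_length, x$period,
              100 * x$probe_length / x$period))
  invisible(x)
}

## Probe intervals of a grid as a two-column matrix (0-based half-open).
## On circular genomes the last probe may run past the origin; its end is
## reported un-wrapped (> genome length) for arithmetic convenience.
probe_intervals <- function(grid) {
  cbind(start = grid$starts, end = grid$starts + grid$probe_length)
}

#' Minimum number of probes a DNA fragment can overlap
#'
#' For sonicated ChIP fragments hybridized to a periodic probe grid, the
#' worst-case placement determines how many probes any fragment is
#' guaranteed to touch.  A ~250-bp fragment on a 60-bp/105-bp grid always
#' overlaps at least two probes, which is why single-probe signals are
#' treated as background noise by the peak caller.
#'
#' @param fragment_length Fragment length in bp.
#' @param grid A [build_probe_grid()] result (only its `probe_length` and
#'   `period` are used; the grid is treated as infinitely periodic).
#' @return Integer: the minimum, over all placements, of the number of
#'   probes whose interval intersects the fragment interval.
#' @examples
#' grid <- build_probe_grid(genome_spec(1e5))
#' min_probes_overlapped(250, grid)   # 2
#' min_probes_overlapped(60, grid)    # 1
#' min_probes_overlapped(1, grid)     # 0 (fits in the 45-bp gap)
#' @export
min_probes_overlapped <- function(fragment_length, grid) {
  stopifnot(inherits(grid, "probe_grid"))
  L <- as.integer(fragment_length)
  if (L < 1L) stop("fragment_length must be >= 1")
  p <- grid$probe_length
  Tt <- grid$period
  ## by periodicity only offsets 0..period-1 matter; a probe k covers
  ## [k*T, k*T + p) and intersects fragment [x, x+L) iff
  ## k*T < x + L and k*T + p > x
  x <- 0:(Tt - 1L)
  hi <- floor((x + L - 1) / Tt)          # largest k with k*T <= x+L-1
  lo <- ceiling((x - p + 1) / Tt)        # smallest k with k*T >= x-p+1
  min(hi - lo + 1L)
}

#' Fraction of the genome covered by probes
#'
#' @param grid A [build_probe_grid()] result.
#' @return Fraction in `[0, 1]`: `probe_length / period` for a full
#'   periodic tiling.
#' @export
probe_coverage <- function(grid) {
  stopifnot(inherits(grid, "probe_grid"))
  min(1, grid$count * grid$probe_length / grid$genome$length)
}
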