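# Independent brute-force oracles used by the property and acceptance
# tests.  These deliberately share no code with the package internals.

# linear grid of m probes (60 bp @ 105 bp) on a non-circular axis
linear_grid <- function(m, probe_length = 60, period = 105) {
  build_probe_grid(genome_spec(m * period, circular = FALSE),
                   probe_length, period)
}

ratio_track <- function(values, circular = FALSE) {
  g <- if (circular) {
    build_probe_grid(genome_spec(length(values) * 105, circular = TRUE))
  } else {
    linear_grid(length(values))
  }
  occupancy_track(values, g, "ratio")
}

# exhaustive enumeration of maximal threshold runs on a linear track
# (max_gap = 0); returns list of c(first, last) probe-index pairs
oracle_runs <- function(hit, min_probes) {
  out <- list()
  i <- 1L
  n <- length(hit)
  while (i <= n) {
    if (hit[i]) {
      j <- i
      while (j < n && hit[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_probes) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# brute-force minimum probe overlap: slide a fragment over every offset
# of one period on an explicit probe layout and count intersections
oracle_min_overlap <- function(fragment_length, probe_length = 60,
                               period = 105) {
  n_probes <- 100
  starts <- (0:(n_probes - 1)) * period
  counts <- vapply(0:(period - 1), function(off) {
    x <- 40 * period + off   # away from the layout edges
    sum(starts < x + fragment_length & starts + probe_length > x)
  }, numeric(1))
  min(counts)
}

# brute-force pairwise interval overlap count (>= 1 bp), per subject
oracle_overlap_counts <- function(q_start, q_end, s_start, s_end) {
  vapply(seq_along(s_start), function(j) {
    sum(q_start < s_end[j] & q_end > s_start[j])
  }, numeric(1))
}
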