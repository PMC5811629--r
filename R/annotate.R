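#' Assign peaks to genes and prophages
#'
#' A peak whose midpoint falls inside an annotated ORF is classed
#' `"ORF-internal"`; otherwise it is a `"spacer"` (intergenic) peak and
#' is reported with the nearest gene within `max_spacer_dist` bp, if
#' any.  Independent of the gene call, a peak is tagged with the name of
#' any prophage its genomic span overlaps by at least one bp.  When a
#' peak straddles several genes, the gene with maximal bp overlap is
#' reported in `overlap_gene` as secondary metadata.
#'
#' @param peaks A [call_peaks()] (ideally [quantify_peaks()]) result.
#' @param ann A [genome_annotation()].
#' @param max_spacer_dist Maximum midpoint-to-gene distance (bp) for
#'   spacer assignment (default `Inf`).
#' @return data.frame: the peak table plus `gene`, `location_class`,
#'   `prophage`, `overlap_gene` columns.
#' @export
assign_peaks <- function(peaks, ann, max_spacer_dist = Inf) {
  stopifnot(inherits(ann, "genome_annotation"))
  pk <- if (inherits(peaks, "peak_set")) peaks$peaks else as.data.frame(peaks)
  genes <- ann$genes
  L <- ann$genome$length
  n <- nrow(pk)
  gene <- rep(NA_character_, n)
  klass <- rep(NA_character_, n)
  ovgene <- rep(NA_character_, n)
  mid <- numeric(n)
  for (i in seq_len(n)) {
    s <- pk$start[i]
    e <- pk$end[i]
    span <- if (!is.null(pk$wraps) && isTRUE(pk$wraps[i])) {
      (e + L - s) # wrapped width
    } else {
      e - s
    }
    m <- (s + span / 2) %% L
    mid[i] <- m
    inside <- which(genes$start <= m & m < genes$end)
    if (length(inside)) {
      ## midpoint in a gene: if several (shouldn't happen for ORFs),
      ## take the smallest containing gene
      j <- inside[which.min(genes$end[inside] - genes$start[inside])]
      gene[i] <- genes$name[j]
      klass[i] <- "ORF-internal"
    } else {
      klass[i] <- "spacer"
      d <- pmax(genes$start - m, m - genes$end, 0)
      if (nrow(genes) && min(d) <= max_spacer_dist) {
        gene[i] <- genes$name[which.min(d)]
      }
    }
    ov <- interval_overlap_bp(s, e, isTRUE(pk$wraps[i]), genes$start,
                              genes$end, L)
    if (any(ov > 0)) ovgene[i] <- genes$name[which.max(ov)]
  }
  prophage <- rep(NA_character_, n)
  if (nrow(ann$prophages)) {
    for (i in seq_len(n)) {
      ov <- interval_overlap_bp(pk$start[i], pk$end[i],
                                isTRUE(pk$wraps[i]),
                                ann$prophages$start, ann$prophages$end, L)
      if (any(ov > 0)) prophage[i] <- ann$prophages$name[which.max(ov)]
    }
  }
  pk$gene <- gene
  pk$location_class <- klass
  pk$prophage <- prophage
  pk$overlap_gene <- ovgene
  pk
}

## bp overlap of the (possibly origin-wrapping) interval [s, e) with each
## interval in (starts, ends); all 0-based half-open on a genome of length L
interval_overlap_bp <- function(s, e, wraps, starts, ends, L) {
  if (!length(starts)) return(numeric(0))
  piece <- function(a, b) pmax(0, pmin(b, ends) - pmax(a, starts))
  if (wraps) piece(s, L) + piece(0, e) else piece(s, e)
}

#' Prophage content of a ranked gene table
#'
#' Given a table of genes ranked by occupancy level (one row per gene,
#' with a `prophage` column that is empty/`NA` for host genes), counts
#' how many of the top `top_n` genes lie in each prophage and what
#' integer percentage of them lie in any prophage.
#'
#' @param ranked_genes data.frame with a `prophage` column; rows already
#'   ordered by rank.
#' @param top_n How many top rows to summarize (default: all rows).
#' @return List of class `prophage_summary`: `per_prophage_counts`
#'   (named integer vector, decreasing), `prophage_fraction` (integer
#'   percent), `total_genes`.
#' @export
summarize_prophages <- function(ranked_genes, top_n = nrow(ranked_genes)) {
  ranked_genes <- as.data.frame(ranked_genes)
  if (!"prophage" %in% names(ranked_genes)) {
    stop("ranked gene table needs a prophage column")
  }
  if (nrow(ranked_genes) < top_n) {
    stop("table has fewer rows than top_n")
  }
  top <- ranked_genes[seq_len(top_n), , drop = FALSE]
  ph <- top$prophage
  ph[ph %in% c("", "-")] <- NA
  counts <- sort(table(ph[!is.na(ph)]), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  frac <- if (top_n > 0) round(100 * sum(!is.na(ph)) / top_n) else 0
  structure(list(per_prophage_counts = counts,
                 prophage_fraction = as.integer(frac),
                 total_genes = as.integer(top_n)),
            class = "prophage_summary")
}

#' @export
print.prophage_summary <- function(x, ...) {
  cat(sprintf("%d%% of %d ranked genes lie in prophages\n",
              x$prophage_fraction, x$total_genes))
  if (length(x$per_prophage_counts)) {
    cat(paste(sprintf("  %s: %d gene(s)", names(x$per_prophage_counts),
                      x$per_prophage_counts), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Count external sites overlapping each prophage
#'
#' Each site is counted once per prophage it touches by at least one bp
#' (a site spanning two adjacent prophages contributes to both).  Used
#' to ask how many constitutive promoters or silencer binding sites fall
#' inside each cryptic prophage.
#'
#' @param track A [site_track()].
#' @param prophages data.frame with `name`, `start`, `end` columns (or a
#'   [genome_annotation()], whose prophage table is used).
#' @return Named integer vector of site counts, one entry per prophage.
#' @export
overlap_sites <- function(track, prophages) {
  stopifnot(inherits(track, "site_track"))
  if (inherits(prophages, "genome_annotation")) {
    prophages <- prophages$prophages
  }
  prophages <- as.data.frame(prophages)
  counts <- stats::setNames(integer(nrow(prophages)), prophages$name)
  if (!nrow(track$sites) || !nrow(prophages)) return(counts)
  q <- IRanges::IRanges(start = track$sites$start + 1,
                        end = track$sites$end)
  s <- IRanges::IRanges(start = prophages$start + 1, end = prophages$end)
  hits <- IRanges::findOverlaps(q, s)
  tab <- table(factor(S4Vectors::subjectHits(hits),
                      levels = seq_len(nrow(prophages))))
  stats::setNames(as.integer(tab), prophages$name)
}
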