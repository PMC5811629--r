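#' Assemble a genome annotation from data frames
#'
#' The annotation bundles gene (ORF) intervals, cryptic prophage
#' intervals and optional external site tracks (e.g. constitutive
#' promoters or nucleoid-silencer binding sites mapped by genomic SELEX)
#' on one genome axis.  Each gene overlapping a prophage by at least one
#' bp is linked to it; full containment is recorded in the `contained`
#' column so partially overlapping genes remain identifiable.
#'
#' @param genes data.frame with columns `name`, `start`, `end` (0-based
#'   half-open bp) and optionally `strand` (`+`/`-`).
#' @param prophages data.frame with columns `name`, `start`, `end`;
#'   intervals must be pairwise non-overlapping.
#' @param genome A [genome_spec()].
#' @param sites Optional named list of site tracks built by
#'   [site_track()].
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, prophages, genome, sites = list()) {
  stopifnot(inherits(genome, "genome_spec"))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  prophages <- as.data.frame(prophages, stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(genes))) {
    stop("genes table needs columns name, start, end")
  }
  if (nrow(prophages) && !all(need %in% names(prophages))) {
    stop("prophage table needs columns name, start, end")
  }
  if (is.null(genes$strand)) genes$strand <- "+"
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  if (anyDuplicated(genes$name)) {
    stop("duplicate gene name: ", genes$name[duplicated(genes$name)][1L])
  }
  check_intervals(genes$start, genes$end, genome, "gene")
  if (nrow(prophages)) {
    prophages$start <- as.numeric(prophages$start)
    prophages$end <- as.numeric(prophages$end)
    if (anyDuplicated(prophages$name)) stop("duplicate prophage name")
    check_intervals(prophages$start, prophages$end, genome, "prophage")
    o <- order(prophages$start)
    ps <- prophages[o, ]
    if (nrow(ps) > 1 && any(ps$start[-1] < ps$end[-nrow(ps)])) {
      stop("prophage intervals overlap")
    }
  }
  link <- link_to_prophage(genes$start, genes$end, prophages)
  genes$prophage <- link$name
  genes$contained <- link$contained
  structure(list(genome = genome, genes = genes, prophages = prophages,
                 sites = sites),
            class = "genome_annotation")
}

## For each query interval, the name of the prophage it overlaps (>= 1 bp)
## and whether the prophage fully contains it.  Prophages do not overlap,
## so an interval maps to at most one by maximal overlap.
link_to_prophage <- function(start, end, prophages) {
  n <- length(start)
  out <- list(name = rep(NA_character_, n), contained = rep(FALSE, n))
  if (!nrow(prophages) || n == 0L) return(out)
  q <- IRanges::IRanges(start = start + 1, end = end)
  s <- IRanges::IRanges(start = prophages$start + 1, end = prophages$end)
  hits <- IRanges::findOverlaps(q, s)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
    best <- tapply(seq_along(qh), qh, function(i) i[which.max(ov[i])])
    idx <- unlist(best, use.names = FALSE)
    out$name[qh[idx]] <- prophages$name[sh[idx]]
    out$contained[qh[idx]] <- start[qh[idx]] >= prophages$start[sh[idx]] &
      end[qh[idx]] <= prophages$end[sh[idx]]
  }
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d genes, %d prophages, %d site track(s) on %s bp genome\n",
    nrow(x$genes), nrow(x$prophages), length(x$sites),
    format(x$genome$length, big.mark = ",")))
  invisible(x)
}

#' A track of scored genomic sites
#'
#' Used for externally mapped interval tracks such as RpoD holoenzyme
#' constitutive promoters or H-NS silencer binding sites.
#'
#' @param label Track label, e.g. `"promoter"` or `"silencer"`.
#' @param sites data.frame with columns `start`, `end` (0-based half-open)
#'   and optionally `score` (non-negative; defaults to 1).
#' @return Object of class `site_track`.
#' @export
site_track <- function(label, sites) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("start", "end") %in% names(sites))) {
    stop("sites table needs columns start, end")
  }
  if (is.null(sites$score)) sites$score <- rep(1, nrow(sites))
  if (any(sites$score < 0)) stop("site scores must be >= 0")
  if (nrow(sites) && any(sites$start >= sites$end)) {
    stop("site intervals must satisfy start < end")
  }
  structure(list(label = as.character(label), sites = sites),
            class = "site_track")
}

#' Read a genome annotation from standard files
#'
#' Genes are read from GFF3 (1-based inclusive coordinates, converted on
#' input) or from a TSV with header `name start end strand prophage`;
#' prophages from BED (0-based half-open, passed through) or a TSV with
#' header `name start end`.  Format is chosen from the file extension
#' (`.gff`/`.gff3` vs `.tsv`/`.txt`; `.bed` vs TSV).
#'
#' @param gene_path Path to the gene file.
#' @param prophage_path Path to the prophage file, or `NULL` for none.
#' @param genome A [genome_spec()].
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gene_path, prophage_path = NULL, genome) {
  genes <- read_gene_table(gene_path)
  prophages <- if (is.null(prophage_path)) {
    data.frame(name = character(), start = numeric(), end = numeric())
  } else {
    read_interval_table(prophage_path)
  }
  genome_annotation(genes, prophages, genome)
}

read_gene_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    nm <- gr$Name
    if (is.null(nm)) nm <- gr$ID
    if (is.null(nm) || anyNA(nm)) {
      stop("GFF3 gene records must carry a Name or ID attribute: ", path)
    }
    data.frame(name = as.character(nm),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                               "-", "+"),
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "start", "end")
    if (!all(need %in% names(tab))) {
      stop("malformed gene TSV (need header name start end strand): ", path)
    }
    bad <- which(is.na(tab$start) | is.na(tab$end))
    if (length(bad)) {
      stop(sprintf("malformed gene record at line %d of %s",
                   bad[1L] + 1L, path))
    }
    if (is.null(tab$strand)) tab$strand <- "+"
    tab[c("name", "start", "end", "strand")]
  }
}

read_interval_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(name = as.character(gr$name),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("name", "start", "end") %in% names(tab))) {
      stop("malformed interval TSV (need header name start end): ", path)
    }
    tab[c("name", "start", "end")]
  }
}

#' Read a site track from a BED or TSV file
#'
#' @param path BED file (`name`/`score` columns optional) or TSV with
#'   header `start end score`.
#' @param label Track label; defaults to the file base name.
#' @return A [site_track()].
#' @export
read_sites <- function(path, label = NULL) {
  if (is.null(label)) {
    label <- tools::file_path_sans_ext(basename(path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    score <- gr$score
    if (is.null(score)) score <- rep(1, length(gr))
    score[is.na(score)] <- 1
    sites <- data.frame(start = GenomicRanges::start(gr) - 1,
                        end = GenomicRanges::end(gr), score = score)
  } else {
    sites <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  site_track(label, sites)
}

#' Write a genome annotation back to files
#'
#' Inverse of [read_annotation()]: genes to GFF3 or TSV, prophages to BED
#' or TSV, chosen by extension.  Coordinates round-trip exactly in every
#' dialect.
#'
#' @param ann A [genome_annotation()].
#' @param gene_path,prophage_path Output paths (`prophage_path` may be
#'   `NULL`).
#' @return `ann`, invisibly.
#' @export
write_annotation <- function(ann, gene_path, prophage_path = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  ext <- tolower(tools::file_ext(gene_path))
  if (ext %in% c("gff", "gff3")) {
    gr <- GenomicRanges::GRanges(
      seqnames = "genome",
      ranges = IRanges::IRanges(start = g$start + 1, end = g$end),
      strand = g$strand)
    gr$source <- "occutile"
    gr$type <- "gene"
    gr$Name <- g$name
    gr$ID <- g$name
    rtracklayer::export(gr, gene_path, format = "gff3")
  } else {
    out <- g[c("name", "start", "end", "strand")]
    out$prophage <- ifelse(is.na(g$prophage), "", g$prophage)
    utils::write.table(out, gene_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(prophage_path) && nrow(ann$prophages)) {
    p <- ann$prophages
    if (tolower(tools::file_ext(prophage_path)) == "bed") {
      ## BED is 0-based half-open already
      bed <- data.frame(chrom = "genome", start = p$start, end = p$end,
                        name = p$name)
      utils::write.table(bed, prophage_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      utils::write.table(p[c("name", "start", "end")], prophage_path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(ann)
}
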