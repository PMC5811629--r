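#' Build a replicated qPCR Ct table
#'
#' @param records data.frame with columns `gene`, `strain` (values
#'   `"wild-type"` / `"mutant"`), `replicate`, `ct` (threshold cycles,
#'   > 0).
#' @param reference_gene Name of the normalization gene, typically the
#'   16S rRNA gene (default `"16S"`).
#' @return Object of class `qpcr_table`.
#' @export
qpcr_table <- function(records, reference_gene = "16S") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("gene", "strain", "replicate", "ct")
  if (!all(need %in% names(records))) {
    stop("Ct table needs columns gene, strain, replicate, ct")
  }
  if (!all(records$strain %in% c("wild-type", "mutant"))) {
    stop('strain must be "wild-type" or "mutant"')
  }
  if (any(records$ct <= 0)) stop("Ct values must be > 0")
  for (st in c("wild-type", "mutant")) {
    if (!any(records$gene == reference_gene & records$strain == st)) {
      stop("reference gene ", reference_gene, " missing for strain ", st)
    }
  }
  structure(list(records = records, reference_gene = reference_gene),
            class = "qpcr_table")
}

#' @export
print.qpcr_table <- function(x, ...) {
  cat(sprintf("<qpcr_table> %d Ct records, %d gene(s), reference %s\n",
              nrow(x$records), length(unique(x$records$gene)),
              x$reference_gene))
  invisible(x)
}

#' Read a Ct table from TSV
#'
#' Dialect: header `gene strain replicate ct`.
#'
#' @param path TSV path.
#' @param reference_gene Normalization gene name.
#' @return A [qpcr_table()].
#' @export
read_qpcr <- function(path, reference_gene = "16S") {
  qpcr_table(utils::read.delim(path, stringsAsFactors = FALSE),
             reference_gene = reference_gene)
}

#' Relative expression by the threshold-cycle (delta-delta-Ct) method
#'
#' For each gene, replicate Ct values are first normalized to the
#' reference gene within the same strain and replicate
#' (dCt = Ct_gene - Ct_reference), then contrasted between strains
#' (ddCt = mean dCt(mutant) - mean dCt(wild-type)).  The relative mRNA
#' level of the mutant over the wild type is `efficiency^(-ddCt)`,
#' with perfect per-cycle doubling (`efficiency = 2`) by default.  The
#' standard deviation of the ratio is propagated from the replicate dCt
#' variances by the delta method on the log-efficiency scale:
#' `sd(ratio) = ratio * log(efficiency) * sd(ddCt)` with
#' `sd(ddCt)^2 = var(dCt_mut)/n_mut + var(dCt_wt)/n_wt`.
#'
#' @param table A [qpcr_table()].
#' @param efficiency Amplification factor per cycle (default 2).
#' @return Object of class `ddct_fit`; `as.data.frame()`/`coef()` give
#'   one row per gene with `ratio` (mutant/wild-type), `sd`,
#'   `reciprocal`, `n_wt`, `n_mut`.  The reference gene is excluded.
#' @examples
#' tab <- qpcr_table(data.frame(
#'   gene = rep(c("16S", "geneA"), each = 2),
#'   strain = rep(c("wild-type", "mutant"), 2),
#'   replicate = 1, ct = c(10, 10, 20, 19)))
#' coef(delta_delta_ct(tab))   # geneA ratio 2: one cycle earlier
#' @export
delta_delta_ct <- function(table, efficiency = 2.0) {
  stopifnot(inherits(table, "qpcr_table"))
  if (efficiency <= 1) stop("efficiency must be > 1")
  rec <- table$records
  ref <- rec[rec$gene == table$reference_gene, ]
  single_rep <- FALSE
  dct_of <- function(gene, strain) {
    g <- rec[rec$gene == gene & rec$strain == strain, ]
    r <- ref[ref$strain == strain, ]
    if (!nrow(g)) stop("no Ct records for ", gene, " in ", strain)
    ## replicate-matched normalization; fall back to the mean reference
    ## Ct when replicate ids do not pair up
    m <- match(g$replicate, r$replicate)
    refct <- ifelse(is.na(m), mean(r$ct), r$ct[m])
    g$ct - refct
  }
  genes <- setdiff(unique(rec$gene), table$reference_gene)
  rows <- lapply(genes, function(gn) {
    dwt <- dct_of(gn, "wild-type")
    dmu <- dct_of(gn, "mutant")
    ddct <- mean(dmu) - mean(dwt)
    ratio <- efficiency^(-ddct)
    if (length(dwt) < 2 || length(dmu) < 2) single_rep <<- TRUE
    v <- (if (length(dmu) > 1) stats::var(dmu) / length(dmu) else 0) +
      (if (length(dwt) > 1) stats::var(dwt) / length(dwt) else 0)
    sd <- ratio * log(efficiency) * sqrt(v)
    data.frame(gene = gn, ratio = ratio, sd = sd,
               reciprocal = 1 / ratio,
               n_wt = length(dwt), n_mut = length(dmu))
  })
  if (single_rep) {
    warning("single-replicate gene(s): sd reported as 0")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(ratios = out, efficiency = efficiency,
                 reference_gene = table$reference_gene),
            class = "ddct_fit")
}

#' @export
print.ddct_fit <- function(x, ...) {
  cat(sprintf(
    "<ddct_fit> %d gene(s), reference %s, efficiency %.2f per cycle\n",
    nrow(x$ratios), x$reference_gene, x$efficiency))
  print(utils::head(x$ratios, 10), ...)
  invisible(x)
}

#' @export
coef.ddct_fit <- function(object, ...) object$ratios

#' @export
as.data.frame.ddct_fit <- function(x, ...) x$ratios

#' @export
summary.ddct_fit <- function(object, thresholds = c(2, 4), ...) {
  out <- list(n = nrow(object$ratios),
              classes = classify_folds(object, thresholds),
              range = range(object$ratios$ratio))
  class(out) <- "summary.ddct_fit"
  out
}

#' @export
print.summary.ddct_fit <- function(x, ...) {
  cat(sprintf("%d genes; ratios in [%.3g, %.3g]\n", x$n, x$range[1],
              x$range[2]))
  cat(sprintf("  > 4-fold up: %d\n  2- to 4-fold up: %d\n  <= 2-fold: %d\n",
              x$classes$gt4, x$classes$gt2_le4, x$classes$le2))
  invisible(x)
}

#' Classify expression ratios into fold-change bands
#'
#' Counts genes more than `thresholds[2]`-fold up (strict `>`), genes
#' between `thresholds[1]` (exclusive) and `thresholds[2]` (inclusive),
#' and the remainder.  The three counts partition the input.
#'
#' @param ratios A [delta_delta_ct()] fit, or a numeric vector of
#'   ratios, or a data.frame with a `ratio` column.
#' @param thresholds Two ascending fold thresholds (default `c(2, 4)`).
#' @return List with integer counts `gt4`, `gt2_le4`, `le2` (named after
#'   the default thresholds).
#' @export
classify_folds <- function(ratios, thresholds = c(2, 4)) {
  r <- extract_ratios(ratios)
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    stop("thresholds must be two ascending values")
  }
  lo <- thresholds[1]
  hi <- thresholds[2]
  list(gt4 = sum(r > hi),
       gt2_le4 = sum(r > lo & r <= hi),
       le2 = sum(r <= lo))
}

extract_ratios <- function(ratios) {
  if (inherits(ratios, "ddct_fit")) return(ratios$ratios$ratio)
  if (is.data.frame(ratios)) {
    if (!"ratio" %in% names(ratios)) stop("need a ratio column")
    return(as.numeric(ratios$ratio))
  }
  as.numeric(ratios)
}

#' Reciprocal-ratio table
#'
#' For decreased-expression reporting, tables often print both the
#' wild-type-over-mutant fold and its mutant-over-wild-type reciprocal;
#' this computes the rounded reciprocal column.
#'
#' @param ratios As in [classify_folds()].
#' @param decimals Rounding for the reciprocal (default 4).
#' @return data.frame with `ratio` and `reciprocal` columns.
#' @examples
#' reciprocal_table(10.29)$reciprocal   # 0.0972
#' @export
reciprocal_table <- function(ratios, decimals = 4) {
  r <- extract_ratios(ratios)
  if (any(r <= 0)) stop("ratios must be > 0")
  data.frame(ratio = r, reciprocal = round(1 / r, decimals))
}

#' Write expression ratios as TSV
#'
#' Dialect: `gene ratio sd reciprocal`.
#'
#' @param fit A [delta_delta_ct()] fit.
#' @param path Output path.
#' @return `fit`, invisibly.
#' @export
write_qpcr_ratios <- function(fit, path) {
  stopifnot(inherits(fit, "ddct_fit"))
  utils::write.table(fit$ratios[c("gene", "ratio", "sd", "reciprocal")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fit)
}
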