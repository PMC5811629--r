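#' Bundled example tables from an RpoZ-deletion ChIP-chip study
#'
#' Four small TSV tables ship with the package, transcribing the ranked
#' results of a published-style experiment comparing RNA polymerase
#' occupancy and transcription between an E. coli K-12 wild type and its
#' rpoZ (omega subunit) deletion mutant:
#'
#' * `"increased"` — the top 30 genes by combined mutant/wild-type
#'   occupancy level (level >= cutoff 5), decreasing order; columns
#'   `gene level func prophage`.  A gene may appear twice when two
#'   distinct peaks fall inside it.
#' * `"decreased"` — the top 31 genes by decreased occupancy, increasing
#'   order of level.
#' * `"qpcr_increased"` — qRT-PCR mutant/wild-type mRNA ratios (± sd)
#'   for 17 genes selected from the increased list; columns
#'   `gene ratio sd func prophage`.
#' * `"qpcr_decreased"` — wild-type-over-mutant folds (`wt_fold` ± sd)
#'   and the reciprocal mutant/wild-type `ratio` for 10 genes; columns
#'   `designation gene wt_fold sd ratio func prophage`.
#'
#' Empty prophage fields mark host (non-prophage) genes and read as
#' `NA`.
#'
#' @param name One of `"increased"`, `"decreased"`, `"qpcr_increased"`,
#'   `"qpcr_decreased"`.
#' @return data.frame.
#' @examples
#' summarize_prophages(occ_example_table("increased"), top_n = 30)
#' @export
occ_example_table <- function(name = c("increased", "decreased",
                                       "qpcr_increased",
                                       "qpcr_decreased")) {
  name <- match.arg(name)
  file <- c(increased = "increased_occupancy_ranked.tsv",
            decreased = "decreased_occupancy_ranked.tsv",
            qpcr_increased = "qpcr_increased_ratios.tsv",
            qpcr_decreased = "qpcr_decreased_ratios.tsv")[[name]]
  path <- system.file("extdata", file, package = "occutile",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = NA)
  if ("prophage" %in% names(tab)) {
    tab$prophage[tab$prophage == ""] <- NA
  }
  tab
}
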