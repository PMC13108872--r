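#' Bundled pan-cancer cohort summary
#'
#' The package ships a small plain-text summary of the public TCGA
#' pan-cancer cohort the full-scale pipeline targets: per cancer type, the
#' total number of tumor samples and the number with each modality
#' (copy-number, RNA-seq, protein array, histopathology embedding)
#' available, plus the complete/incomplete breakdown. Useful for
#' bookkeeping checks and for configuring realistic missingness rates.
#'
#' @return data.frame with one row per cancer type; all columns are
#'   counts.
#' @examples
#' summary <- readCohortSummary()
#' sum(summary$total)
#' @export
readCohortSummary <- function() {
  path <- system.file("extdata", "tcga_cohort_summary.tsv",
                      package = "coherentgen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readCohortSummary
#' @return `readSplitSizes()`: named integer vector with the train /
#'   validation / test sizes of the full-scale stratified split.
#' @export
readSplitSizes <- function() {
  path <- system.file("extdata", "tcga_split_sizes.tsv",
                      package = "coherentgen", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$size), df$partition)
}
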