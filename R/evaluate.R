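# Evaluation harness: correlate per-construct siRNA counts with the
# experimentally observed silencing effect (mean log2 relative
# susceptibility index, a fixed wet-lab-derived vector).

#' Pearson correlation coefficient
#'
#' Thin wrapper over [stats::cor()] with the domain contract: vectors of
#' equal length at least 3, neither constant.
#'
#' @param x,y Numeric vectors.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Published construct evaluation table
#'
#' Per-construct siRNA hit counts (total / HS-mode / HE-mode) on the
#' barley *HvMlo* target for the molecular-clock and window construct
#' series, together with the mean log2 relative susceptibility index
#' (`mean_si`) observed in the transient silencing assay.
#'
#' @param path Optional path to an alternative table (same columns).
#' @return `data.frame` with columns `construct`, `total`, `hs`, `he`,
#'   `mean_si`.
#' @export
construct_evaluation <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mlo_construct_evaluation.tsv",
                                package = "rnaitrigger")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Correlate count columns with the silencing index
#'
#' @param tab A table as returned by [construct_evaluation()] (or the same
#'   columns with recomputed counts).
#' @param count_cols Count columns to correlate (default
#'   `c("total", "hs", "he")`).
#' @return Named numeric vector of Pearson correlations of each count
#'   column with `mean_si`.
#' @examples
#' round(evaluate_counts(construct_evaluation()), 2)
#' @export
evaluate_counts <- function(tab, count_cols = c("total", "hs", "he")) {
  vapply(count_cols, function(cc) pearson_r(tab[[cc]], tab$mean_si),
         numeric(1))
}
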