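#' Two-condition peak count matrices
#'
#' Holds per-peak, per-sample ATAC-seq read counts together with the
#' condition label of each sample (`"target"`, the state of interest, vs
#' `"reference"`).
#'
#' @param counts Non-negative integer matrix, peaks x samples, with rownames
#'   (peak ids) and colnames (sample ids).
#' @param condition Named character vector mapping each sample id to
#'   `"target"` or `"reference"`.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count_matrix: counts must be a matrix with peak rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("count_matrix: counts must be non-negative integers")
  if (!all(colnames(counts) %in% names(condition)))
    stopf("count_matrix: every sample needs a condition label")
  condition <- condition[colnames(counts)]
  if (!all(condition %in% c("target", "reference")))
    stopf("count_matrix: conditions must be 'target' or 'reference'")
  if (!all(c("target", "reference") %in% condition))
    stopf("count_matrix: need at least one sample per condition")
  structure(list(counts = counts, condition = condition), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d peaks x %d samples (%d target, %d reference)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "target"), sum(x$condition == "reference")))
  invisible(x)
}

#' Read a count matrix TSV plus sample-condition table
#'
#' The matrix file has a header row, first column `peak_id`, remaining
#' columns one per sample. The condition file has two tab-separated columns:
#' sample id and condition (`target`/`reference`), no header required.
#'
#' @param path Count matrix TSV path.
#' @param condition_path Sample-to-condition TSV path.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, condition_path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  cond <- utils::read.delim(condition_path, header = FALSE)
  if (identical(tolower(as.character(cond[1, ])), c("sample", "condition")))
    cond <- cond[-1, , drop = FALSE]
  count_matrix(counts, stats::setNames(as.character(cond[[2]]),
                                       as.character(cond[[1]])))
}

#' Write a count matrix and its condition table
#'
#' @param cm A [count_matrix()].
#' @param path Count matrix TSV path.
#' @param condition_path Sample-to-condition TSV path.
#' @export
write_count_matrix <- function(cm, path, condition_path) {
  stopifnot(inherits(cm, "CountMatrix"))
  tab <- data.frame(peak_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cm$condition), condition = unname(cm$condition)),
    condition_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
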