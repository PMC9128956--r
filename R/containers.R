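#' Cell-labelled expression count matrix
#'
#' Lightweight container for raw counts of features (genes, TE loci or TE
#' subfamilies) per cell, together with per-cell metadata. Rows are features,
#' columns are cells; every cell carries a `cell_type` label and a `dataset`
#' tag.
#'
#' @param counts numeric matrix of nonnegative counts, features x cells, with
#'   rownames (feature ids) and colnames (cell ids).
#' @param cell_meta data.frame with columns `cell_id`, `cell_type` and
#'   optionally `dataset`; one row per column of `counts`.
#' @return An object of class `expr_matrix`: a list with elements `counts`
#'   and `cell_meta` (row order matched to the columns of `counts`).
#' @export
expression_matrix <- function(counts, cell_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and cell colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids in counts")
  if (any(counts < 0)) stop("counts must be nonnegative")
  cell_meta <- as.data.frame(cell_meta)
  if (!all(c("cell_id", "cell_type") %in% names(cell_meta)))
    stop("cell_meta needs columns cell_id and cell_type")
  if (is.null(cell_meta$dataset)) cell_meta$dataset <- "dataset1"
  idx <- match(colnames(counts), cell_meta$cell_id)
  if (anyNA(idx)) stop("every cell must have a cell_meta row with a cell_type")
  cell_meta <- cell_meta[idx, , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d cells (%d cell types, %d datasets)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cell_type)),
              length(unique(x$cell_meta$dataset))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Cell-type specificity model
#'
#' A declared expression profile against which features are scored: one
#' weight in [0, 1] per cell type, at least one weight equal to 1. The
#' default is the germline model used for the PGCLC-specific score, an
#' iPSC:iMeLC:PGCLC:MLC:TC:T1LC ratio of 0:0:1:0.5:0:0 (MLC set to 0.5
#' because key PGC transcription factors stay weakly expressed there).
#'
#' @param weights named numeric vector, one entry per cell type, values in
#'   [0, 1], at least one equal to 1.
#' @return Object of class `specificity_model`.
#' @export
specificity_model <- function(weights = c(iPSC = 0, iMeLC = 0, PGCLC = 1,
                                          MLC = 0.5, TC = 0, T1LC = 0)) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by cell type")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  if (!any(weights == 1)) stop("at least one weight must equal 1")
  structure(list(cell_types = names(weights),
                 weights = as.numeric(weights)),
            class = "specificity_model")
}

#' @export
print.specificity_model <- function(x, ...) {
  cat("specificity_model:",
      paste(x$cell_types, x$weights, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# internal: named weight lookup
model_weights <- function(model) {
  stats::setNames(model$weights, model$cell_types)
}
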