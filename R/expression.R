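#' Counts-per-10k normalisation
#'
#' Scales each cell to a total of 10,000 counts (CP10k), the relative
#' expression level used throughout the pipeline, and also returns the
#' log2(CP10k + 1) transform.
#'
#' @param x an [expression_matrix()].
#' @return list with `cp10k` and `log2cp10k` matrices (same dimensions as
#'   the retained counts) and `dropped_cells`, the ids of zero-total cells
#'   removed with a warning.
#' @export
normalize_cp10k <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (nrow(x$counts) == 0L || ncol(x$counts) == 0L)
    stop("empty expression matrix")
  totals <- colSums(x$counts)
  dropped <- colnames(x$counts)[totals == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d cell(s) with zero total counts", length(dropped)))
  }
  keep <- totals > 0
  cp10k <- sweep(x$counts[, keep, drop = FALSE], 2, totals[keep], "/") * 1e4
  list(cp10k = cp10k,
       log2cp10k = log2(cp10k + 1),
       dropped_cells = dropped)
}

#' Aggregate TE locus counts to subfamily level
#'
#' Sums the read counts of TE loci belonging to the same subfamily, per
#' cell, yielding a subfamily-level expression matrix. The grand total of
#' counts is conserved.
#'
#' @param x locus-level [expression_matrix()]; rownames are locus ids.
#' @param te_annotation data.frame with columns `locus_id` and `subfamily`
#'   mapping every locus to exactly one subfamily.
#' @return subfamily-level [expression_matrix()].
#' @export
aggregate_te_subfamilies <- function(x, te_annotation) {
  stopifnot(inherits(x, "expr_matrix"))
  ann <- as.data.frame(te_annotation)
  if (anyDuplicated(ann$locus_id))
    stop("annotation maps some loci to more than one subfamily")
  idx <- match(rownames(x$counts), ann$locus_id)
  if (anyNA(idx)) {
    missing <- rownames(x$counts)[is.na(idx)]
    stop("loci missing from annotation: ", paste(missing, collapse = ", "))
  }
  fam <- factor(ann$subfamily[idx])
  agg <- rowsum(x$counts, group = fam, reorder = TRUE)
  expression_matrix(agg, x$cell_meta)
}

#' Cell-type specificity score
#'
#' Scores how closely each feature's expression profile matches a declared
#' cell-type model. The pipeline is fixed: log2(CP10k + 1) per cell, then a
#' per-feature Z score across all scored cells (population SD), then the
#' mean Z per cell type, rescaled to [0, 1]; the score is
#' -log10(SSR) of the rescaled means against the model weights, with SSR
#' floored at 1e-12 so a perfect match scores 12.
#'
#' Cells whose type is absent from the model are not scored. Features with
#' zero variance across cells, or whose per-type means are all equal (the
#' [0, 1] rescale is then undefined), are excluded and reported in
#' `skipped`, not errored.
#'
#' @param x an [expression_matrix()].
#' @param model a [specificity_model()]; all model cell types must be
#'   present among the cells.
#' @param ssr_floor lower bound applied to the SSR before the -log10
#'   transform.
#' @return data.frame with columns `feature`, `SSR`, `score`, plus the
#'   rescaled per-type mean profile in attribute `"profile"` (matrix) and
#'   the excluded feature ids in attribute `"skipped"`.
#' @export
specificity_score <- function(x, model = specificity_model(),
                              ssr_floor = 1e-12) {
  stopifnot(inherits(x, "expr_matrix"), inherits(model, "specificity_model"))
  keep <- x$cell_meta$cell_type %in% model$cell_types
  if (!all(model$cell_types %in% x$cell_meta$cell_type))
    stop("model cell types missing from data: ",
         paste(setdiff(model$cell_types, x$cell_meta$cell_type), collapse = ", "))
  sub <- expression_matrix(x$counts[, keep, drop = FALSE],
                           x$cell_meta[keep, , drop = FALSE])
  lg <- normalize_cp10k(sub)$log2cp10k
  meta <- sub$cell_meta[match(colnames(lg), sub$cell_meta$cell_id), ]

  mu <- rowMeans(lg)
  sd_pop <- sqrt(rowMeans((lg - mu)^2))
  zero_var <- sd_pop == 0
  z <- (lg - mu) / ifelse(sd_pop == 0, 1, sd_pop)

  type <- factor(meta$cell_type, levels = model$cell_types)
  means <- t(apply(z, 1L, function(row) tapply(row, type, mean)))
  colnames(means) <- model$cell_types

  rng <- apply(means, 1L, function(m) max(m) - min(m))
  degenerate <- rng == 0
  prof <- (means - apply(means, 1L, min)) / ifelse(rng == 0, 1, rng)

  usable <- !(zero_var | degenerate)
  ssr <- rowSums((prof - matrix(model$weights, nrow(prof), ncol(prof),
                                byrow = TRUE))^2)
  out <- data.frame(feature = rownames(lg)[usable],
                    SSR = unname(ssr[usable]),
                    score = -log10(pmax(ssr[usable], ssr_floor)),
                    stringsAsFactors = FALSE)
  attr(out, "profile") <- prof[usable, , drop = FALSE]
  attr(out, "skipped") <- rownames(lg)[!usable]
  out
}
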