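#' Differential upregulation between two cell groups
#'
#' Stand-in two-group differential test used when no external
#' differential-expression table is supplied. Features with low expression
#' (90th percentile of reads-per-million < `rpm_min`) are removed first;
#' the log2 fold change is computed on group means of CP10k with a
#' pseudocount of one, the p-value by a two-sample Wilcoxon rank-sum test
#' on log2(CP10k + 1), and the FDR by Benjamini-Hochberg. An externally
#' computed table (e.g. from a count-model Wald test) can be passed through
#' verbatim with [de_adapter()] for full fidelity.
#'
#' @param x an [expression_matrix()].
#' @param groupA,groupB disjoint character vectors of cell ids.
#' @param rpm_min expression filter threshold on the 90th percentile of
#'   reads per million (default 0.2).
#' @return data.frame with columns `feature`, `log2FC` (A over B), `p`,
#'   `FDR`, `meanA`, `meanB` (mean log2[CP10k+1] per group).
#' @export
differential_upregulation <- function(x, groupA, groupB, rpm_min = 0.2) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be nonempty")
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  cells <- c(groupA, groupB)
  if (!all(cells %in% colnames(x$counts)))
    stop("unknown cell ids in groups")
  sub <- expression_matrix(x$counts[, cells, drop = FALSE],
                           x$cell_meta[match(cells, x$cell_meta$cell_id), ])
  rpm <- sweep(sub$counts, 2, colSums(sub$counts), "/") * 1e6
  q90 <- apply(rpm, 1L, stats::quantile, probs = 0.9, names = FALSE)
  keep <- q90 >= rpm_min
  nm <- normalize_cp10k(sub)
  cp <- nm$cp10k[keep, , drop = FALSE]
  lg <- nm$log2cp10k[keep, , drop = FALSE]
  inA <- colnames(cp) %in% groupA
  mA <- rowMeans(cp[, inA, drop = FALSE])
  mB <- rowMeans(cp[, !inA, drop = FALSE])
  l2fc <- log2((mA + 1) / (mB + 1))
  p <- vapply(seq_len(nrow(lg)), function(i) {
    a <- lg[i, inA]; b <- lg[i, !inA]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  }, numeric(1))
  data.frame(feature = rownames(lg),
             log2FC = unname(l2fc),
             p = p,
             FDR = stats::p.adjust(p, "BH"),
             meanA = rowMeans(lg[, inA, drop = FALSE]),
             meanB = rowMeans(lg[, !inA, drop = FALSE]),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Wrap an external differential-expression table
#'
#' Adapter mode: accepts a pre-computed table (feature, log2FC, p, FDR,
#' optionally group means) and validates it into the layout
#' [differential_upregulation()] produces, so downstream classification is
#' identical whichever route produced the statistics.
#'
#' @param de data.frame with at least `feature`, `log2FC` and `FDR`.
#' @return validated data.frame.
#' @export
de_adapter <- function(de) {
  de <- as.data.frame(de)
  need <- c("feature", "log2FC", "FDR")
  if (!all(need %in% names(de)))
    stop("external DE table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(de$feature)) stop("duplicate features in DE table")
  if (any(de$FDR < 0 | de$FDR > 1, na.rm = TRUE)) stop("FDR outside [0, 1]")
  if (is.null(de$p)) de$p <- de$FDR
  de
}

#' Classify features by specificity score and differential upregulation
#'
#' Reproduces the four-way expression-pattern classification: features in
#' the top fraction of the specificity score are "up in PGCLCs"; features
#' with log2FC > `fc_thresh` and FDR < `fdr_thresh` (naive vs primed) are
#' "up in naive cells"; the intersection is `both`, the exclusive sets
#' `pgclc_only` and `naive_only`, the rest `other`. Ties at the score
#' cutoff are included, so the realized fraction can exceed
#' `top_fraction`; it is reported in attributes. The same rule applies
#' unchanged to open-chromatin peak features.
#'
#' @param scores data.frame from [specificity_score()].
#' @param de data.frame from [differential_upregulation()] or [de_adapter()].
#' @param top_fraction fraction of scored features called score-up
#'   (default 0.10).
#' @param fc_thresh,fdr_thresh differential-upregulation thresholds
#'   (defaults 1 and 0.05).
#' @param overrides optional named character vector of manual label
#'   overrides (feature -> label), applied last and recorded in the
#'   `"overridden"` attribute.
#' @return data.frame with columns `feature`, `score`, `log2FC`, `FDR`,
#'   `category` (factor: both, pgclc_only, naive_only, other); attributes
#'   `"score_cutoff"` and `"realized_fraction"`.
#' @export
classify_features <- function(scores, de, top_fraction = 0.10,
                              fc_thresh = 1, fdr_thresh = 0.05,
                              overrides = NULL) {
  universe <- intersect(scores$feature, de$feature)
  if (length(universe) == 0L) stop("empty feature universe")
  s <- scores$score[match(universe, scores$feature)]
  d <- de[match(universe, de$feature), ]
  n_top <- max(1L, floor(top_fraction * length(universe)))
  cutoff <- sort(s, decreasing = TRUE)[n_top]
  score_up <- s >= cutoff
  de_up <- !is.na(d$log2FC) & !is.na(d$FDR) &
    d$log2FC > fc_thresh & d$FDR < fdr_thresh
  category <- ifelse(score_up & de_up, "both",
              ifelse(score_up, "pgclc_only",
              ifelse(de_up, "naive_only", "other")))
  overridden <- character(0)
  if (!is.null(overrides)) {
    hit <- universe %in% names(overrides)
    category[hit] <- overrides[universe[hit]]
    overridden <- universe[hit]
  }
  out <- data.frame(feature = universe, score = s,
                    log2FC = d$log2FC, FDR = d$FDR,
                    category = factor(category,
                      levels = c("both", "pgclc_only", "naive_only", "other")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "score_cutoff") <- cutoff
  attr(out, "realized_fraction") <- mean(score_up)
  attr(out, "overridden") <- overridden
  out
}

#' Cross-species comparison of shared-upregulated genes
#'
#' Calls genes "likely regulated" by the TE subfamily: genes labelled
#' `both` (up in PGCLCs and naive cells) in the focal species whose
#' ortholog is NOT labelled `both` in the other species, and which lie
#' adjacent to an active TE locus. Only genes with ortholog information
#' enter the comparison.
#'
#' @param human_labels,other_labels data.frames from [classify_features()]
#'   for the two species.
#' @param ortholog_map data.frame with columns `human`, `other`; must be
#'   one-to-one on the reported universe.
#' @param adjacency named logical vector (human gene -> adjacent to an
#'   active locus), e.g. from [genes_near_loci()].
#' @return list with `likely_regulated` (character), `both_human`,
#'   `both_other` (mapped to human ids), `n_overlap`, and the comparison
#'   `universe`.
#' @export
compare_species <- function(human_labels, other_labels, ortholog_map,
                            adjacency) {
  om <- as.data.frame(ortholog_map)
  stopifnot(all(c("human", "other") %in% names(om)))
  om <- om[om$human %in% human_labels$feature &
           om$other %in% other_labels$feature, ]
  if (anyDuplicated(om$human) || anyDuplicated(om$other))
    stop("duplicate ortholog mappings")
  both_h <- om$human[human_labels$category[
    match(om$human, human_labels$feature)] == "both"]
  both_o <- om$human[other_labels$category[
    match(om$other, other_labels$feature)] == "both"]
  adj <- names(adjacency)[adjacency]
  likely <- setdiff(both_h, both_o)
  likely <- likely[likely %in% adj]
  list(likely_regulated = likely,
       both_human = both_h,
       both_other = both_o,
       n_overlap = length(intersect(both_h, both_o)),
       universe = om$human)
}
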