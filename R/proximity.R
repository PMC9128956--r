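#' Define the active TE loci
#'
#' A locus is "active" if its expression is detected (count > 0) in more
#' than `min_cell_fraction` of the cell population in ANY of the supplied
#' expression datasets (strict >), or if it overlaps a peak in ANY of the
#' supplied epigenetic peak sets. Provenance flags record which route
#' activated each locus.
#'
#' @param te_loci `GRanges` of TE loci with a `locus_id` metadata column.
#' @param expression_datasets named list of locus-level
#'   [expression_matrix()] objects (rownames = locus ids); may be empty.
#' @param peak_sets named list of `GRanges`; may be empty.
#' @param min_cell_fraction detection threshold (default 0.005, i.e. 0.5%
#'   of cells).
#' @return data.frame with `locus_id`, `active`, `expressed`, `epigenetic`
#'   and one logical column per input dataset/peak set.
#' @export
define_active_loci <- function(te_loci, expression_datasets = list(),
                               peak_sets = list(),
                               min_cell_fraction = 0.005) {
  ids <- S4Vectors::mcols(te_loci)$locus_id
  if (is.null(ids)) stop("te_loci needs a locus_id metadata column")
  out <- data.frame(locus_id = ids, stringsAsFactors = FALSE)
  expressed <- rep(FALSE, length(ids))
  for (nm in names(expression_datasets)) {
    m <- expression_datasets[[nm]]
    frac <- rep(0, length(ids))
    hit <- match(ids, rownames(m$counts))
    ok <- !is.na(hit)
    frac[ok] <- rowMeans(m$counts[hit[ok], , drop = FALSE] > 0)
    col <- frac > min_cell_fraction
    out[[paste0("expr_", nm)]] <- col
    expressed <- expressed | col
  }
  epigenetic <- rep(FALSE, length(ids))
  for (nm in names(peak_sets)) {
    col <- IRanges::overlapsAny(te_loci, peak_sets[[nm]],
                                ignore.strand = TRUE)
    out[[paste0("peak_", nm)]] <- col
    epigenetic <- epigenetic | col
  }
  out$expressed <- expressed
  out$epigenetic <- epigenetic
  out$active <- expressed | epigenetic
  out
}

#' Gene adjacency to active TE loci
#'
#' For each gene, takes the minimum over all its transcript TSSs of the
#' distance to the closest active locus and calls the gene adjacent iff
#' that minimum is within `distance` bp (inclusive). The distance between
#' a TSS and a locus is 0 if the TSS falls inside the locus, otherwise the
#' gap to the nearer end. TSS positions are strand-aware (start of the
#' range for +, end for -). Supports sensitivity sweeps over the distance
#' threshold via `distance` vectors in [adjacency_sweep()].
#'
#' @param tss `GRanges` of width-1 TSS positions with a `gene` metadata
#'   column (one row per transcript).
#' @param active_loci `GRanges` of active TE loci.
#' @param distance adjacency threshold in bp (default 50000).
#' @return data.frame with `gene`, `min_distance`, `nearest_locus` (index
#'   into `active_loci`, NA if none), `adjacent`.
#' @export
genes_near_loci <- function(tss, active_loci, distance = 50000) {
  genes <- S4Vectors::mcols(tss)$gene
  if (is.null(genes)) stop("tss needs a gene metadata column")
  drop <- is.na(genes)
  if (any(drop)) {
    warning(sprintf("dropping %d TSS row(s) without a gene id", sum(drop)))
    tss <- tss[!drop]; genes <- genes[!drop]
  }
  if (length(active_loci) == 0L) {
    u <- unique(genes)
    return(data.frame(gene = u, min_distance = NA_real_,
                      nearest_locus = NA_integer_, adjacent = FALSE,
                      stringsAsFactors = FALSE))
  }
  # distance = 0 inside the locus, else the coordinate gap to the nearer
  # end (so a TSS one bp upstream of a locus is at distance 1)
  p <- GenomicRanges::start(tss)
  tchr <- as.character(GenomeInfoDb::seqnames(tss))
  ls <- GenomicRanges::start(active_loci)
  le <- GenomicRanges::end(active_loci)
  lchr <- as.character(GenomeInfoDb::seqnames(active_loci))
  d <- rep(NA_real_, length(tss))
  nl <- rep(NA_integer_, length(tss))
  for (ch in unique(tchr)) {
    ti <- which(tchr == ch)
    li <- which(lchr == ch)
    if (!length(li)) next
    dm <- pmax(outer(ls[li], p[ti], "-"),            # locus to the right
               outer(-le[li], p[ti], "+"), 0)        # locus to the left
    best <- apply(dm, 2L, which.min)
    d[ti] <- dm[cbind(best, seq_along(ti))]
    nl[ti] <- li[best]
  }
  ord <- order(genes, d, na.last = TRUE)
  first <- !duplicated(genes[ord])
  res <- data.frame(gene = genes[ord][first],
                    min_distance = d[ord][first],
                    nearest_locus = nl[ord][first],
                    stringsAsFactors = FALSE)
  res$adjacent <- !is.na(res$min_distance) & res$min_distance <= distance
  rownames(res) <- NULL
  res
}

#' Adjacency sweep over distance thresholds
#'
#' Recomputes the adjacent/not-adjacent split of [genes_near_loci()] at
#' several distance thresholds (e.g. 20 kb to 500 kb) for sensitivity
#' analysis.
#'
#' @inheritParams genes_near_loci
#' @param distances numeric vector of thresholds in bp.
#' @return data.frame with `distance`, `n_adjacent`, `n_total`.
#' @export
adjacency_sweep <- function(tss, active_loci,
                            distances = c(2e4, 5e4, 1e5, 2e5, 5e5)) {
  base <- genes_near_loci(tss, active_loci, distance = max(distances))
  do.call(rbind, lapply(distances, function(d) {
    data.frame(distance = d,
               n_adjacent = sum(!is.na(base$min_distance) &
                                base$min_distance <= d),
               n_total = nrow(base))
  }))
}

#' Identify candidate regulators of a TE subfamily
#'
#' For each transcription factor, runs the genomic permutation test of its
#' binding sites against the TE loci and combines the enrichment with the
#' TF's expression pattern. A TF is called a regulator in PGCLCs if its
#' binding enrichment passes (log2 fold > `log2_fold_min`, FDR <
#' `fdr_max`, binding events > `min_events`), it is in the top
#' `top_fraction` of the specificity score, and its mean log2(CP10k+1) in
#' PGCLCs exceeds `min_expression`; a regulator in naive cells if the
#' enrichment passes and the naive-vs-primed differential shows log2FC >
#' `de_fc_min`, FDR < `de_fdr_max` and mean expression > `min_expression`.
#'
#' @param tf_sites named list of `GRanges`, binding sites per TF.
#' @param te_loci `GRanges` of the TE subfamily loci.
#' @param chrom_lengths named chromosome lengths for the shuffles.
#' @param scores specificity-score table ([specificity_score()]) over TFs
#'   (or a larger universe containing them).
#' @param de DE table (naive vs primed) containing the TFs.
#' @param mean_pgclc,mean_naive named numeric vectors of mean
#'   log2(CP10k+1) per TF in PGCLCs and naive cells.
#' @param n_perm,seed permutation settings.
#' @param log2_fold_min,fdr_max,min_events,top_fraction,min_expression,
#'   de_fc_min,de_fdr_max thresholds (defaults 2, 0.05, 20, 0.10, 0.4, 2,
#'   0.05).
#' @return data.frame per TF: enrichment columns plus `regulator_pgclc`,
#'   `regulator_naive`. TFs absent from the expression tables get NA calls
#'   with a warning.
#' @export
identify_regulators <- function(tf_sites, te_loci, chrom_lengths,
                                scores, de, mean_pgclc, mean_naive,
                                n_perm = 100, seed = 1L,
                                log2_fold_min = 2, fdr_max = 0.05,
                                min_events = 20, top_fraction = 0.10,
                                min_expression = 0.4,
                                de_fc_min = 2, de_fdr_max = 0.05) {
  enr <- do.call(rbind, lapply(seq_along(tf_sites), function(i) {
    e <- permutation_enrichment(tf_sites[[i]], list(te = te_loci),
                                chrom_lengths, n_perm = n_perm,
                                seed = seed + i)
    e$query <- names(tf_sites)[i]
    e
  }))
  enr$FDR <- stats::p.adjust(enr$p, "BH")
  n_top <- max(1L, floor(top_fraction * nrow(scores)))
  cutoff <- sort(scores$score, decreasing = TRUE)[n_top]
  enr$log2_fold <- log2(enr$fold)
  enriched <- !is.na(enr$log2_fold) & enr$log2_fold > log2_fold_min &
    enr$FDR < fdr_max & enr$n_events > min_events
  sc <- scores$score[match(enr$query, scores$feature)]
  fc <- de$log2FC[match(enr$query, de$feature)]
  dq <- de$FDR[match(enr$query, de$feature)]
  mp <- mean_pgclc[enr$query]
  mn <- mean_naive[enr$query]
  missing_expr <- is.na(sc) & is.na(fc)
  if (any(missing_expr))
    warning("TF(s) absent from expression tables: ",
            paste(enr$query[missing_expr], collapse = ", "))
  enr$regulator_pgclc <- ifelse(missing_expr, NA,
    enriched & !is.na(sc) & sc >= cutoff & !is.na(mp) & mp > min_expression)
  enr$regulator_naive <- ifelse(missing_expr, NA,
    enriched & !is.na(fc) & fc > de_fc_min & !is.na(dq) & dq < de_fdr_max &
      !is.na(mn) & mn > min_expression)
  rownames(enr) <- NULL
  enr
}
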