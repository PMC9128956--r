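#' Write TE loci as BED6
#'
#' BED output is 0-based half-open; the name column carries the subfamily
#' (with the locus id appended after a `|`) and the score column the
#' Smith-Waterman reliability score.
#'
#' @param te_loci `GRanges` with `locus_id`, `subfamily`, `sw_score`.
#' @param path output file.
#' @export
write_te_bed <- function(te_loci, path) {
  mc <- S4Vectors::mcols(te_loci)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(te_loci)),
                   start = GenomicRanges::start(te_loci) - 1L,
                   end = GenomicRanges::end(te_loci),
                   name = paste0(mc$subfamily, "|", mc$locus_id),
                   score = mc$sw_score,
                   strand = as.character(GenomicRanges::strand(te_loci)))
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker-derived TE BED file
#'
#' Expects BED6 with subfamily (optionally `subfamily|locus_id`) in the
#' name column and the Smith-Waterman score in the score column. Loci
#' with scores below `min_sw_score` are filtered on load, matching the
#' reliability filter applied to RepeatMasker annotations.
#'
#' @param path BED6 file.
#' @param min_sw_score reliability threshold (default 2500); `0` disables.
#' @return `GRanges` with `locus_id`, `subfamily`, `sw_score`.
#' @export
read_te_bed <- function(path, min_sw_score = 2500) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  parts <- strsplit(nm, "|", fixed = TRUE)
  S4Vectors::mcols(gr)$subfamily <- vapply(parts, `[`, character(1), 1L)
  S4Vectors::mcols(gr)$locus_id <- vapply(parts, function(p)
    if (length(p) > 1L) p[2] else NA_character_, character(1))
  miss <- is.na(S4Vectors::mcols(gr)$locus_id)
  S4Vectors::mcols(gr)$locus_id[miss] <- sprintf("te%04d", which(miss))
  S4Vectors::mcols(gr)$sw_score <- S4Vectors::mcols(gr)$score
  keep <- S4Vectors::mcols(gr)$sw_score >= min_sw_score
  gr[keep]
}

#' Write / read an ortholog presence-absence table
#'
#' TSV with a `locus_id` column and one 1/0/NA column per species.
#'
#' @param table data.frame (rownames = locus ids) as produced by
#'   [simulate_ortholog_history()].
#' @param path file path.
#' @export
write_ortholog_table <- function(table, path) {
  df <- data.frame(locus_id = rownames(table), table,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_table
#' @return `read_ortholog_table`: data.frame with locus-id rownames.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rownames(df) <- df$locus_id
  df$locus_id <- NULL
  df
}

#' Write an expression matrix as counts TSV plus cell-metadata TSV
#'
#' @param x an [expression_matrix()].
#' @param counts_path,cells_path output files.
#' @export
write_expression_tsv <- function(x, counts_path, cells_path) {
  utils::write.table(data.frame(feature = rownames(x$counts), x$counts,
                                check.names = FALSE, row.names = NULL),
                     counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$cell_meta, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv`: an [expression_matrix()].
#' @export
read_expression_tsv <- function(counts_path, cells_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  expression_matrix(m, meta)
}
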