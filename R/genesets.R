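#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, members...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, character(1), 1L))
}

#' One-tailed Fisher gene-set enrichment
#'
#' Tests each gene set for over-representation in a query gene list
#' against a background universe: a one-tailed Fisher exact
#' (hypergeometric upper-tail) p-value per set, BH FDR across the
#' collection, and the cross-product odds ratio. Set memberships are
#' intersected with the universe first; query genes outside the universe
#' are dropped and reported.
#'
#' @param query character vector of genes of interest.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe background gene ids.
#' @return data.frame per set: `set`, `overlap`, `set_size`, `odds_ratio`,
#'   `p`, `FDR`, `hits` (comma-joined gene ids); attribute
#'   `"dropped_query"` lists query genes outside the universe. Sets empty
#'   after intersection with the universe are dropped.
#' @export
enrich_gene_sets <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  dropped <- setdiff(query, universe)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(unique(query), universe)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) > 0L]
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    hits <- intersect(query, sets[[nm]])
    a <- length(hits)
    b <- n - a
    cc <- K - a
    d <- N - K - b
    p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    or <- if (a == 0L) 0 else if (b == 0L || cc == 0L) Inf else (a * d) / (b * cc)
    data.frame(set = nm, overlap = a, set_size = K, odds_ratio = or,
               p = p, hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$FDR <- stats::p.adjust(out$p, "BH")
  out <- out[, c("set", "overlap", "set_size", "odds_ratio", "p", "FDR", "hits")]
  attr(out, "dropped_query") <- dropped
  out
}

#' Prune redundant gene sets by odds-ratio-ranked Jaccard overlap
#'
#' Keeps the significant rows (FDR < `fdr_threshold`, and odds ratio >
#' `min_or` when given), ranks them by odds ratio descending (ties broken
#' by smaller p, then set name), and scans down the ranking, removing any
#' set whose membership Jaccard index with an already-kept set exceeds
#' `jaccard_threshold` (strict >; an index of exactly the threshold is
#' retained). Jaccard is computed on full set memberships intersected
#' with the universe, not on hit genes only.
#'
#' @param rows data.frame from [enrich_gene_sets()].
#' @param sets the same named list of gene sets used for the enrichment.
#' @param universe the same background universe.
#' @param jaccard_threshold redundancy threshold (default 0.5).
#' @param fdr_threshold significance filter (default 0.05).
#' @param min_or optional odds-ratio filter (e.g. 2); `NULL` disables it.
#' @return pruned subset of `rows`, ranked.
#' @export
prune_redundant <- function(rows, sets, universe, jaccard_threshold = 0.5,
                            fdr_threshold = 0.05, min_or = NULL) {
  sig <- rows[rows$FDR < fdr_threshold, , drop = FALSE]
  if (!is.null(min_or))
    sig <- sig[sig$odds_ratio > min_or, , drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  sig <- sig[order(-sig$odds_ratio, sig$p, sig$set), , drop = FALSE]
  members <- lapply(sets[sig$set], intersect, unique(universe))
  kept <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    redundant <- FALSE
    for (j in which(kept)) {
      a <- members[[i]]; b <- members[[j]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac > jaccard_threshold) { redundant <- TRUE; break }
    }
    kept[i] <- !redundant
  }
  out <- sig[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
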