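#' Filter a multiple sequence alignment
#'
#' Two fixed steps, in order: (1) remove alignment columns whose non-gap
#' site coverage is below `min_site_coverage`; (2) remove sequences whose
#' gap fraction over the remaining columns exceeds `max_seq_gap_fraction`.
#'
#' @param msa `Biostrings::DNAStringSet` (all sequences equal length) or a
#'   character vector of aligned sequences. Gaps are `-`.
#' @param min_site_coverage minimum fraction of non-gap characters a
#'   column must have to be retained (default 0.85).
#' @param max_seq_gap_fraction maximum gap fraction a sequence may have
#'   over the retained columns (default 0.15).
#' @return filtered `DNAStringSet`; attributes `"removed_columns"` and
#'   `"removed_sequences"` record what was dropped.
#' @export
filter_msa <- function(msa, min_site_coverage = 0.85,
                       max_seq_gap_fraction = 0.15) {
  if (!methods::is(msa, "DNAStringSet"))
    msa <- Biostrings::DNAStringSet(msa)
  if (length(unique(Biostrings::width(msa))) != 1L)
    stop("all sequences must have equal (aligned) length")
  m <- as.matrix(msa)
  gap <- m == "-"
  col_cov <- 1 - colMeans(gap)
  keep_col <- col_cov >= min_site_coverage
  m2 <- m[, keep_col, drop = FALSE]
  gap2 <- gap[, keep_col, drop = FALSE]
  seq_gap_frac <- if (ncol(m2)) rowMeans(gap2) else rep(1, nrow(m2))
  keep_seq <- seq_gap_frac <= max_seq_gap_fraction
  if (!any(keep_seq) || !any(keep_col))
    stop("filtering removed the whole alignment")
  out <- Biostrings::DNAStringSet(apply(m2[keep_seq, , drop = FALSE], 1L,
                                        paste0, collapse = ""))
  names(out) <- names(msa)[keep_seq]
  attr(out, "removed_columns") <- which(!keep_col)
  attr(out, "removed_sequences") <- names(msa)[!keep_seq]
  out
}

#' Detect phylogenetic outlier leaves
#'
#' Standardizes the external (leaf) branch lengths of a tree as Z scores
#' and returns the leaves whose standardized length exceeds `z_max`.
#' Intended as a single-pass pre-filter before final tree construction;
#' removing the reported leaves and re-running may report more (the
#' procedure is deliberately not iterated to convergence).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param z_max standardized-length threshold (default 3).
#' @return character vector of outlier leaf labels (possibly empty).
#' @export
detect_branch_outliers <- function(tree, z_max = 3) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop("need at least 3 leaves")
  tip_edge <- match(seq_len(n_tip), tree$edge[, 2])
  len <- tree$edge.length[tip_edge]
  s <- stats::sd(len)
  if (is.na(s) || s == 0) return(character(0))
  z <- (len - mean(len)) / s
  tree$tip.label[z > z_max]
}

#' Date TE insertions from an ortholog presence/absence table
#'
#' Slides a window of `window` consecutive loci, ordered from oldest to
#' youngest, along the ortholog table. For each species a window qualifies
#' iff at least `min_present` of its loci have an orthologous insertion in
#' that species (missing values count as not-present). The boundary — the
#' "final" copy inserted before the divergence of humans and that species
#' — is the youngest present locus within the youngest qualifying window
#' (the windowing guards the estimate against isolated spurious ortholog
#' calls and missing values); every locus strictly older than the boundary
#' is flagged pre-divergence. With no qualifying window no locus is
#' flagged.
#'
#' @param order character vector of locus ids, oldest first (tree order).
#' @param table data.frame of 1/0/NA, rownames = locus ids, one column per
#'   species.
#' @param window window size in loci (default 10; "more than three out of
#'   ten" is encoded as `min_present = 4`).
#' @param min_present minimum present loci for a window to qualify
#'   (default 4).
#' @return list with `flags` (logical matrix loci x species, tree order)
#'   and `boundary` (named integer: position of the boundary locus per
#'   species, NA when no window qualifies).
#' @export
date_insertions <- function(order, table, window = 10, min_present = 4) {
  if (!all(order %in% rownames(table)))
    stop("ordered loci missing from the ortholog table: ",
         paste(setdiff(order, rownames(table)), collapse = ", "))
  tab <- as.matrix(table[order, , drop = FALSE])
  n <- length(order)
  species <- colnames(tab)
  flags <- matrix(FALSE, n, length(species),
                  dimnames = list(order, species))
  boundary <- stats::setNames(rep(NA_integer_, length(species)), species)
  w <- min(window, n)
  starts <- seq_len(n - w + 1L)
  for (s in species) {
    present <- !is.na(tab[, s]) & tab[, s] == 1
    counts <- vapply(starts, function(i) sum(present[i:(i + w - 1L)]),
                     integer(1))
    qual <- which(counts >= min_present)
    if (length(qual)) {
      qs <- max(qual)                       # youngest qualifying window
      win <- qs:(qs + w - 1L)
      b <- win[max(which(present[win]))]    # youngest present locus in it
      boundary[s] <- b
      if (b > 1L) flags[seq_len(b - 1L), s] <- TRUE
    }
  }
  list(flags = flags, boundary = boundary)
}

#' Assign insertion-branch labels from per-species pre-divergence flags
#'
#' Maps the flags of [date_insertions()] to the five insertion branches:
#' HCGOG (before the gibbon divergence), HCGO (orangutan), HCG (gorilla),
#' HC (chimpanzee), H (human-specific). Conflicting flag patterns (a
#' deeper species flagged but a shallower one not) are resolved by the
#' deepest flagged species, with a warning. Macaque/marmoset flags, if
#' present, are accepted but do not generate labels beyond HCGOG.
#'
#' @param flags logical matrix loci x species from [date_insertions()];
#'   recognised species columns: `gibbon`, `orangutan`, `gorilla`,
#'   `chimpanzee`.
#' @return factor of labels (levels HCGOG, HCGO, HCG, HC, H), named by
#'   locus.
#' @export
assign_branches <- function(flags) {
  depth_order <- c(gibbon = "HCGOG", orangutan = "HCGO",
                   gorilla = "HCG", chimpanzee = "HC")
  sp <- intersect(names(depth_order), colnames(flags))
  lab <- rep("H", nrow(flags))
  for (s in rev(sp)) {          # shallow -> deep so deepest-true wins
    lab[flags[, s]] <- depth_order[[s]]
  }
  # conflict: deeper species flagged while a shallower one is not
  if (length(sp) > 1L) {
    for (i in seq_along(sp)[-length(sp)]) {
      deeper <- flags[, sp[i]]
      shallower <- flags[, sp[i + 1L]]
      n_bad <- sum(deeper & !shallower)
      if (n_bad > 0L)
        warning(sprintf(
          "%d locus/loci flagged pre-%s but not pre-%s; deepest flag wins",
          n_bad, sp[i], sp[i + 1L]))
    }
  }
  factor(stats::setNames(lab, rownames(flags)),
         levels = c("HCGOG", "HCGO", "HCG", "HC", "H"))
}

#' Stratify genes by the insertion date of their associated loci
#'
#' A gene inherits the branch label of its associated loci when that label
#' is unique; genes whose associated loci carry conflicting labels, or are
#' associated with a locus that has no label (e.g. filtered out of the
#' phylogenetic tree), are labelled `ND` (not determined).
#'
#' @param gene_loci named list: gene -> character vector of locus ids.
#' @param locus_labels factor/character of branch labels named by locus
#'   (from [assign_branches()]).
#' @return factor of labels (levels HCGOG, HCGO, HCG, HC, H, ND), named by
#'   gene.
#' @export
stratify_genes_by_date <- function(gene_loci, locus_labels) {
  lv <- c("HCGOG", "HCGO", "HCG", "HC", "H", "ND")
  lab <- vapply(gene_loci, function(loci) {
    if (length(loci) == 0L) return("ND")
    l <- as.character(locus_labels[loci])
    if (anyNA(l)) return("ND")
    u <- unique(l)
    if (length(u) == 1L) u else "ND"
  }, character(1))
  factor(lab, levels = lv)
}
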