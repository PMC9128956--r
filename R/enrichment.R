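#' Length-preserving uniform shuffle of genomic regions
#'
#' Relocates each region uniformly across the genome: the destination
#' chromosome is drawn with probability proportional to the number of
#' valid start positions it offers for that region's width, and the start
#' uniformly among them. Shuffled regions may overlap one another and no
#' exclusion regions are applied.
#'
#' @param regions a `GRanges`.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @return shuffled `GRanges` (strand `*`).
#' @keywords internal
shuffle_regions <- function(regions, chrom_lengths) {
  w <- GenomicRanges::width(regions)
  chroms <- names(chrom_lengths)
  # valid start positions per (chromosome, region); vectorized draw
  slots <- pmax(outer(unname(chrom_lengths), w, "-") + 1, 0)
  tot <- colSums(slots)
  if (any(tot == 0)) stop("region wider than every chromosome")
  cum <- apply(slots, 2L, cumsum)
  u <- stats::runif(length(w)) * tot
  pick <- colSums(cum < rep(u, each = length(chroms))) + 1L
  free <- slots[cbind(pick, seq_along(w))]
  out_start <- floor(stats::runif(length(w)) * free) + 1L
  GenomicRanges::GRanges(chroms[pick],
    IRanges::IRanges(start = out_start, width = w),
    seqinfo = GenomeInfoDb::Seqinfo(chroms, unname(chrom_lengths)))
}

#' Genomic permutation test for TE-subfamily enrichment
#'
#' Tests whether a set of regions (e.g. peaks or TF binding sites)
#' overlaps the loci of each TE subfamily more often than expected by
#' chance. The regions are shuffled length-preserving uniformly across the
#' genome `n_perm` times; the mean overlap count over shuffles is the
#' random expectation lambda, the fold enrichment is observed/lambda, and
#' the p-value is the upper tail P(X >= observed) of a Poisson
#' distribution with rate lambda. A region overlaps a subfamily if it
#' shares at least one bp with any of its loci, strand-agnostic.
#'
#' @param regions `GRanges` of query regions.
#' @param targets `GRanges` of TE loci with a `subfamily` metadata column,
#'   or a named list of `GRanges` (one per subfamily).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_perm number of shuffles (default 100).
#' @param seed integer seed for the shuffles.
#' @return data.frame, one row per subfamily: `query`, `observed`,
#'   `lambda`, `fold`, `p`, `FDR`, `n_events` (= observed), plus a logical
#'   `lambda_floored` flag set when lambda was 0 and floored at 1/n_perm.
#' @export
permutation_enrichment <- function(regions, targets, chrom_lengths,
                                   n_perm = 100, seed = 1L) {
  if (inherits(targets, "GRanges")) {
    fam <- S4Vectors::mcols(targets)$subfamily
    if (is.null(fam)) fam <- rep("target", length(targets))
    targets <- split(targets, fam)
  }
  targets <- as.list(targets)
  w <- GenomicRanges::width(regions)
  chroms <- names(chrom_lengths)
  # lay the chromosomes on one number line with guard gaps wider than any
  # interval, so overlap tests reduce to findInterval on sorted starts
  guard <- max(c(w, unlist(lapply(targets, GenomicRanges::width)), 1)) + 1
  offset <- stats::setNames(
    cumsum(c(0, unname(chrom_lengths[-length(chrom_lengths)]) + guard)),
    chroms)
  abs_targets <- lapply(targets, function(t) {
    t <- GenomicRanges::reduce(t, ignore.strand = TRUE)
    o <- offset[as.character(GenomeInfoDb::seqnames(t))]
    s <- GenomicRanges::start(t) + o
    ord <- order(s)
    list(S = s[ord], E = (GenomicRanges::end(t) + o)[ord])
  })
  count_hits <- function(s_abs, e_abs) {
    vapply(abs_targets, function(t) {
      k <- findInterval(e_abs, t$S)
      sum(k > 0 & t$E[pmax(k, 1L)] >= s_abs)
    }, numeric(1))
  }
  reg_off <- offset[as.character(GenomeInfoDb::seqnames(regions))]
  observed <- as.integer(count_hits(GenomicRanges::start(regions) + reg_off,
                                    GenomicRanges::end(regions) + reg_off))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  slots <- pmax(outer(unname(chrom_lengths), w, "-") + 1, 0)
  tot <- colSums(slots)
  if (any(tot == 0)) stop("region wider than every chromosome")
  cum <- matrix(apply(slots, 2L, cumsum), nrow = length(chroms))
  perm <- matrix(0, n_perm, length(targets))
  for (k in seq_len(n_perm)) {
    u <- stats::runif(length(w)) * tot
    pick <- colSums(cum < rep(u, each = length(chroms))) + 1L
    st <- floor(stats::runif(length(w)) * slots[cbind(pick, seq_along(w))]) +
      1 + offset[pick]
    perm[k, ] <- count_hits(st, st + w - 1)
  }
  lambda <- colMeans(perm)
  floored <- lambda == 0
  lam_p <- ifelse(floored, 1 / n_perm, lambda)
  p <- stats::ppois(observed - 1, lam_p, lower.tail = FALSE)
  fold <- ifelse(floored & observed > 0, Inf, observed / ifelse(floored, NA, lambda))
  fold[floored & observed == 0] <- NaN
  data.frame(query = names(targets),
             observed = observed,
             lambda = lambda,
             fold = fold,
             p = p,
             FDR = stats::p.adjust(p, "BH"),
             n_events = observed,
             lambda_floored = floored,
             row.names = NULL, stringsAsFactors = FALSE)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Proximity-based binomial (GREAT-style) enrichment
#'
#' Tests whether peaks concentrate near the transcription start sites of a
#' gene set of interest. Regions of interest are the +/- `window` bp
#' windows around the TSSs of the genes of interest, background regions
#' the same windows around all background TSSs; overlapping windows are
#' merged within each set before measuring lengths (Li, Lb) and counting
#' peaks (Ci, Cb; a peak is counted once per set). The fold enrichment is
#' (Ci/Cb)/(Li/Lb) and the p-value a binomial upper tail
#' P(X >= Ci | n = Cb, p = Li/Lb).
#'
#' @param peaks `GRanges` of peaks.
#' @param tss_interest,tss_background `GRanges` of TSS positions
#'   (width-1 ranges); interest must be a subset of background.
#' @param window half-width of the TSS window in bp (default 50000).
#' @return one-row data.frame: `Ci`, `Cb`, `Li`, `Lb`, `fold`, `p`.
#' @export
great_enrichment <- function(peaks, tss_interest, tss_background,
                             window = 50000) {
  widen <- function(tss) {
    if (length(tss) == 0L || window == 0)
      return(GenomicRanges::GRanges())
    g <- suppressWarnings(GenomicRanges::resize(tss, width = 2 * window + 1,
                                                fix = "center",
                                                ignore.strand = TRUE))
    g <- GenomicRanges::trim(g)
    GenomicRanges::reduce(g, ignore.strand = TRUE)
  }
  ri <- widen(tss_interest)
  rb <- widen(tss_background)
  Li <- sum(GenomicRanges::width(ri))
  Lb <- sum(GenomicRanges::width(rb))
  Ci <- sum(IRanges::overlapsAny(peaks, ri, ignore.strand = TRUE))
  Cb <- sum(IRanges::overlapsAny(peaks, rb, ignore.strand = TRUE))
  if (Lb > 0 && Cb == 0) stop("no peaks in background regions")
  if (Li == 0 || Lb == 0) {
    warning("zero-length regions (window = 0 or empty TSS set); fold undefined")
    return(data.frame(Ci = Ci, Cb = Cb, Li = Li, Lb = Lb,
                      fold = NA_real_, p = NA_real_))
  }
  great_test(Ci, Cb, Li, Lb)
}

#' Binomial fold test on precomputed region counts and lengths
#'
#' The statistical core of [great_enrichment()], exposed for use with
#' counts and lengths measured elsewhere: fold = (Ci/Cb)/(Li/Lb) and
#' p = P(X >= Ci | n = Cb, p = Li/Lb).
#'
#' @param Ci,Cb peak counts in the interest and background regions
#'   (Ci <= Cb).
#' @param Li,Lb total lengths (bp) of the merged interest and background
#'   regions (Li <= Lb).
#' @return one-row data.frame: `Ci`, `Cb`, `Li`, `Lb`, `fold`, `p`.
#' @export
great_test <- function(Ci, Cb, Li, Lb) {
  stopifnot(Ci <= Cb, Li <= Lb, Cb > 0, Lb > 0)
  fold <- (Ci / Cb) / (Li / Lb)
  p <- stats::pbinom(Ci - 1, Cb, Li / Lb, lower.tail = FALSE)
  data.frame(Ci = Ci, Cb = Cb, Li = Li, Lb = Lb, fold = fold, p = p)
}

#' Fisher enrichment of site sets within region categories
#'
#' For each (region category, site set) pair, builds the 2x2 table of
#' membership in the category against overlap with the site set over all
#' regions, and reports the cross-product odds ratio ad/bc, the two-tailed
#' Fisher exact p-value, and BH FDR across site sets within each category.
#'
#' @param regions `GRanges` of all regions (the universe).
#' @param categories factor or character vector, one label per region;
#'   labels partition the universe.
#' @param site_sets named list of `GRanges` (e.g. one per transcription
#'   factor).
#' @return data.frame with one row per (category, site_set):
#'   `category`, `site_set`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `FDR`.
#'   Degenerate margins give NA with a warning.
#' @export
fisher_category_enrichment <- function(regions, categories, site_sets) {
  stopifnot(length(categories) == length(regions))
  categories <- as.factor(categories)
  out <- list()
  for (cat in levels(categories)) {
    in_cat <- categories == cat
    rows <- lapply(names(site_sets), function(nm) {
      ov <- IRanges::overlapsAny(regions, site_sets[[nm]],
                                 ignore.strand = TRUE)
      a <- sum(in_cat & ov); b <- sum(in_cat & !ov)
      cc <- sum(!in_cat & ov); d <- sum(!in_cat & !ov)
      if (sum(in_cat) == 0L) {
        return(data.frame(category = cat, site_set = nm, a = a, b = b,
                          c = cc, d = d, odds_ratio = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      if (sum(!in_cat) == 0L) {
        warning("category '", cat, "' equals the universe; odds ratio undefined")
        return(data.frame(category = cat, site_set = nm, a = a, b = b,
                          c = cc, d = d, odds_ratio = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      or <- if (b == 0L || cc == 0L) {
        if (a == 0L || d == 0L) NA_real_ else Inf
      } else (a * d) / (b * cc)
      if (a == 0L) or <- 0
      p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
      data.frame(category = cat, site_set = nm, a = a, b = b, c = cc, d = d,
                 odds_ratio = or, p = p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$FDR <- stats::p.adjust(tab$p, "BH")
    out[[cat]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
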