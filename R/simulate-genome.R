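#' Design for the synthetic genome generator
#'
#' @param chrom_lengths named chromosome lengths in bp.
#' @param n_te_loci named counts of TE loci per subfamily.
#' @param te_length_range (min, max) TE locus length in bp.
#' @param n_peaks named counts of peaks per category.
#' @param planted_overlap_rate fraction of each peak category placed on a
#'   TE locus of `target_subfamily` (in [0, 1]).
#' @param target_subfamily subfamily receiving the planted overlaps
#'   (default: first subfamily).
#' @param n_genes number of genes (one TSS each, strand-aware).
#' @param peak_length peak width in bp.
#' @param seed integer seed.
#' @return list of class `genome_design`.
#' @export
genome_design <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 1.5e6),
                          n_te_loci = c(LTR5_Hs = 60, LTR5B = 40),
                          te_length_range = c(500, 1000),
                          n_peaks = c(atac = 80),
                          planted_overlap_rate = 0.3,
                          target_subfamily = names(n_te_loci)[1],
                          n_genes = 100,
                          peak_length = 300,
                          seed = 1L) {
  stopifnot(all(chrom_lengths > 0), all(n_te_loci >= 1),
            length(te_length_range) == 2L,
            te_length_range[1] <= te_length_range[2],
            all(n_peaks >= 1),
            planted_overlap_rate >= 0, planted_overlap_rate <= 1,
            n_genes >= 1, peak_length >= 1)
  if (te_length_range[2] > max(chrom_lengths))
    stop("TE length exceeds every chromosome")
  structure(list(chrom_lengths = chrom_lengths, n_te_loci = n_te_loci,
                 te_length_range = te_length_range, n_peaks = n_peaks,
                 planted_overlap_rate = planted_overlap_rate,
                 target_subfamily = target_subfamily,
                 n_genes = n_genes, peak_length = peak_length,
                 seed = as.integer(seed)),
            class = "genome_design")
}

# place n intervals of given widths uniformly; reject those hitting `avoid`
# (a GRanges) if supplied; cap 1000 tries per interval
place_intervals <- function(n, widths, chrom_lengths, avoid = NULL) {
  chroms <- names(chrom_lengths)
  si <- GenomeInfoDb::Seqinfo(chroms, unname(chrom_lengths))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- widths[min(i, length(widths))]
    placed <- FALSE
    for (try in seq_len(1000L)) {
      slots <- pmax(chrom_lengths - w + 1, 0)
      if (all(slots == 0)) stop("chromosomes too short for interval width ", w)
      ch <- sample(chroms, 1L, prob = slots)
      st <- sample.int(slots[[ch]], 1L)
      g <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = w),
                                  seqinfo = si)
      if (is.null(avoid) || !any(IRanges::overlapsAny(g, avoid,
                                                      ignore.strand = TRUE))) {
        out[[i]] <- g; placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place interval after 1000 tries")
  }
  suppressWarnings(do.call(c, out))
}

#' Simulate a genome: TE annotation, peak sets and TSS table
#'
#' Places TE loci of each subfamily uniformly (with Smith-Waterman-style
#' reliability scores >= 2500 so none are filtered on load), then places
#' each peak category such that exactly `round(planted_overlap_rate *
#' n_peaks)` peaks overlap a TE locus of the target subfamily and the
#' remainder overlap no TE locus at all (rejection-sampled). TSSs are
#' strand-aware single positions. Byte-identical output under a fixed
#' seed.
#'
#' @param design a [genome_design()].
#' @return list with `te_loci` (`GRanges`: `locus_id`, `subfamily`,
#'   `sw_score`), `peaks` (named list of `GRanges`), `tss` (`GRanges`,
#'   width 1, with `gene`), and `chrom_lengths`.
#' @export
simulate_genome <- function(design) {
  stopifnot(inherits(design, "genome_design"))
  d <- design
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(d$seed)
  si <- GenomeInfoDb::Seqinfo(names(d$chrom_lengths),
                              unname(d$chrom_lengths))

  te <- list()
  for (fam in names(d$n_te_loci)) {
    n <- d$n_te_loci[[fam]]
    widths <- sample(seq(d$te_length_range[1], d$te_length_range[2]), n,
                     replace = TRUE)
    g <- place_intervals(n, widths, d$chrom_lengths,
                         avoid = if (length(te))
                           suppressWarnings(do.call(c, unname(te))))
    S4Vectors::mcols(g)$subfamily <- fam
    te[[fam]] <- g
  }
  te_loci <- suppressWarnings(do.call(c, unname(te)))
  te_loci <- GenomicRanges::sort(te_loci, ignore.strand = TRUE)
  S4Vectors::mcols(te_loci)$locus_id <-
    sprintf("te%04d", seq_along(te_loci))
  S4Vectors::mcols(te_loci)$sw_score <-
    2500L + sample.int(5000L, length(te_loci), replace = TRUE)

  target <- te_loci[S4Vectors::mcols(te_loci)$subfamily == d$target_subfamily]
  peaks <- list()
  for (cat in names(d$n_peaks)) {
    n <- d$n_peaks[[cat]]
    n_on <- round(d$planted_overlap_rate * n)
    on_list <- list()
    if (n_on > 0) {
      anchors <- sample(seq_along(target), n_on, replace = TRUE)
      for (k in seq_len(n_on)) {
        a <- target[anchors[k]]
        # start inside the locus so overlap is guaranteed
        st <- GenomicRanges::start(a) +
          sample.int(max(GenomicRanges::width(a) - 1L, 1L), 1L) - 1L
        st <- min(st, d$chrom_lengths[[as.character(
          GenomeInfoDb::seqnames(a))]] - d$peak_length + 1L)
        on_list[[k]] <- GenomicRanges::GRanges(
          GenomeInfoDb::seqnames(a),
          IRanges::IRanges(st, width = d$peak_length), seqinfo = si)
      }
    }
    off <- if (n - n_on > 0)
      place_intervals(n - n_on, rep(d$peak_length, n - n_on),
                      d$chrom_lengths, avoid = te_loci)
    g <- suppressWarnings(do.call(c, c(on_list, if (!is.null(off)) list(off))))
    peaks[[cat]] <- GenomicRanges::sort(g, ignore.strand = TRUE)
  }

  tss_pos <- place_intervals(d$n_genes, rep(1L, d$n_genes), d$chrom_lengths)
  GenomicRanges::strand(tss_pos) <-
    sample(c("+", "-"), d$n_genes, replace = TRUE)
  S4Vectors::mcols(tss_pos)$gene <- sprintf("gene%04d", seq_len(d$n_genes))

  list(te_loci = te_loci, peaks = peaks, tss = tss_pos,
       chrom_lengths = d$chrom_lengths)
}
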