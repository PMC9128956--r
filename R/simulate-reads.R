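#' Design for the synthetic split-read generator
#'
#' @param absent_loci locus ids planted as carrying an absent allele.
#' @param reads_per_junction junction-spanning reads per absent locus.
#' @param read_length read length in bp (>= 2 * min_clip).
#' @param noise_reads soft-clipped reads with `SA` descriptors whose clip
#'   points are far (> 25 nt) from any element boundary.
#' @param min_clip minimum mapped length of each read segment (default 20).
#' @param seed integer seed.
#' @return list of class `readsim_design`.
#' @export
readsim_design <- function(absent_loci = character(0),
                           reads_per_junction = 4,
                           read_length = 100,
                           noise_reads = 10,
                           min_clip = 20,
                           seed = 1L) {
  stopifnot(reads_per_junction >= 0, noise_reads >= 0, min_clip >= 1)
  if (read_length < 2 * min_clip)
    stop("read_length shorter than twice the minimum clip (",
         2 * min_clip, ")")
  structure(list(absent_loci = absent_loci,
                 reads_per_junction = as.integer(reads_per_junction),
                 read_length = as.integer(read_length),
                 noise_reads = as.integer(noise_reads),
                 min_clip = as.integer(min_clip),
                 seed = as.integer(seed)),
            class = "readsim_design")
}

sam_record <- function(qname, flag, chrom, pos, cigar, seq, sa = NULL) {
  tags <- if (!is.null(sa)) paste0("\tSA:Z:", sa) else ""
  paste0(qname, "\t", flag, "\t", chrom, "\t", pos, "\t60\t", cigar,
         "\t*\t0\t0\t", seq, "\t*", tags)
}

#' Simulate split-read alignments over the empty insertion sites
#'
#' For each planted absent locus, emits `reads_per_junction` primary
#' soft-clipped SAM records whose non-clipped segment maps to one flank
#' of the element and whose clipped segment (described in the `SA` tag)
#' maps to the other flank, i.e. the read spans the empty site. Noise
#' reads are soft-clipped records with `SA` descriptors whose breakpoints
#' fall in TE-free territory, more than 25 nt from every element
#' boundary. Base sequences are arbitrary (all `A`). The output is a
#' valid SAM file body with header.
#'
#' @param design a [readsim_design()]; `absent_loci` must be a subset of
#'   the annotation's locus ids.
#' @param te_loci nonempty `GRanges` with `locus_id` metadata.
#' @param chrom_lengths named chromosome lengths for the header.
#' @return character vector of SAM lines; attribute `"truth"` holds the
#'   planted absent locus ids. Write with `writeLines()`.
#' @export
simulate_alignments <- function(design, te_loci, chrom_lengths) {
  stopifnot(inherits(design, "readsim_design"))
  if (length(te_loci) == 0L) stop("te_loci must be nonempty")
  ids <- S4Vectors::mcols(te_loci)$locus_id
  if (!all(design$absent_loci %in% ids))
    stop("absent_loci must be a subset of annotated loci")
  d <- design
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(d$seed)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  seq_full <- strrep("A", d$read_length)
  lines <- character(0)
  k <- 0L
  for (loc in d$absent_loci) {
    g <- te_loci[ids == loc]
    chrom <- as.character(GenomeInfoDb::seqnames(g))
    L <- GenomicRanges::start(g)       # first base of the element, 1-based
    R <- GenomicRanges::end(g)         # last base
    for (r in seq_len(d$reads_per_junction)) {
      k <- k + 1L
      left_len <- sample(seq(d$min_clip, d$read_length - d$min_clip), 1L)
      left_len <- min(left_len, L - 1L)
      if (left_len < d$min_clip)
        stop("element ", loc, " too close to the chromosome start")
      right_len <- d$read_length - left_len
      pos1 <- L - left_len             # left segment covers [pos1, L-1]
      cigar1 <- sprintf("%dM%dS", left_len, right_len)
      sa <- sprintf("%s,%d,+,%dS%dM,60,0;", chrom, R + 1L, left_len,
                    right_len)
      lines <- c(lines, sam_record(sprintf("skip%05d", k), 0L, chrom, pos1,
                                   cigar1, seq_full, sa))
    }
  }
  # noise: clip points in TE-free space, > 25 nt from any element boundary
  guard <- suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
    te_loci, width = GenomicRanges::width(te_loci) + 300L, fix = "center")))
  if (d$noise_reads > 0) {
    spots <- place_intervals(d$noise_reads,
                             rep(2L * d$read_length, d$noise_reads),
                             chrom_lengths, avoid = guard)
    half <- d$read_length %/% 2L
    for (i in seq_len(d$noise_reads)) {
      chrom <- as.character(GenomeInfoDb::seqnames(spots[i]))
      pos1 <- GenomicRanges::start(spots[i])
      cigar1 <- sprintf("%dM%dS", half, d$read_length - half)
      sa <- sprintf("%s,%d,+,%dS%dM,60,0;", chrom,
                    pos1 + half + 40L, half, d$read_length - half)
      lines <- c(lines, sam_record(sprintf("noise%05d", i), 0L, chrom, pos1,
                                   cigar1, seq_full, sa))
    }
  }
  out <- c(header, lines)
  attr(out, "truth") <- d$absent_loci
  out
}
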