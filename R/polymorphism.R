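# reference-consumed length of a CIGAR (M/D/N/=/X)
cigar_ref_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || paste0(ops, collapse = "") != cigar) return(NA_integer_)
  n <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

has_soft_clip <- function(cigar) grepl("S", cigar, fixed = TRUE)

#' Read a SAM file into a record table
#'
#' Thin wrapper over Rsamtools: converts the SAM to BAM and scans the
#' fields and the supplementary-alignment (`SA`) tag used by the
#' split-read caller.
#'
#' @param sam_path path to a SAM file with a valid header.
#' @return data.frame with `qname`, `flag`, `chrom`, `pos`, `cigar`, `sa`
#'   (NA when the tag is absent).
#' @export
read_alignments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "SA"))[[1]]
  sa <- res$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, length(res$qname))
  data.frame(qname = res$qname, flag = res$flag,
             chrom = as.character(res$rname), pos = res$pos,
             cigar = res$cigar, sa = sa, stringsAsFactors = FALSE)
}

#' Extract split-read candidates
#'
#' Keeps primary, soft-clipped records that carry a supplementary-
#' alignment descriptor, resolves the mapped span of the non-clipped
#' portion (from the record) and of the clipped portion (from the
#' descriptor's first entry), and discards pairs whose two segments map to
#' different chromosomes. Duplicate read ids are collapsed. Supplementary
#' and secondary records are excluded up front.
#'
#' @param records data.frame from [read_alignments()].
#' @return data.frame of candidates: `qname`, `chrom`, `left_end` (1-based
#'   last aligned base of the left segment), `right_start` (1-based first
#'   aligned base of the right segment); attribute `"n_malformed"` counts
#'   records skipped for unparseable CIGARs.
#' @export
extract_candidates <- function(records) {
  r <- records
  primary <- bitwAnd(r$flag, 0x100) == 0 & bitwAnd(r$flag, 0x800) == 0
  r <- r[primary & !is.na(r$sa) & has_soft_clip(r$cigar), , drop = FALSE]
  r <- r[!duplicated(r$qname), , drop = FALSE]
  n_malformed <- 0L
  rows <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    ref1 <- cigar_ref_len(r$cigar[i])
    sa1 <- strsplit(r$sa[i], ";", fixed = TRUE)[[1]][1]
    f <- strsplit(sa1, ",", fixed = TRUE)[[1]]
    if (is.na(ref1) || length(f) < 4L) { n_malformed <- n_malformed + 1L; next }
    ref2 <- cigar_ref_len(f[4])
    if (is.na(ref2)) { n_malformed <- n_malformed + 1L; next }
    if (f[1] != r$chrom[i]) next  # segments on different chromosomes
    s1 <- r$pos[i]; e1 <- r$pos[i] + ref1 - 1L
    s2 <- as.integer(f[2]); e2 <- s2 + ref2 - 1L
    if (s1 <= s2) {
      rows[[i]] <- data.frame(qname = r$qname[i], chrom = r$chrom[i],
                              left_end = e1, right_start = s2,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(qname = r$qname[i], chrom = r$chrom[i],
                              left_end = e2, right_start = s1,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(qname = character(0), chrom = character(0),
                      left_end = integer(0), right_start = integer(0),
                      stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Count junction-spanning ("skipping") reads per locus
#'
#' A candidate read supports a locus if its left segment's inner
#' breakpoint lies within `tolerance` nt of the locus's left boundary and
#' its right segment's inner breakpoint within `tolerance` nt of the right
#' boundary — i.e. the two mapped segments flank the element on opposite
#' sides, spanning the empty insertion site. Each read counts at most once
#' per locus.
#'
#' @param candidates data.frame from [extract_candidates()].
#' @param te_loci `GRanges` of annotated elements with `locus_id` metadata.
#' @param tolerance breakpoint distance allowance in nt (default 25).
#' @return data.frame per locus: `locus_id`, `n_reads`.
#' @export
count_skipping_reads <- function(candidates, te_loci, tolerance = 25) {
  ids <- S4Vectors::mcols(te_loci)$locus_id
  chrom <- as.character(GenomeInfoDb::seqnames(te_loci))
  L <- GenomicRanges::start(te_loci)   # 1-based first base of the element
  R <- GenomicRanges::end(te_loci)     # 1-based last base
  n <- integer(length(te_loci))
  for (j in seq_along(te_loci)) {
    hit <- candidates$chrom == chrom[j] &
      abs(candidates$left_end + 1L - L[j]) <= tolerance &
      abs(candidates$right_start - 1L - R[j]) <= tolerance
    n[j] <- length(unique(candidates$qname[hit]))
  }
  data.frame(locus_id = ids, n_reads = n, stringsAsFactors = FALSE)
}

#' Call absent alleles from skipping-read counts
#'
#' An individual is called as lacking at least one allele of an element if
#' `min_reads` or more skipping reads support the empty site (the >= 2
#' default guards against index hopping and similar artifacts). Also
#' summarises, per locus, how many samples of the cohort lack an allele.
#'
#' @param evidence data.frame with `locus_id`, `sample_id`, `n_reads`
#'   (stack the per-sample output of [count_skipping_reads()]).
#' @param min_reads minimum skipping reads for a call (default 2).
#' @return list with `calls` (evidence plus logical `absent`) and
#'   `summary` (per locus: `n_samples_lacking`, `fraction_lacking`).
#' @export
call_absent_alleles <- function(evidence, min_reads = 2) {
  ev <- as.data.frame(evidence)
  stopifnot(all(c("locus_id", "sample_id", "n_reads") %in% names(ev)))
  ev$absent <- ev$n_reads >= min_reads
  n_samples <- length(unique(ev$sample_id))
  agg <- stats::aggregate(absent ~ locus_id, data = ev, FUN = sum)
  names(agg)[2] <- "n_samples_lacking"
  agg$fraction_lacking <- agg$n_samples_lacking / n_samples
  list(calls = ev, summary = agg)
}
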