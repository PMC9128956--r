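# shared fixtures and independent oracles, built in code at test time

# a matrix whose log2(CP10k+1) per-cell-type profile is exactly `levels`
# (one value per cell type, n_per cells each, equal library size `total`):
# feature "probe" carries the profile, feature "filler" absorbs the rest
profile_matrix <- function(levels,
                           cell_types = c("iPSC", "iMeLC", "PGCLC", "MLC",
                                          "TC", "T1LC"),
                           n_per = 2, total = 1e6) {
  stopifnot(length(levels) == length(cell_types))
  type <- rep(cell_types, each = n_per)
  probe <- rep((2^levels - 1) * total / 1e4, each = n_per)
  counts <- rbind(probe = probe, filler = total - probe)
  colnames(counts) <- sprintf("c%02d", seq_along(type))
  expression_matrix(counts,
                    data.frame(cell_id = colnames(counts), cell_type = type))
}

# brute-force reimplementation of the specificity score: explicit loops,
# no shared code with the package path
brute_specificity <- function(counts, cell_type, weights,
                              ssr_floor = 1e-12) {
  n_feat <- nrow(counts); n_cell <- ncol(counts)
  lg <- matrix(0, n_feat, n_cell)
  for (j in seq_len(n_cell)) {
    tot <- sum(counts[, j])
    for (i in seq_len(n_feat)) lg[i, j] <- log2(counts[i, j] / tot * 1e4 + 1)
  }
  types <- names(weights)
  out <- rep(NA_real_, n_feat)
  for (i in seq_len(n_feat)) {
    v <- lg[i, ]
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    if (s == 0) next
    z <- (v - m) / s
    tm <- sapply(types, function(ct) mean(z[cell_type == ct]))
    if (max(tm) == min(tm)) next
    d <- (tm - min(tm)) / (max(tm) - min(tm))
    ssr <- sum((d - weights)^2)
    out[i] <- -log10(max(ssr, ssr_floor))
  }
  out
}

# exact binomial upper tail by enumeration (for n <= 30)
binom_tail_enum <- function(k, n, p) {
  sum(vapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
             numeric(1)))
}

# exact hypergeometric upper tail by enumeration: P(X >= a) drawing n from
# a universe of N with K successes
hyper_tail_enum <- function(a, N, K, n) {
  xs <- a:min(K, n)
  sum(vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

# exact Poisson upper tail P(X >= k) by summation to negligible mass
pois_tail_enum <- function(k, lambda) {
  upper <- max(k, ceiling(lambda)) + 200
  sum(vapply(k:upper, function(x)
    exp(-lambda + x * log(lambda) - lgamma(x + 1)), numeric(1)))
}

# small deterministic GRanges helper
gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

toy_chroms <- c(chr1 = 1e6, chr2 = 5e5)

# n uniform random regions of width w, placed like a null draw
shuffle_regions_for_test <- function(n, w, chrom_lengths, seed) {
  set.seed(seed)
  slots <- chrom_lengths - w + 1
  ch <- sample(names(chrom_lengths), n, replace = TRUE, prob = slots)
  st <- vapply(ch, function(c) sample.int(slots[[c]], 1L), integer(1))
  gr(ch, st, st + w - 1)
}
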