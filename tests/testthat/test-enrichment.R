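test_that("permutation test recovers planted enrichment and the Poisson tail", {
  gen <- simulate_genome(genome_design(planted_overlap_rate = 0.5, seed = 5))
  pe <- permutation_enrichment(gen$peaks$atac, gen$te_loci,
                               gen$chrom_lengths, seed = 9)
  row <- pe[pe$query == "LTR5_Hs", ]
  expect_equal(row$observed, 40)          # 0.5 * 80 planted
  expect_gt(row$fold, 1)
  expect_lt(row$FDR, 0.05)
  # regions identical to targets: every region overlaps, strong enrichment
  tgt <- gen$te_loci[S4Vectors::mcols(gen$te_loci)$subfamily == "LTR5_Hs"]
  pe2 <- permutation_enrichment(tgt, list(LTR5_Hs = tgt),
                                gen$chrom_lengths, seed = 9)
  expect_equal(pe2$observed, length(tgt))
  expect_gt(pe2$fold, 1)
})

test_that("saturated targets give fold 1 and the exact Poisson upper tail", {
  # targets covering the whole genome: every shuffle overlaps everything,
  # so lambda is exactly the region count and the p-value is pure Poisson
  chroms <- c(chr1 = 1e5)
  all_genome <- gr("chr1", 1, 1e5)
  regions <- gr("chr1", seq(1, 5e4, length.out = 5),
                seq(1, 5e4, length.out = 5) + 99)
  pe <- permutation_enrichment(regions, list(everything = all_genome),
                               chroms, n_perm = 20, seed = 3)
  expect_equal(pe$lambda, 5)
  expect_equal(pe$fold, 1)
  expect_equal(pe$p, pois_tail_enum(5, 5), tolerance = 1e-9)
  expect_equal(pois_tail_enum(5, 5), 0.5595, tolerance = 1e-4)
})

test_that("permutation null is calibrated (fold near 1, type-I controlled)", {
  chroms <- c(chr1 = 2e5, chr2 = 1e5)
  set.seed(17)
  targets <- gr(sample(names(chroms), 60, TRUE, prob = c(2, 1)),
                st <- sample.int(9e4, 60), st + 499)
  n_rep <- 200
  folds <- ps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    regions <- shuffle_regions_for_test(30, 200, chroms, seed = 1000 + r)
    pe <- permutation_enrichment(regions, list(t = targets), chroms,
                                 n_perm = 60, seed = 5000 + r)
    folds[r] <- pe$fold; ps[r] <- pe$p
  }
  lam_big <- mean(folds[is.finite(folds)])
  expect_gt(lam_big, 0.7)
  expect_lt(lam_big, 1.4)
  expect_lte(mean(ps < 0.05), 0.10)
})

test_that("lambda of zero is floored and reported", {
  chroms <- c(chr1 = 1e8)
  targets <- gr("chr1", 1, 100)          # tiny target: shuffles never hit
  regions <- gr("chr1", 50, 80)          # but the observed region does
  pe <- permutation_enrichment(regions, list(t = targets), chroms,
                               n_perm = 10, seed = 2)
  expect_true(pe$lambda_floored)
  expect_equal(pe$p, ppois(0, 1 / 10, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(is.infinite(pe$fold))
})

test_that("GREAT binomial test matches exact enumeration", {
  res <- great_test(Ci = 8, Cb = 10, Li = 1000, Lb = 2000)
  expect_equal(res$fold, 1.6)
  expect_equal(res$p, 56 / 1024, tolerance = 1e-12)
  expect_equal(res$p, binom_tail_enum(8, 10, 0.5), tolerance = 1e-12)
  # enumeration agreement across a grid of small tables
  for (Cb in c(5, 12, 30)) {
    for (Ci in c(0, 1, Cb %/% 2, Cb)) {
      for (frac in c(0.1, 0.5, 0.9)) {
        expect_equal(great_test(Ci, Cb, frac * 1000, 1000)$p,
                     binom_tail_enum(Ci, Cb, frac), tolerance = 1e-9,
                     label = sprintf("Ci=%d Cb=%d frac=%.1f", Ci, Cb, frac))
      }
    }
  }
})

test_that("GREAT windows merge and behave at the degenerate limits", {
  si <- GenomeInfoDb::Seqinfo("chr1", 1e6)
  tss_all <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1e5, 1.5e5, 6e5), width = 1), seqinfo = si)
  tss_int <- tss_all[1:2]
  peaks <- gr("chr1", c(9e4, 1.4e5, 5.9e5, 8e5), c(9.05e4, 1.41e5, 5.95e5, 8.05e5))
  res <- great_enrichment(peaks, tss_int, tss_all, window = 5e4)
  # the two interest windows overlap and must be merged, not double-counted:
  # [50kb,150kb] u [100kb,200kb] -> one 150,001-bp region
  expect_equal(res$Li, 150001)
  expect_equal(res$Ci, 2)
  expect_equal(res$Cb, 3)
  # interest == background: fold 1, p 1
  res2 <- great_enrichment(peaks, tss_all, tss_all, window = 5e4)
  expect_equal(res2$fold, 1)
  expect_equal(res2$p, 1)
  # window 0: undefined fold, warning not error
  expect_warning(res3 <- great_enrichment(peaks, tss_int, tss_all, window = 0))
  expect_true(is.na(res3$fold))
  # no background peaks at all
  far_peaks <- gr("chr1", 9.5e5, 9.6e5)
  expect_error(great_enrichment(far_peaks, tss_int, tss_all, window = 1e4),
               "background")
})

test_that("window merging is idempotent and Li monotone in window size", {
  set.seed(31)
  si <- GenomeInfoDb::Seqinfo("chr1", 1e6)
  tss <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(9e5, 40), width = 1), seqinfo = si)
  peaks <- gr("chr1", s <- sample.int(9e5, 30), s + 200)
  prev <- 0
  for (w in c(1e3, 1e4, 5e4, 2e5)) {
    res <- great_enrichment(peaks, tss, tss, window = w)
    expect_gte(res$Li, prev)
    prev <- res$Li
  }
})

test_that("Fisher category enrichment matches the cross-product and hypergeometric", {
  # craft regions realising the table [[10,10],[10,70]]
  regions <- gr("chr1", seq(1, by = 1000, length.out = 100),
                seq(1, by = 1000, length.out = 100) + 99)
  categories <- rep(c("hot", "cold"), c(20, 80))
  overlapping <- c(1:10, 21:30)   # 10 in category, 10 outside
  sites <- regions[overlapping]
  res <- fisher_category_enrichment(regions, categories,
                                    list(tf = sites))
  row <- res[res$category == "hot", ]
  expect_equal(row$odds_ratio, 7.0)
  expect_equal(unlist(row[, c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 10, 10, 70))
  expect_equal(row$p,
               fisher.test(matrix(c(10, 10, 10, 70), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # one-sided hypergeometric enumeration bounds the two-sided p
  expect_lte(hyper_tail_enum(10, 100, 20, 20), row$p * (1 + 1e-9))

  # zero overlap in category -> OR 0
  res0 <- fisher_category_enrichment(regions, categories,
                                     list(tf = regions[25:40]))
  expect_equal(res0$odds_ratio[res0$category == "hot"], 0)

  # category == universe -> NA with warning
  expect_warning(
    resU <- fisher_category_enrichment(regions, rep("all", 100),
                                       list(tf = sites)),
    "universe")
  expect_true(is.na(resU$odds_ratio))
})

test_that("two-tailed Fisher p matches hypergeometric enumeration on small tables", {
  # two-tailed p = sum of all hypergeometric outcomes no more likely than
  # the observed one (n <= 20)
  two_tailed_enum <- function(a, b, c, d) {
    K <- a + b; n <- a + c; N <- a + b + c + d
    xs <- max(0, n - (N - K)):min(K, n)
    dens <- vapply(xs, function(x)
      choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1))
    sum(dens[dens <= dens[xs == a] * (1 + 1e-7)])
  }
  for (tab in list(c(3, 2, 1, 4), c(5, 0, 2, 3), c(2, 6, 5, 7))) {
    p_pkg <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, two_tailed_enum(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7, label = paste(tab, collapse = ","))
  }
})
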