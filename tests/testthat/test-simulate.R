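test_that("expression generator is seed-deterministic and validates designs", {
  d <- expression_design(n_cells_per_type = 20,
                         n_genes_per_class = c(both_up = 50, pgclc_only = 10,
                                               naive_only = 10, null = 30),
                         seed = 1)
  a <- simulate_expression(d)
  b <- simulate_expression(d)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_equal(nrow(a$truth), 100)
  expect_equal(as.vector(table(a$truth$class)[c("both_up", "null")]),
               c(50, 30))
  expect_error(
    simulate_expression(expression_design(
      n_cells_per_type = c(iPSC = 0, iMeLC = 5, PGCLC = 5, MLC = 5, TC = 5,
                           T1LC = 5, naiveESC = 5, primedESC = 5))),
    "iPSC")
})

test_that("a no-signal design still emits the truth table and flat scores", {
  d <- expression_design(n_cells_per_type = 60, effect_size = 1,
                         n_genes_per_class = c(both_up = 50, pgclc_only = 50,
                                               naive_only = 50, null = 50),
                         seed = 3)
  sim <- simulate_expression(d)
  expect_equal(nrow(sim$truth), 200)
  sc <- specificity_score(sim$matrix)
  cls <- sim$truth$class[match(sc$feature, sim$truth$gene)]
  # score distributions indistinguishable across truth classes
  p <- kruskal.test(sc$score, factor(cls))$p.value
  expect_gt(p, 0.01)
})

test_that("near-Poisson library sizes match the design mean", {
  lib <- 10000
  d <- expression_design(n_cells_per_type = 30, effect_size = 1,
                         n_genes_per_class = c(both_up = 1, pgclc_only = 1,
                                               naive_only = 1, null = 200),
                         library_size = lib, dispersion = 1e-4, seed = 9)
  sim <- simulate_expression(d)
  totals <- colSums(sim$matrix$counts)
  # Poisson limit: total ~ Poisson(lib), SD sqrt(lib); mean of n cells
  n <- length(totals)
  expect_lt(abs(mean(totals) - lib), 3 * sqrt(lib / n))
})

test_that("genome generator plants exact overlap counts and is reproducible", {
  d0 <- genome_design(planted_overlap_rate = 0, seed = 2)
  g0 <- simulate_genome(d0)
  expect_equal(sum(IRanges::overlapsAny(g0$peaks$atac, g0$te_loci)), 0)

  d1 <- genome_design(planted_overlap_rate = 1, n_peaks = c(atac = 40),
                      seed = 2)
  g1 <- simulate_genome(d1)
  tgt <- g1$te_loci[S4Vectors::mcols(g1$te_loci)$subfamily == "LTR5_Hs"]
  expect_equal(sum(IRanges::overlapsAny(g1$peaks$atac, tgt)), 40)

  f1 <- tempfile(); f2 <- tempfile()
  write_te_bed(simulate_genome(d1)$te_loci, f1)
  write_te_bed(simulate_genome(d1)$te_loci, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical output
  unlink(c(f1, f2))

  expect_error(genome_design(chrom_lengths = c(chr1 = 100),
                             te_length_range = c(500, 1000)),
               "exceeds")
})

test_that("TE BED round-trip preserves loci and applies the score filter", {
  g <- simulate_genome(genome_design(seed = 4))
  f <- tempfile(fileext = ".bed")
  write_te_bed(g$te_loci, f)
  back <- read_te_bed(f, min_sw_score = 0)
  expect_equal(length(back), length(g$te_loci))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(g$te_loci))
  expect_equal(S4Vectors::mcols(back)$subfamily,
               S4Vectors::mcols(g$te_loci)$subfamily)
  # reliability filter on load
  hi <- read_te_bed(f, min_sw_score = 5000)
  expect_true(all(S4Vectors::mcols(hi)$sw_score >= 5000))
  expect_lt(length(hi), length(back))
  unlink(f)
})

test_that("ortholog history is a staircase honouring planted branches", {
  h <- simulate_ortholog_history(history_design(n_loci = 50,
                                                missing_rate = 0, seed = 6))
  tab <- as.matrix(h$table)
  expect_false(anyNA(tab))
  # species presence follows the planted branch exactly
  for (i in seq_len(nrow(tab))) {
    br <- h$truth$branch[i]
    expected <- switch(br,
      HCGOG = c(1, 1, 1, 1, 0, 0), HCGO = c(1, 1, 1, 0, 0, 0),
      HCG = c(1, 1, 0, 0, 0, 0), HC = c(1, 0, 0, 0, 0, 0),
      H = c(0, 0, 0, 0, 0, 0))
    expect_equal(unname(tab[i, ]), expected)
  }
  # older branches strictly precede younger ones in the order
  ranks <- match(h$truth$branch, c("HCGOG", "HCGO", "HCG", "HC", "H"))
  expect_true(!is.unsorted(ranks))

  h_all_h <- simulate_ortholog_history(
    history_design(n_loci = 20, branch_proportions = c(HCGOG = 0, HCGO = 0,
                                                       HCG = 0, HC = 0, H = 1),
                   seed = 1))
  expect_true(all(as.matrix(h_all_h$table) == 0))
})

test_that("missing-value masking hits the designed rate", {
  rate <- 0.3
  h <- simulate_ortholog_history(history_design(n_loci = 200,
                                                missing_rate = rate,
                                                seed = 8))
  n_cells <- prod(dim(h$table))
  obs <- sum(is.na(h$table))
  # binomial 99% interval around the design rate
  ci <- qbinom(c(0.005, 0.995), n_cells, rate)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("read simulator emits valid SAM that round-trips through Rsamtools", {
  gen <- simulate_genome(genome_design(n_te_loci = c(LTR5_Hs = 20), seed = 3))
  absent <- S4Vectors::mcols(gen$te_loci)$locus_id[c(2, 9)]
  sam <- simulate_alignments(readsim_design(absent_loci = absent,
                                            reads_per_junction = 3,
                                            noise_reads = 5, seed = 4),
                             gen$te_loci, gen$chrom_lengths)
  expect_equal(attr(sam, "truth"), absent)
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  expect_no_warning(rec <- read_alignments(f))
  expect_equal(nrow(rec), 2 * 3 + 5)
  expect_true(all(!is.na(rec$sa)))
  unlink(f)
  expect_error(readsim_design(read_length = 30), "read_length")
})
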