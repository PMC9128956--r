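test_that("MSA filtering removes low-coverage columns then gappy sequences", {
  # 10 sequences x 10 columns; column 1 has 8/10 non-gaps (80% < 85%)
  base <- strrep("A", 10)
  seqs <- rep(base, 10)
  substr(seqs[1], 1, 1) <- "-"
  substr(seqs[2], 1, 1) <- "-"
  msa <- Biostrings::DNAStringSet(setNames(seqs, sprintf("s%02d", 1:10)))
  out <- filter_msa(msa)
  expect_equal(unique(Biostrings::width(out)), 9)
  expect_equal(attr(out, "removed_columns"), 1L)
  expect_length(out, 10)

  # a sequence with 20% gaps in the retained columns is removed
  seqs2 <- rep(strrep("A", 10), 10)
  seqs2[1] <- paste0("--", strrep("A", 8))   # 2/10 gaps = 20%
  out2 <- filter_msa(Biostrings::DNAStringSet(
    setNames(seqs2, sprintf("s%02d", 1:10))))
  expect_equal(attr(out2, "removed_sequences"), "s01")
  expect_length(out2, 9)

  # gap-free alignment: identity
  clean <- Biostrings::DNAStringSet(setNames(rep("ACGTACGT", 5),
                                             sprintf("s%d", 1:5)))
  out3 <- filter_msa(clean)
  expect_equal(as.character(out3), as.character(clean))
})

test_that("branch outliers are found by standardized external branch length", {
  tr <- ape::stree(101, type = "star")
  tr$edge.length <- c(rep(1, 100), 50)
  out <- detect_branch_outliers(tr)
  expect_equal(out, tr$tip.label[101])
  # direct z-score oracle
  len <- tr$edge.length
  z <- (50 - mean(len)) / sd(len)
  expect_equal(z, 9.950372, tolerance = 1e-6)
  expect_gt(z, 3)
  # equal branches: no outliers
  tr2 <- ape::stree(10, type = "star")
  tr2$edge.length <- rep(1, 10)
  expect_length(detect_branch_outliers(tr2), 0)
  tr3 <- ape::stree(2, type = "star")
  tr3$edge.length <- c(1, 2)
  expect_error(detect_branch_outliers(tr3), "3 leaves")
})

test_that("window dating finds the youngest reliable ortholog boundary", {
  # 15 loci; chimp present at 1-6, missing at 7, absent 8-15
  ids <- sprintf("L%02d", 1:15)
  tab <- data.frame(chimpanzee = c(rep(1, 6), NA, rep(0, 8)),
                    row.names = ids)
  res <- date_insertions(ids, tab, window = 10, min_present = 4)
  # qualifying windows start at 1-3 (counts 6,5,4); youngest window is
  # loci 3-12, whose youngest present locus is L06 -> loci 1-5 flagged
  expect_equal(unname(res$boundary["chimpanzee"]), 6)
  expect_equal(unname(which(res$flags[, "chimpanzee"])), 1:5)

  # species absent everywhere: no qualifying window, no flags
  tab0 <- data.frame(gorilla = rep(0, 15), row.names = ids)
  res0 <- date_insertions(ids, tab0)
  expect_true(is.na(res0$boundary))
  expect_false(any(res0$flags))

  # species present everywhere: boundary is the last locus
  tab1 <- data.frame(gibbon = rep(1, 15), row.names = ids)
  res1 <- date_insertions(ids, tab1)
  expect_equal(unname(res1$boundary), 15)
  expect_equal(sum(res1$flags), 14)

  # fewer loci than the window: single-window evaluation
  short <- date_insertions(ids[1:5],
                           data.frame(chimpanzee = c(1, 1, 1, 1, 0),
                                      row.names = ids[1:5]))
  expect_equal(unname(short$boundary), 4)
})

test_that("pre-divergence flags are monotone with tree order", {
  for (seed in 1:3) {
    h <- simulate_ortholog_history(history_design(n_loci = 120,
                                                  missing_rate = 0.25,
                                                  seed = seed))
    res <- date_insertions(h$order, h$table)
    for (s in colnames(res$flags)) {
      fl <- res$flags[, s]
      if (any(fl)) expect_true(all(fl[seq_len(max(which(fl)))]))
    }
  }
})

test_that("raising the missing rate never adds qualifying windows", {
  count_flags <- function(rate, seed) {
    h <- simulate_ortholog_history(history_design(n_loci = 150,
                                                  missing_rate = rate,
                                                  seed = seed))
    sum(date_insertions(h$order, h$table)$flags)
  }
  for (seed in 1:3) {
    f <- vapply(c(0, 0.3, 0.6), count_flags, numeric(1), seed = seed)
    expect_true(all(diff(f) <= 0))
  }
})

test_that("branch assignment follows the deepest flagged species", {
  flags <- rbind(l1 = c(chimpanzee = TRUE, gorilla = TRUE,
                        orangutan = FALSE, gibbon = FALSE),
                 l2 = c(FALSE, FALSE, FALSE, FALSE),
                 l3 = c(TRUE, TRUE, TRUE, TRUE))
  lab <- assign_branches(flags)
  expect_equal(as.character(lab[c("l1", "l2", "l3")]),
               c("HCG", "H", "HCGOG"))
  # conflicting flags: deepest-true wins, with a warning
  conflict <- rbind(l4 = c(chimpanzee = FALSE, gorilla = FALSE,
                           orangutan = FALSE, gibbon = TRUE))
  expect_warning(lab2 <- assign_branches(conflict), "deepest")
  expect_equal(as.character(lab2), "HCGOG")
})

test_that("branch recovery meets the planted-history targets", {
  h0 <- simulate_ortholog_history(history_design(n_loci = 200,
                                                 missing_rate = 0, seed = 4))
  br0 <- assign_branches(date_insertions(h0$order, h0$table)$flags)
  agree0 <- as.character(br0) == h0$truth$branch
  expect_gte(mean(agree0), 0.95)
  # errors only at branch boundaries: any locus >= window length away from
  # every truth-branch change is recovered exactly
  changes <- which(diff(match(h0$truth$branch,
                              c("HCGOG", "HCGO", "HCG", "HC", "H"))) != 0)
  far <- vapply(seq_along(agree0), function(i)
    all(abs(i - changes) > 10), logical(1))
  expect_true(all(agree0[far]))

  h3 <- simulate_ortholog_history(history_design(n_loci = 200,
                                                 missing_rate = 0.3, seed = 4))
  br3 <- assign_branches(date_insertions(h3$order, h3$table)$flags)
  expect_gte(mean(as.character(br3) == h3$truth$branch), 0.85)
})

test_that("gene stratification propagates unique labels and flags conflicts", {
  labels <- factor(setNames(c("HC", "H", "HC"), c("l1", "l2", "l3")),
                   levels = c("HCGOG", "HCGO", "HCG", "HC", "H"))
  out <- stratify_genes_by_date(
    list(g1 = "l1", g2 = c("l1", "l3"), g3 = c("l1", "l2"), g4 = "l9"),
    labels)
  expect_equal(as.character(out), c("HC", "HC", "ND", "ND"))
})

test_that("ortholog table TSV round-trips", {
  h <- simulate_ortholog_history(history_design(n_loci = 30,
                                                missing_rate = 0.2, seed = 2))
  f <- tempfile(fileext = ".tsv")
  write_ortholog_table(h$table, f)
  back <- read_ortholog_table(f)
  expect_equal(as.matrix(back), as.matrix(h$table))
  unlink(f)
})
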