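#' Default synthetic pipeline configuration
#'
#' Returns the configuration for a fully synthetic end-to-end run. All
#' analysis thresholds default to the values used throughout the package:
#' top 10% specificity score, log2FC > 1 / FDR < 0.05 upregulation, 50 kb
#' adjacency, 100 permutations, dating window 10 with min present 4,
#' 25 nt breakpoint tolerance, 2 skipping reads, Jaccard 0.5, and 0.5%
#' cell detection. The single `seed` is expanded into fixed per-stage
#' streams so skipping one stage does not shift another's randomness.
#'
#' @param seed integer master seed.
#' @param output_dir directory for stage tables and the JSON summary.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, output_dir = tempfile("ervrun")) {
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    expression = list(n_cells_per_type = 200, effect_size = 4,
                      n_genes_per_class = c(both_up = 100, pgclc_only = 100,
                                            naive_only = 100, null = 1700),
                      library_size = 10000, dispersion = 0.3),
    other_species = list(lineage_specific_fraction = 0.5),
    genome = list(chrom_lengths = c(chr1 = 2e6, chr2 = 1.5e6),
                  n_te_loci = c(LTR5_Hs = 60, LTR5B = 40),
                  n_peaks = c(atac = 80), planted_overlap_rate = 0.3,
                  n_genes = 400),
    thresholds = list(top_fraction = 0.10, fc = 1, fdr = 0.05,
                      window_distance = 5e4, n_perm = 100,
                      dating_window = 10, dating_min_present = 4,
                      tolerance = 25, min_reads = 2, jaccard = 0.5,
                      min_cell_fraction = 0.005),
    history = list(missing_rate = 0.1),
    polymorphism = list(n_samples = 20, n_absent = 5,
                        reads_per_junction = 4, noise_reads = 10),
    overrides = NULL,
    external_de = NULL),
    class = "pipeline_config")
}

stage_seed <- function(config, k) (config$seed %% 100000L) * 10L + k

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in dependency order on synthetic inputs with
#' known ground truth: expression simulation and specificity scoring,
#' four-way classification, genomic enrichment (permutation and
#' GREAT-style), regulator-style active-locus and proximity definitions,
#' cross-species comparison, insertion dating, polymorphism calling, and
#' gene-set enrichment with redundancy pruning. Writes one TSV per stage
#' plus a machine-readable JSON summary into `config$output_dir`;
#' deterministic (byte-identical) under a fixed seed. An externally
#' supplied differential-expression table (`config$external_de`) replaces
#' the internal stand-in test, leaving downstream stages unchanged.
#'
#' @param config a [default_config()] list, or the path to a YAML file
#'   with the same structure.
#' @return (invisibly) the report: a named list of stage tables.
#' @export
run_all <- function(config = default_config()) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    base <- default_config(seed = cfg$seed %||% 1L)
    config <- utils::modifyList(base, cfg)
    class(config) <- "pipeline_config"
  }
  th <- config$thresholds
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()

  ## 1. expression + specificity scores -------------------------------
  des_h <- expression_design(
    n_cells_per_type = config$expression$n_cells_per_type,
    n_genes_per_class = config$expression$n_genes_per_class,
    effect_size = config$expression$effect_size,
    library_size = config$expression$library_size,
    dispersion = config$expression$dispersion,
    seed = stage_seed(config, 1L))
  sim_h <- simulate_expression(des_h)
  scores <- specificity_score(sim_h$matrix)
  report$scores <- scores

  ## 2. differential + classification ---------------------------------
  meta <- sim_h$matrix$cell_meta
  naive <- meta$cell_id[meta$cell_type == "naiveESC"]
  primed <- meta$cell_id[meta$cell_type == "primedESC"]
  de <- if (!is.null(config$external_de)) de_adapter(config$external_de)
        else differential_upregulation(sim_h$matrix, naive, primed)
  labels <- classify_features(scores, de, top_fraction = th$top_fraction,
                              fc_thresh = th$fc, fdr_thresh = th$fdr,
                              overrides = config$overrides)
  report$classification <- labels
  report$truth_expression <- sim_h$truth

  ## 3. genome + enrichment -------------------------------------------
  des_g <- genome_design(
    chrom_lengths = config$genome$chrom_lengths,
    n_te_loci = config$genome$n_te_loci,
    n_peaks = config$genome$n_peaks,
    planted_overlap_rate = config$genome$planted_overlap_rate,
    n_genes = config$genome$n_genes,
    seed = stage_seed(config, 3L))
  gen <- simulate_genome(des_g)
  perm <- permutation_enrichment(gen$peaks[[1]], gen$te_loci,
                                 gen$chrom_lengths, n_perm = th$n_perm,
                                 seed = stage_seed(config, 4L))
  report$enrichment_permutation <- perm

  tss_genes <- S4Vectors::mcols(gen$tss)$gene
  interest <- tss_genes[tss_genes %in%
    labels$feature[labels$category == "both"]]
  great <- great_enrichment(gen$peaks[[1]],
                            gen$tss[tss_genes %in% interest],
                            gen$tss, window = th$window_distance)
  report$enrichment_great <- great

  ## 3b. regulator calling --------------------------------------------
  # two synthetic TFs named after simulated genes: one with binding sites
  # planted on the target subfamily's loci, one binding TE-free space
  target_fam0 <- names(config$genome$n_te_loci)[1]
  tgt <- gen$te_loci[S4Vectors::mcols(gen$te_loci)$subfamily == target_fam0]
  old_rs <- .Random.seed_save(); set.seed(stage_seed(config, 9L))
  anchors <- sample(seq_along(tgt), 30, replace = TRUE)
  planted_sites <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(tgt)[anchors],
    IRanges::IRanges(GenomicRanges::start(tgt)[anchors] + 10L, width = 50L))
  null_sites <- place_intervals(30, rep(50L, 30), gen$chrom_lengths,
                                avoid = gen$te_loci)
  .Random.seed_restore(old_rs)
  lg_all <- normalize_cp10k(sim_h$matrix)$log2cp10k
  type_of <- meta$cell_type[match(colnames(lg_all), meta$cell_id)]
  mean_in <- function(ct) rowMeans(lg_all[, type_of == ct, drop = FALSE])
  tf_names <- c(sim_h$truth$gene[sim_h$truth$class == "both_up"][1],
                sim_h$truth$gene[sim_h$truth$class == "null"][1])
  tf_sites <- stats::setNames(list(planted_sites, null_sites), tf_names)
  mp <- mean_in("PGCLC")[tf_names]
  mn <- mean_in("naiveESC")[tf_names]
  regulators <- identify_regulators(tf_sites, tgt, gen$chrom_lengths,
                                    scores, de, mp, mn,
                                    n_perm = th$n_perm,
                                    seed = stage_seed(config, 10L),
                                    top_fraction = th$top_fraction)
  report$regulators <- regulators

  ## 4. active loci + proximity genes ---------------------------------
  active_tab <- define_active_loci(gen$te_loci, peak_sets = gen$peaks,
                                   min_cell_fraction = th$min_cell_fraction)
  target_fam <- names(config$genome$n_te_loci)[1]
  is_target <- S4Vectors::mcols(gen$te_loci)$subfamily == target_fam
  active <- gen$te_loci[active_tab$active & is_target]
  near <- genes_near_loci(gen$tss, active, distance = th$window_distance)
  report$active_loci <- active_tab
  report$proximity <- near

  ## 5. cross-species comparison --------------------------------------
  # the other species lacks the TE-driven upregulation for a planted
  # fraction of the shared-up genes (its truth flips them to null)
  des_o <- des_h
  des_o$seed <- stage_seed(config, 5L)
  sim_o <- simulate_expression(des_o)
  n_flip <- round(config$other_species$lineage_specific_fraction *
                  sum(sim_h$truth$class == "both_up"))
  flip <- sim_h$truth$gene[sim_h$truth$class == "both_up"][seq_len(n_flip)]
  # remove the planted effect in the flipped genes of the other species
  des_o2 <- des_o
  counts_o <- sim_o$matrix$counts
  null_template <- simulate_expression(
    utils::modifyList(des_o2, list(effect_size = 1)))
  counts_o[flip, ] <- null_template$matrix$counts[flip, ]
  mat_o <- expression_matrix(counts_o, sim_o$matrix$cell_meta)
  scores_o <- specificity_score(mat_o)
  de_o <- differential_upregulation(mat_o, naive, primed)
  labels_o <- classify_features(scores_o, de_o,
                                top_fraction = th$top_fraction,
                                fc_thresh = th$fc, fdr_thresh = th$fdr)
  adjacency <- stats::setNames(near$adjacent, near$gene)
  omap <- data.frame(human = labels$feature, other = labels$feature)
  comp <- compare_species(labels, labels_o, omap, adjacency)
  report$species_comparison <- comp
  report$truth_lineage_specific <- flip

  ## 6. insertion dating ----------------------------------------------
  des_t <- history_design(n_loci = sum(is_target),
                          missing_rate = config$history$missing_rate,
                          seed = stage_seed(config, 6L))
  hist <- simulate_ortholog_history(des_t)
  dated <- date_insertions(hist$order, hist$table,
                           window = th$dating_window,
                           min_present = th$dating_min_present)
  branches <- assign_branches(dated$flags)
  # synthetic linkage: the i-th target locus corresponds to the i-th
  # history locus, so proximity genes can be stratified by insertion date
  te_ids <- S4Vectors::mcols(gen$te_loci)$locus_id[is_target]
  locus_labels <- stats::setNames(as.character(branches), te_ids)
  adj_genes <- near$gene[near$adjacent]
  active_ids <- S4Vectors::mcols(active)$locus_id
  gene_loci <- lapply(stats::setNames(adj_genes, adj_genes), function(g)
    active_ids[near$nearest_locus[near$gene == g]])
  gene_branches <- stratify_genes_by_date(gene_loci, locus_labels)
  report$dating <- data.frame(locus_id = te_ids,
                              branch = as.character(branches),
                              truth = hist$truth$branch,
                              stringsAsFactors = FALSE)
  report$gene_dating <- data.frame(gene = names(gene_branches),
                                   branch = as.character(gene_branches),
                                   stringsAsFactors = FALSE)

  ## 7. polymorphism calling ------------------------------------------
  pm <- config$polymorphism
  absent <- te_ids[seq_len(min(pm$n_absent, length(te_ids)))]
  target_loci <- gen$te_loci[is_target]
  evidence <- list()
  for (s in seq_len(pm$n_samples)) {
    carries <- s <= ceiling(pm$n_samples / 2)   # half the cohort
    des_r <- readsim_design(
      absent_loci = if (carries) absent else character(0),
      reads_per_junction = pm$reads_per_junction,
      noise_reads = pm$noise_reads,
      seed = stage_seed(config, 7L) + s)
    sam <- simulate_alignments(des_r, target_loci, gen$chrom_lengths)
    f <- tempfile(fileext = ".sam")
    writeLines(sam, f)
    cand <- extract_candidates(read_alignments(f))
    unlink(f)
    cnt <- count_skipping_reads(cand, target_loci,
                                tolerance = th$tolerance)
    cnt$sample_id <- sprintf("sample%02d", s)
    evidence[[s]] <- cnt
  }
  calls <- call_absent_alleles(do.call(rbind, evidence),
                               min_reads = th$min_reads)
  report$polymorphism <- calls$summary
  report$truth_absent <- absent

  ## 8. gene-set enrichment -------------------------------------------
  universe <- labels$feature
  both_genes <- labels$feature[labels$category == "both"]
  set_seeds <- stage_seed(config, 8L)
  old <- .Random.seed_save(); set.seed(set_seeds)
  sets <- list(
    planted_shared = sim_h$truth$gene[sim_h$truth$class == "both_up"],
    planted_shared_half = sim_h$truth$gene[
      sim_h$truth$class == "both_up"][
        seq_len(min(50, sum(sim_h$truth$class == "both_up")))],
    planted_pgclc = sim_h$truth$gene[sim_h$truth$class == "pgclc_only"],
    random_a = sample(universe, 80),
    random_b = sample(universe, 120))
  .Random.seed_restore(old)
  gs <- enrich_gene_sets(both_genes, sets, universe)
  pruned <- prune_redundant(gs, sets, universe,
                            jaccard_threshold = th$jaccard,
                            fdr_threshold = th$fdr)
  report$gene_sets <- gs
  report$gene_sets_pruned <- pruned

  write_report(report, config)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write stage TSVs plus one JSON summary; byte-stable across reruns
write_report <- function(report, config) {
  outdir <- config$output_dir
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$scores, "scores")
  wt(report$classification, "classification")
  wt(report$enrichment_permutation, "enrichment_permutation")
  wt(report$enrichment_great, "enrichment_great")
  wt(report$regulators, "regulators")
  wt(report$active_loci, "active_loci")
  wt(report$proximity, "proximity")
  lr <- report$species_comparison$likely_regulated
  wt(data.frame(gene = if (length(lr)) lr else character(0)),
     "likely_regulated")
  wt(report$dating, "dating")
  wt(report$gene_dating, "gene_dating")
  wt(report$polymorphism, "polymorphism")
  wt(report$gene_sets, "gene_sets")
  wt(report$gene_sets_pruned, "gene_sets_pruned")

  cfg <- unclass(config)
  cfg$output_dir <- NULL   # hash the analysis settings, not the paths
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  summary <- list(
    provenance = list(config_md5 = cfg_hash, seed = config$seed),
    category_counts = as.list(table(report$classification$category)),
    n_active_loci = sum(report$active_loci$active),
    n_adjacent_genes = sum(report$proximity$adjacent),
    n_likely_regulated = length(report$species_comparison$likely_regulated),
    dating_histogram = as.list(table(factor(report$dating$branch,
      levels = c("HCGOG", "HCGO", "HCG", "HC", "H")))),
    n_polymorphic_loci = sum(report$polymorphism$n_samples_lacking > 0),
    n_gene_sets_kept = nrow(report$gene_sets_pruned))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
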