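#' Design for the synthetic ortholog-history generator
#'
#' @param n_loci total TE loci.
#' @param branch_proportions named fractions over the insertion branches
#'   HCGOG, HCGO, HCG, HC, H; must sum to 1.
#' @param missing_rate probability a presence/absence cell is masked to NA
#'   (in [0, 1)).
#' @param seed integer seed.
#' @return list of class `history_design`.
#' @export
history_design <- function(n_loci = 200,
                           branch_proportions = c(HCGOG = 0.30, HCGO = 0.15,
                                                  HCG = 0.15, HC = 0.15,
                                                  H = 0.25),
                           missing_rate = 0,
                           seed = 1L) {
  stopifnot(n_loci >= 1, missing_rate >= 0, missing_rate < 1)
  need <- c("HCGOG", "HCGO", "HCG", "HC", "H")
  if (!all(need %in% names(branch_proportions)))
    stop("branch_proportions needs: ", paste(need, collapse = ", "))
  bp <- branch_proportions[need]
  if (abs(sum(bp) - 1) > 1e-8) stop("branch_proportions must sum to 1")
  structure(list(n_loci = as.integer(n_loci), branch_proportions = bp,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "history_design")
}

# which species carry an ortholog for each insertion branch
branch_presence <- function() {
  species <- c("chimpanzee", "gorilla", "orangutan", "gibbon",
               "macaque", "marmoset")
  m <- rbind(HCGOG = c(1, 1, 1, 1, 0, 0),
             HCGO  = c(1, 1, 1, 0, 0, 0),
             HCG   = c(1, 1, 0, 0, 0, 0),
             HC    = c(1, 0, 0, 0, 0, 0),
             H     = c(0, 0, 0, 0, 0, 0))
  colnames(m) <- species
  m
}

#' Simulate an ortholog presence/absence history with planted branches
#'
#' Assigns each locus an insertion branch (multinomial rounding of the
#' design proportions), orders loci old to young (all HCGOG loci before
#' HCGO loci, and so on, as a tree-derived ladder order would), fills the
#' species presence/absence staircase implied by each branch (e.g. an HCG
#' locus is present in chimpanzee and gorilla and absent elsewhere), and
#' finally masks cells to missing at `missing_rate`.
#'
#' @param design a [history_design()].
#' @return list with `order` (locus ids, oldest first), `table`
#'   (data.frame of 1/0/NA, rownames = locus ids, species columns), and
#'   `truth` (data.frame `locus_id`, `branch`).
#' @export
simulate_ortholog_history <- function(design) {
  stopifnot(inherits(design, "history_design"))
  d <- design
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(d$seed)

  branches <- names(d$branch_proportions)
  n_per <- floor(d$branch_proportions * d$n_loci)
  rem <- d$n_loci - sum(n_per)
  if (rem > 0) {
    frac <- d$branch_proportions * d$n_loci - n_per
    top_up <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_per[top_up] <- n_per[top_up] + 1L
  }
  branch <- rep(branches, n_per)           # oldest branch first
  ids <- sprintf("locus%04d", seq_len(d$n_loci))

  pres <- branch_presence()[branch, , drop = FALSE]
  rownames(pres) <- ids
  if (d$missing_rate > 0) {
    mask <- matrix(stats::runif(length(pres)) < d$missing_rate,
                   nrow(pres), ncol(pres))
    pres[mask] <- NA
  }
  list(order = ids,
       table = as.data.frame(pres),
       truth = data.frame(locus_id = ids, branch = branch,
                          stringsAsFactors = FALSE))
}
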