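# SNP-diversity metrics: principal-component axes fitted once on the founder
# generation, later cycles projected onto those fixed axes so PC1 scores are
# comparable across the whole selection trajectory; replicate aggregation of
# cycle records into mean +/- SD trajectories.

#' Fit diversity axes on a reference population
#'
#' Principal components of the centered (not variance-scaled) SNP dosage
#' matrix of the reference population, the founders by convention. PC signs
#' are canonicalized (lowest-index individual with a nonzero score is
#' non-negative) for determinism.
#'
#' @param reference a `population` tracking SNP loci.
#' @param k number of axes to keep (default 2).
#' @return A `diversity_projection`: per-SNP `loadings` (unit norm columns),
#'   the reference `center` (per-SNP mean dosage) and the reference `scores`.
#' @export
fit_diversity_axes <- function(reference, k = 2L) {
  x <- dosages(reference, "SNP")
  k <- min(k, nrow(x) - 1L, ncol(x))
  pc <- pc_scores(x, k = k)
  structure(list(loadings = pc$loadings, center = pc$center,
                 scores = pc$scores, sdev = pc$sdev),
            class = "diversity_projection")
}

#' Project a population onto fitted diversity axes
#'
#' Scores are `(dosages - reference_center) %*% loadings`; projecting the
#' reference population reproduces its fit scores exactly, and clones of a
#' reference individual score identically to it.
#'
#' @param pop a `population` with the same SNP loci as the reference.
#' @param proj a `diversity_projection` from [fit_diversity_axes()].
#' @return An individuals-by-axes score matrix.
#' @export
project_population <- function(pop, proj) {
  x <- dosages(pop, "SNP")
  if (ncol(x) != nrow(proj$loadings))
    fail("population has %d SNP loci but the projection was fitted on %d",
         ncol(x), nrow(proj$loadings))
  sweep(x, 2L, proj$center) %*% proj$loadings
}

#' Per-pool PC1 range summary
#'
#' The minimum, mean and maximum PC1 score per pool -- the three lines of a
#' diversity-trajectory panel.
#'
#' @param scores per-individual PC1 scores.
#' @param pools pool label per individual.
#' @return A data.frame with one row per pool: `pool`, `pc1_min`,
#'   `pc1_mean`, `pc1_max`.
#' @export
pool_pc1_summary <- function(scores, pools) {
  if (length(scores) != length(pools))
    fail("scores and pool labels differ in length")
  if (any(tapply(scores, pools, length) == 0L)) fail("empty pool")
  out <- do.call(rbind, lapply(split(scores, pools), function(s) {
    data.frame(pc1_min = min(s), pc1_mean = mean(s), pc1_max = max(s))
  }))
  cbind(pool = rownames(out), out, row.names = NULL)
}

#' Mean absolute allele-frequency divergence between two pools
#'
#' The mean over loci of |freq(pool A) - freq(pool B)|; under RRS the pools
#' drift and are driven apart, so this grows over cycles.
#'
#' @param pop_a,pop_b inbred `population`s over the same loci.
#' @param type locus type to use (`"SNP"`, `"QTN"` or `"all"`).
#' @return A single number in [0, 1].
#' @export
pool_allele_divergence <- function(pop_a, pop_b, type = "SNP") {
  fa <- colMeans(dosages(pop_a, type)) / 2
  fb <- colMeans(dosages(pop_b, type)) / 2
  mean(abs(fa - fb))
}

#' Aggregate replicate trajectories into mean and SD
#'
#' Collapses raw per-cycle records over replicates into the mean and SD
#' (n - 1 denominator) of every statistic, keyed by scenario cell.
#'
#' @param records a data.frame of cycle records carrying at least
#'   `replicate`, `strategy`, `cycle`, `pool` and the statistic columns;
#'   grid runs add `n_qtn` and `dom_mean`.
#' @return A data.frame with one row per (strategy, n_qtn, dom_mean, cycle,
#'   pool) cell and `<stat>_mean` / `<stat>_sd` columns, plus `n_reps`.
#' @export
aggregate_replicates <- function(records) {
  keys <- intersect(c("strategy", "n_qtn", "dom_mean", "cycle", "pool"),
                    names(records))
  stats_cols <- setdiff(names(records), c(keys, "replicate"))
  stats_cols <- stats_cols[vapply(records[stats_cols], is.numeric,
                                  logical(1L))]
  cell <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  n_reps <- tapply(records$replicate, cell, function(r) length(unique(r)))
  if (length(unique(n_reps)) > 1L) {
    bad <- names(n_reps)[n_reps < max(n_reps)]
    fail("ragged replicate sets: cell(s) %s have fewer replicates than the rest",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (max(n_reps) < 2L) fail("need at least 2 replicates per cell")
  first <- !duplicated(cell)
  out <- records[first, keys, drop = FALSE]
  ord_cells <- cell[first]
  for (s in stats_cols) {
    out[[paste0(s, "_mean")]] <- as.numeric(
      tapply(records[[s]], cell, mean)[as.character(ord_cells)])
    out[[paste0(s, "_sd")]] <- as.numeric(
      tapply(records[[s]], cell, stats::sd)[as.character(ord_cells)])
  }
  out$n_reps <- as.integer(n_reps[as.character(ord_cells)])
  rownames(out) <- NULL
  out[order(cell[first]), , drop = FALSE]
}
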