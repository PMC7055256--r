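# Reciprocal recurrent selection on true GCA (RRS-TGV) and the per se
# selection control.
#
# RRS-TGV, per cycle and per pool: 500 random matings among the 50 parents,
# one DH progeny per mating; every progeny is crossed (exactly, via the
# deterministic F1 TGV) with all 50 current parents of the opposite pool and
# its GCA is the mean of those hybrid TGVs; the top 10% of progeny become the
# pool's next parents. Both pools are updated synchronously from the parents
# that entered the cycle. Inbred summaries use all DH progeny per pool and
# are averaged over the two pools; hybrid summaries report future hybrid
# performance among the selected parent lines -- the between-pool crosses of
# the two newly selected parent sets -- mirroring the control's half diallel
# of its selections so the two schemes are compared on the same footing.
#
# The control is not split into pools: 1,000 random matings among the current
# parents (cycle 1: the 100 founders), one DH per mating, lines ranked on
# their own TGV, top 10% promoted; hybrid summaries come from the half
# diallel of the 100 selections, selfs excluded.

#' Breeding scheme configuration
#'
#' Defaults follow the standard scheme: 500 matings per pool (1,000 control
#' matings), 10% selection, 30 cycles -- the same census (1,000 new DH) and
#' selection proportion in RRS and control.
#'
#' @param n_matings_per_pool DH progeny per pool per RRS cycle.
#' @param n_matings_control DH progeny per control cycle (normally
#'   `2 * n_matings_per_pool`).
#' @param selection_proportion fraction selected each cycle; must give an
#'   integral count for both schemes.
#' @param n_cycles number of selection cycles.
#' @return A `scheme_config` list.
#' @export
scheme_config <- function(n_matings_per_pool = 500L,
                          n_matings_control = 1000L,
                          selection_proportion = 0.10,
                          n_cycles = 30L) {
  if (selection_proportion <= 0 || selection_proportion > 1)
    fail("selection_proportion must be in (0, 1]")
  for (nm in c("n_matings_per_pool", "n_matings_control")) {
    n_sel <- selection_proportion * get(nm)
    if (abs(n_sel - round(n_sel)) > 1e-9)
      fail("selection_proportion x %s = %g is not an integer", nm, n_sel)
  }
  structure(list(n_matings_per_pool = as.integer(n_matings_per_pool),
                 n_matings_control = as.integer(n_matings_control),
                 selection_proportion = selection_proportion,
                 n_cycles = as.integer(n_cycles)),
            class = "scheme_config")
}

#' Reduced "desk" scheme for fast runs
#'
#' 100 matings per pool, 200 control matings, 10% selection, 10 cycles --
#' the structural invariants of the full scheme (balanced pools, equal
#' census, integral selection counts) at a fraction of the compute.
#'
#' @return A `scheme_config`.
#' @export
desk_scheme <- function() {
  scheme_config(n_matings_per_pool = 100L, n_matings_control = 200L,
                selection_proportion = 0.10, n_cycles = 10L)
}

#' True general combining ability against a tester pool
#'
#' The GCA of each progeny line is the mean TGV of its F1 hybrids with every
#' tester, computed exactly from the deterministic inbred-by-inbred F1
#' genotypes (no sampling, no error term).
#'
#' @param progeny an inbred `population` of candidates.
#' @param testers an inbred `population` of testers (the opposite pool's
#'   parents).
#' @param arch a `trait_arch`.
#' @return A list: `scores` (GCA per progeny) and `hybrid_tgv` (the full
#'   progeny-by-tester hybrid TGV matrix).
#' @export
gca_scores <- function(progeny, testers, arch) {
  if (n_ind(testers) == 0L) fail("tester population is empty")
  h <- hybrid_tgv_matrix(progeny$hap[, qtn_cols(progeny), drop = FALSE],
                         testers$hap[, qtn_cols(testers), drop = FALSE],
                         arch)
  list(scores = rowMeans(h), hybrid_tgv = h)
}

#' Truncation selection
#'
#' Indices of the top `round(proportion * n)` scores; ties are broken by
#' original index (lower index wins), making selection deterministic.
#'
#' @param scores numeric selection criterion, one per individual.
#' @param proportion fraction to select, in (0, 1].
#' @return Integer indices of the selected individuals, in score order.
#' @export
truncation_select <- function(scores, proportion) {
  n <- length(scores)
  if (n == 0L) fail("cannot select from an empty score vector")
  if (proportion <= 0 || proportion > 1)
    fail("selection proportion must be in (0, 1]")
  n_sel <- as.integer(round(proportion * n))
  order(-scores, seq_len(n))[seq_len(max(1L, n_sel))]
}

# Summaries of one pool's cycle: inbred TGV moments plus PC1 range of the
# progeny on the founder diversity axes.
pool_cycle_stats <- function(progeny, arch, proj) {
  line_tgv <- tgv_population(progeny, arch)
  pc <- if (is.null(proj)) c(NA_real_, NA_real_, NA_real_) else {
    s <- project_population(progeny, proj)[, 1L]
    c(min(s), mean(s), max(s))
  }
  list(inbred_mean = mean(line_tgv), inbred_var = sample_var(line_tgv),
       pc1 = pc)
}

#' Run one cycle of RRS-TGV
#'
#' @param parents_a,parents_b the two pools' current parents (inbred
#'   `population`s of equal size).
#' @param arch a `trait_arch`.
#' @param config a [scheme_config()].
#' @param genmap a [make_genmap()] for the tracked loci.
#' @param proj optional `diversity_projection` for PC1 reporting.
#' @return A list with the next-cycle `parents_a` and `parents_b`, a
#'   two-row `record` data.frame (one row per pool; inbred summaries are the
#'   pool averages, hybrid summaries the selected-parent between-pool
#'   crosses, PC1 columns are per pool) and the `selected` progeny indices
#'   per pool. Uses the ambient RNG stream.
#' @export
run_rrs_cycle <- function(parents_a, parents_b, arch, config, genmap,
                          proj = NULL) {
  cyc <- parents_a$cycle + 1L
  run_pool <- function(parents, testers, pool) {
    pairs <- random_matings(n_ind(parents), config$n_matings_per_pool)
    progeny <- dh_population(parents, pairs, genmap, pool = pool, cycle = cyc)
    g <- gca_scores(progeny, testers, arch)
    sel <- truncation_select(g$scores, config$selection_proportion)
    list(progeny = progeny, selected = sel,
         stats = pool_cycle_stats(progeny, arch, proj))
  }
  res_a <- run_pool(parents_a, parents_b, "A")
  res_b <- run_pool(parents_b, parents_a, "B")
  new_a <- subset_population(res_a$progeny, res_a$selected)
  new_b <- subset_population(res_b$progeny, res_b$selected)
  # future hybrid performance among the selected parent lines: all
  # between-pool crosses of the two freshly selected parent sets
  sel_hyb <- hybrid_tgv_matrix(new_a$hap[, qtn_cols(new_a), drop = FALSE],
                               new_b$hap[, qtn_cols(new_b), drop = FALSE],
                               arch)
  avg <- function(field) {
    (res_a$stats[[field]] + res_b$stats[[field]]) / 2
  }
  record <- data.frame(
    cycle = cyc, pool = c("A", "B"),
    inbred_mean = avg("inbred_mean"), inbred_var = avg("inbred_var"),
    hybrid_mean = mean(sel_hyb), hybrid_var = sample_var(as.numeric(sel_hyb)),
    pc1_min = c(res_a$stats$pc1[1L], res_b$stats$pc1[1L]),
    pc1_mean = c(res_a$stats$pc1[2L], res_b$stats$pc1[2L]),
    pc1_max = c(res_a$stats$pc1[3L], res_b$stats$pc1[3L]))
  list(parents_a = new_a, parents_b = new_b, record = record,
       selected = list(A = res_a$selected, B = res_b$selected))
}

#' Run the per se selection control scheme
#'
#' @param founders the founder `population` (cycle-1 parents).
#' @param arch a `trait_arch`.
#' @param config a [scheme_config()].
#' @param genmap a [make_genmap()].
#' @param proj optional `diversity_projection` for PC1 reporting.
#' @param seed optional integer seed.
#' @return A data.frame of cycle records (one row per cycle, `pool =
#'   "control"`).
#' @export
run_perse_scheme <- function(founders, arch, config, genmap, proj = NULL,
                             seed = NULL) {
  with_seed(seed, {
    parents <- founders
    parents$pool <- "control"
    records <- vector("list", config$n_cycles)
    for (cyc in seq_len(config$n_cycles)) {
      pairs <- random_matings(n_ind(parents), config$n_matings_control)
      progeny <- dh_population(parents, pairs, genmap, pool = "control",
                               cycle = cyc)
      line_tgv <- tgv_population(progeny, arch)
      sel <- truncation_select(line_tgv, config$selection_proportion)
      sel_hap <- progeny$hap[sel, qtn_cols(progeny), drop = FALSE]
      hyb <- hybrid_tgv_matrix(sel_hap, sel_hap, arch)
      hyb <- hyb[upper.tri(hyb)] # half diallel, selfs excluded
      st <- pool_cycle_stats(progeny, arch, proj)
      records[[cyc]] <- data.frame(
        cycle = cyc, pool = "control",
        inbred_mean = st$inbred_mean, inbred_var = st$inbred_var,
        hybrid_mean = mean(hyb), hybrid_var = sample_var(hyb),
        pc1_min = st$pc1[1L], pc1_mean = st$pc1[2L], pc1_max = st$pc1[3L])
      parents <- subset_population(progeny, sel, cycle = cyc)
    }
    do.call(rbind, records)
  })
}

#' Run a full breeding scenario
#'
#' Splits the founders by the requested strategy and runs `config$n_cycles`
#' of RRS-TGV, or runs the per se control. The same founder population and
#' trait architecture can be passed to all four strategies of a replicate.
#'
#' @param founders the founder `population` (SNP and QTN loci tracked).
#' @param arch a calibrated `trait_arch`.
#' @param strategy one of `"random"`, `"genetic_distance"`,
#'   `"hybrid_performance"`, `"control"`.
#' @param config a [scheme_config()].
#' @param genetic_length chromosome genetic length in Morgans (default 1).
#' @param seed integer seed for the whole scenario.
#' @param proj optional precomputed `diversity_projection`; by default the
#'   diversity axes are fitted once on the founders and all cycles are
#'   projected onto them.
#' @param ga GA settings for the hybrid-performance split.
#' @return A data.frame of cycle records with `strategy` prepended.
#' @export
run_scenario <- function(founders, arch, strategy, config = scheme_config(),
                         genetic_length = 1, seed = NULL, proj = NULL,
                         ga = ga_params()) {
  strategies <- c("random", "genetic_distance", "hybrid_performance",
                  "control")
  if (!strategy %in% strategies)
    fail("unknown strategy '%s' (expected one of: %s)", strategy,
         paste(strategies, collapse = ", "))
  genmap <- make_genmap(founders$loci, genetic_length)
  if (is.null(proj)) proj <- fit_diversity_axes(founders)
  records <- with_seed(seed, {
    if (strategy == "control") {
      run_perse_scheme(founders, arch, config, genmap, proj)
    } else {
      split <- switch(strategy,
        random = split_random(founders),
        genetic_distance = split_genetic_distance(founders),
        hybrid_performance = split_hybrid_performance(full_diallel(founders,
                                                                   arch), ga))
      parents_a <- subset_population(founders, split$pool_a, pool = "A",
                                     cycle = 0L)
      parents_b <- subset_population(founders, split$pool_b, pool = "B",
                                     cycle = 0L)
      recs <- vector("list", config$n_cycles)
      for (cyc in seq_len(config$n_cycles)) {
        step <- run_rrs_cycle(parents_a, parents_b, arch, config, genmap,
                              proj)
        parents_a <- step$parents_a
        parents_b <- step$parents_b
        recs[[cyc]] <- step$record
      }
      do.call(rbind, recs)
    }
  })
  cbind(strategy = strategy, records)
}
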