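# Scenario-grid orchestration: QTN levels x dominance levels x strategies x
# replicates, with deterministic per-cell seed derivation and shared founders
# across the four strategies of a replicate.

#' Scenario grid configuration
#'
#' The full experiment crosses three QTN counts (500, 2,000, 8,000) with
#' three mean dominance degrees (0.2, 0.4, 0.8) and four strategies (three
#' pool splits plus the per se control), 20 replicates each. Within a
#' (qtn, dom, replicate) cell the founder population, locus assignment and
#' trait architecture are identical across the four strategies; replicate
#' seeds are derived deterministically from `master_seed` via
#' [derive_seed()].
#'
#' @param qtn_levels QTN counts to simulate.
#' @param dom_levels mean degrees of dominance.
#' @param strategies subset of `"random"`, `"genetic_distance"`,
#'   `"hybrid_performance"`, `"control"`.
#' @param n_replicates replicates per cell.
#' @param scheme a [scheme_config()].
#' @param genome a [genome_params()].
#' @param n_founders number of inbred founders.
#' @param n_snp SNP panel size.
#' @param dom_variance variance of the degree of dominance.
#' @param master_seed integer master seed.
#' @param ga GA settings for the hybrid-performance split.
#' @return A `scenario_grid` object.
#' @export
scenario_grid <- function(qtn_levels = c(500L, 2000L, 8000L),
                          dom_levels = c(0.2, 0.4, 0.8),
                          strategies = c("random", "genetic_distance",
                                         "hybrid_performance", "control"),
                          n_replicates = 20L,
                          scheme = scheme_config(),
                          genome = genome_params(),
                          n_founders = 100L,
                          n_snp = 10000L,
                          dom_variance = 0.2,
                          master_seed = 1L,
                          ga = ga_params()) {
  stopifnot(inherits(scheme, "scheme_config"), inherits(genome, "genome_params"))
  if (n_founders < 4L || n_founders %% 2L != 0L)
    fail("n_founders must be an even number >= 4, got %d", n_founders)
  if (n_snp %% genome$n_chromosomes != 0L)
    fail("n_snp (%d) must be divisible by the number of chromosomes (%d)",
         n_snp, genome$n_chromosomes)
  bad <- qtn_levels[qtn_levels %% genome$n_chromosomes != 0L]
  if (length(bad))
    fail("QTN level(s) %s not divisible by the number of chromosomes (%d)",
         paste(bad, collapse = ", "), genome$n_chromosomes)
  known <- c("random", "genetic_distance", "hybrid_performance", "control")
  if (!all(strategies %in% known))
    fail("unknown strategy: %s", paste(setdiff(strategies, known),
                                       collapse = ", "))
  if (n_replicates < 1L) fail("n_replicates must be >= 1")
  structure(list(qtn_levels = as.integer(qtn_levels),
                 dom_levels = dom_levels, strategies = strategies,
                 n_replicates = as.integer(n_replicates), scheme = scheme,
                 genome = genome, n_founders = as.integer(n_founders),
                 n_snp = as.integer(n_snp), dom_variance = dom_variance,
                 master_seed = as.integer(master_seed), ga = ga),
            class = "scenario_grid")
}

#' Reduced "desk" scenario grid
#'
#' 40 founders on the [desk_genome()], 1,000 SNP, 200 QTN, the
#' [desk_scheme()] (100 matings per pool, 10 cycles) and 5 replicates:
#' every structural invariant of the full grid at roughly 100x less compute.
#'
#' @param qtn_levels,dom_levels,strategies,n_replicates,master_seed overrides.
#' @return A `scenario_grid`.
#' @export
desk_grid <- function(qtn_levels = 200L, dom_levels = 0.8,
                      strategies = c("random", "genetic_distance",
                                     "hybrid_performance", "control"),
                      n_replicates = 5L, master_seed = 1L) {
  scenario_grid(qtn_levels = qtn_levels, dom_levels = dom_levels,
                strategies = strategies, n_replicates = n_replicates,
                scheme = desk_scheme(), genome = desk_genome(),
                n_founders = 40L, n_snp = 1000L, master_seed = master_seed)
}

#' Validate a raw configuration document into a scenario grid
#'
#' Accepts a nested list (or a YAML file path, if the yaml package is
#' available) with optional `genome`, `scheme` and `grid` blocks mirroring
#' [genome_params()], [scheme_config()] and [scenario_grid()] fields;
#' missing keys take the full-scale defaults, so an empty document yields
#' the default grid. All structural invariants (Morgan/bp consistency,
#' equal loci per chromosome, integral selection counts) are validated and
#' violations are reported with the offending key.
#'
#' @param config a named list, a YAML path, or `NULL` for all defaults.
#' @return A `scenario_grid`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      fail("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) fail("config must be a named list or a YAML path")
  unknown <- setdiff(names(config), c("genome", "scheme", "grid"))
  if (length(unknown))
    fail("unknown config block(s): %s", paste(unknown, collapse = ", "))
  take <- function(block, fn) {
    args <- config[[block]]
    if (is.null(args)) args <- list()
    allowed <- names(formals(fn))
    bad <- setdiff(names(args), allowed)
    if (length(bad))
      fail("unknown key(s) in '%s' block: %s", block,
           paste(bad, collapse = ", "))
    args
  }
  genome <- do.call(genome_params, take("genome", genome_params))
  scheme <- do.call(scheme_config, take("scheme", scheme_config))
  grid_args <- take("grid", scenario_grid)
  do.call(scenario_grid,
          c(grid_args, list(scheme = scheme, genome = genome)))
}

#' Simulate the shared inputs of one replicate
#'
#' Generates the founder haplotype panel, assigns SNP and QTN loci, builds
#' the inbred founders, samples and calibrates the trait and fits the
#' founder diversity axes -- everything the four strategies of a replicate
#' share.
#'
#' @param grid a `scenario_grid`.
#' @param n_qtn QTN count for this cell.
#' @param dom_mean mean degree of dominance for this cell.
#' @param seed integer seed for founders and trait draws.
#' @return A list: `founders`, `arch` (calibrated), `proj`, `loci`.
#' @export
simulate_replicate_inputs <- function(grid, n_qtn, dom_mean, seed) {
  panel <- simulate_founder_haplotypes(
    grid$genome, n_haplotypes = grid$n_founders,
    seed = derive_seed(seed, 1L),
    min_sites = grid$n_snp + n_qtn)
  loci <- select_loci(panel, n_snp = grid$n_snp, n_qtn = n_qtn,
                      seed = derive_seed(seed, 2L))
  founders <- make_inbred_founders(panel, loci)
  arch <- sample_effects(loci,
                         dominance_config(dom_mean, grid$dom_variance),
                         seed = derive_seed(seed, 3L))
  arch <- calibrate_trait(arch, founders)
  list(founders = founders, arch = arch,
       proj = fit_diversity_axes(founders), loci = loci)
}

#' Run a scenario grid
#'
#' Executes every (qtn, dom, strategy, replicate) cell, optionally writing a
#' tidy per-cell CSV under `out_dir` (cells whose file already exists are
#' skipped unless `force = TRUE`, making long runs resumable). A failing
#' cell is recorded and does not abort the remaining cells.
#'
#' @param grid a `scenario_grid`.
#' @param out_dir optional directory for per-cell CSVs and the aggregated
#'   summary.
#' @param force rerun cells whose output already exists?
#' @param verbose print per-cell progress?
#' @return A list: `records` (raw tidy cycle records over all cells),
#'   `summary` ([aggregate_replicates()] output, `NULL` with a single
#'   replicate) and `failures` (data.frame of failed cells, zero rows if
#'   none).
#' @export
run_grid <- function(grid, out_dir = NULL, force = FALSE, verbose = TRUE) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  strat_code <- stats::setNames(seq_along(grid$strategies), grid$strategies)
  all_records <- list()
  failures <- list()
  for (qi in seq_along(grid$qtn_levels)) {
    for (di in seq_along(grid$dom_levels)) {
      for (rep_i in seq_len(grid$n_replicates)) {
        rep_seed <- derive_seed(grid$master_seed, qi, di, rep_i)
        inputs <- NULL
        for (strat in grid$strategies) {
          tag <- sprintf("qtn%d_dom%g_%s_rep%d", grid$qtn_levels[qi],
                         grid$dom_levels[di], strat, rep_i)
          path <- if (is.null(out_dir)) NULL
                  else file.path(out_dir, paste0(tag, ".csv"))
          if (!is.null(path) && file.exists(path) && !force) {
            all_records[[tag]] <- utils::read.csv(path)
            if (verbose) message("skipping finished cell ", tag)
            next
          }
          t0 <- Sys.time()
          res <- tryCatch({
            if (is.null(inputs))
              inputs <- simulate_replicate_inputs(
                grid, grid$qtn_levels[qi], grid$dom_levels[di], rep_seed)
            rec <- run_scenario(
              inputs$founders, inputs$arch, strat, grid$scheme,
              genetic_length = grid$genome$genetic_length,
              seed = derive_seed(rep_seed, 100L + strat_code[[strat]]),
              proj = inputs$proj, ga = grid$ga)
            cbind(replicate = rep_i, n_qtn = grid$qtn_levels[qi],
                  dom_mean = grid$dom_levels[di], rec)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failures[[tag]] <- data.frame(cell = tag,
                                          message = conditionMessage(res))
            if (verbose) message("cell ", tag, " FAILED: ",
                                 conditionMessage(res))
            next
          }
          if (!is.null(path))
            utils::write.csv(res, path, row.names = FALSE)
          all_records[[tag]] <- res
          if (verbose)
            message(sprintf("cell %s done in %.1fs (seed %d)", tag,
                            as.numeric(difftime(Sys.time(), t0, units = "secs")),
                            rep_seed))
        }
      }
    }
  }
  records <- do.call(rbind, c(all_records, list(make.row.names = FALSE)))
  summary <- if (grid$n_replicates >= 2L && length(all_records))
    aggregate_replicates(records) else NULL
  if (!is.null(out_dir)) {
    utils::write.csv(records, file.path(out_dir, "trajectories_raw.csv"),
                     row.names = FALSE)
    if (!is.null(summary))
      utils::write.csv(summary, file.path(out_dir, "trajectories_summary.csv"),
                       row.names = FALSE)
  }
  list(records = records, summary = summary,
       failures = if (length(failures)) do.call(rbind, failures)
                  else data.frame(cell = character(), message = character()))
}
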