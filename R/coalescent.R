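# Neutral coalescent simulation of founder haplotypes.
#
# The genome is cut into windows of equal genetic length; each window receives
# an independent Kingman genealogy over the sampled haplotypes (free
# recombination between windows, complete linkage within a window). Mutations
# are dropped on the genealogy branches under the infinite-sites model, so
# every simulated site is biallelic and segregating in the sample by
# construction, and the expected number of segregating sites per chromosome
# equals Watterson's theta * a_{n-1} with theta = 4 * Ne * mu * L regardless
# of the window count.

# One Kingman window: returns a list of derived-allele carrier sets, one per
# segregating site. theta_w = 4 Ne mu L_w; time in units of 2Ne generations,
# mutations Poisson(theta_w/2) per lineage per unit time.
sim_kingman_window <- function(n, theta_w) {
  lineages <- as.list(seq_len(n))
  carriers <- vector("list", 64L)
  s <- 0L
  k <- n
  while (k > 1L) {
    t_epoch <- stats::rexp(1L, rate = k * (k - 1) / 2)
    m <- stats::rpois(k, lambda = t_epoch * theta_w / 2)
    for (j in which(m > 0L)) {
      for (q in seq_len(m[j])) {
        s <- s + 1L
        if (s > length(carriers)) length(carriers) <- 2L * length(carriers)
        carriers[[s]] <- lineages[[j]]
      }
    }
    pair <- sample.int(k, 2L)
    lineages[[pair[1L]]] <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages[[pair[2L]]] <- NULL
    k <- k - 1L
  }
  length(carriers) <- s
  carriers
}

# Default engine: windowed Kingman coalescent for one chromosome.
# Returns list(pos = integer bp positions, hap = n x S binary matrix).
coalescent_engine_windows <- function(params, n_haplotypes, n_windows = 50L) {
  theta_chr <- 4 * params$effective_pop_size * params$mutation_rate *
    params$physical_length
  theta_w <- theta_chr / n_windows
  bounds <- round(seq(0, params$physical_length, length.out = n_windows + 1L))
  carriers <- vector("list", 0L)
  pos <- numeric(0L)
  for (w in seq_len(n_windows)) {
    cw <- sim_kingman_window(n_haplotypes, theta_w)
    if (length(cw) == 0L) next
    lo <- bounds[w] + 1L
    hi <- bounds[w + 1L]
    pw <- sort(sample.int(hi - lo + 1L, length(cw), replace = FALSE)) + lo - 1L
    carriers <- c(carriers, cw)
    pos <- c(pos, pw)
  }
  ord <- order(pos)
  pos <- pos[ord]
  carriers <- carriers[ord]
  hap <- matrix(0L, nrow = n_haplotypes, ncol = length(pos))
  for (s in seq_along(carriers)) hap[carriers[[s]], s] <- 1L
  list(pos = as.integer(pos), hap = hap)
}

#' Simulate founder haplotypes under a neutral coalescent
#'
#' Draws `n_haplotypes` phased binary haplotypes per chromosome under a
#' neutral coalescent with mutation and (free-between-window) recombination at
#' the rates in `params`, with constant effective population size. Every site
#' in the returned panel is biallelic and segregating in the sample; allele 1
#' is the derived (mutant) allele.
#'
#' @param params a [genome_params()] object.
#' @param n_haplotypes number of haplotypes to sample (>= 2).
#' @param seed integer seed; fixed seeds give bit-identical panels.
#' @param min_sites minimum total number of segregating sites required, e.g.
#'   the number of SNP plus QTN to be assigned downstream. An error naming the
#'   required and obtained counts is raised if the coalescent yields fewer.
#' @param n_windows number of independent-genealogy windows per chromosome;
#'   controls how finely recombination breaks up linkage along the chromosome.
#' @param engine optional replacement simulator, a
#'   `function(params, n_haplotypes)` returning a per-chromosome
#'   `list(pos=, hap=)`; used to plug in alternative generators.
#' @return An object of class `haplotype_panel`: a list with `params`,
#'   `n_haplotypes`, and `chrom`, a per-chromosome list of `pos` (1-based bp,
#'   strictly increasing), `gpos` (Morgans, `pos * recombination_rate`) and
#'   `hap` (haplotype-by-site binary matrix).
#' @export
#' @examples
#' panel <- simulate_founder_haplotypes(
#'   genome_params(n_chromosomes = 2, physical_length = 1e6,
#'                 recombination_rate = 1e-6, mutation_rate = 2.5e-6),
#'   n_haplotypes = 10, seed = 1)
#' sapply(panel$chrom, function(ch) ncol(ch$hap))
simulate_founder_haplotypes <- function(params, n_haplotypes, seed = NULL,
                                        min_sites = 0L, n_windows = 50L,
                                        engine = NULL) {
  stopifnot(inherits(params, "genome_params"))
  if (!is.numeric(n_haplotypes) || n_haplotypes < 2)
    fail("n_haplotypes must be >= 2, got %s", n_haplotypes)
  n_haplotypes <- as.integer(n_haplotypes)
  chrom <- with_seed(seed, {
    lapply(seq_len(params$n_chromosomes), function(c_idx) {
      res <- if (is.null(engine)) {
        coalescent_engine_windows(params, n_haplotypes, n_windows = n_windows)
      } else {
        engine(params, n_haplotypes)
      }
      freq <- colMeans(res$hap)
      keep <- freq > 0 & freq < 1 # engine plug-ins may emit fixed sites
      list(pos = res$pos[keep],
           gpos = res$pos[keep] * params$recombination_rate,
           hap = res$hap[, keep, drop = FALSE])
    })
  })
  total <- sum(vapply(chrom, function(ch) ncol(ch$hap), integer(1L)))
  if (total < min_sites)
    fail(paste0("coalescent simulation produced %d segregating sites in ",
                "total but %d are required; increase mutation rate, sample ",
                "size or genome length"), total, as.integer(min_sites))
  structure(list(params = params, n_haplotypes = n_haplotypes, chrom = chrom),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  s <- vapply(x$chrom, function(ch) ncol(ch$hap), integer(1L))
  cat(sprintf("Haplotype panel: %d haplotypes, %d chromosomes, %d segregating sites\n",
              x$n_haplotypes, length(x$chrom), sum(s)))
  invisible(x)
}
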