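#' Genome parameters for founder simulation
#'
#' Describes the simulated genome: number of chromosome pairs, genetic and
#' physical length per chromosome, per-bp recombination and mutation rates and
#' the effective population size of the coalescent history. Defaults model a
#' crop genome of 10 chromosomes of 1 Morgan / 1e8 bp each, recombination
#' 1e-8 per bp, mutation 2.5e-8 per bp and Ne = 100.
#'
#' The genetic length must equal `physical_length * recombination_rate`
#' (1 Morgan = 1e8 bp x 1e-8 / bp for the defaults); this identity is
#' validated for any override.
#'
#' @param n_chromosomes number of chromosome pairs (>= 1).
#' @param physical_length physical chromosome length in base pairs.
#' @param recombination_rate per-bp per-meiosis recombination rate (Morgans/bp).
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param effective_pop_size effective population size of the coalescent
#'   history (constant through time).
#' @param genetic_length genetic chromosome length in Morgans; defaults to
#'   `physical_length * recombination_rate` and must equal it.
#' @return An object of class `genome_params`.
#' @export
#' @examples
#' genome_params() # full-scale crop genome
#' genome_params(n_chromosomes = 2, physical_length = 1e7,
#'               recombination_rate = 1e-7, mutation_rate = 2.5e-7)
genome_params <- function(n_chromosomes = 10,
                          physical_length = 1e8,
                          recombination_rate = 1e-8,
                          mutation_rate = 2.5e-8,
                          effective_pop_size = 100,
                          genetic_length = physical_length * recombination_rate) {
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1 ||
      n_chromosomes != round(n_chromosomes))
    fail("n_chromosomes must be a positive integer, got %s", n_chromosomes)
  for (nm in c("physical_length", "recombination_rate", "mutation_rate",
               "effective_pop_size", "genetic_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      fail("%s must be a single strictly positive number", nm)
  }
  if (abs(genetic_length - physical_length * recombination_rate) >
      1e-9 * genetic_length)
    fail(paste0("genetic_length (%g M) must equal physical_length x ",
                "recombination_rate (%g M)"),
         genetic_length, physical_length * recombination_rate)
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         genetic_length = genetic_length,
         physical_length = physical_length,
         recombination_rate = recombination_rate,
         mutation_rate = mutation_rate,
         effective_pop_size = effective_pop_size),
    class = "genome_params")
}

#' @export
print.genome_params <- function(x, ...) {
  cat(sprintf(
    "Genome: %d chromosomes, %g Morgan / %g bp each\n  rec %g /bp, mut %g /bp, Ne = %g\n",
    x$n_chromosomes, x$genetic_length, x$physical_length,
    x$recombination_rate, x$mutation_rate, x$effective_pop_size))
  invisible(x)
}

#' Reduced "desk" genome for fast runs
#'
#' Two chromosomes of 1e7 bp kept at 1 Morgan genetic length (recombination
#' 1e-7 per bp) with mutation rate 2.5e-7 per bp, so both the per-chromosome
#' crossover process and the expected density of segregating sites per
#' chromosome match the full-scale genome at roughly 100x less compute.
#'
#' @return A `genome_params` object.
#' @export
desk_genome <- function() {
  genome_params(n_chromosomes = 2, physical_length = 1e7,
                recombination_rate = 1e-7, mutation_rate = 2.5e-7,
                effective_pop_size = 100)
}
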