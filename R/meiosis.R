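# Meiosis and doubled-haploid (DH) production.
#
# Crossovers follow a Poisson process on the genetic map with no
# interference: per chromosome the crossover count is Poisson(genetic length
# in Morgans), crossover positions are uniform on the map, and the starting
# parental strand is chosen with probability 1/2. A DH progeny of two inbred
# parents is their (deterministic) F1's single meiotic gamete, doubled.

#' Build a genetic map from a locus table
#'
#' Precomputes per-chromosome locus indices and genetic positions for
#' [meiosis_gamete()].
#'
#' @param loci a locus data.frame with `chrom` and `gpos` (Morgans) columns,
#'   e.g. a population's `loci`.
#' @param genetic_length chromosome genetic length in Morgans (scalar,
#'   shared by all chromosomes).
#' @return A `genmap` list with one entry per chromosome: column indices
#'   (`cols`), genetic positions (`gpos`) and the chromosome length (`glen`).
#' @export
make_genmap <- function(loci, genetic_length = 1) {
  chroms <- sort(unique(loci$chrom))
  structure(lapply(chroms, function(c_idx) {
    cols <- which(loci$chrom == c_idx)
    list(cols = cols, gpos = loci$gpos[cols], glen = genetic_length)
  }), class = "genmap")
}

#' Draw one meiotic gamete
#'
#' Recombines the two phased parental haplotypes. An inbred parent
#' (`h1 == h2`) returns the parental haplotype whatever the crossovers; an F1
#' of two inbreds is phased by construction, its haplotypes being the two
#' parental genomes.
#'
#' @param h1,h2 the parent's two haplotypes (binary vectors over the tracked
#'   loci).
#' @param genmap a [make_genmap()] object.
#' @return A recombinant binary haplotype. Uses the ambient RNG stream;
#'   seed at the caller for reproducibility.
#' @export
meiosis_gamete <- function(h1, h2, genmap) {
  gamete <- h1
  for (chr in genmap) {
    n_xo <- stats::rpois(1L, chr$glen)
    start <- sample.int(2L, 1L) - 1L
    if (n_xo == 0L) {
      strand <- start
    } else {
      xo <- sort(stats::runif(n_xo, 0, chr$glen))
      strand <- (start + findInterval(chr$gpos, xo)) %% 2L
    }
    take2 <- strand == 1L
    if (any(take2)) gamete[chr$cols[take2]] <- h2[chr$cols[take2]]
  }
  gamete
}

#' Doubled-haploid progeny of two inbred parents
#'
#' Forms the deterministic F1 of the two inbreds, draws one meiotic gamete
#' from it and doubles the gamete, giving a fully homozygous line whose
#' haplotype is the gamete itself.
#'
#' @param h1,h2 parental haplotypes (each parent inbred, so one haplotype
#'   represents its genotype).
#' @param genmap a [make_genmap()] object.
#' @return The progeny haplotype (binary vector); its dosages are twice this.
#' @export
dh_progeny <- function(h1, h2, genmap) {
  meiosis_gamete(h1, h2, genmap)
}

#' Draw random matings among parents
#'
#' Each mating is an unordered pair of two distinct parents drawn uniformly;
#' pairs may repeat across matings (selfs are excluded: the self of a DH
#' line is a clone).
#'
#' @param n_parents number of parents (>= 2).
#' @param n_matings number of matings to draw.
#' @param seed optional integer seed.
#' @return An `n_matings` x 2 integer matrix of parent indices.
#' @export
random_matings <- function(n_parents, n_matings, seed = NULL) {
  if (n_parents < 2L) fail("random matings need at least 2 parents, got %d",
                           n_parents)
  with_seed(seed, {
    p1 <- sample.int(n_parents, n_matings, replace = TRUE)
    p2 <- sample.int(n_parents - 1L, n_matings, replace = TRUE)
    p2 <- p2 + (p2 >= p1) # shift past p1: uniform over distinct partners
    cbind(p1, p2, deparse.level = 0L)
  })
}

# DH progeny population from a parent population and a mating plan.
dh_population <- function(parents, pairs, genmap, pool = parents$pool,
                          cycle = parents$cycle + 1L) {
  hap <- matrix(0L, nrow = nrow(pairs), ncol = ncol(parents$hap))
  for (m in seq_len(nrow(pairs))) {
    hap[m, ] <- dh_progeny(parents$hap[pairs[m, 1L], ],
                           parents$hap[pairs[m, 2L], ], genmap)
  }
  new_population(hap, parents$loci, pool = pool, cycle = cycle)
}
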