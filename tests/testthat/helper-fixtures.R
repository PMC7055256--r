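# Shared fixtures and independent oracles for the test suite.

# Small 1-Morgan genome: 2 chromosomes x 1e6 bp, theta = 4*Ne*mu*L = 100 per
# chromosome, so coalescent panels stay small and fast.
tiny_genome <- function() {
  genome_params(n_chromosomes = 2, physical_length = 1e6,
                recombination_rate = 1e-6, mutation_rate = 2.5e-7,
                effective_pop_size = 100)
}

# Build an inbred population directly from a haplotype matrix (rows =
# individuals), with loci evenly spread over `n_chrom` 1-Morgan chromosomes.
toy_population <- function(hap, types = rep("QTN", ncol(hap)),
                           n_chrom = 1L, pool = "founders") {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  n_loci <- ncol(hap)
  per <- ceiling(n_loci / n_chrom)
  chrom <- rep(seq_len(n_chrom), each = per)[seq_len(n_loci)]
  gpos <- stats::ave(seq_len(n_loci), chrom,
                     FUN = function(i) seq(0.05, 0.95, length.out = length(i)))
  loci <- data.frame(chrom = chrom, site = seq_len(n_loci),
                     pos = round(gpos * 1e6), gpos = gpos, type = types)
  heteropools:::new_population(hap, loci, pool = pool)
}

# Trait architecture with hand-set effects (for closed-form checks).
toy_arch <- function(a, d = rep(0, length(a)), scale = 1, intercept = 0) {
  delta <- ifelse(a == 0, 0, d / abs(a))
  structure(list(loci = data.frame(chrom = 1L, pos = seq_along(a)),
                 a = a, delta = delta, d = d,
                 scale = scale, intercept = intercept,
                 dom = dominance_config(0.4)),
            class = "trait_arch")
}

# Independent TGV oracle: plain per-individual, per-locus loops.
tgv_brute <- function(dosage, a, d, scale = 1, intercept = 0) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  vapply(seq_len(nrow(dosage)), function(i) {
    g <- 0
    for (k in seq_along(a)) {
      x <- dosage[i, k]
      g <- g + a[k] * (x - 1) + if (x == 1) d[k] else 0
    }
    intercept + scale * g
  }, numeric(1))
}

# Exhaustive oracle for the balanced-bipartition objective: the best mean
# between-pool hybrid TGV over all C(n-1, n/2-1) balanced splits (founder 1
# pinned to pool A to halve the label symmetry).
exhaustive_best_split <- function(diallel) {
  n <- nrow(diallel)
  half <- n %/% 2L
  combos <- utils::combn(2:n, half - 1L)
  best <- -Inf
  all_obj <- numeric(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    a <- c(1L, combos[, j])
    b <- setdiff(seq_len(n), a)
    all_obj[j] <- mean(diallel[a, b])
    if (all_obj[j] > best) best <- all_obj[j]
  }
  list(best = best, all = all_obj)
}

# Random founders + trait over a handful of QTN, for small GA/diallel
# instances.
random_instance <- function(n_founders, n_qtn = 30L, dom_mean = 0.6) {
  hap <- matrix(rbinom(n_founders * n_qtn, 1L, 0.5), nrow = n_founders)
  pop <- toy_population(hap)
  arch <- sample_effects(pop$loci, dominance_config(dom_mean))
  list(pop = pop, arch = arch, diallel = full_diallel(pop, arch))
}

# Two clearly separated founder clusters over SNP loci (plus a few QTN so
# trait code keeps working): cluster membership drives half the SNPs.
two_cluster_founders <- function(n_per = 10L, n_snp = 40L, n_qtn = 10L) {
  n <- 2L * n_per
  snp <- matrix(rbinom(n * n_snp, 1L, 0.5), nrow = n)
  marker <- seq_len(n_snp %/% 2L)
  snp[seq_len(n_per), marker] <- 0L
  snp[n_per + seq_len(n_per), marker] <- 1L
  qtn <- matrix(rbinom(n * n_qtn, 1L, 0.5), nrow = n)
  toy_population(cbind(snp, qtn),
                 types = rep(c("SNP", "QTN"), c(n_snp, n_qtn)))
}

# Desk-scale replicate inputs, cached per (qtn, dom, seed) within a test run.
desk_inputs <- local({
  cache <- list()
  function(n_qtn, dom_mean, seed) {
    key <- paste(n_qtn, dom_mean, seed, sep = "_")
    if (is.null(cache[[key]])) {
      grid <- desk_grid(qtn_levels = n_qtn, dom_levels = dom_mean)
      cache[[key]] <<- simulate_replicate_inputs(grid, n_qtn, dom_mean, seed)
    }
    cache[[key]]
  }
})
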