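# Heterotic pool formation: balanced bipartitions of the founders by random
# draw, SNP genetic distance (PC1) or a genetic algorithm maximising mean
# between-pool F1 hybrid TGV over the full founder diallel.

#' F1 genotype of two inbred parents
#'
#' For fully homozygous parents the F1 is deterministic: per-locus dosage is
#' the mean of the parental dosages (0/1/2 from ref x ref, ref x alt,
#' alt x alt) -- no meiosis sampling is involved.
#'
#' @param dosage1,dosage2 parental dosage vectors (values 0 or 2).
#' @return F1 dosage vector.
#' @export
f1_hybrid_dosage <- function(dosage1, dosage2) {
  if (!all(dosage1 %in% c(0, 2)) || !all(dosage2 %in% c(0, 2)))
    fail("f1_hybrid_dosage() requires fully homozygous parents (dosages 0/2); a heterozygous parent makes the F1 non-deterministic")
  (dosage1 + dosage2) / 2
}

# TGV of all F1s between inbred haplotype sets A (n1 x q) and B (n2 x q) at
# the QTN. Per locus k the F1 dosage is hA + hB, so the additive part is
# a_k (hA + hB - 1) and the heterozygote indicator is XOR(hA, hB)
# = hA + hB - 2 hA hB; everything reduces to matrix products.
hybrid_tgv_matrix <- function(hap_a, hap_b, arch) {
  a <- arch$a
  d <- arch$d
  add_a <- as.numeric(hap_a %*% a)
  add_b <- as.numeric(hap_b %*% a)
  dom_a <- as.numeric(hap_a %*% d)
  dom_b <- as.numeric(hap_b %*% d)
  cross <- sweep(hap_a, 2L, d, "*") %*% t(hap_b)
  raw <- outer(add_a + dom_a, add_b + dom_b, "+") - sum(a) - 2 * cross
  arch$intercept + arch$scale * raw
}

#' Full diallel of F1 hybrid TGV among inbred founders
#'
#' Computes the TGV of every pairwise F1 among the founders. The table is
#' symmetric and its diagonal equals the founders' own TGV (the self of an
#' inbred reproduces the parent genotype).
#'
#' @param founders an inbred `population`.
#' @param arch a `trait_arch`.
#' @return A `diallel_table`: an n-by-n symmetric numeric matrix.
#' @export
full_diallel <- function(founders, arch) {
  h <- founders$hap[, qtn_cols(founders), drop = FALSE]
  m <- hybrid_tgv_matrix(h, h, arch)
  dimnames(m) <- NULL
  structure(m, class = c("diallel_table", "matrix", "array"))
}

# Pool assignment constructor.
new_pool_assignment <- function(pool_a, pool_b, strategy,
                                objective = NA_real_, converged = NA) {
  pool_a <- sort(as.integer(pool_a))
  pool_b <- sort(as.integer(pool_b))
  if (length(intersect(pool_a, pool_b)))
    fail("pools overlap")
  if (length(pool_a) != length(pool_b))
    fail("pools must be the same size (got %d and %d)",
         length(pool_a), length(pool_b))
  structure(list(pool_a = pool_a, pool_b = pool_b, strategy = strategy,
                 objective = objective, converged = converged),
            class = "pool_assignment")
}

#' @export
print.pool_assignment <- function(x, ...) {
  cat(sprintf("Pool assignment (%s): %d + %d founders", x$strategy,
              length(x$pool_a), length(x$pool_b)))
  if (!is.na(x$objective))
    cat(sprintf(", mean between-pool hybrid TGV %.4f", x$objective))
  cat("\n")
  invisible(x)
}

#' Mean between-pool hybrid TGV of a bipartition
#'
#' The objective optimised by the hybrid-performance split: the mean of the
#' diallel F1 TGV over all pairs with one parent in each pool.
#'
#' @param diallel a `diallel_table`.
#' @param pool_a,pool_b founder index vectors.
#' @return A single number.
#' @export
between_pool_mean <- function(diallel, pool_a, pool_b) {
  mean(diallel[pool_a, pool_b, drop = FALSE])
}

#' Random balanced split into two heterotic pools
#'
#' @param founders an inbred `population` with an even number of members.
#' @param seed integer seed.
#' @return A `pool_assignment` with strategy `"random"`.
#' @export
split_random <- function(founders, seed = NULL) {
  n <- n_ind(founders)
  if (n %% 2L != 0L) fail("cannot split %d founders into two equal pools", n)
  with_seed(seed, {
    a <- sort(sample.int(n, n %/% 2L))
    new_pool_assignment(a, setdiff(seq_len(n), a), "random")
  })
}

# First principal component of a centered dosage matrix, sign-canonicalized:
# the lowest-index individual with a nonzero score scores non-negative.
pc_scores <- function(x, k = 2L) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12))
    fail("all individuals are identical at these loci; principal components are undefined")
  sv <- svd(xc, nu = 0L, nv = k)
  scores <- xc %*% sv$v
  for (j in seq_len(ncol(scores))) {
    nz <- which(abs(scores[, j]) > 1e-9)
    if (length(nz) && scores[nz[1L], j] < 0) {
      scores[, j] <- -scores[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  list(scores = scores, loadings = sv$v, center = attr(xc, "scaled:center"),
       sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1L)))
}

#' Split pools by SNP genetic distance (PC1)
#'
#' Principal component analysis of the centered founder SNP dosage matrix
#' (no variance scaling); founders are ranked on their PC1 score and the
#' lower half forms pool A, the upper half pool B. Ties are broken by founder
#' index, and the PC1 sign is canonicalized, so the split is deterministic.
#'
#' @param founders an inbred `population` tracking SNP loci.
#' @return A `pool_assignment` with strategy `"genetic_distance"`.
#' @export
split_genetic_distance <- function(founders) {
  n <- n_ind(founders)
  if (n %% 2L != 0L) fail("cannot split %d founders into two equal pools", n)
  pc1 <- pc_scores(dosages(founders, "SNP"), k = 1L)$scores[, 1L]
  ord <- order(pc1, seq_len(n))
  new_pool_assignment(ord[seq_len(n %/% 2L)], ord[(n %/% 2L + 1L):n],
                      "genetic_distance")
}

#' Genetic algorithm settings for the hybrid-performance split
#'
#' @param pop_size GA population size.
#' @param generations maximum generations.
#' @param stagnation stop early after this many generations without
#'   improvement of the best objective.
#' @param tournament tournament size for parent selection.
#' @param mutation_rate per-offspring probability of a swap mutation
#'   (exchange one pool-A member with one pool-B member).
#' @param elitism number of best solutions copied unchanged each generation.
#' @return A `ga_params` list.
#' @export
ga_params <- function(pop_size = 200L, generations = 500L, stagnation = 100L,
                      tournament = 3L, mutation_rate = 0.05, elitism = 2L) {
  if (pop_size < 2L || generations < 1L || tournament < 1L ||
      mutation_rate < 0 || mutation_rate > 1 || elitism < 0L ||
      elitism >= pop_size)
    fail("invalid GA parameters")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 stagnation = as.integer(stagnation),
                 tournament = as.integer(tournament),
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism)),
            class = "ga_params")
}

# Repair a logical membership vector to exactly n/2 TRUE by randomly flipping
# surplus entries on the majority side.
repair_balance <- function(member, half) {
  excess <- sum(member) - half
  if (excess > 0L) {
    member[sample(which(member), excess)] <- FALSE
  } else if (excess < 0L) {
    member[sample(which(!member), -excess)] <- TRUE
  }
  member
}

#' Optimized split maximising between-pool hybrid performance
#'
#' Searches balanced bipartitions of the founders for the one maximising the
#' mean F1 hybrid TGV between pools, using a genetic algorithm over binary
#' membership vectors: tournament selection, uniform crossover with a
#' balance-restoring repair step, swap mutation and elitism, stopping early
#' when the best objective stagnates. On small instances the GA attains the
#' exhaustive optimum over all balanced bipartitions.
#'
#' @param diallel a `diallel_table` of F1 TGV among the founders.
#' @param params a [ga_params()] configuration.
#' @param seed integer seed.
#' @return A `pool_assignment` with strategy `"hybrid_performance"`, the
#'   attained `objective`, and a `converged` flag (`FALSE` with a warning if
#'   the generation budget ran out while still improving).
#' @export
split_hybrid_performance <- function(diallel, params = ga_params(),
                                     seed = NULL) {
  n <- nrow(diallel)
  if (n %% 2L != 0L) fail("cannot split %d founders into two equal pools", n)
  half <- n %/% 2L
  fit_of <- function(member) mean(diallel[member, !member, drop = FALSE])
  with_seed(seed, {
    pop <- replicate(params$pop_size, {
      m <- rep(FALSE, n)
      m[sample.int(n, half)] <- TRUE
      m
    }, simplify = FALSE)
    fit <- vapply(pop, fit_of, numeric(1L))
    best_fit <- max(fit)
    stagnant <- 0L
    gen <- 0L
    while (gen < params$generations && stagnant < params$stagnation) {
      gen <- gen + 1L
      ord <- order(fit, decreasing = TRUE)
      nextgen <- pop[ord[seq_len(params$elitism)]]
      while (length(nextgen) < params$pop_size) {
        pick <- function() {
          cand <- sample.int(params$pop_size, params$tournament)
          pop[[cand[which.max(fit[cand])]]]
        }
        p1 <- pick()
        p2 <- pick()
        take <- stats::runif(n) < 0.5
        child <- ifelse(take, p1, p2)
        child <- repair_balance(child, half)
        if (stats::runif(1L) < params$mutation_rate) {
          i <- sample(which(child), 1L)
          j <- sample(which(!child), 1L)
          child[c(i, j)] <- c(FALSE, TRUE)
        }
        nextgen[[length(nextgen) + 1L]] <- child
      }
      pop <- nextgen
      fit <- vapply(pop, fit_of, numeric(1L))
      if (max(fit) > best_fit + 1e-12) {
        best_fit <- max(fit)
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
    }
    converged <- stagnant >= params$stagnation
    if (!converged)
      warning("GA generation budget exhausted while the objective was still improving; returning the best split found")
    best <- pop[[which.max(fit)]]
    new_pool_assignment(which(best), which(!best), "hybrid_performance",
                        objective = max(fit), converged = converged)
  })
}

#' Write a pool assignment to a two-column TSV
#'
#' @param assignment a `pool_assignment`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pools_tsv <- function(assignment, file) {
  df <- data.frame(
    founder_id = c(assignment$pool_a, assignment$pool_b),
    pool = rep(c("A", "B"),
               c(length(assignment$pool_a), length(assignment$pool_b))))
  df <- df[order(df$founder_id), ]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
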