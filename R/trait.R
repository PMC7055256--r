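# Quantitative trait under the additive-dominance model.
#
# Each QTN i contributes a_i * (x - 1) + d_i * 1{x == 1} to the true genetic
# value (TGV) of an individual with alt-allele dosage x in {0, 1, 2}:
# homozygotes sit at -a and +a, the heterozygote at d. The degree of
# dominance delta_i = d_i / |a_i| expresses dominance relative to the
# additive effect; incomplete dominance means |delta| < 1. Raw effects are
# linearly scaled and shifted once, in the founders, so that founder TGV has
# a target mean and variance (100 and 10 by default).

#' Dominance configuration
#'
#' Degrees of dominance are drawn from Normal(mean_degree, variance_degree).
#' The trait scenarios use mean 0.2, 0.4 or 0.8 with variance 0.2. The
#' normal is not truncated by default even though its mass can exceed 1
#' (complete dominance); set `truncate = TRUE` to resample draws outside
#' (-1, 1) and enforce strictly incomplete dominance.
#'
#' @param mean_degree mean degree of dominance (dimensionless).
#' @param variance_degree variance (not SD) of the degree of dominance.
#' @param truncate resample degrees outside (-1, 1)?
#' @return A `dominance_config` list.
#' @export
dominance_config <- function(mean_degree = 0.4, variance_degree = 0.2,
                             truncate = FALSE) {
  stopifnot(is.finite(mean_degree), variance_degree > 0)
  structure(list(mean_degree = mean_degree, variance_degree = variance_degree,
                 truncate = isTRUE(truncate)),
            class = "dominance_config")
}

#' Sample QTN effects
#'
#' Additive effects `a` are i.i.d. standard normal; degrees of dominance
#' `delta` are i.i.d. Normal(mean, variance) from `dom`; dominance effects
#' are `d = delta * |a|`. The returned architecture is unscaled
#' (`scale = 1`, `intercept = 0`); apply [calibrate_trait()] to pin the
#' founder TGV distribution.
#'
#' @param qtn_loci a `loci_assignment` (its QTN rows define the trait), or any
#'   data.frame of QTN loci.
#' @param dom a [dominance_config()].
#' @param seed integer seed.
#' @return A `trait_arch`: `loci` (QTN map), `a`, `delta`, `d` (raw effects),
#'   `scale`, `intercept`.
#' @export
sample_effects <- function(qtn_loci, dom = dominance_config(), seed = NULL) {
  loci <- as.data.frame(qtn_loci)
  if ("type" %in% names(loci)) loci <- loci[loci$type == "QTN", , drop = FALSE]
  n <- nrow(loci)
  if (n == 0L) fail("no QTN loci to assign effects to")
  with_seed(seed, {
    a <- stats::rnorm(n)
    delta <- stats::rnorm(n, dom$mean_degree, sqrt(dom$variance_degree))
    if (dom$truncate) {
      bad <- which(abs(delta) >= 1)
      while (length(bad)) {
        delta[bad] <- stats::rnorm(length(bad), dom$mean_degree,
                                   sqrt(dom$variance_degree))
        bad <- bad[abs(delta[bad]) >= 1]
      }
    }
    structure(list(loci = loci, a = a, delta = delta, d = delta * abs(a),
                   scale = 1, intercept = 0, dom = dom),
              class = "trait_arch")
  })
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf(
    "Trait architecture: %d QTN, mean dominance degree %.2f (var %.2f)\n  scale %.4g, intercept %.4g\n",
    length(x$a), x$dom$mean_degree, x$dom$variance_degree, x$scale,
    x$intercept))
  invisible(x)
}

#' True genetic value of genotypes
#'
#' TGV = intercept + sum_i scale * (a_i (x_i - 1) + d_i 1\{x_i = 1\}) over
#' QTN dosages x. Fully deterministic; no environmental error.
#'
#' @param dosage individuals-by-QTN matrix (or a single dosage vector) with
#'   values in \{0, 1, 2\}.
#' @param arch a `trait_arch`.
#' @return Numeric vector of TGV, one per individual.
#' @export
tgv <- function(dosage, arch) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1L)
  check_dosages(dosage)
  if (ncol(dosage) != length(arch$a))
    fail("dosage matrix has %d columns but the trait has %d QTN",
         ncol(dosage), length(arch$a))
  add <- (dosage - 1) %*% arch$a
  het <- (dosage == 1) %*% arch$d
  as.numeric(arch$intercept + arch$scale * (add + het))
}

#' TGV of an inbred population
#'
#' Convenience wrapper computing [tgv()] from a population's QTN dosages.
#'
#' @param pop a `population` tracking QTN loci.
#' @param arch a `trait_arch`.
#' @return Numeric vector of TGV.
#' @export
tgv_population <- function(pop, arch) {
  tgv(dosages(pop, "QTN"), arch)
}

#' Calibrate the trait in the founders
#'
#' Linearly rescales all effects and adds a fixed intercept so that founder
#' TGV has the target mean and variance: `scale` is set to
#' `sqrt(target_variance / var(unscaled founder TGV))` (sample variance,
#' n - 1 denominator) and `intercept` so that the mean hits `target_mean`.
#' Calibration is idempotent and invariant to any prior positive rescaling
#' of the raw effects. Dominance effects are scaled by the same factor, so
#' `d / |a| = delta` is preserved.
#'
#' @param arch a `trait_arch`.
#' @param founders the founder `population`.
#' @param target_mean target founder mean TGV (default 100).
#' @param target_variance target founder TGV variance (default 10).
#' @return The calibrated `trait_arch`.
#' @export
calibrate_trait <- function(arch, founders, target_mean = 100,
                            target_variance = 10) {
  raw <- structure(arch, class = "trait_arch")
  raw$scale <- 1
  raw$intercept <- 0
  g <- tgv_population(founders, raw)
  v <- sample_var(g)
  if (v <= 0)
    fail("founder TGV variance is zero under the unscaled effects; founders are degenerate at the QTN")
  arch$scale <- sqrt(target_variance / v)
  arch$intercept <- target_mean - arch$scale * mean(g)
  arch
}

#' Effect table for audit or export
#'
#' @param arch a `trait_arch`.
#' @return A data.frame with chromosome, position, raw additive effect `a`,
#'   degree of dominance `delta`, scaled effects `a_scaled` / `d_scaled`,
#'   and `scale` / `intercept` attributes.
#' @export
effects_table <- function(arch) {
  out <- data.frame(chrom = arch$loci$chrom, pos = arch$loci$pos,
                    a = arch$a, delta = arch$delta, d = arch$d,
                    a_scaled = arch$a * arch$scale,
                    d_scaled = arch$d * arch$scale)
  attr(out, "scale") <- arch$scale
  attr(out, "intercept") <- arch$intercept
  out
}

#' Write the trait architecture to a TSV file
#'
#' Scale and intercept are recorded as `##key=value` header lines above the
#' column header.
#'
#' @param arch a `trait_arch`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trait_tsv <- function(arch, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("##scale=%.17g", arch$scale),
               sprintf("##intercept=%.17g", arch$intercept)), con)
  utils::write.table(effects_table(arch)[, c("chrom", "pos", "a", "delta", "d")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
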