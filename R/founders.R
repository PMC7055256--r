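# Founder populations, SNP/QTN locus assignment and VCF interchange.
#
# Individuals are always fully inbred (doubled haploid) lines, so a genotype
# is stored as a single binary haplotype row over the tracked loci; dosages
# are twice the haplotype. Tracked loci are the SNP panel plus the QTN;
# surplus segregating sites from the coalescent stay in the panel but are
# neutral and untracked downstream.

#' Assign segregating sites to SNP and QTN panels
#'
#' Randomly selects disjoint SNP and QTN locus sets from the segregating sites
#' of a haplotype panel, with exactly equal numbers of SNP and of QTN on every
#' chromosome (e.g. 10,000 SNP and 2,000 QTN on 10 chromosomes give 1,000 SNP
#' and 200 QTN per chromosome).
#'
#' @param panel a `haplotype_panel`.
#' @param n_snp total number of SNP loci (default 10,000).
#' @param n_qtn total number of QTN (500, 2,000 or 8,000 in the default trait
#'   scenarios).
#' @param seed integer seed; a fixed seed gives an identical assignment.
#' @return A `loci_assignment`: a data.frame with columns `chrom`, `site`
#'   (index into the panel chromosome), `pos` (bp), `gpos` (Morgans) and
#'   `type` (`"SNP"` or `"QTN"`), ordered by chromosome and position, with
#'   attributes `n_snp` and `n_qtn`.
#' @export
select_loci <- function(panel, n_snp = 10000L, n_qtn = 2000L, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_chr <- length(panel$chrom)
  if (n_snp %% n_chr != 0L || n_qtn %% n_chr != 0L)
    fail("n_snp (%d) and n_qtn (%d) must both be divisible by the number of chromosomes (%d)",
         n_snp, n_qtn, n_chr)
  snp_per <- n_snp %/% n_chr
  qtn_per <- n_qtn %/% n_chr
  out <- with_seed(seed, {
    lapply(seq_len(n_chr), function(c_idx) {
      ch <- panel$chrom[[c_idx]]
      s_avail <- ncol(ch$hap)
      if (s_avail < snp_per + qtn_per)
        fail("chromosome %d has %d segregating sites but %d are needed (%d SNP + %d QTN)",
             c_idx, s_avail, snp_per + qtn_per, snp_per, qtn_per)
      pick <- sample.int(s_avail, snp_per + qtn_per, replace = FALSE)
      snp <- sort(pick[seq_len(snp_per)])
      qtn <- sort(pick[snp_per + seq_len(qtn_per)])
      data.frame(
        chrom = c_idx,
        site = c(snp, qtn),
        pos = ch$pos[c(snp, qtn)],
        gpos = ch$gpos[c(snp, qtn)],
        type = rep(c("SNP", "QTN"), c(snp_per, qtn_per)))
    })
  })
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  structure(loci, class = c("loci_assignment", "data.frame"),
            n_snp = as.integer(n_snp), n_qtn = as.integer(n_qtn))
}

#' Build a fully inbred founder population from a haplotype panel
#'
#' Founder i carries haplotype i doubled, so every founder is fully
#' homozygous (dosage 0 or 2 at every locus) and founder allele frequencies
#' equal the haplotype-panel frequencies.
#'
#' @param panel a `haplotype_panel` with at least `n_founders` haplotypes.
#' @param loci optional `loci_assignment`; when supplied the population tracks
#'   only the assigned SNP and QTN loci (the usual case), otherwise every
#'   segregating site is tracked with type `"SITE"`.
#' @param n_founders number of founders (default: all haplotypes).
#' @return A `population` object: `hap` (founders-by-loci binary matrix),
#'   `loci` (the tracked locus map), `pool` label and `cycle` index 0.
#' @export
make_inbred_founders <- function(panel, loci = NULL,
                                 n_founders = panel$n_haplotypes) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_founders > panel$n_haplotypes)
    fail("requested %d founders but the panel has only %d haplotypes",
         n_founders, panel$n_haplotypes)
  if (is.null(loci)) {
    loci <- do.call(rbind, lapply(seq_along(panel$chrom), function(c_idx) {
      ch <- panel$chrom[[c_idx]]
      data.frame(chrom = c_idx, site = seq_along(ch$pos), pos = ch$pos,
                 gpos = ch$gpos, type = "SITE")
    }))
    rownames(loci) <- NULL
  }
  hap <- do.call(cbind, lapply(sort(unique(loci$chrom)), function(c_idx) {
    lc <- loci[loci$chrom == c_idx, , drop = FALSE]
    panel$chrom[[c_idx]]$hap[seq_len(n_founders), lc$site, drop = FALSE]
  }))
  new_population(hap, loci, pool = "founders", cycle = 0L)
}

# Population constructor shared by founder setup and the breeding cycle.
new_population <- function(hap, loci, pool = NA_character_, cycle = 0L) {
  stopifnot(is.matrix(hap), ncol(hap) == nrow(loci))
  storage.mode(hap) <- "integer"
  structure(list(hap = hap, loci = loci, pool = pool,
                 cycle = as.integer(cycle)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population '%s' (cycle %d): %d inbred individuals, %d tracked loci (%s)\n",
              x$pool, x$cycle, nrow(x$hap), ncol(x$hap),
              paste(sprintf("%d %s", table(x$loci$type),
                            names(table(x$loci$type))), collapse = ", ")))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `population`.
#' @return Integer count.
#' @export
n_ind <- function(pop) nrow(pop$hap)

# Column indices of QTN / SNP among the tracked loci.
qtn_cols <- function(pop) which(pop$loci$type == "QTN")
snp_cols <- function(pop) which(pop$loci$type == "SNP")

#' Genotype dosages of an inbred population
#'
#' @param pop a `population` (all members fully homozygous).
#' @param type restrict to `"QTN"` or `"SNP"` loci, or `"all"`.
#' @return Individuals-by-loci dosage matrix with values 0/2.
#' @export
dosages <- function(pop, type = c("all", "QTN", "SNP")) {
  type <- match.arg(type)
  cols <- switch(type, all = seq_len(ncol(pop$hap)),
                 QTN = qtn_cols(pop), SNP = snp_cols(pop))
  2L * pop$hap[, cols, drop = FALSE]
}

# Subset a population by individual indices.
subset_population <- function(pop, idx, pool = pop$pool, cycle = pop$cycle) {
  new_population(pop$hap[idx, , drop = FALSE], pop$loci, pool, cycle)
}

#' Export an inbred population to VCF
#'
#' Writes a VCF v4.2 text file with one sample per individual, phased
#' homozygous genotypes (`0|0` / `1|1`), contigs `chr1..chrN` and an INFO tag
#' `LT` recording the tracked locus type (SNP, QTN or SITE). REF/ALT are
#' written as A/T placeholders: the simulation is biallelic 0/1 without
#' nucleotide-level realism.
#'
#' @param pop a `population`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_population_vcf <- function(pop, file) {
  con <- file(file, "w")
  on.exit(close(con))
  ids <- rownames(pop$hap)
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(nrow(pop$hap)))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr%d>", sort(unique(pop$loci$chrom))),
    "##INFO=<ID=LT,Number=1,Type=String,Description=\"Tracked locus type (SNP/QTN/SITE)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  gt <- ifelse(t(pop$hap) == 1L, "1|1", "0|0")
  body <- paste(
    sprintf("chr%d", pop$loci$chrom), pop$loci$pos,
    sprintf("%s_%d_%d", tolower(pop$loci$type), pop$loci$chrom, pop$loci$pos),
    "A", "T", ".", "PASS", sprintf("LT=%s", pop$loci$type), "GT",
    apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(file)
}

#' Import an inbred population from VCF
#'
#' Reads a VCF written by [write_population_vcf()] (or any biallelic,
#' fully homozygous VCF with `chrN` contigs) back into a `population`.
#' Requires the vcfR package.
#'
#' @param file VCF path.
#' @param recombination_rate per-bp rate used to rebuild genetic positions.
#' @return A `population`.
#' @export
read_population_vcf <- function(file, recombination_rate = 1e-8) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    fail("read_population_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  allele <- t(gt == "1|1" | gt == "1/1")
  storage.mode(allele) <- "integer"
  fix <- vcfR::getFIX(v)
  info <- vcfR::extract.info(v, "LT")
  loci <- data.frame(
    chrom = as.integer(sub("^chr", "", fix[, "CHROM"])),
    site = NA_integer_,
    pos = as.integer(fix[, "POS"]),
    gpos = as.integer(fix[, "POS"]) * recombination_rate,
    type = ifelse(is.na(info), "SITE", info))
  ord <- order(loci$chrom, loci$pos)
  new_population(allele[, ord, drop = FALSE], loci[ord, ], pool = "founders")
}
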