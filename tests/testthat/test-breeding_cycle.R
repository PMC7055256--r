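# Meiosis, DH production and the selection schemes.

test_that("gametes of a homozygous parent reproduce the parent", {
  set.seed(41)
  h <- rbinom(60, 1, 0.5)
  loci <- toy_population(rbind(h, h), n_chrom = 2)$loci
  gm <- make_genmap(loci, genetic_length = 1)
  for (i in 1:20) expect_equal(meiosis_gamete(h, h, gm), h)
})

test_that("crossover counts follow the map length (Haldane per interval)", {
  set.seed(42)
  n_loci <- 101L
  loci <- data.frame(chrom = 1L, site = seq_len(n_loci),
                     pos = seq_len(n_loci),
                     gpos = seq(0, 1, length.out = n_loci), type = "SNP")
  gm <- make_genmap(loci, genetic_length = 1)
  h1 <- rep(0L, n_loci)
  h2 <- rep(1L, n_loci)
  switches <- vapply(1:10000, function(i) {
    sum(diff(meiosis_gamete(h1, h2, gm)) != 0)
  }, numeric(1))
  # observed strand switches per interval of length g have expectation
  # (1 - exp(-2g)) / 2 (Haldane); 100 intervals of 0.01 Morgan
  expected <- 100 * (1 - exp(-0.02)) / 2
  se <- sd(switches) / sqrt(length(switches))
  expect_lt(abs(mean(switches) - expected), 3 * se)
})

test_that("two-locus recombinant fraction matches Haldane's map function", {
  set.seed(43)
  loci <- data.frame(chrom = 1L, site = 1:2, pos = c(1, 2),
                     gpos = c(0.45, 0.55), type = "SNP")
  gm <- make_genmap(loci, genetic_length = 1)
  rec <- vapply(1:10000, function(i) {
    g <- meiosis_gamete(c(0L, 0L), c(1L, 1L), gm)
    g[1] != g[2]
  }, logical(1))
  expected <- (1 - exp(-2 * 0.1)) / 2
  se <- sqrt(expected * (1 - expected) / length(rec))
  expect_lt(abs(mean(rec) - expected), 3 * se)
})

test_that("DH progeny are homozygous recombinants of their parents", {
  set.seed(44)
  pop <- toy_population(matrix(rbinom(2 * 40, 1, 0.5), nrow = 2),
                        n_chrom = 2)
  gm <- make_genmap(pop$loci, genetic_length = 1)
  h1 <- pop$hap[1, ]
  h2 <- pop$hap[2, ]
  expect_equal(dh_progeny(h1, h1, gm), h1)
  for (i in 1:20) {
    g <- dh_progeny(h1, h2, gm)
    expect_true(all(g == h1 | g == h2)) # allele containment per locus
  }
  # a single segregating locus is inherited 0/2 with probability 1/2
  one <- vapply(1:10000, function(i) dh_progeny(0L, 1L,
    make_genmap(data.frame(chrom = 1L, gpos = 0.5), 1)), integer(1))
  expect_lt(abs(mean(one) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("random matings draw distinct uniform pairs", {
  m <- random_matings(50, 500, seed = 7)
  expect_equal(dim(m), c(500L, 2L))
  expect_true(all(m[, 1] != m[, 2]))
  expect_identical(m, random_matings(50, 500, seed = 7))
  m2 <- random_matings(2, 10, seed = 1)
  expect_true(all(sort(unique(as.vector(m2))) == c(1L, 2L)))
  expect_error(random_matings(1, 5), "at least 2")
  # each parent appears ~ 2 * n_matings / n_parents times
  counts <- tabulate(as.vector(random_matings(10, 20000, seed = 2)), 10)
  expect_true(all(abs(counts - 4000) < 3 * sqrt(40000 * 0.1 * 0.9)))
})

test_that("GCA is the exact mean hybrid TGV against the testers", {
  set.seed(45)
  inst <- random_instance(8)
  prog <- heteropools:::subset_population(inst$pop, 1:4)
  test <- heteropools:::subset_population(inst$pop, 5:8)
  g <- gca_scores(prog, test, inst$arch)
  expect_equal(dim(g$hybrid_tgv), c(4L, 4L))
  expect_equal(g$scores, rowMeans(g$hybrid_tgv))
  expect_equal(g$hybrid_tgv[2, 3], inst$diallel[2, 7])
  one <- gca_scores(prog, heteropools:::subset_population(inst$pop, 5),
                    inst$arch)
  expect_equal(one$scores, as.numeric(inst$diallel[1:4, 5]))
  # a progeny identical to a tester hybridizes with it at its own line TGV
  clone <- gca_scores(heteropools:::subset_population(inst$pop, 5),
                      test, inst$arch)
  expect_equal(clone$hybrid_tgv[1, 1], inst$diallel[5, 5])
})

test_that("with zero dominance GCA is the additive midparent closed form", {
  set.seed(46)
  hap <- matrix(rbinom(10 * 12, 1, 0.5), nrow = 10)
  pop <- toy_population(hap)
  arch <- toy_arch(a = rnorm(12), d = rep(0, 12), scale = 2, intercept = 9)
  prog <- heteropools:::subset_population(pop, 1:5)
  test <- heteropools:::subset_population(pop, 6:10)
  g <- gca_scores(prog, test, arch)
  line <- tgv(2L * hap, arch)
  expect_equal(g$scores, (line[1:5] + mean(line[6:10])) / 2)
})

test_that("truncation selection takes the top fraction with index ties", {
  s <- c(5, 1, 9, 9, 3)
  expect_equal(truncation_select(s, 0.4), c(3L, 4L))
  expect_equal(truncation_select(rep(1, 10), 0.5), 1:5)
  expect_equal(sort(truncation_select(s, 1)), 1:5)
  expect_error(truncation_select(numeric(0), 0.1), "empty")
  expect_error(truncation_select(s, 0), "proportion")
  sc <- rnorm(500)
  sel <- truncation_select(sc, 0.10)
  expect_length(sel, 50)
  expect_gte(min(sc[sel]), max(sc[-sel]))
})

test_that("scheme configuration enforces census and integral selection", {
  cfg <- scheme_config()
  expect_equal(cfg$n_matings_per_pool * 2L, cfg$n_matings_control)
  expect_equal(cfg$selection_proportion * cfg$n_matings_control, 100)
  expect_error(scheme_config(selection_proportion = 0.123), "not an integer")
})

test_that("one RRS cycle keeps the census and selection bookkeeping", {
  inp <- desk_inputs(200, 0.4, seed = 5)
  cfg <- desk_scheme()
  split <- split_random(inp$founders, seed = 1)
  pa <- heteropools:::subset_population(inp$founders, split$pool_a, "A")
  pb <- heteropools:::subset_population(inp$founders, split$pool_b, "B")
  gm <- make_genmap(inp$founders$loci, 1)
  set.seed(99)
  step <- run_rrs_cycle(pa, pb, inp$arch, cfg, gm, inp$proj)
  expect_equal(n_ind(step$parents_a), 10) # 10% of 100 matings
  expect_equal(n_ind(step$parents_b), 10)
  expect_length(step$selected$A, 10)
  expect_equal(step$record$cycle, c(1L, 1L))
  expect_equal(step$record$pool, c("A", "B"))
  expect_true(all(step$record$inbred_var >= 0))
  expect_true(all(dosages(step$parents_a) %in% c(0L, 2L)))
})

test_that("degenerate identical pools stay constant under RRS", {
  h <- rbinom(20, 1, 0.5)
  hap <- matrix(rep(h, 8), nrow = 8, byrow = TRUE)
  pop <- toy_population(hap, n_chrom = 2)
  arch <- toy_arch(a = rnorm(20), d = rnorm(20), intercept = 100)
  pa <- heteropools:::subset_population(pop, 1:4, "A")
  pb <- heteropools:::subset_population(pop, 5:8, "B")
  gm <- make_genmap(pop$loci, 1)
  cfg <- scheme_config(n_matings_per_pool = 20, n_matings_control = 40,
                       selection_proportion = 0.1, n_cycles = 2)
  set.seed(50)
  s1 <- run_rrs_cycle(pa, pb, arch, cfg, gm)
  s2 <- run_rrs_cycle(s1$parents_a, s1$parents_b, arch, cfg, gm)
  line <- tgv(matrix(2L * h, nrow = 1), arch)
  expect_equal(s1$record$inbred_mean, rep(line, 2))
  expect_equal(s2$record$inbred_mean, rep(line, 2))
  expect_equal(s1$record$hybrid_mean, rep(line, 2))
  expect_equal(s1$record$inbred_var, c(0, 0))
  expect_equal(s1$selected$A, 1:2) # index-deterministic under ties
})

test_that("the per se control promotes the top tenth and reports the half diallel", {
  inp <- desk_inputs(200, 0.4, seed = 5)
  cfg <- scheme_config(n_matings_per_pool = 100, n_matings_control = 200,
                       selection_proportion = 0.1, n_cycles = 2)
  rec <- run_perse_scheme(inp$founders, inp$arch, cfg,
                          make_genmap(inp$founders$loci, 1),
                          proj = inp$proj, seed = 60)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$pool, rep("control", 2))
  expect_true(all(rec$hybrid_var >= 0))
  # selection acts: cycle means increase from the founder mean of 100
  expect_gt(rec$inbred_mean[2], rec$inbred_mean[1])
})

test_that("scenarios are reproducible and share founders across strategies", {
  inp <- desk_inputs(200, 0.4, seed = 5)
  cfg <- scheme_config(n_matings_per_pool = 20, n_matings_control = 40,
                       selection_proportion = 0.1, n_cycles = 3)
  r1 <- run_scenario(inp$founders, inp$arch, "random", cfg, seed = 8,
                     proj = inp$proj)
  r2 <- run_scenario(inp$founders, inp$arch, "random", cfg, seed = 8,
                     proj = inp$proj)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 6) # 3 cycles x 2 pool rows
  expect_error(run_scenario(inp$founders, inp$arch, "bogus", cfg),
               "unknown strategy")
  rc <- run_scenario(inp$founders, inp$arch, "control", cfg, seed = 8,
                     proj = inp$proj)
  expect_equal(nrow(rc), 3)
})

test_that("selection raises means and erodes variance over replicates", {
  set.seed(70)
  gains <- replicate(20, {
    hap <- matrix(rbinom(20 * 30, 1, 0.5), nrow = 20)
    pop <- toy_population(hap, types = rep(c("SNP", "QTN"), c(10, 20)),
                          n_chrom = 2)
    arch <- calibrate_trait(sample_effects(pop$loci, dominance_config(0.4)),
                            pop)
    cfg <- scheme_config(n_matings_per_pool = 20, n_matings_control = 40,
                         selection_proportion = 0.1, n_cycles = 5)
    rec <- run_perse_scheme(pop, arch, cfg, make_genmap(pop$loci, 1))
    c(gain = rec$inbred_mean[5] - rec$inbred_mean[1],
      var_drop = rec$inbred_var[1] - rec$inbred_var[5])
  })
  # monotone trend: final mean exceeds cycle-1 mean in expectation
  expect_gt(mean(gains["gain", ]), 0)
  expect_gte(sum(gains["gain", ] > 0), 19)
  # variance erosion in nearly all replicates
  expect_gte(sum(gains["var_drop", ] > 0), 19)
})

test_that("RRS drives the pools' allele frequencies apart", {
  set.seed(71)
  diverged <- replicate(10, {
    hap <- matrix(rbinom(20 * 30, 1, 0.5), nrow = 20)
    pop <- toy_population(hap, types = rep(c("SNP", "QTN"), c(10, 20)),
                          n_chrom = 2)
    arch <- calibrate_trait(sample_effects(pop$loci, dominance_config(0.8)),
                            pop)
    cfg <- scheme_config(n_matings_per_pool = 20, n_matings_control = 40,
                         selection_proportion = 0.1, n_cycles = 6)
    gm <- make_genmap(pop$loci, 1)
    split <- split_random(pop)
    pa <- heteropools:::subset_population(pop, split$pool_a, "A")
    pb <- heteropools:::subset_population(pop, split$pool_b, "B")
    d0 <- pool_allele_divergence(pa, pb, "all")
    for (cyc in 1:6) {
      step <- run_rrs_cycle(pa, pb, arch, cfg, gm)
      pa <- step$parents_a
      pb <- step$parents_b
    }
    pool_allele_divergence(pa, pb, "all") - d0
  })
  expect_gte(sum(diverged > 0), 9)
})

test_that("with zero dominance the first-cycle RRS response matches per se selection", {
  # under pure additivity GCA ranks lines exactly like their own TGV, so
  # selecting the top 10% within each pool responds like selecting the top
  # 10% overall; compared on the first cycle, before within-pool drift can
  # differentiate the schemes
  res <- sapply(seq_len(20), function(r) {
    set.seed(720 + r)
    hap <- matrix(rbinom(40 * 60, 1, 0.5), nrow = 40)
    pop <- toy_population(hap, types = rep(c("SNP", "QTN"), c(20, 40)),
                          n_chrom = 2)
    arch <- sample_effects(pop$loci, dominance_config(0.4))
    arch$delta <- rep(0, length(arch$delta))
    arch$d <- rep(0, length(arch$d))
    arch <- calibrate_trait(arch, pop)
    cfg <- scheme_config(n_matings_per_pool = 100, n_matings_control = 200,
                         selection_proportion = 0.1, n_cycles = 1)
    rrs <- run_scenario(pop, arch, "random", cfg)
    ctl <- run_scenario(pop, arch, "control", cfg)
    # with d = 0 the hybrid mean IS the selected-parent mean (midparent
    # identity), so this compares the two schemes' selection response
    c(sel = rrs$hybrid_mean[1] - ctl$hybrid_mean[1],
      prog = rrs$inbred_mean[1] - ctl$inbred_mean[1])
  })
  expect_lt(abs(mean(res["sel", ])), 3 * sd(res["sel", ]) / sqrt(20))
  expect_lt(abs(mean(res["prog", ])), 3 * sd(res["prog", ]) / sqrt(20))
})
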