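test_that("sampled effects satisfy the dominance identity and their moments", {
  loci <- data.frame(chrom = rep(1:2, each = 4000), pos = 1:8000,
                     type = "QTN")
  arch <- sample_effects(loci, dominance_config(0.8, 0.2), seed = 1)
  arch2 <- sample_effects(loci, dominance_config(0.8, 0.2), seed = 1)
  expect_identical(arch, arch2)
  expect_equal(arch$d, arch$delta * abs(arch$a))
  expect_equal(arch$d / abs(arch$a), arch$delta)
  # mean(delta) within 3 SE of the configured mean: SE = sqrt(0.2 / 8000)
  expect_lt(abs(mean(arch$delta) - 0.8), 3 * sqrt(0.2 / 8000))
  # var(a) near 1: SD of the sample variance of N(0,1) is sqrt(2 / (n - 1))
  expect_lt(abs(var(arch$a) - 1), 3 * sqrt(2 / 7999))
  expect_error(sample_effects(loci[0, ], dominance_config()), "no QTN")
})

test_that("truncated sampling keeps all dominance degrees inside (-1, 1)", {
  loci <- data.frame(chrom = 1, pos = 1:2000, type = "QTN")
  arch <- sample_effects(loci, dominance_config(0.8, 0.2, truncate = TRUE),
                         seed = 2)
  expect_true(all(abs(arch$delta) < 1))
  # untruncated N(0.8, 0.2) must put draws beyond 1 in a sample this large
  arch_u <- sample_effects(loci, dominance_config(0.8, 0.2), seed = 2)
  expect_true(any(abs(arch_u$delta) >= 1))
})

test_that("TGV follows the additive-dominance parameterization", {
  arch <- toy_arch(a = 1, d = 0.5)
  expect_equal(tgv(matrix(c(0, 1, 2), ncol = 1), arch), c(-1, 0.5, 1))
  arch2 <- toy_arch(a = c(1, -2), d = c(0.5, 1), scale = 3, intercept = 7)
  dos <- rbind(c(0, 1), c(2, 2), c(1, 0))
  expect_equal(tgv(dos, arch2), tgv_brute(dos, c(1, -2), c(0.5, 1), 3, 7))
  expect_error(tgv(matrix(3, 1, 1), arch), "dosages")
  expect_error(tgv(matrix(1, 1, 5), arch), "5 columns")
})

test_that("dominance is inert in fully homozygous populations", {
  set.seed(11)
  hap <- matrix(rbinom(80, 1, 0.5), nrow = 8)
  dos <- 2L * hap
  a <- rnorm(10)
  base <- tgv(dos, toy_arch(a, d = rep(0, 10)))
  for (i in 1:5) {
    expect_equal(tgv(dos, toy_arch(a, d = rnorm(10))), base)
  }
})

test_that("calibration pins founder TGV to mean 100 and variance 10", {
  inp <- desk_inputs(200, 0.4, seed = 5)
  g <- tgv_population(inp$founders, inp$arch)
  expect_equal(mean(g), 100, tolerance = 1e-9)
  expect_equal(var(g), 10, tolerance = 1e-9)
  # idempotence
  arch2 <- calibrate_trait(inp$arch, inp$founders)
  expect_equal(arch2$scale, inp$arch$scale, tolerance = 1e-12)
  expect_equal(arch2$intercept, inp$arch$intercept, tolerance = 1e-9)
  # invariance to a prior positive rescaling of the raw effects
  inflated <- inp$arch
  inflated$a <- inflated$a * 4.2
  inflated$d <- inflated$d * 4.2
  recal <- calibrate_trait(inflated, inp$founders)
  expect_equal(tgv_population(inp$founders, recal), g, tolerance = 1e-9)
})

test_that("degenerate founders fail calibration with a clear error", {
  hap <- matrix(1L, nrow = 6, ncol = 4)
  pop <- toy_population(hap)
  arch <- sample_effects(pop$loci, dominance_config(), seed = 1)
  expect_error(calibrate_trait(arch, pop), "degenerate")
})

test_that("mean F1 TGV over a pool cross matches the closed form and brute force", {
  set.seed(21)
  hap <- matrix(rbinom(6 * 12, 1, 0.5), nrow = 6)
  pop <- toy_population(hap)
  arch <- sample_effects(pop$loci, dominance_config(0.6), seed = 3)
  pool1 <- 1:3
  pool2 <- 4:6
  # brute force: every parent pair, per-locus loops
  brute <- mean(sapply(pool1, function(i) sapply(pool2, function(j) {
    tgv_brute(hap[i, ] + hap[j, ], arch$a, arch$d, arch$scale,
              arch$intercept)
  })))
  # closed form from pool allele frequencies
  p1 <- colMeans(hap[pool1, , drop = FALSE])
  p2 <- colMeans(hap[pool2, , drop = FALSE])
  closed <- arch$intercept + arch$scale *
    sum(arch$a * (p1 + p2 - 1) + arch$d * (p1 + p2 - 2 * p1 * p2))
  dia <- full_diallel(pop, arch)
  expect_equal(between_pool_mean(dia, pool1, pool2), brute)
  expect_equal(between_pool_mean(dia, pool1, pool2), closed)
})

test_that("with zero dominance every hybrid equals its midparent mean", {
  set.seed(22)
  hap <- matrix(rbinom(8 * 10, 1, 0.5), nrow = 8)
  pop <- toy_population(hap)
  arch <- toy_arch(a = rnorm(10), d = rep(0, 10), scale = 1.7,
                   intercept = 50)
  dia <- full_diallel(pop, arch)
  line <- tgv(2L * hap, arch)
  expect_equal(unclass(dia), outer(line, line, "+") / 2)
})

test_that("the effect table and TSV round-trip carry scale and intercept", {
  inp <- desk_inputs(200, 0.4, seed = 5)
  tab <- effects_table(inp$arch)
  expect_equal(nrow(tab), 200)
  expect_equal(tab$a_scaled, tab$a * attr(tab, "scale"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trait_tsv(inp$arch, f)
  lines <- readLines(f, n = 2)
  expect_match(lines[1], "^##scale=")
  body <- read.delim(f, skip = 2)
  expect_equal(body$a, inp$arch$a)
  expect_equal(body$d, inp$arch$d)
})
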