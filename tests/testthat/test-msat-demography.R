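test_that("imbalance index: equilibrium calibration and degenerate input", {
  # dataset of identical homozygous individuals: undefined
  g0 <- genoFromPairs(list(cbind(rep(50L, 2), rep(50L, 2)),
                           cbind(rep(40L, 2), rep(40L, 2))))
  expect_false(kimmelBeta(g0)$defined)
  # single-step equilibrium: mean ln beta near 0
  set.seed(31)
  lb <- vapply(1:60, function(r) kimmelBeta(mkGeno(25, 10, 5))$ln_beta, 0)
  expect_lt(abs(mean(lb, na.rm = TRUE)), 0.25)
})

test_that("imbalance index detects expansion after a bottleneck", {
  # crash then recovery leaves theta_V inflated relative to homozygosity
  set.seed(32)
  sites <- data.frame(pop = "P", lat = 0, lon = 0, n_seq = 0, n_geno = 25)
  beta <- numeric(15)
  for (r in 1:15) {
    cfg <- simulationConfig(sites, NULL, N = 2500, m_f = 0, m_m = 0,
                            migration_mode = "island",
                            history = list(type = "bottleneck",
                                           time_gen = 2000, strength = 100),
                            msat_model = list(n_loci = 10, mu = 5e-4, p_s = 1,
                                              delta_g = 3.5, repeat_unit = 2L,
                                              anc = 100L))
    g <- simulateMicrosatellites(cfg, 900 + r)$genotypes
    beta[r] <- kimmelBeta(g)$beta
  }
  expect_gt(median(beta, na.rm = TRUE), 1)
})

test_that("expansion index: equilibrium mean, hand formula, direction", {
  set.seed(33)
  sk <- vapply(1:60, function(r)
    zhivotovskySk(mkGeno(25, 10, 5), R_k = 1)$S_k, 0)
  expect_lt(abs(mean(sk, na.rm = TRUE)), 0.15)
  # two-allele loci one repeat apart: finite S_k equal to direct evaluation
  gh <- genoFromPairs(list(cbind(rep(50L, 6), rep(51L, 6)),
                           cbind(rep(50L, 6), rep(51L, 6))),
                      repeat_unit = 1L)
  res <- zhivotovskySk(gh, R_k = 6.3)
  x <- rep(c(50, 51), 6)
  mom <- riverpopgen:::.sizeMoments(x)
  V <- mom["V"]; K <- mom["K"]
  expect_equal(res$S_k, unname(1 - (K - 6.3 * V / 2) / (5 * V^2)))
  expect_true(is.finite(res$S_k))
  # strong bottleneck: median S_k < 0 with depressed V
  set.seed(34)
  sites <- data.frame(pop = "P", lat = 0, lon = 0, n_seq = 0, n_geno = 25)
  skB <- VB <- numeric(15)
  for (r in 1:15) {
    cfg <- simulationConfig(sites, NULL, N = 50, m_f = 0, m_m = 0,
                            migration_mode = "island",
                            history = list(type = "bottleneck",
                                           time_gen = 200, strength = 100),
                            msat_model = list(n_loci = 10, mu = 5e-4, p_s = 1,
                                              delta_g = 3.5, repeat_unit = 2L,
                                              anc = 100L))
    g <- simulateMicrosatellites(cfg, 950 + r)$genotypes
    z <- zhivotovskySk(g, R_k = 1)
    skB[r] <- z$S_k; VB[r] <- z$V
  }
  expect_lt(median(skB, na.rm = TRUE), 0)
})

test_that("M ratio arithmetic and invariances", {
  g <- genoFromPairs(list(cbind(c(50L, 52L, 50L), c(52L, 50L, 52L)),
                          cbind(c(30L, 36L, 30L), c(30L, 36L, 36L)),
                          cbind(rep(44L, 3), rep(44L, 3))))
  gw <- gwMRatio(g)
  expect_equal(gw$per_locus$M, c(2 / 3, 2 / 7, 1))
  expect_true(gw$per_locus$monomorphic[3])
  # alleles at every state in the range: M = 1
  gg <- genoFromPairs(list(cbind(c(50L, 51L, 52L), c(50L, 51L, 52L))),
                      repeat_unit = 1L)
  expect_equal(gwMRatio(gg)$per_locus$M, 1)
  # scale invariance to the repeat-unit convention: the container already
  # holds repeat counts, so M is unchanged whether sizes came from 2 bp or
  # 4 bp raw units
  gp <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "Pop", "a1 , 100104", "a2 , 100100"), gp)
  m2 <- gwMRatio(readGenepop(gp, 2L))$per_locus$M   # 50, 52
  writeLines(c("t", "locA", "Pop", "a1 , 100108", "a2 , 100100"), gp)
  m4 <- gwMRatio(readGenepop(gp, 4L))$per_locus$M   # 25, 27
  expect_equal(m2, m4)
  # beta and S_k invariant to adding a constant to all allele sizes
  set.seed(35)
  gA <- mkGeno(20, 6, 4)
  gB <- GenotypeMatrix(alleleMatrix(gA, 1) + 7L, alleleMatrix(gA, 2) + 7L,
                       repeatUnits(gA), pop = populations(gA))
  expect_equal(kimmelBeta(gA)$beta, kimmelBeta(gB)$beta)
  expect_equal(zhivotovskySk(gA)$S_k, zhivotovskySk(gB)$S_k)
})

test_that("equilibrium M null: limits, ordering, monotonicity", {
  # theta -> 0: nearly all replicates monomorphic, mean M near 1
  low <- gwNullDistribution(theta = 0.01, p_s = 1, n_genes = 20,
                            reps = 1000, seed = 1)
  expect_gt(low$mean, 0.97)
  # pure single-step mean M exceeds two-phase mean M at equal theta
  s1 <- gwNullDistribution(theta = 3, p_s = 1, delta_g = 3.5,
                           n_genes = 40, reps = 1500, seed = 2)
  s08 <- gwNullDistribution(theta = 3, p_s = 0.8, delta_g = 3.5,
                            n_genes = 40, reps = 1500, seed = 3)
  expect_gt(s1$mean, s08$mean)
  # mean M non-increasing in theta
  th <- c(0.5, 2, 8)
  ms <- vapply(seq_along(th), function(i)
    gwNullDistribution(theta = th[i], p_s = 1, n_genes = 40,
                       reps = 1000, seed = 10 + i)$mean, 0)
  expect_true(all(diff(ms) < 0))
  # rank probability and critical value are consistent
  gn <- gwNullDistribution(theta = 2, p_s = 0.9, n_genes = 40,
                           reps = 1000, seed = 4, observed_M = 0.5)
  expect_identical(gn$significant, 0.5 < gn$M_c)
  expect_error(gwNullDistribution(theta = -1, n_genes = 10), "theta")
  expect_error(gwNullDistribution(theta = 1, n_genes = 10, reps = 10),
               "1000")
})

test_that("intralocus kurtosis test: binomial significance is exact", {
  # build 6 platykurtic (two-point) and 4 leptokurtic (peaked) loci
  flat <- function() cbind(rep(c(40L, 60L), 8), rep(c(40L, 60L), 8))
  peak <- function() cbind(c(rep(50L, 14), 40L, 60L), rep(50L, 16))
  g <- genoFromPairs(c(replicate(6, flat(), simplify = FALSE),
                       replicate(4, peak(), simplify = FALSE)))
  rk <- reichKTest(g)
  expect_identical(rk$n_loci, 10L)
  expect_identical(rk$n_positive, 4L)
  expect_equal(rk$p, pbinom(4, 10, 0.515))
  expect_equal(round(rk$p, 3), 0.341)
  # oracle identity: p equals exhaustive summation of the binomial mass
  expect_equal(rk$p, sum(dbinom(0:4, 10, 0.515)))
  # all-positive: whole support, p = 1
  gpos <- genoFromPairs(replicate(10, peak(), simplify = FALSE))
  expect_equal(reichKTest(gpos)$p, 1)
  # all-negative: p = 0.485^10
  gneg <- genoFromPairs(replicate(10, flat(), simplify = FALSE))
  expect_equal(reichKTest(gneg)$p, 0.485^10)
  # monomorphic loci are excluded from the trial count
  gm <- genoFromPairs(c(replicate(3, flat(), simplify = FALSE),
                        list(cbind(rep(50L, 16), rep(50L, 16)))))
  expect_identical(reichKTest(gm)$n_loci, 3L)
})

test_that("interlocus variance test: minimum, calibration and power", {
  # identical per-locus variances: interlocus variance 0, g at its minimum
  same <- cbind(rep(c(50L, 52L), 8), rep(c(52L, 50L), 8))
  g0 <- genoFromPairs(replicate(5, same, simplify = FALSE))
  r0 <- reichGTest(g0, reps = 200, seed = 1)
  expect_equal(r0$g, 0)
  expect_true(r0$significant)
  # constant-size data: rejection near the nominal 5%
  set.seed(36)
  rej <- vapply(1:40, function(r) {
    g <- mkGeno(20, 8, 4)
    rg <- reichGTest(g, reps = 150, seed = 400 + r)
    isTRUE(rg$significant)
  }, TRUE)
  expect_lt(mean(rej), 0.2)
  # expansion data reject more often than constant-size data
  sites <- data.frame(pop = "P", lat = 0, lon = 0, n_seq = 0, n_geno = 20)
  rejE <- vapply(1:15, function(r) {
    cfg <- simulationConfig(sites, NULL, N = 20000, m_f = 0, m_m = 0,
                            migration_mode = "island",
                            history = list(type = "expansion",
                                           time_gen = 3000, factor = 200),
                            msat_model = list(n_loci = 8, mu = 5e-4, p_s = 1,
                                              delta_g = 3.5, repeat_unit = 2L,
                                              anc = 100L))
    g <- simulateMicrosatellites(cfg, 980 + r)$genotypes
    isTRUE(reichGTest(g, reps = 150, seed = 500 + r)$significant)
  }, TRUE)
  expect_gt(mean(rejE), mean(rej))
})
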