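test_that("heterozygosity matches closed forms and a counting oracle", {
  # monomorphic locus
  g <- genoFromPairs(list(cbind(rep(50L, 6), rep(50L, 6))))
  md <- msatDiversity(g)
  expect_equal(md$per_locus$He, 0)
  expect_equal(md$per_locus$k, 1)
  # single heterozygous individual: Ho = 1, unbiased He = 1
  g1 <- genoFromPairs(list(cbind(50L, 52L)))
  md1 <- msatDiversity(g1)
  expect_equal(md1$per_locus$Ho, 1)
  expect_equal(md1$per_locus$He, 1)
  # 10-individual toy vs exhaustive counting
  set.seed(5)
  g10 <- mkGeno(10, 3, theta = 3)
  md10 <- msatDiversity(g10)
  for (li in 1:3) {
    l <- lociNames(g10)[li]
    al <- c(alleleMatrix(g10, 1)[, l], alleleMatrix(g10, 2)[, l])
    p <- table(al) / length(al)
    n <- 10
    expect_equal(md10$per_locus$He[li],
                 2 * n * (1 - sum(p^2)) / (2 * n - 1))
    expect_equal(md10$per_locus$Ho[li],
                 mean(alleleMatrix(g10, 1)[, l] != alleleMatrix(g10, 2)[, l]))
    expect_equal(md10$per_locus$k[li], length(p))
  }
  # unbiased He >= plug-in gene diversity
  expect_true(all(md10$per_locus$He >=
                    vapply(1:3, function(li) {
                      l <- lociNames(g10)[li]
                      al <- c(alleleMatrix(g10, 1)[, l],
                              alleleMatrix(g10, 2)[, l])
                      1 - sum((table(al) / length(al))^2)
                    }, 0)))
})

test_that("HWE exact machinery: perfect proportions, fixation, enumeration", {
  # 25/50/25 at two alleles: f near 0, p near 1
  pairs <- rbind(cbind(rep(50L, 25), rep(50L, 25)),
                 cbind(rep(50L, 50), rep(52L, 50)),
                 cbind(rep(52L, 25), rep(52L, 25)))
  g <- genoFromPairs(list(pairs))
  hw <- hweTests(g, mcmc = list(demem = 500, batches = 5, iters = 200),
                 seed = 1)
  expect_lt(abs(hw$tests$f_RH), 0.05)
  expect_gt(hw$tests$p, 0.5)
  # all homozygotes at two alleles: f = 1, small exact p
  gh <- genoFromPairs(list(cbind(c(rep(50L, 5), rep(52L, 5)),
                                 c(rep(50L, 5), rep(52L, 5)))))
  hwh <- hweTests(gh, seed = 1)
  expect_equal(hwh$tests$f_RH, 1)
  expect_lt(hwh$tests$p, 0.01)
  # Fisher combination df is twice the number of combined tests
  set.seed(6)
  gm <- mkGeno(15, 4, theta = 2)
  hwm <- hweTests(gm, mcmc = list(demem = 500, batches = 5, iters = 200),
                  seed = 2)
  expect_identical(hwm$fisher_by_pop$df, 2L * nrow(hwm$tests))
})

test_that("HWE Markov chain agrees with full enumeration (3 alleles, n = 10)", {
  # exhaustive enumeration over genotype tables with fixed allele counts
  enumHwe <- function(M) {
    a <- riverpopgen:::.alleleCountsFromGenos(M)
    k <- length(a)
    obsLp <- riverpopgen:::.hweLogProb(M)
    cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    n <- sum(M)
    tot <- 0; hit <- 0
    rec <- function(ci, left, tab) {
      if (ci > nrow(cells)) {
        if (left != 0) return()
        counts <- riverpopgen:::.alleleCountsFromGenos(tab)
        if (!all(counts == a)) return()
        lp <- riverpopgen:::.hweLogProb(tab)
        p <- exp(lp)
        tot <<- tot + p
        if (lp <= obsLp + 1e-9) hit <<- hit + p
        return()
      }
      for (x in 0:left) {
        tab[cells[ci, 1], cells[ci, 2]] <- x
        rec(ci + 1, left - x, tab)
      }
    }
    rec(1, n, matrix(0L, k, k))
    hit / tot
  }
  set.seed(7)
  repeat {            # a polymorphic 3-allele sample of 10 individuals
    g <- mkGeno(10, 1, theta = 3)
    M <- riverpopgen:::.genoTable(g, "L01", 1:10)
    if (nrow(M) == 3) break
  }
  exact <- enumHwe(M)
  set.seed(8)
  mc <- riverpopgen:::.hweMcmc(M, demem = 5000, batches = 20, iters = 2000)
  expect_lt(abs(mc$p - exact), max(3 * mc$se, 0.02))
})

test_that("F-statistics behave at the fixed and panmictic extremes", {
  # identical allele frequencies, moderate n: F_ST near 0
  set.seed(9)
  base <- mkGeno(60, 5, theta = 3)
  pops <- rep(c("A", "B"), 30)
  gS <- GenotypeMatrix(alleleMatrix(base, 1), alleleMatrix(base, 2),
                       repeatUnits(base),
                       pop = setNames(pops, sampleIDs(base)))
  f0 <- fStats(gS, randomizations = 100, seed = 1)
  expect_lt(abs(f0$multilocus["F_ST"]), 0.05)
  expect_gt(f0$p_G, 0.05)
  # two populations fixed for different alleles: F_ST = 1, Nm = 0
  gf <- genoFromPairs(list(cbind(c(rep(50L, 5), rep(60L, 5)),
                                 c(rep(50L, 5), rep(60L, 5)))),
                      pop = rep(c("A", "B"), each = 5))
  ff <- fStats(gf, randomizations = 50, seed = 2)
  expect_equal(unname(ff$multilocus["F_ST"]), 1)
  expect_equal(ff$pairwise_Nm["A", "B"], 0)
  expect_lt(ff$p_G, 0.05)
  # merging two copies of the same population: pairwise F_ST ~ 0
  expect_lt(abs(f0$pairwise_FST["A", "B"]), 0.05)
})

test_that("Nei (1978) distance matches hand computation and flags", {
  # identical populations: D = 0
  gI <- genoFromPairs(list(cbind(rep(c(50L, 52L), 4), rep(c(52L, 50L), 4))),
                      pop = rep(c("A", "B"), each = 4))
  expect_equal(neiDistance(gI)$D["A", "B"], 0, tolerance = 1e-12)
  # no shared alleles: infinite, flagged
  gN <- genoFromPairs(list(cbind(c(rep(50L, 4), rep(60L, 4)),
                                 c(rep(50L, 4), rep(60L, 4)))),
                      pop = rep(c("A", "B"), each = 4))
  ndN <- neiDistance(gN)
  expect_identical(ndN$D["A", "B"], Inf)
  expect_identical(ndN$infinite_pairs, "A:B")
  # 2-locus hand example
  # pop A: locus1 alleles all 50; locus2 half 50 half 52
  # pop B: locus1 half 50 half 52; locus2 all 52
  gH <- genoFromPairs(list(
    cbind(c(50L, 50L, 50L, 52L), c(50L, 50L, 50L, 52L)),
    cbind(c(50L, 50L, 52L, 52L), c(52L, 52L, 52L, 52L))),
    pop = c("A", "A", "B", "B"))
  nd <- neiDistance(gH)
  jx <- jy <- jxy <- numeric(2)
  for (l in 1:2) {
    fa <- table(factor(c(alleleMatrix(gH, 1)[1:2, l],
                         alleleMatrix(gH, 2)[1:2, l]), levels = c(50, 52))) / 4
    fb <- table(factor(c(alleleMatrix(gH, 1)[3:4, l],
                         alleleMatrix(gH, 2)[3:4, l]), levels = c(50, 52))) / 4
    jx[l] <- (4 * sum(fa^2) - 1) / 3
    jy[l] <- (4 * sum(fb^2) - 1) / 3
    jxy[l] <- sum(fa * fb)
  }
  expect_equal(nd$D["A", "B"],
               -log(mean(jxy) / sqrt(mean(jx) * mean(jy))))
})

test_that("exact differentiation tests and the Bonferroni layer", {
  # identical populations: p near 1
  gI <- genoFromPairs(list(cbind(rep(50L, 8), rep(c(50L, 52L), 4))),
                      pop = rep(c("A", "B"), each = 4))
  edI <- exactDifferentiation(gI, mode = "genic",
                              mcmc = list(demem = 500, batches = 5,
                                          iters = 200), seed = 1)
  expect_gt(edI$per_locus$p[1], 0.5)
  # fixed differences across several loci: tiny global p
  mkfix <- function() cbind(c(rep(50L, 6), rep(60L, 6)),
                            c(rep(50L, 6), rep(60L, 6)))
  gF <- genoFromPairs(list(mkfix(), mkfix(), mkfix()),
                      pop = rep(c("A", "B"), each = 6))
  edF <- exactDifferentiation(gF, mode = "genic",
                              mcmc = list(demem = 500, batches = 5,
                                          iters = 200), seed = 2)
  expect_lt(edF$global_p, 0.001)
  # genotypic mode runs on the same data
  edG <- exactDifferentiation(gF, mode = "genotypic",
                              mcmc = list(demem = 500, batches = 5,
                                          iters = 200), seed = 3)
  expect_lt(edG$global_p, 0.001)
  # Bonferroni arithmetic for 28 pairwise comparisons
  expect_equal(round(0.05 / 28, 5), 0.00179)
  expect_error(exactDifferentiation(
    genoFromPairs(list(cbind(rep(50L, 4), rep(50L, 4)))), mode = "genic"),
    ">= 2 populations")
})

test_that("private-allele gene flow responds to structure", {
  # no private alleles: inapplicable
  gI <- genoFromPairs(list(cbind(rep(c(50L, 52L), 4), rep(c(50L, 52L), 4))),
                      pop = rep(c("A", "B"), each = 4))
  expect_false(privateAlleleNm(gI)$applicable)
  # one population owning all alleles of a locus at high frequency: small Nm
  gP <- genoFromPairs(list(cbind(c(rep(50L, 6), rep(60L, 6)),
                                 c(rep(50L, 6), rep(60L, 6))),
                           cbind(rep(52L, 12), rep(52L, 12))),
                      pop = rep(c("A", "B"), each = 6))
  rp <- privateAlleleNm(gP)
  expect_true(rp$applicable)
  expect_lt(rp$Nm, 1)
  # higher migration -> higher Nm (monotonicity via private-allele freq)
  sites <- data.frame(pop = c("A", "B"), lat = 0:1, lon = 0:1,
                      n_seq = 0, n_geno = c(20, 20))
  nmLow <- nmHigh <- numeric(8)
  for (r in 1:8) {
    cl <- simulationConfig(sites, NULL, N = 500, m_f = 2e-4, m_m = 2e-4,
                           migration_mode = "island",
                           msat_model = list(n_loci = 8, mu = 2e-4, p_s = 1,
                                             delta_g = 3.5, repeat_unit = 2L,
                                             anc = 50L))
    ch <- simulationConfig(sites, NULL, N = 500, m_f = 2e-2, m_m = 2e-2,
                           migration_mode = "island",
                           msat_model = list(n_loci = 8, mu = 2e-4, p_s = 1,
                                             delta_g = 3.5, repeat_unit = 2L,
                                             anc = 50L))
    rl <- privateAlleleNm(simulateMicrosatellites(cl, 700 + r)$genotypes)
    rh <- privateAlleleNm(simulateMicrosatellites(ch, 800 + r)$genotypes)
    nmLow[r] <- if (rl$applicable) rl$Nm else NA
    nmHigh[r] <- if (rh$applicable) rh$Nm else NA
  }
  expect_gt(median(nmHigh, na.rm = TRUE), median(nmLow, na.rm = TRUE))
})

test_that("assignment: trivial cases and the leave-one-out oracle", {
  # individual carrying alleles present only in pop A is assigned to A
  gA <- genoFromPairs(list(cbind(c(50L, 50L, 50L, 60L, 60L, 50L),
                                 c(50L, 50L, 50L, 60L, 60L, 50L)),
                           cbind(c(40L, 40L, 40L, 44L, 44L, 40L),
                                 c(40L, 40L, 40L, 44L, 44L, 40L))),
                      pop = c("A", "A", "A", "B", "B", "B"))
  as1 <- assignIndividuals(gA, criterion = "frequency",
                           exclusion_sims = 100, seed = 1)
  expect_identical(unname(as1$assigned["i006"]), "A")  # B resident, A alleles
  expect_true(as1$L["i006" == sampleIDs(gA)] < 1)
  # resident of its only population: L = 1
  gS <- genoFromPairs(list(cbind(c(50L, 52L), c(50L, 52L))),
                      pop = c("A", "A"))
  asS <- assignIndividuals(gS, criterion = "frequency",
                           exclusion_sims = 0, seed = 1)
  expect_equal(unname(asS$L), c(1, 1))
  # leave-one-out likelihood equals a from-scratch recount
  set.seed(11)
  g <- mkGeno(12, 3, theta = 3, pop = rep(c("A", "B"), each = 6))
  as2 <- assignIndividuals(g, criterion = "frequency",
                           exclusion_sims = 0, seed = 1)
  i <- 1  # resident of A
  rows <- setdiff(which(populations(g) == "A"), i)
  ll <- 0
  for (l in lociNames(g)) {
    al <- c(alleleMatrix(g, 1)[rows, l], alleleMatrix(g, 2)[rows, l])
    tb <- table(al)
    pr <- function(x) {
      v <- tb[as.character(x)]
      if (is.na(v) || v == 0) 0.01 else v / sum(tb)
    }
    a <- alleleMatrix(g, 1)[i, l]; b <- alleleMatrix(g, 2)[i, l]
    ll <- ll + if (a == b) log(pr(a)^2) else log(2 * pr(a) * pr(b))
  }
  expect_equal(unname(as2$scores[i, "A"]), unname(ll))
  # invariance to locus and individual order (frequency criterion)
  g2 <- GenotypeMatrix(alleleMatrix(g, 1)[12:1, 3:1],
                       alleleMatrix(g, 2)[12:1, 3:1],
                       repeatUnits(g)[3:1], pop = populations(g)[12:1])
  as3 <- assignIndividuals(g2, criterion = "frequency",
                           exclusion_sims = 0, seed = 1)
  expect_equal(as3$scores[sampleIDs(g), colnames(as2$scores)], as2$scores)
  # bayesian and distance criteria run and assign everyone
  for (cr in c("bayesian", "nei_distance", "chord_distance")) {
    ax <- assignIndividuals(g, criterion = cr, exclusion_sims = 0, seed = 1)
    expect_true(all(!is.na(ax$assigned)))
  }
})
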