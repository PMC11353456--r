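test_that("island-model gene flow conversion matches closed forms", {
  expect_equal(round(islandNm(0.3771, "haploid"), 2), 0.83)
  expect_equal(round(islandNm(0.2504, "haploid"), 2), 1.50)
  expect_equal(round(islandNm(0.2509, "haploid"), 2), 1.49)
  expect_equal(islandNm(0.5, "haploid"), 0.5)
  expect_identical(islandNm(0, "haploid"), Inf)
  expect_equal(islandNm(1, "diploid"), 0)
  expect_error(islandNm(1.2), "0, 1")
  # strictly decreasing, and the inverse recovers F
  F <- seq(0.05, 0.95, by = 0.05)
  nm <- islandNm(F, "haploid")
  expect_true(all(diff(nm) < 0))
  expect_equal(1 / (1 + 2 * nm), F)
  nm4 <- islandNm(F, "diploid")
  expect_equal(1 / (1 + 4 * nm4), F)
})

test_that("Kimura 2P distances match the closed form", {
  s1 <- strrep("A", 100)
  # 10 transitions (A->G), 5 transversions (A->C)
  s2 <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  pm <- toyPopmap(c("X", "Y"), c("a", "b"))
  k <- kimura2pMatrix(HaplotypeAlignment(c(a = s1, b = s2)), pm)
  expect_equal(k$pairwise["a", "b"],
               -0.5 * log(1 - 2 * 0.10 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-10)
  # identical sequences: zero distance; net distance of a pop vs itself is 0
  aln <- toyAlignment()
  pm6 <- toyPopmap()
  k2 <- kimura2pMatrix(aln, pm6)
  expect_equal(k2$pairwise["a", "b"], 0)
  expect_equal(unname(diag(k2$net)), c(0, 0))
})

test_that("Hudson statistics equal a brute-force implementation", {
  aln <- toyAlignment()
  pop <- c("P1", "P1", "P1", "P2", "P2", "P2")
  d <- riverpopgen:::.pairwiseDiffs(aln)
  hap <- haplotypeIndex(aln)
  got <- riverpopgen:::.hudsonStats(d, hap, setNames(pop, letters[1:6]))
  # independent K_ST: population-size-weighted mean within-group pairwise
  # difference over the grand mean
  kwithin <- function(idx) mean(d[idx, idx][upper.tri(d[idx, idx])])
  KS <- 0.5 * kwithin(1:3) + 0.5 * kwithin(4:6)
  KT <- mean(d[upper.tri(d)])
  expect_equal(unname(got["K_ST"]), 1 - KS / KT)
  # independent F_ST: pooled within pairs vs between pairs
  win <- c(d[1, 2], d[1, 3], d[2, 3], d[4, 5], d[4, 6], d[5, 6])
  btw <- as.vector(d[1:3, 4:6])
  expect_equal(unname(got["F_ST"]), 1 - mean(win) / mean(btw))
  # independent Snn with equal tie weights
  x <- vapply(1:6, function(i) {
    di <- d[i, -i]
    nn <- which(di == min(di))
    mean(pop[-i][nn] == pop[i])
  }, 0)
  expect_equal(unname(got["S_nn"]), mean(x))
})

test_that("permutation p is exact on an enumerable two-population toy", {
  # two populations fixed for haplotypes 5 steps apart
  h1 <- strrep("A", 40)
  h2 <- paste0(strrep("T", 5), strrep("A", 35))
  aln <- HaplotypeAlignment(setNames(c(h1, h1, h1, h2, h2, h2),
                                     letters[1:6]))
  pm <- toyPopmap()
  res <- hudsonHeterogeneity(aln, pm, perms = 500, seed = 9)
  # K_ST at its maximum for this configuration: K_S = 0
  expect_equal(unname(res$stats["K_ST"]), 1)
  # exhaustive label enumeration: 20 assignments, 2 reach K_ST = 1
  pop <- c("P1", "P1", "P1", "P2", "P2", "P2")
  d <- riverpopgen:::.pairwiseDiffs(aln)
  hap <- haplotypeIndex(aln)
  combs <- combn(6, 3)
  exact <- apply(combs, 2, function(ii) {
    pp <- rep("P2", 6); pp[ii] <- "P1"
    riverpopgen:::.hudsonStats(d, hap, setNames(pp, letters[1:6]))["K_ST"]
  })
  expect_equal(mean(exact >= 1), 2 / 20)
  # the permutation p concentrates near the enumeration value
  expect_lt(res$p["K_ST"], 0.2)
  expect_gt(res$p["K_ST"], 1 / 501)
  # a random split of one panmictic population: indices near zero
  set.seed(10)
  alnN <- HaplotypeAlignment(setNames(rep(c(h1, h2), 5), paste0("n", 1:10)))
  pmN <- toyPopmap(rep(c("P1", "P2"), each = 5), paste0("n", 1:10))
  resN <- hudsonHeterogeneity(alnN, pmN, perms = 200, seed = 3)
  expect_gt(resN$p["K_ST"], 0.05)
})

test_that("haplotype contingency table gives the expected chi2 and df", {
  # identical haplotype distributions: chi-square 0
  aln <- HaplotypeAlignment(setNames(rep(c("AAAA", "TTTT"), 3:4),
                                     paste0("s", 1:7)))
  pm <- toyPopmap(c("P1", "P1", "P1", "P1", "P2", "P2", "P2"),
                  paste0("s", 1:7))
  # construct equal distributions explicitly
  aln2 <- HaplotypeAlignment(setNames(c("AAAA", "TTTT", "AAAA", "TTTT"),
                                      paste0("q", 1:4)))
  pm2 <- toyPopmap(c("P1", "P1", "P2", "P2"), paste0("q", 1:4))
  ct <- haplotypeContingency(aln2, pm2)
  expect_equal(ct$chi2, 0)
  expect_identical(ct$df, 1L)
  # df = (H-1)(P-1)
  expect_identical(ct$df, (2L - 1L) * (2L - 1L))
  # [[5,0],[0,5]] analog: two pops fixed for different haplotypes
  aln3 <- HaplotypeAlignment(setNames(c(rep("AAAA", 5), rep("TTTT", 5)),
                                      paste0("x", 1:10)))
  pm3 <- toyPopmap(rep(c("P1", "P2"), each = 5), paste0("x", 1:10))
  ct3 <- haplotypeContingency(aln3, pm3)
  expect_equal(ct3$p, 2 / choose(10, 5), tolerance = 1e-9)
})

test_that("pairwise exact tests agree with enumeration and are reproducible", {
  tab <- matrix(c(5L, 0L, 0L, 5L), 2, 2)
  enum <- riverpopgen:::.enumExactRx2(tab, "prob")
  expect_equal(enum, 2 / 252, tolerance = 1e-9)
  set.seed(1)
  mc <- riverpopgen:::.mcmcExactTest(tab, "prob", 2000, 20, 1000)
  expect_lt(abs(mc$p - enum), max(3 * mc$se, 0.01))
  # identical single-haplotype populations: p = 1
  aln <- HaplotypeAlignment(setNames(rep("ACGT", 4), paste0("s", 1:4)))
  pm <- toyPopmap(c("P1", "P1", "P2", "P2"), paste0("s", 1:4))
  pw <- pairwiseExactTests(aln, pm, seed = 5)
  expect_equal(pw$p["P1", "P2"], 1)
  # determinism: same seed, same result
  aln2 <- toyAlignment()
  pm2 <- toyPopmap()
  r1 <- pairwiseExactTests(aln2, pm2, mcmc = list(demem = 200, batches = 5,
                                                  iters = 100), seed = 11)
  r2 <- pairwiseExactTests(aln2, pm2, mcmc = list(demem = 200, batches = 5,
                                                  iters = 100), seed = 11)
  expect_identical(r1$p, r2$p)
})

test_that("AMOVA components match a direct sums-of-squares oracle", {
  # all identical: zero everywhere
  alnI <- HaplotypeAlignment(setNames(rep("ACGTACGT", 8), paste0("s", 1:8)))
  pmI <- toyPopmap(rep(c("P1", "P2", "P3", "P4"), each = 2), paste0("s", 1:8))
  grp <- setNames(c("G1", "G1", "G2", "G2"), c("P1", "P2", "P3", "P4"))
  amI <- amovaSeq(alnI, pmI, grp, perms = 20, seed = 1)
  expect_equal(unname(amI$components), c(0, 0, 0))
  # two groups fixed for distinct haplotypes: 100% among groups
  alnF <- HaplotypeAlignment(setNames(c(rep("AAAAAAAA", 4), rep("TTTTAAAA", 4)),
                                      paste0("s", 1:8)))
  amF <- amovaSeq(alnF, pmI, grp, perms = 50, seed = 2)
  expect_equal(unname(amF$percent["among_groups"]), 100)
  # 8-sequence toy vs direct evaluation of the nested decomposition
  set.seed(4)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), "")
  alnR <- HaplotypeAlignment(setNames(seqs, paste0("s", 1:8)))
  am <- amovaSeq(alnR, pmI, grp, perms = 50, seed = 3)
  d2 <- riverpopgen:::.pairwiseDiffs(alnR)
  pop <- rep(c("P1", "P2", "P3", "P4"), each = 2)
  gv <- grp[pop]
  ss <- function(idx) sum(d2[idx, idx][upper.tri(d2[idx, idx])])
  SST <- ss(1:8) / 8
  SSWP <- sum(vapply(unique(pop), function(p) ss(which(pop == p)) / 2, 0))
  SSWG <- sum(vapply(unique(gv), function(g) ss(which(gv == g)) / 4, 0))
  MS_wp <- SSWP / (8 - 4)
  MS_ap <- (SSWG - SSWP) / (4 - 2)
  MS_ag <- (SST - SSWG) / (2 - 1)
  # balanced design: n' = 2, n'' = 2, n''' = 4
  sc <- MS_wp; sb <- (MS_ap - sc) / 2; sa <- (MS_ag - sc - 2 * sb) / 4
  expect_equal(unname(am$components),
               c(sa, sb, sc), tolerance = 1e-12)
  expect_equal(sum(am$percent), 100, tolerance = 1e-9)
  # permutation p-values are never exactly zero
  expect_true(all(am$p > 0))
})
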