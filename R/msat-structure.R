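#' @include AllClasses.R AllGenerics.R
NULL

.genoPop <- function(geno, popmap) {
  if (is.null(popmap)) {
    pop <- populations(geno)
    if (!length(pop)) stop("no population information")
    pop[sampleIDs(geno)]
  } else .checkPopmap(geno, popmap)
}

# allele count table of one locus in a set of rows
.alleleCounts <- function(geno, locus, rows) {
  a <- c(geno@a1[rows, locus], geno@a2[rows, locus])
  a <- a[!is.na(a)]
  table(a)
}

#' Microsatellite diversity summaries
#'
#' Per-locus allele counts, mean number of alleles (MNA +/- sd across
#' loci), observed heterozygosity and unbiased expected heterozygosity
#' \code{He = 2n(1-sum p^2)/(2n-1)}, overall and per population. Missing
#' genotypes are excluded per locus; fully missing loci are flagged and
#' excluded from MNA.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param popmap Optional \linkS4class{PopulationAssignment} (defaults to
#'   the container's pop slot).
#' @return list of class \code{msat_diversity}: \code{per_locus}
#'   (data.frame locus, k, n, Ho, He), \code{MNA, MNA_sd, Ho, He},
#'   \code{per_pop} (data.frame pop, locus, k, n, Ho, He),
#'   \code{empty_loci}.
#' @export
msatDiversity <- function(geno, popmap = NULL) {
  pop <- .genoPop(geno, popmap)
  loci <- lociNames(geno)
  hoHe <- function(rows, locus) {
    a1 <- geno@a1[rows, locus]; a2 <- geno@a2[rows, locus]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n == 0) return(c(k = NA, n = 0, Ho = NA, He = NA))
    p <- .alleleCounts(geno, locus, rows)
    p <- p / sum(p)
    Ho <- mean(a1[ok] != a2[ok])
    He <- 2 * n * (1 - sum(p^2)) / (2 * n - 1)
    c(k = length(p), n = n, Ho = Ho, He = He)
  }
  per_locus <- as.data.frame(t(vapply(loci, function(l)
    hoHe(seq_len(nrow(geno@a1)), l), numeric(4))))
  per_locus <- cbind(locus = loci, per_locus)
  empty <- loci[per_locus$n == 0]
  ok <- per_locus$n > 0
  rows <- list()
  for (p in unique(pop)) for (l in loci) {
    v <- hoHe(which(pop == p), l)
    rows[[length(rows) + 1]] <- data.frame(pop = p, locus = l,
                                           k = v["k"], n = v["n"],
                                           Ho = v["Ho"], He = v["He"])
  }
  per_pop <- do.call(rbind, rows)
  rownames(per_pop) <- NULL
  structure(list(per_locus = per_locus,
                 MNA = mean(per_locus$k[ok]),
                 MNA_sd = stats::sd(per_locus$k[ok]),
                 Ho = mean(per_locus$Ho[ok], na.rm = TRUE),
                 He = mean(per_locus$He[ok], na.rm = TRUE),
                 per_pop = per_pop, empty_loci = empty),
            class = "msat_diversity")
}

#' @export
print.msat_diversity <- function(x, ...) {
  cat(sprintf("Microsatellite diversity: MNA = %.2f +/- %.2f, Ho = %.3f, He = %.3f\n",
              x$MNA, x$MNA_sd, x$Ho, x$He))
  print(x$per_locus, row.names = FALSE)
  invisible(x)
}

# ---- Hardy-Weinberg exact machinery --------------------------------

# log-probability of a genotype count matrix (upper triangular, k x k)
# under HWE conditioned on allele counts (Levene/Haldane)
.hweLogProb <- function(M) {
  n <- sum(M)
  a <- .alleleCountsFromGenos(M)
  h <- sum(M[upper.tri(M)])
  lgamma(n + 1) + sum(lgamma(a + 1)) + h * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(M[upper.tri(M, diag = TRUE)] + 1))
}

.alleleCountsFromGenos <- function(M) {
  k <- nrow(M)
  Mf <- M + t(M)
  diag(Mf) <- 2 * diag(M)
  rowSums(Mf)
}

# exact HWE test for a biallelic locus by enumeration over the
# heterozygote count (parity-constrained support)
.hweExact2 <- function(M) {
  a <- .alleleCountsFromGenos(M)
  n <- sum(M)
  hobs <- M[1, 2] + M[2, 1]
  hs <- seq(a[1] %% 2, min(a), by = 2)
  lp <- vapply(hs, function(h) {
    n11 <- (a[1] - h) / 2; n22 <- (a[2] - h) / 2
    lgamma(n + 1) + sum(lgamma(a + 1)) + h * log(2) -
      lgamma(2 * n + 1) - (lgamma(n11 + 1) + lgamma(n22 + 1) + lgamma(h + 1))
  }, 0)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  sum(p[lp <= lp[match(hobs, hs)] + 1e-9])
}

# Guo-Thompson style chain: uniform random re-pairing of gene copies.
# Proposal (pick 2 individuals, re-pair their 4 alleles) is symmetric on
# the space of matchings, so every move is accepted; the genotype table
# then follows the exact conditional null.
.hweMcmc <- function(M, demem = 10000, batches = 20, iters = 5000) {
  k <- nrow(M)
  gen1 <- integer(0); gen2 <- integer(0)
  for (i in seq_len(k)) for (j in i:k) {
    cnt <- M[i, j] + if (j > i) M[j, i] else 0L
    if (cnt > 0) { gen1 <- c(gen1, rep(i, cnt)); gen2 <- c(gen2, rep(j, cnt)) }
  }
  n <- length(gen1)
  obsLp <- .hweLogProb(M)
  tabLp <- function() {
    Mt <- matrix(0L, k, k)
    for (x in seq_len(n)) Mt[gen1[x], gen2[x]] <- Mt[gen1[x], gen2[x]] + 1L
    .hweLogProb(Mt)
  }
  curLp <- obsLp
  # incremental bookkeeping: h and sum lgamma(n_ij + 1)
  cnt <- new.env(hash = TRUE)
  key <- function(i, j) paste(min(i, j), max(i, j))
  for (x in seq_len(n)) {
    kk <- key(gen1[x], gen2[x])
    cnt[[kk]] <- (if (is.null(cnt[[kk]])) 0L else cnt[[kk]]) + 1L
  }
  h <- sum(gen1 != gen2)
  slg <- sum(vapply(ls(cnt), function(kk) lgamma(cnt[[kk]] + 1), 0))
  step <- function() {
    xy <- sample.int(n, 2L)
    x <- xy[1]; y <- xy[2]
    a <- gen1[x]; b <- gen2[x]; c <- gen1[y]; d <- gen2[y]
    # alternative pairing of the four gene copies
    if (stats::runif(1) < 0.5) { ng1 <- c(a, b); ng2 <- c(c, d) }
    else { ng1 <- c(a, b); ng2 <- c(d, c) }
    o1 <- c(min(a, b), min(c, d)); o2 <- c(max(a, b), max(c, d))
    p1 <- pmin(ng1, ng2); p2 <- pmax(ng1, ng2)
    if (identical(c(o1, o2), c(p1, p2))) return()
    dec <- c(key(a, b), key(c, d))
    inc <- c(key(p1[1], p2[1]), key(p1[2], p2[2]))
    for (kk in dec) {
      slg <<- slg - lgamma(cnt[[kk]] + 1)
      cnt[[kk]] <- cnt[[kk]] - 1L
      slg <<- slg + lgamma(cnt[[kk]] + 1)
    }
    for (kk in inc) {
      v <- if (is.null(cnt[[kk]])) 0L else cnt[[kk]]
      slg <<- slg - lgamma(v + 1)
      cnt[[kk]] <- v + 1L
      slg <<- slg + lgamma(v + 2)
    }
    h <<- h - (a != b) - (c != d) + (p1[1] != p2[1]) + (p1[2] != p2[2])
    gen1[x] <<- p1[1]; gen2[x] <<- p2[1]
    gen1[y] <<- p1[2]; gen2[y] <<- p2[2]
  }
  base <- obsLp - (h0 <- sum(gen1 != gen2)) * log(2) + slg  # constant part
  for (b in seq_len(demem)) step()
  bp <- numeric(batches)
  for (bt in seq_len(batches)) {
    hits <- 0L
    for (it in seq_len(iters)) {
      step()
      curLp <- base + h * log(2) - slg
      hits <- hits + (curLp <= obsLp + 1e-9)
    }
    bp[bt] <- hits / iters
  }
  list(p = mean(bp), se = stats::sd(bp) / sqrt(batches))
}

# genotype count matrix (k x k upper incl diag) of one locus-pop cell
.genoTable <- function(geno, locus, rows) {
  a1 <- geno@a1[rows, locus]; a2 <- geno@a2[rows, locus]
  ok <- !is.na(a1)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  k <- length(alleles)
  M <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (x in which(ok)) {
    i <- match(min(a1[x], a2[x]), alleles)
    j <- match(max(a1[x], a2[x]), alleles)
    M[i, j] <- M[i, j] + 1L
  }
  M
}

# Robertson-Hill f estimator from a genotype table
.robertsonHillF <- function(M) {
  n <- sum(M)
  if (n == 0) return(NA_real_)
  a <- .alleleCountsFromGenos(M)
  p <- a / sum(a)
  k <- length(p)
  if (k < 2) return(NA_real_)
  Pii <- diag(M) / n
  (sum(Pii / p) - 1) / (k - 1)
}

#' Hardy-Weinberg exact tests with Fisher combination
#'
#' Per locus and population: exact test of HWE conditioned on allele
#' counts (full enumeration for biallelic tables, otherwise a Markov chain
#' over random re-pairings of gene copies with the given
#' dememorisation/batch schedule), Robertson-Hill's f, and the
#' Weir-Cockerham F_IS per locus; Fisher's method combines p-values per
#' population (across loci) and per locus (across populations), with
#' df = 2 x number of combined tests.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param popmap Optional \linkS4class{PopulationAssignment}.
#' @param mcmc list(demem, batches, iters).
#' @param seed Integer seed.
#' @return list of class \code{hwe_result}: \code{tests} (data.frame pop,
#'   locus, n, p, se, f_RH), \code{fisher_by_pop}, \code{fisher_by_locus}
#'   (data.frames with chi2, df, p), \code{F_IS} (per locus, W&C across
#'   populations), \code{untestable} (monomorphic locus-pop cells).
#' @export
hweTests <- function(geno, popmap = NULL,
                     mcmc = list(demem = 10000, batches = 20, iters = 5000),
                     seed = 1) {
  pop <- .genoPop(geno, popmap)
  loci <- lociNames(geno)
  set.seed(seed)
  rows <- list(); skip <- list()
  for (p in unique(pop)) for (l in loci) {
    M <- .genoTable(geno, l, which(pop == p))
    if (nrow(M) < 2 || sum(M) < 2) {
      skip[[length(skip) + 1]] <- data.frame(pop = p, locus = l)
      next
    }
    r <- if (nrow(M) == 2) list(p = .hweExact2(M), se = 0)
         else .hweMcmc(M, mcmc$demem, mcmc$batches, mcmc$iters)
    rows[[length(rows) + 1]] <-
      data.frame(pop = p, locus = l, n = sum(M), p = r$p, se = r$se,
                 f_RH = .robertsonHillF(M))
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pop = character(), locus = character(), n = integer(),
               p = numeric(), se = numeric(), f_RH = numeric())
  fisher <- function(ps) {
    ps <- ps[!is.na(ps)]
    ps <- pmax(ps, 1e-300)
    chi2 <- -2 * sum(log(ps))
    df <- 2L * length(ps)
    data.frame(chi2 = chi2, df = df,
               p = stats::pchisq(chi2, df, lower.tail = FALSE))
  }
  byPop <- do.call(rbind, lapply(split(tests$p, tests$pop), fisher))
  byPop <- cbind(pop = rownames(byPop), byPop); rownames(byPop) <- NULL
  byLoc <- do.call(rbind, lapply(split(tests$p, tests$locus), fisher))
  byLoc <- cbind(locus = rownames(byLoc), byLoc); rownames(byLoc) <- NULL
  wc <- .wcFstats(geno, pop)
  structure(list(tests = tests, fisher_by_pop = byPop,
                 fisher_by_locus = byLoc,
                 F_IS = wc$per_locus$F_IS,
                 untestable = if (length(skip)) do.call(rbind, skip) else NULL),
            class = "hwe_result")
}

# ---- Weir & Cockerham variance components (Michalakis-Excoffier
#      equivalent) -----------------------------------------------------

# per-locus a, b, c sums over alleles; returns per-locus and multilocus F
.wcFstats <- function(geno, pop) {
  loci <- lociNames(geno)
  pops <- unique(pop)
  r <- length(pops)
  perloc <- data.frame(locus = loci, a = NA_real_, b = NA_real_,
                       c = NA_real_, F_IS = NA_real_, F_ST = NA_real_,
                       F_IT = NA_real_)
  for (li in seq_along(loci)) {
    l <- loci[li]
    a1 <- geno@a1[, l]; a2 <- geno@a2[, l]
    ok <- !is.na(a1)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2) next
    ni <- vapply(pops, function(p) sum(ok & pop == p), 0)
    use <- ni > 0
    if (sum(use) < 2) next
    ni <- ni[use]; popsU <- pops[use]
    rU <- length(popsU)
    nbar <- mean(ni)
    nc <- (rU * nbar - sum(ni^2) / (rU * nbar)) / (rU - 1)
    A <- B <- C <- 0
    for (al in alleles) {
      pi <- vapply(popsU, function(p) {
        ii <- ok & pop == p
        (sum(a1[ii] == al) + sum(a2[ii] == al)) / (2 * sum(ii))
      }, 0)
      hi <- vapply(popsU, function(p) {
        ii <- ok & pop == p
        mean((a1[ii] == al) != (a2[ii] == al))
      }, 0)
      pbar <- sum(ni * pi) / (rU * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((rU - 1) * nbar)
      hbar <- sum(ni * hi) / (rU * nbar)
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (rU - 1) / rU * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (rU - 1) / rU * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
    perloc$a[li] <- A; perloc$b[li] <- B; perloc$c[li] <- C
    tot <- A + B + C
    perloc$F_ST[li] <- if (tot != 0) A / tot else NA
    perloc$F_IS[li] <- if ((B + C) != 0) 1 - C / (B + C) else NA
    perloc$F_IT[li] <- if (tot != 0) 1 - C / tot else NA
  }
  okl <- !is.na(perloc$a)
  SA <- sum(perloc$a[okl]); SB <- sum(perloc$b[okl]); SC <- sum(perloc$c[okl])
  multi <- c(F_IS = if ((SB + SC) != 0) 1 - SC / (SB + SC) else NA,
             F_ST = if ((SA + SB + SC) != 0) SA / (SA + SB + SC) else NA,
             F_IT = if ((SA + SB + SC) != 0) 1 - SC / (SA + SB + SC) else NA)
  list(per_locus = perloc, multilocus = multi)
}

#' Wright F-statistics with genotype-randomisation significance
#'
#' Weir-Cockerham variance-component estimators of F_IS, F_ST and F_IT per
#' locus and multilocus (components summed over loci; negative component
#' estimates are retained, not truncated), a pairwise F_ST matrix with
#' diploid island-model Nm, and significance of overall differentiation by
#' randomising multilocus genotypes among populations with the
#' log-likelihood G statistic summed over loci.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param popmap Optional \linkS4class{PopulationAssignment}.
#' @param randomizations Genotype randomisations for the G test.
#' @param seed Integer seed.
#' @return list of class \code{fstats_result}: \code{per_locus},
#'   \code{multilocus}, \code{pairwise_FST}, \code{pairwise_Nm},
#'   \code{G}, \code{p_G}, \code{low_confidence_pairs} (pairs involving a
#'   population of size 1).
#' @export
fStats <- function(geno, popmap = NULL, randomizations = 10000, seed = 1) {
  pop <- .genoPop(geno, popmap)
  if (length(unique(pop)) < 2) stop("need >= 2 populations")
  wc <- .wcFstats(geno, pop)
  loci <- lociNames(geno)
  gOf <- function(pp) {
    g <- 0
    for (l in loci) {
      a1 <- geno@a1[, l]; a2 <- geno@a2[, l]
      ok <- !is.na(a1)
      gt <- paste(a1[ok], a2[ok])
      tab <- table(gt, pp[ok])
      if (nrow(tab) > 1 && ncol(tab) > 1) g <- g + .gStat(tab)
    }
    g
  }
  obsG <- gOf(pop)
  set.seed(seed)
  nullG <- vapply(seq_len(randomizations), function(i) gOf(sample(pop)), 0)
  pops <- unique(pop)
  P <- length(pops)
  pF <- pN <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  lowconf <- character(0)
  sizes <- table(pop)
  for (a in seq_len(P - 1)) for (b in (a + 1):P) {
    sel <- pop %in% pops[c(a, b)]
    sub <- new("GenotypeMatrix", a1 = geno@a1[sel, , drop = FALSE],
               a2 = geno@a2[sel, , drop = FALSE],
               repeatUnit = geno@repeatUnit, pop = character(0))
    f <- .wcFstats(sub, pop[sel])$multilocus["F_ST"]
    pF[a, b] <- pF[b, a] <- f
    pN[a, b] <- pN[b, a] <- if (is.na(f)) NA
      else if (f <= 0) Inf else islandNm(min(f, 1), "diploid")
    if (min(sizes[pops[c(a, b)]]) < 2)
      lowconf <- c(lowconf, paste(pops[a], pops[b], sep = ":"))
  }
  structure(list(per_locus = wc$per_locus, multilocus = wc$multilocus,
                 pairwise_FST = pF, pairwise_Nm = pN,
                 G = obsG, p_G = .permP(nullG, obsG),
                 low_confidence_pairs = lowconf),
            class = "fstats_result")
}

#' Nei's (1978) unbiased genetic distance between populations
#'
#' \code{D = -ln(Jxy / sqrt(Jx Jy))} with the small-sample correction
#' \code{Jx = (2n sum x^2 - 1)/(2n - 1)} per locus, identity coefficients
#' averaged over shared scored loci. Pairs sharing no alleles at any locus
#' are infinite and flagged.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param popmap Optional \linkS4class{PopulationAssignment}.
#' @return list: \code{D} (pop x pop matrix), \code{infinite_pairs},
#'   \code{missing_pairs} (no shared scored loci).
#' @export
neiDistance <- function(geno, popmap = NULL) {
  pop <- .genoPop(geno, popmap)
  loci <- lociNames(geno)
  pops <- unique(pop)
  P <- length(pops)
  D <- matrix(0, P, P, dimnames = list(pops, pops))
  infinitePairs <- missingPairs <- character(0)
  freqs <- lapply(pops, function(p) lapply(loci, function(l) {
    tb <- .alleleCounts(geno, l, which(pop == p))
    if (!sum(tb)) return(NULL)
    list(p = tb / sum(tb), n = sum(tb) / 2)
  }))
  for (a in seq_len(P - 1)) for (b in (a + 1):P) {
    jx <- jy <- jxy <- numeric(0)
    for (li in seq_along(loci)) {
      fa <- freqs[[a]][[li]]; fb <- freqs[[b]][[li]]
      if (is.null(fa) || is.null(fb)) next
      als <- union(names(fa$p), names(fb$p))
      xa <- stats::setNames(rep(0, length(als)), als); xa[names(fa$p)] <- fa$p
      xb <- stats::setNames(rep(0, length(als)), als); xb[names(fb$p)] <- fb$p
      jx <- c(jx, (2 * fa$n * sum(xa^2) - 1) / (2 * fa$n - 1))
      jy <- c(jy, (2 * fb$n * sum(xb^2) - 1) / (2 * fb$n - 1))
      jxy <- c(jxy, sum(xa * xb))
    }
    key <- paste(pops[a], pops[b], sep = ":")
    if (!length(jx)) {
      D[a, b] <- D[b, a] <- NA
      missingPairs <- c(missingPairs, key)
    } else if (mean(jxy) <= 0) {
      D[a, b] <- D[b, a] <- Inf
      infinitePairs <- c(infinitePairs, key)
    } else {
      D[a, b] <- D[b, a] <-
        max(0, -log(mean(jxy) / sqrt(mean(jx) * mean(jy))))
    }
  }
  list(D = D, infinite_pairs = infinitePairs, missing_pairs = missingPairs)
}

#' Exact genic / genotypic differentiation tests
#'
#' Per-locus exact G tests on allele (genic) or genotype (genotypic)
#' contingency tables across populations via the Metropolis Markov chain
#' over tables with fixed margins (enumeration for small biallelic
#' tables), combined across loci by Fisher's method.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param popmap Optional \linkS4class{PopulationAssignment}.
#' @param mode "genic" or "genotypic".
#' @param mcmc list(demem, batches, iters).
#' @param max_enum Enumeration bound on the table space.
#' @param seed Integer seed.
#' @return list of class \code{exact_diff_result}: \code{per_locus}
#'   (data.frame locus, p, se), \code{global_chi2, global_df, global_p}.
#' @export
exactDifferentiation <- function(geno, popmap = NULL,
                                 mode = c("genic", "genotypic"),
                                 mcmc = list(demem = 10000, batches = 20,
                                             iters = 5000),
                                 max_enum = 1e5, seed = 1) {
  mode <- match.arg(mode)
  pop <- .genoPop(geno, popmap)
  if (length(unique(pop)) < 2) stop("need >= 2 populations")
  if (any(table(pop) == 0)) stop("empty population")
  loci <- lociNames(geno)
  set.seed(seed)
  rows <- list()
  for (l in loci) {
    a1 <- geno@a1[, l]; a2 <- geno@a2[, l]
    ok <- !is.na(a1)
    if (mode == "genic") {
      tab <- table(c(a1[ok], a2[ok]), c(pop[ok], pop[ok]))
    } else {
      tab <- table(paste(a1[ok], a2[ok]), pop[ok])
    }
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      rows[[length(rows) + 1]] <- data.frame(locus = l, p = NA, se = NA)
      next
    }
    if (ncol(tab) == 2 && prod(rowSums(tab) + 1) <= max_enum) {
      rows[[length(rows) + 1]] <-
        data.frame(locus = l, p = .enumExactRx2(tab, "G"), se = 0)
    } else {
      r <- .mcmcExactTest(tab, "G", mcmc$demem, mcmc$batches, mcmc$iters)
      rows[[length(rows) + 1]] <- data.frame(locus = l, p = r$p, se = r$se)
    }
  }
  per_locus <- do.call(rbind, rows)
  ps <- pmax(per_locus$p[!is.na(per_locus$p)], 1e-300)
  chi2 <- -2 * sum(log(ps)); df <- 2L * length(ps)
  structure(list(per_locus = per_locus, global_chi2 = chi2,
                 global_df = df,
                 global_p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "exact_diff_result")
}

#' Private-allele estimate of gene flow
#'
#' Mean frequency of private alleles (alleles observed in exactly one
#' population), converted to Nm through the published log-linear
#' regressions for reference sample sizes 10, 25 and 50 (nearest size
#' used), with the usual sample-size correction \code{Nm * n_ref / n_bar}.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param popmap Optional \linkS4class{PopulationAssignment}.
#' @return list: \code{p1} (mean private-allele frequency), \code{Nm},
#'   \code{n_private}, \code{applicable}.
#' @export
privateAlleleNm <- function(geno, popmap = NULL) {
  pop <- .genoPop(geno, popmap)
  pops <- unique(pop)
  if (length(pops) < 2) stop("need >= 2 populations")
  loci <- lociNames(geno)
  pfreqs <- numeric(0)
  nUsed <- numeric(0)
  for (l in loci) {
    byPop <- lapply(pops, function(p) .alleleCounts(geno, l, which(pop == p)))
    names(byPop) <- pops
    allAl <- unique(unlist(lapply(byPop, names)))
    for (al in allAl) {
      holders <- pops[vapply(byPop, function(tb) al %in% names(tb), TRUE)]
      if (length(holders) == 1) {
        tb <- byPop[[holders]]
        pfreqs <- c(pfreqs, tb[[al]] / sum(tb))
        nUsed <- c(nUsed, sum(tb) / 2)
      }
    }
  }
  if (!length(pfreqs))
    return(list(p1 = NA, Nm = NA, n_private = 0L, applicable = FALSE))
  p1 <- mean(pfreqs)
  # Barton & Slatkin (1986) regression ln p(1) = a + b ln(Nm)
  ref <- data.frame(n = c(10, 25, 50),
                    a = c(-2.44, -2.26, -2.14),
                    b = c(-0.505, -0.576, -0.612))
  nbar <- mean(table(pop))
  i <- which.min(abs(ref$n - nbar))
  Nm <- exp((log(p1) - ref$a[i]) / ref$b[i]) * ref$n[i] / nbar
  list(p1 = p1, Nm = Nm, n_private = length(pfreqs), applicable = TRUE)
}

# ---- assignment and first-generation-migrant detection --------------

# per-pop allele frequency lists for one locus, with optional
# leave-one-out removal of a focal individual
.lociFreqs <- function(geno, pop, exclude = NULL) {
  loci <- lociNames(geno)
  pops <- unique(pop)
  out <- list()
  for (p in pops) {
    rows <- which(pop == p)
    if (!is.null(exclude)) rows <- setdiff(rows, exclude)
    out[[p]] <- lapply(loci, function(l) {
      tb <- .alleleCounts(geno, l, rows)
      if (!sum(tb)) return(NULL)
      list(counts = tb, n2 = sum(tb))
    })
    names(out[[p]]) <- loci
  }
  out
}

# log-likelihood of one individual's multilocus genotype given per-locus
# allele frequencies under the chosen criterion
.genoLogLik <- function(g1, g2, freqs, criterion, missing_freq = 0.01) {
  ll <- 0
  for (l in names(freqs)) {
    a <- g1[l]; b <- g2[l]
    if (is.na(a)) next
    f <- freqs[[l]]
    if (is.null(f)) { ll <- ll + 2 * log(missing_freq); next }
    k <- length(f$counts)
    getp <- function(al) {
      idx <- match(as.character(al), names(f$counts))
      if (criterion == "bayesian") {
        x <- if (is.na(idx)) 0 else f$counts[[idx]]
        (x + 1 / max(k, 2)) / (f$n2 + 1)
      } else {
        if (is.na(idx) || f$counts[[idx]] == 0) missing_freq
        else f$counts[[idx]] / f$n2
      }
    }
    pa <- getp(a); pb <- getp(b)
    ll <- ll + if (a == b) log(pa^2) else log(2 * pa * pb)
  }
  ll
}

# genetic distance between an individual (treated as a population of one)
# and a population frequency set
.genoDistance <- function(g1, g2, freqs, criterion) {
  dsum <- 0; nl <- 0
  for (l in names(freqs)) {
    a <- g1[l]; b <- g2[l]
    if (is.na(a)) next
    f <- freqs[[l]]
    if (is.null(f)) next
    als <- union(names(f$counts), as.character(c(a, b)))
    px <- stats::setNames(rep(0, length(als)), als)
    px[as.character(a)] <- px[as.character(a)] + 0.5
    px[as.character(b)] <- px[as.character(b)] + 0.5
    py <- stats::setNames(rep(0, length(als)), als)
    py[names(f$counts)] <- f$counts / f$n2
    if (criterion == "nei_distance") {
      num <- sum(px * py)
      den <- sqrt(sum(px^2) * sum(py^2))
      dsum <- dsum + if (num > 0) -log(num / den) else 25
    } else {                      # chord distance
      dsum <- dsum + sqrt(2 * (1 - sum(sqrt(px * py))))
    }
    nl <- nl + 1
  }
  if (nl == 0) NA else dsum / nl
}

#' Assignment and first-generation-migrant tests
#'
#' Leave-one-out assignment of individuals to candidate populations under
#' a frequency, Bayesian (posterior-predictive frequencies), or genetic
#' distance criterion; Monte-Carlo exclusion probabilities (genotypes
#' simulated from each candidate population's leave-one-out frequencies);
#' and detection of first-generation migrants from the ratio
#' \code{L = L_home / L_max}, flagged when the observed ratio falls below
#' the alpha quantile of its simulated resident null.
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param popmap Optional \linkS4class{PopulationAssignment}.
#' @param criterion One of "frequency", "bayesian", "nei_distance",
#'   "chord_distance". The migrant test requires a likelihood criterion.
#' @param exclusion_sims Simulated genotypes per candidate population.
#' @param alpha Significance level for the migrant flag.
#' @param missing_freq Substitute frequency for unobserved alleles under
#'   the frequency criterion.
#' @param seed Integer seed.
#' @return list of class \code{assignment_result}: \code{scores}
#'   (individuals x populations log-likelihood or -distance),
#'   \code{assigned}, \code{L} (L_home/L_max), \code{p_L}, \code{migrant}
#'   (logical), \code{exclusion_p} (individuals x populations),
#'   \code{unassigned} (all-missing individuals).
#' @export
assignIndividuals <- function(geno, popmap = NULL,
                              criterion = c("frequency", "bayesian",
                                            "nei_distance", "chord_distance"),
                              exclusion_sims = 10000, alpha = 0.01,
                              missing_freq = 0.01, seed = 1) {
  criterion <- match.arg(criterion)
  pop <- .genoPop(geno, popmap)
  pops <- unique(pop)
  ids <- sampleIDs(geno)
  n <- length(ids)
  loci <- lociNames(geno)
  likBased <- criterion %in% c("frequency", "bayesian")
  set.seed(seed)
  scores <- matrix(NA_real_, n, length(pops), dimnames = list(ids, pops))
  exclP <- matrix(NA_real_, n, length(pops), dimnames = list(ids, pops))
  L <- pL <- rep(NA_real_, n)
  migrant <- rep(FALSE, n)
  unassigned <- character(0)
  baseFreqs <- .lociFreqs(geno, pop)
  # pre-simulated resident null of L per home population
  for (i in seq_len(n)) {
    g1 <- geno@a1[i, ]; g2 <- geno@a2[i, ]
    if (all(is.na(g1))) { unassigned <- c(unassigned, ids[i]); next }
    home <- pop[i]
    for (p in pops) {
      fr <- if (p == home) .lociFreqs(geno, pop, exclude = i)[[p]]
            else baseFreqs[[p]]
      scores[i, p] <- if (likBased)
        .genoLogLik(g1, g2, fr, criterion, missing_freq)
      else -.genoDistance(g1, g2, fr, criterion)
    }
    if (likBased) L[i] <- exp(scores[i, home] - max(scores[i, ]))
  }
  assigned <- pops[apply(scores, 1, function(r)
    if (all(is.na(r))) NA else which.max(r))]
  names(assigned) <- ids
  if (likBased && exclusion_sims > 0) {
    simGeno <- function(fr) {
      s1 <- s2 <- stats::setNames(rep(NA_integer_, length(loci)), loci)
      for (l in loci) {
        f <- fr[[l]]
        if (is.null(f)) next
        al <- as.integer(names(f$counts))
        pr <- as.numeric(f$counts)
        pick <- sample(length(al), 2, replace = TRUE, prob = pr)
        s1[l] <- al[pick[1]]; s2[l] <- al[pick[2]]
      }
      list(g1 = s1, g2 = s2)
    }
    for (p in pops) {
      fr <- baseFreqs[[p]]
      simLL <- matrix(NA_real_, exclusion_sims, length(pops),
                      dimnames = list(NULL, pops))
      for (s in seq_len(exclusion_sims)) {
        g <- simGeno(fr)
        for (q in pops)
          simLL[s, q] <- .genoLogLik(g$g1, g$g2, baseFreqs[[q]],
                                     criterion, missing_freq)
      }
      # exclusion: where does each observed individual fall in the
      # simulated likelihood distribution of residents of p?
      for (i in seq_len(n)) {
        if (is.na(scores[i, p])) next
        exclP[i, p] <- (sum(simLL[, p] <= scores[i, p]) + 1) /
          (exclusion_sims + 1)
      }
      # migrant null of L for residents of p
      simL <- exp(simLL[, p] - apply(simLL, 1, max))
      for (i in which(pop == p)) {
        if (is.na(L[i])) next
        pL[i] <- (sum(simL <= L[i]) + 1) / (exclusion_sims + 1)
        migrant[i] <- !is.na(pL[i]) && pL[i] < alpha
      }
    }
  }
  structure(list(scores = scores, assigned = assigned, L = L, p_L = pL,
                 migrant = migrant, exclusion_p = exclP,
                 criterion = criterion, alpha = alpha,
                 unassigned = unassigned),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("Assignment (", x$criterion, " criterion)\n", sep = "")
  ok <- !is.na(x$assigned)
  cat(sprintf("  %d/%d assigned; %d flagged as first-generation migrants (alpha = %g)\n",
              sum(ok), length(ok), sum(x$migrant), x$alpha))
  invisible(x)
}
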