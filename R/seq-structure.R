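#' @include AllClasses.R AllGenerics.R
NULL

#' Infinite-island gene-flow conversion
#'
#' Converts a fixation index into the equilibrium number of migrants per
#' generation under the infinite island model: \code{Nm = (1-F)/(2F)} for
#' haploid (organelle) markers and \code{(1-F)/(4F)} for diploid nuclear
#' markers.
#'
#' @param F Fixation index in [0, 1].
#' @param ploidy_mode "haploid" or "diploid".
#' @return Nm (Inf when F = 0).
#' @export
islandNm <- function(F, ploidy_mode = c("haploid", "diploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (any(F < 0 | F > 1)) stop("F must lie in [0, 1]")
  div <- if (ploidy_mode == "haploid") 2 else 4
  ifelse(F == 0, Inf, (1 - F) / (div * F))
}

#' Kimura two-parameter distances within and between populations
#'
#' Per-pair K2P distances (pairwise deletion), population mean within- and
#' between-distances, and net between distances
#' \code{d_net = d_XY - (d_X + d_Y)/2}. Saturated pairs (log argument
#' non-positive) are returned as NA and flagged.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @return list of class \code{k2p_result}: \code{pairwise} (full matrix),
#'   \code{within} (per pop), \code{between}, \code{net} (pop x pop
#'   matrices), \code{saturated} (count of flagged pairs).
#' @export
kimura2pMatrix <- function(aln, popmap) {
  pop <- .checkPopmap(aln, popmap)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(as.character(aln@seqs)), ""),
                               identity))
  d <- suppressWarnings(
    as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE)))
  dimnames(d) <- list(sampleIDs(aln), sampleIDs(aln))
  saturated <- sum(!is.finite(d[upper.tri(d)]))
  d[!is.finite(d)] <- NA
  pops <- unique(pop)
  P <- length(pops)
  within <- stats::setNames(numeric(P), pops)
  between <- net <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (a in seq_len(P)) {
    ia <- which(pop == pops[a])
    within[a] <- if (length(ia) > 1)
      mean(d[ia, ia][upper.tri(d[ia, ia])], na.rm = TRUE) else NA
    for (b in seq_len(P)) {
      if (a == b) next
      ib <- which(pop == pops[b])
      between[a, b] <- mean(d[ia, ib], na.rm = TRUE)
    }
  }
  for (a in seq_len(P)) for (b in seq_len(P)) {
    if (a == b) { net[a, b] <- 0; next }
    net[a, b] <- between[a, b] - (within[a] + within[b]) / 2
  }
  diag(between) <- within
  structure(list(pairwise = d, within = within, between = between,
                 net = net, saturated = saturated),
            class = "k2p_result")
}

# ---- Hudson-family statistics on a fixed difference matrix ----------

# unbiased haploid gene diversity from counts
.gdiv <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# all Hudson/fixation statistics given the difference matrix, haplotype
# index and population labels; the permutation test re-calls this with
# shuffled labels
.hudsonStats <- function(d, hap, pop) {
  n <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ut <- upper.tri(d)
  dstar <- log(1 + d)
  sizes <- as.integer(table(factor(pop, levels = pops)))
  w <- sizes / n
  withinMask <- outer(pop, pop, "==") & ut
  # K_ST and K_ST* (population-size weights; log(1+d) for the star)
  Kj <- Kjs <- numeric(P)
  for (j in seq_len(P)) {
    ii <- pop == pops[j]
    sub <- d[ii, ii, drop = FALSE]; subs <- dstar[ii, ii, drop = FALSE]
    m <- upper.tri(sub)
    Kj[j] <- if (sizes[j] > 1) mean(sub[m]) else NA
    Kjs[j] <- if (sizes[j] > 1) mean(subs[m]) else NA
  }
  ok <- !is.na(Kj)
  KS <- sum((w[ok] / sum(w[ok])) * Kj[ok])
  KT <- mean(d[ut])
  KSs <- sum((w[ok] / sum(w[ok])) * Kjs[ok])
  KTs <- mean(dstar[ut])
  K_ST <- if (KT > 0) 1 - KS / KT else 0
  K_ST_star <- if (KTs > 0) 1 - KSs / KTs else 0
  # H_ST on haplotype heterozygosities (same weights)
  Hj <- vapply(pops, function(p)
    .gdiv(table(hap[pop == p])), 0)
  HT <- .gdiv(table(hap))
  okH <- !is.na(Hj)
  HS <- sum((w[okH] / sum(w[okH])) * Hj[okH])
  H_ST <- if (isTRUE(HT > 0)) 1 - HS / HT else 0
  # Z and Z* from ranks of pairwise distances (ties share average rank)
  rk <- d; rk[ut] <- rank(d[ut]); rk[lower.tri(rk)] <- t(rk)[lower.tri(rk)]
  Zj <- Zjs <- numeric(P)
  for (j in seq_len(P)) {
    ii <- pop == pops[j]
    if (sizes[j] < 2) { Zj[j] <- Zjs[j] <- NA; next }
    rr <- rk[ii, ii][upper.tri(rk[ii, ii])]
    Zj[j] <- mean(rr)
    Zjs[j] <- mean(log(rr))
  }
  okZ <- !is.na(Zj)
  Z_S <- sum((w[okZ] / sum(w[okZ])) * Zj[okZ])
  Z_S_star <- sum((w[okZ] / sum(w[okZ])) * Zjs[okZ])
  # Snn: nearest neighbours, ties share weight equally
  x <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    nn <- which(di == min(di))
    samepop <- pop[-i][nn] == pop[i]
    x[i] <- mean(samepop)
  }
  S_nn <- mean(x)
  # gamma_ST from haplotype frequencies (Nei & Chesser-style corrections)
  freq <- vapply(pops, function(p) {
    f <- tabulate(hap[pop == p], nbins = max(hap))
    f / sum(f)
  }, numeric(max(hap)))
  ntilde <- P / sum(1 / sizes)
  hS0 <- 1 - mean(colSums(freq^2))
  hS <- ntilde / (ntilde - 1) * hS0
  pbar <- rowMeans(freq)
  hT <- 1 - sum(pbar^2) + hS / (ntilde * P)
  gamma_ST <- if (hT > 0) 1 - hS / hT else 0
  # N_ST: same structure on mean pairwise sequence differences
  piMat <- matrix(NA_real_, P, P)
  for (a in seq_len(P)) for (b in a:P) {
    ia <- which(pop == pops[a]); ib <- which(pop == pops[b])
    piMat[a, b] <- piMat[b, a] <- if (a == b) {
      if (sizes[a] > 1) mean(d[ia, ia][upper.tri(d[ia, ia])]) else NA
    } else mean(d[ia, ib])
  }
  piS <- mean(diag(piMat), na.rm = TRUE)
  piT <- mean(piMat, na.rm = TRUE)
  N_ST <- if (piT > 0) (piT - piS) / piT else 0
  # F_ST (Hudson-Slatkin-Maddison): 1 - mean within / mean between, pooled
  Hw <- mean(d[withinMask])
  Hb <- mean(d[!outer(pop, pop, "==") & ut])
  F_ST <- if (isTRUE(Hb > 0)) 1 - Hw / Hb else 0
  c(H_ST = H_ST, K_ST = K_ST, K_ST_star = K_ST_star,
    Z_S = Z_S, Z_S_star = Z_S_star, S_nn = S_nn,
    gamma_ST = gamma_ST, N_ST = N_ST, F_ST = F_ST)
}

#' Hudson-family sequence differentiation with permutation nulls
#'
#' Computes H_ST, K_ST, K_ST*, Z_S, Z_S*, S_nn (Hudson statistics),
#' gamma_ST, N_ST and F_ST on the pairwise-difference matrix, with
#' significance from permutations of population labels. p-values follow
#' the (exceedances+1)/(permutations+1) convention; Z_S and Z_S* are
#' tested in the lower tail (small mean within-population rank indicates
#' structure), all other statistics in the upper tail. Nm is attached for
#' the fixation-type indices using the haploid island model.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param popmap A \linkS4class{PopulationAssignment} (>= 2 populations).
#' @param perms Number of label permutations.
#' @param seed Integer seed.
#' @return list of class \code{hudson_result}: \code{stats} (named vector),
#'   \code{p} (named vector), \code{Nm} (for gamma_ST, N_ST, F_ST),
#'   \code{small_pops} (populations of size 1 excluded from within-pop
#'   terms).
#' @export
hudsonHeterogeneity <- function(aln, popmap, perms = 10000, seed = 1) {
  pop <- .checkPopmap(aln, popmap)
  if (length(unique(pop)) < 2) stop("need >= 2 populations")
  d <- .pairwiseDiffs(aln)
  hap <- haplotypeIndex(aln)
  obs <- .hudsonStats(d, hap, pop)
  lowTail <- c("Z_S", "Z_S_star")
  set.seed(seed)
  exceed <- stats::setNames(numeric(length(obs)), names(obs))
  for (b in seq_len(perms)) {
    sim <- .hudsonStats(d, hap, sample(pop))
    for (nm in names(obs)) {
      if (nm %in% lowTail) exceed[nm] <- exceed[nm] + (sim[nm] <= obs[nm])
      else exceed[nm] <- exceed[nm] + (sim[nm] >= obs[nm])
    }
  }
  p <- (exceed + 1) / (perms + 1)
  Nm <- vapply(c("gamma_ST", "N_ST", "F_ST"), function(nm)
    islandNm(max(min(obs[nm], 1), 0), "haploid"), 0)
  sizes <- table(pop)
  structure(list(stats = obs, p = p, Nm = Nm,
                 small_pops = names(sizes)[sizes < 2]),
            class = "hudson_result")
}

#' @export
print.hudson_result <- function(x, ...) {
  cat("Hudson-family differentiation\n")
  for (nm in names(x$stats))
    cat(sprintf("  %-10s %8.4f   p = %.5f%s\n", nm, x$stats[nm], x$p[nm],
                if (nm %in% names(x$Nm))
                  sprintf("   Nm = %.2f", x$Nm[nm]) else ""))
  invisible(x)
}

#' Haplotype-by-population contingency test
#'
#' Pearson chi-square on the haplotype x population count table with
#' df = (H-1)(P-1); when expected counts are small the p-value is replaced
#' by an exact (2x2, full enumeration over fixed margins) or Monte-Carlo
#' estimate.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @param B Monte-Carlo replicates for sparse tables.
#' @param seed Integer seed.
#' @return list: \code{chi2, df, p, method, table}.
#' @export
haplotypeContingency <- function(aln, popmap, B = 10000, seed = 1) {
  pop <- .checkPopmap(aln, popmap)
  tab <- table(haplotypeIndex(aln), pop)
  H <- nrow(tab); P <- ncol(tab)
  if (H < 2 || P < 2)
    return(list(chi2 = 0, df = 0L, p = NA_real_,
                method = "inapplicable", table = tab))
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chi2 <- unname(cs$statistic)
  df <- (H - 1L) * (P - 1L)
  if (all(cs$expected >= 5)) {
    list(chi2 = chi2, df = df, p = unname(cs$p.value),
         method = "asymptotic", table = tab)
  } else if (H == 2 && P == 2) {
    list(chi2 = chi2, df = df,
         p = stats::fisher.test(tab)$p.value,
         method = "exact", table = tab)
  } else {
    set.seed(seed)
    cs2 <- suppressWarnings(
      stats::chisq.test(tab, simulate.p.value = TRUE, B = B))
    list(chi2 = chi2, df = df, p = unname(cs2$p.value),
         method = "monte-carlo", table = tab)
  }
}

# ---- exact probability tests on R x C count tables ------------------

# log-probability of a table under the fixed-margins null
.logTabProb <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# G (log-likelihood ratio) statistic of a table
.gStat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  i <- tab > 0
  2 * sum(tab[i] * log(tab[i] / e[i]))
}

# enumerate all R x 2 tables with the observed margins (recursion over
# rows); returns exact p for the chosen statistic
.enumExactRx2 <- function(tab, stat = c("prob", "G")) {
  stat <- match.arg(stat)
  r <- rowSums(tab); c1 <- colSums(tab)[1]
  R <- length(r)
  obsLp <- .logTabProb(tab)
  obsG <- .gStat(tab)
  tol <- 1e-9
  total <- 0; hit <- 0
  rec <- function(i, left, cells) {
    if (i == R) {
      if (left < 0 || left > r[R]) return()
      x1 <- c(cells, left)
      t2 <- cbind(x1, r - x1)
      lp <- .logTabProb(t2)
      p <- exp(lp)
      total <<- total + p
      extreme <- if (stat == "prob") lp <= obsLp + tol
                 else .gStat(t2) >= obsG - tol
      if (extreme) hit <<- hit + p
      return()
    }
    lo <- max(0L, left - sum(r[(i + 1):R]))
    hi <- min(r[i], left)
    if (hi < lo) return()
    for (x in lo:hi) rec(i + 1L, left - x, c(cells, x))
  }
  rec(1L, c1, integer(0))
  hit / total
}

# Metropolis chain over tables with fixed margins (Raymond & Rousset);
# returns p estimate and batch-based s.e. for the chosen statistic
.mcmcExactTest <- function(tab, stat = c("prob", "G"),
                           demem = 10000, batches = 20, iters = 5000) {
  stat <- match.arg(stat)
  tab <- as.matrix(tab)
  R <- nrow(tab); C <- ncol(tab)
  obsLp <- .logTabProb(tab)
  obsG <- .gStat(tab)
  tol <- 1e-9
  cur <- tab
  curLp <- obsLp
  curExtreme <- TRUE
  step <- function() {
    ij <- sample.int(R, 2); kl <- sample.int(C, 2)
    i <- ij[1]; j <- ij[2]; k <- kl[1]; l <- kl[2]
    # propose +1/-1 swap preserving margins
    if (cur[i, k] == 0 || cur[j, l] == 0) return(FALSE)
    dlp <- log(cur[i, k]) + log(cur[j, l]) -
      log(cur[i, l] + 1) - log(cur[j, k] + 1)
    if (log(stats::runif(1)) < dlp) {
      cur[i, k] <<- cur[i, k] - 1L; cur[j, l] <<- cur[j, l] - 1L
      cur[i, l] <<- cur[i, l] + 1L; cur[j, k] <<- cur[j, k] + 1L
      curLp <<- curLp + dlp
      curExtreme <<- if (stat == "prob") curLp <= obsLp + tol
                     else .gStat(cur) >= obsG - tol
      return(TRUE)
    }
    FALSE
  }
  for (b in seq_len(demem)) step()
  bp <- numeric(batches)
  for (bt in seq_len(batches)) {
    hits <- 0L
    for (it in seq_len(iters)) {
      step()
      hits <- hits + curExtreme
    }
    bp[bt] <- hits / iters
  }
  list(p = mean(bp), se = stats::sd(bp) / sqrt(batches))
}

#' Pairwise exact differentiation tests on haplotype tables
#'
#' For each population pair, the exact probability test on the
#' haplotype x 2 count table: full enumeration over fixed margins when the
#' table space is small, otherwise a Metropolis Markov chain with the
#' given dememorisation/batch schedule (s.e. from batch means). Pairwise
#' Nm from the haploid island model applied to pairwise F_ST is attached.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @param mcmc list(demem, batches, iters) for the Markov chain.
#' @param max_enum Enumerate exhaustively when the product of row ranges
#'   is below this bound.
#' @param seed Integer seed.
#' @return list of class \code{pairwise_seq_result}: \code{p, se, Nm}
#'   (pop x pop matrices), \code{npairs}.
#' @export
pairwiseExactTests <- function(aln, popmap,
                               mcmc = list(demem = 10000, batches = 20,
                                           iters = 5000),
                               max_enum = 1e6, seed = 1) {
  pop <- .checkPopmap(aln, popmap)
  hap <- haplotypeIndex(aln)
  d <- .pairwiseDiffs(aln)
  pops <- unique(pop)
  P <- length(pops)
  pm <- sem <- nm <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  set.seed(seed)
  for (a in seq_len(P - 1)) for (b in (a + 1):P) {
    sel <- pop %in% pops[c(a, b)]
    tab <- table(hap[sel], pop[sel])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2) { pm[a, b] <- pm[b, a] <- 1; sem[a, b] <- sem[b, a] <- 0 }
    else if (prod(rowSums(tab) + 1) <= max_enum) {
      pm[a, b] <- pm[b, a] <- .enumExactRx2(tab, "prob")
      sem[a, b] <- sem[b, a] <- 0
    } else {
      r <- .mcmcExactTest(tab, "prob", mcmc$demem, mcmc$batches, mcmc$iters)
      pm[a, b] <- pm[b, a] <- r$p
      sem[a, b] <- sem[b, a] <- r$se
    }
    ia <- which(pop == pops[a]); ib <- which(pop == pops[b])
    Hw <- mean(c(d[ia, ia][upper.tri(d[ia, ia])],
                 d[ib, ib][upper.tri(d[ib, ib])]))
    Hb <- mean(d[ia, ib])
    fst <- if (isTRUE(Hb > 0)) max(0, 1 - Hw / Hb) else 0
    nm[a, b] <- nm[b, a] <- islandNm(min(fst, 1), "haploid")
  }
  structure(list(p = pm, se = sem, Nm = nm, npairs = P * (P - 1) / 2),
            class = "pairwise_seq_result")
}

#' Analysis of molecular variance (AMOVA) on sequence differences
#'
#' Hierarchical decomposition of molecular variance (among groups, among
#' populations within groups, within populations) on the pairwise
#' nucleotide-difference matrix, with Phi statistics and permutation
#' p-values: individuals permuted across the whole sample for Phi_ST,
#' among populations within groups for Phi_SC, and whole populations
#' among groups for Phi_CT.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @param grouping Named character vector population -> group; NULL for a
#'   one-level AMOVA (every population its own group).
#' @param perms Number of permutations.
#' @param seed Integer seed.
#' @return list of class \code{amova_result}: \code{components} (named:
#'   among_groups, among_pops_within, within_pops), \code{percent},
#'   \code{phi} (PhiCT, PhiSC, PhiST), \code{p}, \code{df}.
#' @export
amovaSeq <- function(aln, popmap, grouping = NULL, perms = 1000, seed = 1) {
  pop <- .checkPopmap(aln, popmap)
  d2 <- .pairwiseDiffs(aln)        # differences used as squared distances
  if (is.null(grouping))
    grouping <- stats::setNames(unique(pop), unique(pop))
  if (!all(unique(pop) %in% names(grouping)))
    stop("grouping must cover all populations")
  grp <- grouping[pop]
  comp <- .amovaComponents(d2, pop, grp)
  set.seed(seed)
  nullST <- nullSC <- nullCT <- numeric(perms)
  pops <- unique(pop)
  for (b in seq_len(perms)) {
    # Phi_ST: permute individuals across the whole sample
    ppop <- sample(pop)
    nullST[b] <- .amovaComponents(d2, ppop, grouping[ppop])$phi["PhiST"]
    # Phi_SC: permute individuals among populations within groups
    ppop2 <- pop
    for (g in unique(grp)) {
      ii <- which(grp == g)
      ppop2[ii] <- sample(pop[ii])
    }
    nullSC[b] <- .amovaComponents(d2, ppop2, grouping[ppop2])$phi["PhiSC"]
    # Phi_CT: permute whole populations among groups
    pg <- stats::setNames(sample(grouping[pops]), pops)
    nullCT[b] <- .amovaComponents(d2, pop, pg[pop])$phi["PhiCT"]
  }
  p <- c(PhiCT = .permP(nullCT, comp$phi["PhiCT"]),
         PhiSC = .permP(nullSC, comp$phi["PhiSC"]),
         PhiST = .permP(nullST, comp$phi["PhiST"]))
  structure(c(comp, list(p = p)), class = "amova_result")
}

.amovaComponents <- function(d2, pop, grp) {
  N <- length(pop)
  pops <- unique(pop); P <- length(pops)
  grps <- unique(grp); G <- length(grps)
  ssAll <- function(idx) if (length(idx) < 2) 0 else
    sum(d2[idx, idx][upper.tri(d2[idx, idx])])
  SST <- ssAll(seq_len(N)) / N
  SSWP <- sum(vapply(pops, function(p)
    ssAll(which(pop == p)) / sum(pop == p), 0))
  SSWG <- sum(vapply(grps, function(g)
    ssAll(which(grp == g)) / sum(grp == g), 0))
  SSAP <- SSWG - SSWP
  SSAG <- SST - SSWG
  dfAG <- G - 1; dfAP <- P - G; dfWP <- N - P
  npop <- vapply(pops, function(p) sum(pop == p), 0)
  ngrp <- vapply(grps, function(g) sum(grp == g), 0)
  popGrp <- grp[match(pops, pop)]
  sumA <- sum(vapply(grps, function(g)
    sum(npop[popGrp == g]^2) / ngrp[match(g, grps)], 0))
  n1 <- if (dfAP > 0) (N - sumA) / dfAP else NA
  n2 <- if (dfAG > 0) (sumA - sum(npop^2) / N) / dfAG else NA
  n3 <- if (dfAG > 0) (N - sum(ngrp^2) / N) / dfAG else NA
  sc <- if (dfWP > 0) SSWP / dfWP else 0
  sb <- if (dfAP > 0) (SSAP / dfAP - sc) / n1 else 0
  sa <- if (dfAG > 0) (SSAG / dfAG - sc - n2 * sb) / n3 else 0
  tot <- sa + sb + sc
  phi <- c(PhiCT = if (tot > 0) sa / tot else 0,
           PhiSC = if ((sb + sc) > 0) sb / (sb + sc) else 0,
           PhiST = if (tot > 0) (sa + sb) / tot else 0)
  comps <- c(among_groups = sa, among_pops_within = sb, within_pops = sc)
  list(components = comps,
       percent = if (tot != 0) 100 * comps / tot else comps * NA,
       phi = phi,
       df = c(among_groups = dfAG, among_pops_within = dfAP,
              within_pops = dfWP))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(df = x$df, sigma2 = x$components, percent = x$percent)
  print(round(tab, 4))
  cat(sprintf("  PhiCT = %.4f (p = %.4f), PhiSC = %.4f (p = %.4f), PhiST = %.4f (p = %.4f)\n",
              x$phi["PhiCT"], x$p["PhiCT"], x$phi["PhiSC"], x$p["PhiSC"],
              x$phi["PhiST"], x$p["PhiST"]))
  invisible(x)
}
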