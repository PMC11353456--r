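#' @include AllClasses.R AllGenerics.R synthetic.R
NULL

# allele sizes (all gene copies, repeat units) of one locus
.locusSizes <- function(geno, locus) {
  x <- c(geno@a1[, locus], geno@a2[, locus])
  x[!is.na(x)]
}

# unbiased variance / bias-corrected fourth central moment of allele sizes
.sizeMoments <- function(x) {
  n <- length(x)
  if (n < 4) return(c(V = NA, K = NA))
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  V <- n * m2 / (n - 1)
  K <- (n * (n^2 - 2 * n + 3) * m4 - 3 * n * (2 * n - 3) * m2^2) /
    ((n - 1) * (n - 2) * (n - 3))
  c(V = V, K = K)
}

# delete-one-locus jackknife: returns estimate, jackknife se, t, p (df=L-1)
.jackknifeT <- function(values_fn, L, est) {
  if (L < 2) return(list(se = NA, t = NA, p = NA))
  reps <- vapply(seq_len(L), values_fn, 0)
  ok <- is.finite(reps)
  Lk <- sum(ok)
  if (Lk < 2) return(list(se = NA, t = NA, p = NA))
  se <- sqrt((Lk - 1) / Lk * sum((reps[ok] - mean(reps[ok]))^2))
  t <- est / se
  list(se = se, t = t,
       p = 2 * stats::pt(abs(t), df = Lk - 1, lower.tail = FALSE))
}

#' Imbalance index of allele-size variance against homozygosity
#'
#' Contrasts two single-step-mutation estimators of theta: theta_V = 2V
#' from the allele-size variance and theta_P0 from homozygosity (inverting
#' the equilibrium relation P0 = 1/sqrt(1+2 theta)). Their multilocus
#' ratio beta equals 1 at mutation-drift equilibrium; beta > 1 (ln beta >
#' 0) signals an expansion following a bottleneck, beta < 1 an expansion
#' from equilibrium. Significance of ln beta by delete-one-locus jackknife
#' and Student's t with (loci - 1) df.
#'
#' @param geno A \linkS4class{GenotypeMatrix} (one population).
#' @param seed Unused placeholder for interface symmetry; the statistic is
#'   deterministic.
#' @return list of class \code{kimmel_beta}: \code{per_locus} (data.frame
#'   locus, theta_V, theta_P0), \code{beta, ln_beta, se, t, p, defined}.
#' @export
kimmelBeta <- function(geno, seed = NULL) {
  loci <- lociNames(geno)
  tv <- tp <- rep(NA_real_, length(loci))
  for (li in seq_along(loci)) {
    x <- .locusSizes(geno, loci[li])
    if (length(x) < 4 || length(unique(x)) < 2) next
    n2 <- length(x)
    V <- stats::var(x)
    tv[li] <- 2 * V
    tb <- table(x)
    P0 <- (n2 * sum((tb / n2)^2) - 1) / (n2 - 1)   # unbiased identity
    P0 <- max(P0, 1 / n2)
    tp[li] <- (1 / P0^2 - 1) / 2
  }
  ok <- is.finite(tv) & is.finite(tp) & tp > 0
  if (sum(ok) < 2)
    return(structure(list(per_locus = data.frame(locus = loci, theta_V = tv,
                                                 theta_P0 = tp),
                          beta = NA, ln_beta = NA, se = NA, t = NA, p = NA,
                          defined = FALSE), class = "kimmel_beta"))
  # multilocus: average V and P0 over loci first, then transform — the
  # homozygosity inversion is convex, so transforming the per-locus
  # values would bias ln(beta) downwards at moderate loci counts
  p0 <- 1 / sqrt(1 + 2 * tp)            # back to the P0 scale
  idx <- which(ok)
  betaOf <- function(keep)
    2 * mean(tv[keep] / 2) / ((1 / mean(p0[keep])^2 - 1) / 2)
  beta <- betaOf(idx)
  jk <- .jackknifeT(function(j) log(betaOf(idx[-j])),
                    length(idx), log(beta))
  structure(list(per_locus = data.frame(locus = loci, theta_V = tv,
                                        theta_P0 = tp),
                 beta = beta, ln_beta = log(beta),
                 se = jk$se, t = jk$t, p = jk$p, defined = TRUE),
            class = "kimmel_beta")
}

#' @export
print.kimmel_beta <- function(x, ...) {
  if (!x$defined) { cat("Imbalance index undefined (insufficient polymorphism)\n"); return(invisible(x)) }
  cat(sprintf("Imbalance index: beta = %.3f (ln beta = %.3f +/- %.3f), t = %.2f, p = %.4f\n",
              x$beta, x$ln_beta, x$se, x$t, x$p))
  invisible(x)
}

#' Allele-size kurtosis expansion index
#'
#' \code{S_k = 1 - (K - R_k V / 2) / (5 V^2)} with V the bias-corrected
#' allele-size variance and K the bias-corrected fourth central moment,
#' both averaged over loci; R_k is the kurtosis/variance ratio of the
#' mutational step distribution (6.3 for dinucleotide repeats). S_k is 0
#' at equilibrium under symmetric stepwise mutation, positive after an
#' expansion and negative after a bottleneck. Jackknife t over loci.
#'
#' @param geno A \linkS4class{GenotypeMatrix} (one population).
#' @param R_k Mutational kurtosis/variance ratio.
#' @param sigma2_m Variance of mutational step sizes (recorded alongside
#'   the result; enters only through R_k = k_m / sigma2_m).
#' @return list of class \code{zhivotovsky_sk}: \code{per_locus}, \code{V,
#'   K, S_k, se, t, p, defined}.
#' @export
zhivotovskySk <- function(geno, R_k = 6.3, sigma2_m = 2.39) {
  loci <- lociNames(geno)
  mom <- t(vapply(loci, function(l) .sizeMoments(.locusSizes(geno, l)),
                  numeric(2)))
  ok <- is.finite(mom[, "V"]) & mom[, "V"] > 0
  if (sum(ok) < 2)
    return(structure(list(per_locus = data.frame(locus = loci, mom),
                          V = NA, K = NA, S_k = NA, se = NA, t = NA,
                          p = NA, defined = FALSE),
                     class = "zhivotovsky_sk"))
  skOf <- function(idx) {
    V <- mean(mom[idx, "V"]); K <- mean(mom[idx, "K"])
    # unbiased estimate of (E V)^2: Vbar^2 minus the sampling variance of
    # Vbar across loci (plain Vbar^2 pushes S_k upward at few loci)
    V2 <- V^2 - stats::var(mom[idx, "V"]) / length(idx)
    if (!is.finite(V2) || V2 <= 0) V2 <- V^2
    1 - (K - R_k * V / 2) / (5 * V2)
  }
  idx <- which(ok)
  Sk <- skOf(idx)
  jk <- .jackknifeT(function(j) skOf(idx[-j]), length(idx), Sk)
  structure(list(per_locus = data.frame(locus = loci, mom),
                 V = mean(mom[idx, "V"]), K = mean(mom[idx, "K"]),
                 S_k = Sk, R_k = R_k, sigma2_m = sigma2_m,
                 se = jk$se, t = jk$t, p = jk$p, defined = TRUE),
            class = "zhivotovsky_sk")
}

#' @export
print.zhivotovsky_sk <- function(x, ...) {
  if (!x$defined) { cat("Expansion index undefined\n"); return(invisible(x)) }
  cat(sprintf("Expansion index: S_k = %.3f (V = %.3f, K = %.3f), t = %.2f, p = %.4f\n",
              x$S_k, x$V, x$K, x$t, x$p))
  invisible(x)
}

#' Garza-Williamson M ratio
#'
#' Per locus, \code{M = k / r} with k the number of distinct alleles and
#' r the inclusive allelic range in repeat units (max - min + 1); the mean
#' across loci is depressed after a bottleneck. Monomorphic loci give
#' M = 1 by convention and are flagged.
#'
#' @param geno A \linkS4class{GenotypeMatrix} (one population).
#' @return list of class \code{gw_m}: \code{per_locus} (data.frame locus,
#'   k, r, M, monomorphic), \code{mean_M}.
#' @export
gwMRatio <- function(geno) {
  loci <- lociNames(geno)
  rows <- lapply(loci, function(l) {
    x <- .locusSizes(geno, l)
    if (!length(x)) return(data.frame(locus = l, k = NA, r = NA, M = NA,
                                      monomorphic = NA))
    k <- length(unique(x))
    r <- max(x) - min(x) + 1L
    data.frame(locus = l, k = k, r = r, M = k / r, monomorphic = k == 1)
  })
  per_locus <- do.call(rbind, rows)
  structure(list(per_locus = per_locus,
                 mean_M = mean(per_locus$M, na.rm = TRUE)),
            class = "gw_m")
}

#' @export
print.gw_m <- function(x, ...) {
  cat(sprintf("M ratio: mean M = %.4f\n", x$mean_M))
  print(x$per_locus, row.names = FALSE)
  invisible(x)
}

#' Equilibrium null distribution of the M ratio
#'
#' Coalescent simulation of a single locus with \code{n_genes} gene copies
#' under the two-phase mutation model (single-step with probability
#' \code{p_s}, otherwise a geometric step of mean \code{delta_g}, sign
#' symmetric) at mutation-drift equilibrium with the given theta = 4 Ne
#' mu. Returns the simulated M values, their mean, the fifth-percentile
#' critical value M_c, and (when an observed M is supplied) the rank
#' probability: the fraction of equilibrium replicates below the observed
#' value, significant evidence of a size reduction when below 5
#' percent (equivalently observed M < M_c).
#'
#' @param theta 4 Ne mu of the equilibrium population.
#' @param p_s Fraction of single-step mutations.
#' @param delta_g Mean size of multi-step mutations (at least two repeat
#'   units; sizes are 2 plus a geometric excess so their mean is
#'   \code{delta_g}).
#' @param n_genes Gene copies sampled (2 x individuals).
#' @param n_loci Loci per replicate; each replicate's M is the mean over
#'   \code{n_loci} independent loci, matching an observed mean computed
#'   over that many markers. 1 gives the single-locus distribution.
#' @param reps Simulation replicates (>= 1000).
#' @param seed Integer seed.
#' @param observed_M Optional observed mean M to rank.
#' @return list of class \code{m_ratio_null}: \code{M} (simulated values),
#'   \code{mean, M_c, p_rank, significant}.
#' @export
gwNullDistribution <- function(theta, p_s = 0.88, delta_g = 3.5,
                               n_genes, n_loci = 1, reps = 10000, seed = 1,
                               observed_M = NULL) {
  if (theta <= 0) stop("theta must be > 0")
  if (p_s <= 0 || p_s > 1) stop("p_s must be in (0, 1]")
  if (reps < 1000) stop("need >= 1000 replicates for a stable 5th percentile")
  set.seed(seed)
  M <- numeric(reps)
  oneM <- function() {
    x <- round(.simSMMLocus(n_genes, theta, p_s, delta_g))
    length(unique(x)) / (max(x) - min(x) + 1)
  }
  for (r in seq_len(reps))
    M[r] <- mean(vapply(seq_len(n_loci), function(l) oneM(), 0))
  Mc <- sort(M)[max(1L, floor(0.05 * reps))]
  out <- list(M = M, mean = mean(M), M_c = Mc)
  if (!is.null(observed_M)) {
    out$p_rank <- mean(M < observed_M)
    out$significant <- observed_M < Mc
  }
  structure(out, class = "m_ratio_null")
}

#' @export
print.m_ratio_null <- function(x, ...) {
  cat(sprintf("Equilibrium M null: mean = %.4f, M_c (5%%) = %.4f over %d reps\n",
              x$mean, x$M_c, length(x$M)))
  if (!is.null(x$p_rank))
    cat(sprintf("  rank p of observed M = %.4f (%ssignificant reduction)\n",
                x$p_rank, if (x$significant) "" else "not "))
  invisible(x)
}

# bias-corrected sample excess kurtosis (G2); only its sign enters the
# intralocus test
.excessKurtosis <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Intralocus kurtosis test for population expansion
#'
#' In constant-size populations allele-length distributions tend to be
#' multi-peaked; expansion smooths them. Each polymorphic locus
#' contributes the sign of its allele-size kurtosis statistic; under
#' constant size a locus is positive with probability \code{p_pos}
#' (0.515). The one-tailed binomial probability of observing at most the
#' observed number of positive loci is the significance of expansion.
#'
#' @param geno A \linkS4class{GenotypeMatrix} (one population).
#' @param p_pos Probability of a positive locus under constant size.
#' @return list of class \code{reich_k}: \code{per_locus} (data.frame
#'   locus, k_stat, sign), \code{n_loci, n_positive, p}.
#' @export
reichKTest <- function(geno, p_pos = 0.515) {
  loci <- lociNames(geno)
  ks <- vapply(loci, function(l) .excessKurtosis(.locusSizes(geno, l)), 0)
  ok <- is.finite(ks)
  npos <- sum(ks[ok] > 0)
  nloc <- sum(ok)
  p <- stats::pbinom(npos, nloc, p_pos)
  structure(list(per_locus = data.frame(locus = loci, k_stat = ks,
                                        sign = ifelse(!is.finite(ks), NA,
                                                      ifelse(ks > 0, "+", "-"))),
                 n_loci = nloc, n_positive = npos, p = p),
            class = "reich_k")
}

#' @export
print.reich_k <- function(x, ...) {
  cat(sprintf("Intralocus kurtosis test: %d/%d loci positive, binomial p = %.3f\n",
              x$n_positive, x$n_loci, x$p))
  invisible(x)
}

#' Interlocus test of allele-size-variance homogeneity
#'
#' Expansions homogenise per-locus allele-size variances, so a low
#' normalized interlocus variance g signals expansion. g is the observed
#' variance of per-locus allele-size variances divided by (4/3) Vbar^2
#' (its approximate constant-size expectation, so g is near 1 at
#' equilibrium); the fifth-percentile cutoff comes from constant-size
#' coalescent simulation matched to the number of loci, sample size and
#' theta estimated from the mean variance (theta = 2 Vbar).
#'
#' @param geno A \linkS4class{GenotypeMatrix} (one population).
#' @param cutoff_source Only "simulated" is supported: the matched
#'   coalescent null.
#' @param reps Null replicates.
#' @param p_s,delta_g Mutation model of the null (defaults to strict
#'   single-step, the model under which the test was derived).
#' @param seed Integer seed.
#' @return list of class \code{reich_g}: \code{g, V_locus} (per-locus
#'   variances), \code{cutoff, p, significant, defined}.
#' @export
reichGTest <- function(geno, cutoff_source = "simulated", reps = 1000,
                       p_s = 1, delta_g = 3.5, seed = 1) {
  if (cutoff_source != "simulated")
    stop("only the simulated matched null is available")
  loci <- lociNames(geno)
  V <- vapply(loci, function(l) {
    x <- .locusSizes(geno, l)
    if (length(x) < 2) NA_real_ else stats::var(x)
  }, 0)
  ok <- is.finite(V) & V > 0
  if (sum(ok) < 2)
    return(structure(list(g = NA, V_locus = V, cutoff = NA, p = NA,
                          significant = NA, defined = FALSE),
                     class = "reich_g"))
  gOf <- function(v) stats::var(v) / ((4 / 3) * mean(v)^2)
  g <- gOf(V[ok])
  nloc <- sum(ok)
  ngenes <- max(vapply(loci[ok], function(l)
    length(.locusSizes(geno, l)), 0L))
  theta <- 2 * mean(V[ok])
  set.seed(seed)
  nullg <- vapply(seq_len(reps), function(r) {
    vs <- vapply(seq_len(nloc), function(l) {
      x <- .simSMMLocus(ngenes, theta, p_s, delta_g)
      stats::var(x)
    }, 0)
    vs <- vs[vs > 0]
    if (length(vs) < 2) NA_real_ else gOf(vs)
  }, 0)
  nullg <- nullg[is.finite(nullg)]
  cutoff <- stats::quantile(nullg, 0.05, names = FALSE, type = 1)
  p <- (sum(nullg <= g) + 1) / (length(nullg) + 1)
  structure(list(g = g, V_locus = V, cutoff = cutoff, p = p,
                 significant = g < cutoff, defined = TRUE),
            class = "reich_g")
}

#' @export
print.reich_g <- function(x, ...) {
  if (!x$defined) { cat("Interlocus test undefined\n"); return(invisible(x)) }
  cat(sprintf("Interlocus test: g = %.3f, 5%% cutoff = %.3f, p = %.3f\n",
              x$g, x$cutoff, x$p))
  invisible(x)
}
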