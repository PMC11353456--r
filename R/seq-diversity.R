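#' @include AllClasses.R AllGenerics.R
NULL

# harmonic sums used by Watterson / Tajima / Fu & Li constants
.a1 <- function(n) sum(1 / seq_len(n - 1))
.a2 <- function(n) sum(1 / seq_len(n - 1)^2)

# per-site allele counting on the clean site set
.siteCounts <- function(aln) {
  m <- .alnMatrix(aln)
  keep <- .cleanSites(m)
  m <- m[, keep, drop = FALSE]
  list(m = m, L = length(keep))
}

#' Within-sample sequence diversity statistics
#'
#' Haplotype count and diversity, nucleotide diversity, mean pairwise
#' differences, segregating sites and Watterson's theta (per sequence),
#' with the classical sampling standard deviations. Sites containing a gap
#' or N anywhere are excluded (complete deletion), so S, pi and haplotype
#' identity refer to one coherent site set.
#'
#' @param aln A \linkS4class{HaplotypeAlignment} with >= 2 sequences.
#' @return list of class \code{diversity_stats}: \code{n, L, H,
#'   haplotype_freqs, H_d, H_d_sd, pi, pi_sd, k_bar, S, theta_seq,
#'   theta_seq_sd}.
#' @export
diversityStats <- function(aln) {
  n <- length(aln)
  if (n < 2) stop("need at least 2 sequences")
  sc <- .siteCounts(aln)
  m <- sc$m; L <- sc$L
  hap <- haplotypeIndex(aln)
  counts <- as.integer(table(hap))
  p <- counts / n
  H <- length(counts)
  Hd <- n * (1 - sum(p^2)) / (n - 1)
  # Nei (1987) sampling variance of haplotype diversity
  s2 <- sum(p^2); s3 <- sum(p^3)
  varHd <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  # segregating sites and mean pairwise differences
  nAll <- apply(m, 2, function(col) length(unique(col)))
  S <- sum(nAll > 1)
  d <- .pairwiseDiffs(aln)
  kbar <- mean(d[upper.tri(d)])
  pi <- kbar / L
  varPi <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  a1 <- .a1(n); a2 <- .a2(n)
  th <- S / a1
  varTh <- (a1 * th + a2 * th^2) / a1^2   # Watterson, theta per sequence
  structure(list(n = n, L = L, H = H, haplotype_freqs = counts,
                 H_d = Hd, H_d_sd = sqrt(max(varHd, 0)),
                 pi = pi, pi_sd = sqrt(max(varPi, 0)),
                 k_bar = kbar, S = S,
                 theta_seq = th, theta_seq_sd = sqrt(max(varTh, 0))),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("Sequence diversity (n =", x$n, ", sites =", x$L, ")\n")
  cat(sprintf("  haplotypes H = %d, Hd = %.3f +/- %.3f\n",
              x$H, x$H_d, x$H_d_sd))
  cat(sprintf("  pi = %.4g +/- %.4g, k = %.3f, S = %d, theta(seq) = %.3f +/- %.3f\n",
              x$pi, x$pi_sd, x$k_bar, x$S, x$theta_seq, x$theta_seq_sd))
  invisible(x)
}

# ---- statistic kernels operating on summary quantities --------------

.tajimaD <- function(n, S, kbar) {
  if (S == 0) return(NA_real_)
  a1 <- .a1(n); a2 <- .a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) starred statistics (no outgroup), total mutations eta and
# singleton mutations eta_s in the folded sense
.fuLiConstants <- function(n) {
  an <- .a1(n); bn <- .a2(n)
  an1 <- an + 1 / n
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uDs <- n / (n - 1) * (an - n / (n - 1)) - vDs
  vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
            2 / (n - 1) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vFs
  list(an = an, uDs = uDs, vDs = vDs, uFs = uFs, vFs = vFs)
}

.fuLiDstar <- function(n, eta, eta_s) {
  if (eta == 0) return(NA_real_)
  k <- .fuLiConstants(n)
  (n / (n - 1) * eta - k$an * eta_s) /
    sqrt(k$uDs * eta + k$vDs * eta^2)
}

.fuLiFstar <- function(n, eta, eta_s, kbar) {
  if (eta == 0) return(NA_real_)
  k <- .fuLiConstants(n)
  (kbar - (n - 1) / n * eta_s) / sqrt(k$uFs * eta + k$vFs * eta^2)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n)
.logStirling1 <- function(n) {
  ls <- -Inf
  cur <- 0                       # row 1: |s(1,1)| = 1
  if (n == 1) return(cur)
  prev <- cur
  for (m in 2:n) {
    prev <- c(-Inf, prev, -Inf)  # pad k = 0 and k = m
    a <- prev[seq_len(m)]        # |s(m-1, k-1)|
    b <- prev[2:(m + 1)]         # |s(m-1, k)|
    bl <- log(m - 1) + b
    mx <- pmax(a, bl)
    cur <- ifelse(is.infinite(mx) & mx < 0, -Inf,
                  mx + log(exp(a - mx) + exp(bl - mx)))
    prev <- cur
  }
  cur
}

# Fu's Fs via the Ewens sampling distribution of the allele count at
# theta = kbar, in log space (stable up to n in the hundreds)
.fuFs <- function(n, K, kbar) {
  if (kbar <= 0) return(NA_real_)
  ls <- .logStirling1(n)
  lth <- log(kbar)
  lnum <- ls + seq_len(n) * lth
  lden <- sum(log(kbar + 0:(n - 1)))
  lp <- lnum - lden              # log P(K = k), k = 1..n
  mx <- max(lp[K:n])
  lSp <- mx + log(sum(exp(lp[K:n] - mx)))
  Sp <- exp(lSp)
  Sp <- min(max(Sp, 1e-300), 1 - 1e-12)
  log(Sp / (1 - Sp))
}

.r2stat <- function(n, U, kbar, S) {
  if (S == 0) return(NA_real_)
  sqrt(sum((U - kbar / 2)^2) / n) / S
}

# observed folded counts: total mutations eta, singleton mutations eta_s,
# and per-sequence singleton load U
.foldedCounts <- function(aln) {
  sc <- .siteCounts(aln)
  m <- sc$m
  n <- nrow(m)
  eta <- 0L; eta_s <- 0L
  U <- integer(n)
  for (j in seq_len(ncol(m))) {
    tb <- table(m[, j])
    if (length(tb) < 2) next
    eta <- eta + length(tb) - 1L
    ones <- names(tb)[tb == 1]
    for (al in ones) {
      eta_s <- eta_s + 1L
      U[which(m[, j] == al)] <- U[which(m[, j] == al)] + 1L
    }
  }
  list(eta = eta, eta_s = eta_s, U = U)
}

# one neutral constant-size coalescent replicate (infinite sites),
# returning the summaries all five statistics need
.simNeutralStats <- function(n, theta) {
  nn <- 2L * n - 1L
  parent <- integer(nn); ntime <- numeric(nn)
  active <- seq_len(n); t <- 0; nxt <- n + 1L
  for (k in n:2) {
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- nxt
    ntime[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  blen <- numeric(nn)
  blen[-nn] <- ntime[parent[-nn]] - ntime[seq_len(nn - 1L)]
  nmut <- stats::rpois(nn, theta / 2 * pmax(blen, 0))
  desc <- c(rep(1L, n), integer(n - 1L))
  for (node in seq_len(nn - 1L)) desc[parent[node]] <- desc[parent[node]] + desc[node]
  S <- sum(nmut[-nn])
  kbar <- sum(nmut[-nn] * desc[-nn] * (n - desc[-nn])) / (n * (n - 1) / 2)
  U <- nmut[seq_len(n)]
  eta_s <- sum(U)
  rc <- which(parent == nn)            # the two root children
  big <- rc[desc[rc] == n - 1L]
  if (length(big) == 1L) {             # mutations there fold onto the
    other <- rc[rc != big]             # leaf hanging off the root
    if (other <= n) {
      U[other] <- U[other] + nmut[big]
      eta_s <- eta_s + nmut[big]
    }
  }
  # haplotype count: leaves share a haplotype iff no mutation separates them
  key <- character(n)
  mutb <- which(nmut > 0 & seq_len(nn) < nn)
  anc <- function(i) {
    path <- integer(0)
    while (i != nn) { path <- c(path, i); i <- parent[i] }
    path
  }
  if (length(mutb)) {
    for (i in seq_len(n))
      key[i] <- paste(intersect(anc(i), mutb), collapse = ",")
  }
  K <- length(unique(key))
  list(S = S, kbar = kbar, eta = S, eta_s = eta_s, U = U, K = K)
}

#' Neutrality and demographic-change tests for sequence data
#'
#' Tajima's D, Fu and Li's D* and F* (folded, no outgroup), Fu's Fs and
#' the R2 statistic, with p-values from neutral constant-size coalescent
#' simulations conditioned on the sample size and theta estimated by the
#' mean pairwise difference. D, D* and F* are tested two-tailed; Fs and R2
#' one-tailed towards their expansion-sensitive (low) tail.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param coalescent_reps Number of coalescent replicates for the null.
#' @param seed Integer seed.
#' @return list of class \code{neutrality_tests} with elements
#'   \code{tajima_D, fuli_Dstar, fuli_Fstar, fu_Fs, R2}, matching
#'   \code{p_*} values, and \code{defined} (FALSE when S = 0).
#' @export
neutralityTests <- function(aln, coalescent_reps = 10000, seed = 1) {
  n <- length(aln)
  if (n < 2) stop("need at least 2 sequences")
  ds <- diversityStats(aln)
  if (n < 4) {
    # D is identically 0 at n = 2 and the D*/F* variance constants need
    # n >= 4: degenerate, flagged rather than silently returned
    return(structure(list(defined = FALSE,
                          tajima_D = NA, fuli_Dstar = NA, fuli_Fstar = NA,
                          fu_Fs = NA, R2 = NA,
                          p_tajima_D = NA, p_fuli_Dstar = NA,
                          p_fuli_Fstar = NA, p_fu_Fs = NA, p_R2 = NA),
                     class = "neutrality_tests"))
  }
  if (ds$S == 0) {
    return(structure(list(defined = FALSE,
                          tajima_D = NA, fuli_Dstar = NA, fuli_Fstar = NA,
                          fu_Fs = NA, R2 = NA,
                          p_tajima_D = NA, p_fuli_Dstar = NA,
                          p_fuli_Fstar = NA, p_fu_Fs = NA, p_R2 = NA),
                     class = "neutrality_tests"))
  }
  fc <- .foldedCounts(aln)
  K <- length(unique(haplotypeIndex(aln)))
  obs <- c(D  = .tajimaD(n, ds$S, ds$k_bar),
           Ds = .fuLiDstar(n, fc$eta, fc$eta_s),
           Fs2 = .fuLiFstar(n, fc$eta, fc$eta_s, ds$k_bar),
           FuFs = .fuFs(n, K, ds$k_bar),
           R2 = .r2stat(n, fc$U, ds$k_bar, ds$S))
  set.seed(seed)
  sim <- matrix(NA_real_, coalescent_reps, 5)
  for (r in seq_len(coalescent_reps)) {
    s <- .simNeutralStats(n, ds$k_bar)
    sim[r, ] <- c(.tajimaD(n, s$S, s$kbar),
                  .fuLiDstar(n, s$eta, s$eta_s),
                  .fuLiFstar(n, s$eta, s$eta_s, s$kbar),
                  .fuFs(n, s$K, s$kbar),
                  .r2stat(n, s$U, s$kbar, s$S))
  }
  twoTail <- function(col, o) {
    v <- sim[, col]; v <- v[!is.na(v)]
    if (!length(v) || is.na(o)) return(NA_real_)
    lo <- (sum(v <= o) + 1) / (length(v) + 1)
    hi <- (sum(v >= o) + 1) / (length(v) + 1)
    min(1, 2 * min(lo, hi))
  }
  oneTailLow <- function(col, o) {
    v <- sim[, col]; v <- v[!is.na(v)]
    if (!length(v) || is.na(o)) return(NA_real_)
    (sum(v <= o) + 1) / (length(v) + 1)
  }
  structure(list(defined = TRUE,
                 tajima_D = unname(obs["D"]),
                 fuli_Dstar = unname(obs["Ds"]),
                 fuli_Fstar = unname(obs["Fs2"]),
                 fu_Fs = unname(obs["FuFs"]),
                 R2 = unname(obs["R2"]),
                 p_tajima_D = twoTail(1, obs["D"]),
                 p_fuli_Dstar = twoTail(2, obs["Ds"]),
                 p_fuli_Fstar = twoTail(3, obs["Fs2"]),
                 p_fu_Fs = oneTailLow(4, obs["FuFs"]),
                 p_R2 = oneTailLow(5, obs["R2"])),
            class = "neutrality_tests")
}

#' @export
print.neutrality_tests <- function(x, ...) {
  if (!x$defined) { cat("Neutrality tests: undefined (no polymorphism)\n"); return(invisible(x)) }
  cat("Neutrality tests (coalescent p-values)\n")
  for (nm in c("tajima_D", "fuli_Dstar", "fuli_Fstar", "fu_Fs", "R2"))
    cat(sprintf("  %-11s %8.3f   p = %.4f\n", nm, x[[nm]],
                x[[paste0("p_", nm)]]))
  invisible(x)
}

# sudden-expansion expected mismatch frequencies at difference count i,
# exact mixture integral in terms of incomplete gamma functions
.mismatchModel <- function(imax, tau, th0, th1) {
  i <- 0:imax
  A <- (1 / th1) / (1 + 1 / th1)^(i + 1) *
    stats::pgamma(tau, shape = i + 1, rate = 1 + 1 / th1)
  B <- vapply(i, function(ii) {
    j <- 0:ii
    exp(-tau * (1 + 1 / th1)) / th0 *
      sum(tau^(ii - j) / factorial(ii - j) / (1 + 1 / th0)^(j + 1))
  }, 0)
  A + B
}

.raggedness <- function(relfreq) sum(diff(c(relfreq, 0))^2)

.fitSuddenExpansion <- function(obsRel, kbar) {
  imax <- length(obsRel) - 1
  ssd <- function(par) {
    tau <- exp(par[1]); th0 <- exp(par[2]); th1 <- exp(par[3])
    sum((obsRel - .mismatchModel(imax, tau, th0, th1))^2)
  }
  init <- log(c(max(kbar, 0.5), 0.1, max(10 * kbar, 5)))
  fit <- stats::optim(init, ssd, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  list(tau = exp(fit$par[1]), theta0 = exp(fit$par[2]),
       theta1 = exp(fit$par[3]), SSD = fit$value)
}

# coalescent replicate under the fitted sudden-expansion demography;
# returns a pairwise-difference histogram (relative frequencies)
.simMismatch <- function(n, tau, th0, th1) {
  tb <- tau / th1                    # epoch boundary in scaled time
  nn <- 2L * n - 1L
  parent <- integer(nn); ntime <- numeric(nn)
  active <- seq_len(n); t <- 0; nxt <- n + 1L
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1) / 2 * if (t >= tb) th1 / th0 else 1
    dt <- stats::rexp(1, rate)
    if (t < tb && t + dt >= tb) { t <- tb; next }
    t <- t + dt
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- nxt
    ntime[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L; k <- k - 1L
  }
  blen <- numeric(nn)
  blen[-nn] <- ntime[parent[-nn]] - ntime[seq_len(nn - 1L)]
  nmut <- stats::rpois(nn, th1 / 2 * pmax(blen, 0))
  desc <- c(rep(1L, n), integer(n - 1L))
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- i
  ord <- order(ntime[(n + 1L):nn]) + n
  for (node in ord) {
    ch <- which(parent == node)
    below[[node]] <- unlist(below[ch])
  }
  d <- matrix(0L, n, n)
  for (b in which(nmut > 0 & seq_len(nn) < nn)) {
    inb <- below[[b]]
    d[inb, -inb] <- d[inb, -inb] + nmut[b]
    d[-inb, inb] <- d[-inb, inb] + nmut[b]
  }
  d[upper.tri(d)]
}

#' Mismatch distribution with sudden-expansion model fit
#'
#' Observed pairwise-difference histogram, least-squares fit of the
#' sudden-expansion curve (tau, theta0, theta1), Harpending's raggedness,
#' and parametric-bootstrap p-values for the sum of squared deviations and
#' the raggedness (simulating coalescent samples under the fitted model
#' and refitting each).
#'
#' @param aln A \linkS4class{HaplotypeAlignment} with >= 3 sequences.
#' @param bootstrap_reps Parametric bootstrap replicates.
#' @param seed Integer seed.
#' @return list of class \code{mismatch_result}: \code{observed} (counts at
#'   0..max), \code{tau, theta0, theta1, SSD, rg, p_SSD, p_rg,
#'   applicable}.
#' @export
mismatchDistribution <- function(aln, bootstrap_reps = 200, seed = 1) {
  n <- length(aln)
  if (n < 3) stop("need at least 3 sequences")
  d <- .pairwiseDiffs(aln)
  dv <- d[upper.tri(d)]
  obs <- tabulate(dv + 1L, nbins = max(dv) + 1L)
  names(obs) <- 0:max(dv)
  if (max(dv) == 0) {
    return(structure(list(observed = obs, applicable = FALSE,
                          tau = NA, theta0 = NA, theta1 = NA, SSD = NA,
                          rg = NA, p_SSD = NA, p_rg = NA),
                     class = "mismatch_result"))
  }
  rel <- obs / sum(obs)
  kbar <- mean(dv)
  fit <- .fitSuddenExpansion(rel, kbar)
  rg <- .raggedness(rel)
  set.seed(seed)
  ssdN <- rgN <- numeric(bootstrap_reps)
  for (r in seq_len(bootstrap_reps)) {
    dvS <- .simMismatch(n, fit$tau, fit$theta0, fit$theta1)
    relS <- tabulate(dvS + 1L, nbins = max(dvS) + 1L)
    relS <- relS / sum(relS)
    fS <- .fitSuddenExpansion(relS, mean(dvS))
    ssdN[r] <- fS$SSD
    rgN[r] <- .raggedness(relS)
  }
  structure(list(observed = obs, applicable = TRUE,
                 tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 SSD = fit$SSD, rg = rg,
                 p_SSD = .permP(ssdN, fit$SSD),
                 p_rg = .permP(rgN, rg)),
            class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat("Mismatch distribution\n")
  if (!x$applicable) { cat("  model inapplicable (no variation)\n"); return(invisible(x)) }
  cat(sprintf("  tau = %.3f, theta0 = %.3f, theta1 = %.3f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.4g (p = %.3f), raggedness = %.4g (p = %.3f)\n",
              x$SSD, x$p_SSD, x$rg, x$p_rg))
  invisible(x)
}
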