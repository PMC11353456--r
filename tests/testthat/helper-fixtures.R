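# shared fixture builders: everything is generated in code at test time

# small aligned toy with two populations
toyAlignment <- function() {
  HaplotypeAlignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGAACGTAC",
                       d = "ACGAACGTAT", e = "ACGTACGTAC", f = "ACGAACGTAT"))
}

toyPopmap <- function(pops = c("P1", "P1", "P1", "P2", "P2", "P2"),
                      ids = letters[1:6]) {
  u <- unique(pops)
  PopulationAssignment(stats::setNames(pops, ids),
                       data.frame(pop = u,
                                  lat = -14 - seq_along(u) / 10,
                                  lon = -65 + seq_along(u) / 10))
}

# diploid genotypes from a coalescent SMM/TPM locus simulator
mkGeno <- function(nind, nloc, theta, p_s = 1, delta_g = 3.5, anc = 100,
                   pop = NULL) {
  a1 <- a2 <- matrix(NA_integer_, nind, nloc)
  for (l in seq_len(nloc)) {
    x <- round(riverpopgen:::.simSMMLocus(2 * nind, theta, p_s, delta_g)) + anc
    a1[, l] <- x[seq(1, 2 * nind, 2)]
    a2[, l] <- x[seq(2, 2 * nind, 2)]
  }
  ids <- sprintf("i%03d", seq_len(nind))
  dimnames(a1) <- dimnames(a2) <- list(ids, sprintf("L%02d", seq_len(nloc)))
  if (is.null(pop)) pop <- rep("P", nind)
  GenotypeMatrix(a1, a2,
                 stats::setNames(rep(2L, nloc), colnames(a1)),
                 pop = stats::setNames(pop, ids))
}

# explicit genotype container from allele-pair lists (one locus per element)
genoFromPairs <- function(pairs, pop = NULL, repeat_unit = 2L) {
  nind <- nrow(pairs[[1]])
  a1 <- matrix(unlist(lapply(pairs, function(p) p[, 1])), nrow = nind)
  a2 <- matrix(unlist(lapply(pairs, function(p) p[, 2])), nrow = nind)
  ids <- sprintf("i%03d", seq_len(nind))
  loci <- sprintf("L%02d", seq_along(pairs))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (is.null(pop)) pop <- rep("P", nind)
  GenotypeMatrix(a1, a2, stats::setNames(rep(repeat_unit, length(pairs)), loci),
                 pop = stats::setNames(pop, ids))
}

# brute-force pairwise-difference statistics used as oracles
oracleDiversity <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  diffs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  p <- table(apply(m, 1, paste, collapse = "")) / n
  list(kbar = mean(diffs),
       S = sum(apply(m, 2, function(col) length(unique(col)) > 1)),
       Hd = n / (n - 1) * (1 - sum(p^2)),
       H = length(p))
}

# two-deme island-model sequence F_ST (1 - Hw/Hb) for calibration checks
hsmFst <- function(aln, popmap) {
  d <- riverpopgen:::.pairwiseDiffs(aln)
  pop <- populations(popmap)[sampleIDs(aln)]
  ut <- upper.tri(d)
  same <- outer(pop, pop, "==")
  1 - mean(d[same & ut]) / mean(d[!same & ut])
}
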