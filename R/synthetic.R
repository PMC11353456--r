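#' @include AllClasses.R AllGenerics.R
NULL

# ------------------------------------------------------------------
# Structured-coalescent generator for river-network metapopulations.
#
# Migration convention: each lineage emigrates at per-generation rate m
# into a migrant pool redistributed uniformly over ALL candidate demes
# (including the source), i.e. the classical island-model convention; the
# effective move rate is m*(d-1)/d. Under this convention the equilibrium
# expectations E[F_ST] = 1/(1+2Nm) (haploid) and 1/(1+4Nm) (diploid) hold
# for the 1 - Hw/Hb estimator. In "river" mode the candidate demes are the
# network neighbours of the source plus the source itself (stepping-stone).
# ------------------------------------------------------------------

#' Configuration of a synthetic river metapopulation
#'
#' Bundles the full generative description used by
#' \code{\link{simulateSequences}} and \code{\link{simulateMicrosatellites}}:
#' geography, per-site sample sizes, sex-specific migration, demographic
#' history and the mutation models of both markers.
#'
#' @param sites data.frame with columns \code{pop,lat,lon,n_seq,n_geno}
#'   (samples sequenced / genotyped per site).
#' @param edges data.frame with columns \code{from,to} naming adjacent
#'   sites on the river network (ignored when \code{migration_mode} is
#'   \code{"island"}).
#' @param N_f Female effective size per deme (number of mitochondrial gene
#'   copies).
#' @param N Diploid effective size per deme (autosomal gene copies = 2N).
#' @param m_f,m_m Per-generation female / male emigration rates. The
#'   maternal marker migrates at \code{m_f}; autosomal loci at the sex
#'   average \code{(m_f+m_m)/2}.
#' @param migration_mode \code{"river"} (stepping-stone over \code{edges})
#'   or \code{"island"} (uniform over all demes).
#' @param history Demographic history, one of
#'   \code{list(type="constant")},
#'   \code{list(type="bottleneck", time_gen=, strength=)} (ancestral size =
#'   present size times \code{strength}, i.e. a crash \code{time_gen}
#'   generations ago), or
#'   \code{list(type="expansion", time_gen=, factor=)} (present size =
#'   ancestral times \code{factor}).
#' @param seq_model list: \code{L} sites, \code{mu_site_year} substitution
#'   rate per site per year, \code{gen_years} generation time,
#'   \code{tstv} transition/transversion ratio.
#' @param msat_model list: \code{n_loci}, per-generation rate \code{mu},
#'   single-step fraction \code{p_s}, mean multistep size \code{delta_g},
#'   \code{repeat_unit} (bp), ancestral size \code{anc} (repeat units).
#' @return A \code{sim_config} list.
#' @export
simulationConfig <- function(sites,
                             edges = NULL,
                             N_f = 1500, N = 2500,
                             m_f = 1e-3, m_m = 0.05,
                             migration_mode = c("river", "island"),
                             history = list(type = "constant"),
                             seq_model = list(L = 400L,
                                              mu_site_year = 1.5e-8,
                                              gen_years = 7,
                                              tstv = 10),
                             msat_model = list(n_loci = 10L, mu = 1.5e-5,
                                               p_s = 0.8682, delta_g = 3.5,
                                               repeat_unit = 2L, anc = 50L)) {
  migration_mode <- match.arg(migration_mode)
  stopifnot(all(c("pop", "lat", "lon", "n_seq") %in% names(sites)))
  if (is.null(sites$n_geno)) sites$n_geno <- sites$n_seq
  if (any(sites$n_seq < 0) || any(sites$n_geno < 0))
    stop("sample sizes must be >= 0")
  if (migration_mode == "river" && is.null(edges) && nrow(sites) > 1)
    stop("river mode needs an edge list")
  if (m_f < 0 || m_m < 0) stop("migration rates must be >= 0")
  structure(list(sites = sites, edges = edges, N_f = N_f, N = N,
                 m_f = m_f, m_m = m_m, migration_mode = migration_mode,
                 history = history, seq_model = seq_model,
                 msat_model = msat_model),
            class = "sim_config")
}

# epoch scaling of deme sizes: multiplier on gene copies at time t (gens ago)
.historyScale <- function(history) {
  switch(history$type,
    constant = list(breaks = numeric(0), factors = 1),
    bottleneck = list(breaks = history$time_gen,
                      factors = c(1, history$strength)),
    expansion = list(breaks = history$time_gen,
                     factors = c(1, 1 / history$factor)),
    stop("unknown history type: ", history$type))
}

# backward migration rate matrix under the island-pool convention
.migrationMatrix <- function(d, m, mode, edges, popNames) {
  M <- matrix(0, d, d)
  if (d == 1 || m == 0) return(M)
  if (mode == "island") {
    M[] <- m / d
  } else {
    adj <- matrix(FALSE, d, d, dimnames = list(popNames, popNames))
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$from[k], popNames); j <- match(edges$to[k], popNames)
      if (is.na(i) || is.na(j)) stop("edge names a site not in sites")
      adj[i, j] <- adj[j, i] <- TRUE
    }
    for (i in seq_len(d)) {
      nb <- which(adj[i, ])
      if (length(nb)) M[i, nb] <- m / (length(nb) + 1L)
    }
  }
  diag(M) <- 0
  M
}

# Structured coalescent of one locus. Returns parent pointers (0 = root),
# node times in generations, and the deme of each leaf.
# demeOf: integer deme per sampled gene copy; G: gene copies per deme.
.coalTree <- function(demeOf, G, M, scaling = list(breaks = numeric(0),
                                                   factors = 1)) {
  n <- length(demeOf)
  nn <- 2L * n - 1L
  parent <- integer(nn)
  ntime <- numeric(nn)
  lin <- seq_len(n)             # node id of each active lineage
  deme <- demeOf
  d <- length(G)
  t <- 0; nxt <- n + 1L
  emig <- rowSums(M)
  bks <- c(scaling$breaks, Inf)
  while (length(lin) > 1L) {
    ep <- findInterval(t, c(0, scaling$breaks), rightmost.closed = FALSE)
    sc <- scaling$factors[ep]
    kd <- tabulate(deme, d)
    coalR <- kd * (kd - 1) / 2 / (G * sc)
    migR <- if (d > 1) kd * emig else 0
    tot <- sum(coalR) + sum(migR)
    if (tot <= 0) stop("no events possible: disconnected demes with >1 lineage")
    dt <- stats::rexp(1, tot)
    if (t + dt >= bks[ep]) { t <- bks[ep]; next }
    t <- t + dt
    if (stats::runif(1) < sum(coalR) / tot) {
      dm <- sample.int(d, 1L, prob = coalR)
      pick <- sample(which(deme == dm), 2L)
      parent[lin[pick]] <- nxt
      ntime[nxt] <- t
      lin <- c(lin[-pick], nxt)
      deme <- c(deme[-pick], dm)
      nxt <- nxt + 1L
    } else {
      i <- sample.int(length(lin), 1L, prob = migR[deme] / kd[deme])
      deme[i] <- sample.int(d, 1L, prob = M[deme[i], ])
    }
  }
  list(parent = parent, time = ntime, n = n)
}

# per-branch Poisson mutation counts; rate per generation per lineage
.branchMutations <- function(tree, rate) {
  nn <- 2L * tree$n - 1L
  blen <- numeric(nn)
  blen[-nn] <- tree$time[tree$parent[-nn]] - tree$time[seq_len(nn - 1L)]
  stats::rpois(nn, rate * pmax(blen, 0))
}

# drop finite-sites mutations (K80-like) down the tree; returns leaf matrix
.evolveSequences <- function(tree, L, mu_site_gen, tstv) {
  nn <- 2L * tree$n - 1L
  nmut <- .branchMutations(tree, L * mu_site_gen)
  seqs <- matrix(0L, nn, L)
  seqs[nn, ] <- sample.int(4L, L, replace = TRUE)
  pTs <- tstv / (tstv + 1)
  for (node in (nn - 1L):1L) {
    s <- seqs[tree$parent[node], ]
    k <- nmut[node]
    if (k > 0) {
      sites <- sample.int(L, k, replace = TRUE)
      for (site in sites) {
        b <- s[site]
        if (stats::runif(1) < pTs) {
          s[site] <- if (b <= 2L) b + 2L else b - 2L   # A<->G, C<->T
        } else {
          opp <- if (b == 1L || b == 3L) c(2L, 4L) else c(1L, 3L)
          s[site] <- opp[sample.int(2L, 1L)]
        }
      }
    }
    seqs[node, ] <- s
  }
  seqs[seq_len(tree$n), , drop = FALSE]
}

# net allele-size change per branch under SMM/TPM; returns leaf sizes
.evolveMicrosat <- function(tree, mu_gen, p_s, delta_g, anc) {
  nn <- 2L * tree$n - 1L
  nmut <- .branchMutations(tree, mu_gen)
  tot <- sum(nmut)
  step <- numeric(nn)
  if (tot > 0) {
    sz <- ifelse(stats::runif(tot) < p_s, 1L,
                 stats::rgeom(tot, 1 / max(delta_g - 1, 1e-9)) + 2L)
    sgn <- sample(c(-1L, 1L), tot, replace = TRUE)
    step <- unname(vapply(split(sz * sgn,
                                factor(rep(seq_len(nn), nmut),
                                       levels = seq_len(nn))), sum, 0))
  }
  val <- numeric(nn)
  val[nn] <- anc
  for (node in (nn - 1L):1L) {
    v <- val[tree$parent[node]] + step[node]
    if (v < 1) v <- 2 - v        # reflective floor at one repeat
    val[node] <- v
  }
  round(val[seq_len(tree$n)])
}

#' Simulate control-region-like sequences on a river metapopulation
#'
#' Runs a structured coalescent over the configured river network using the
#' female migration rate (maternal marker), then drops finite-sites
#' mutations with transition bias down the genealogy.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return list(alignment, popmap) as produced by
#'   \code{\link{readFastaWithPopmap}}.
#' @export
simulateSequences <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  sites <- config$sites
  keep <- sites$n_seq > 0
  if (!any(keep)) stop("no sequences requested")
  d <- nrow(sites)
  demeOf <- rep(seq_len(d), sites$n_seq)
  M <- .migrationMatrix(d, config$m_f, config$migration_mode,
                        config$edges, sites$pop)
  tree <- .coalTree(demeOf, rep(config$N_f, d), M,
                    .historyScale(config$history))
  sm <- config$seq_model
  mu_gen <- sm$mu_site_year * sm$gen_years
  leaf <- .evolveSequences(tree, sm$L, mu_gen, sm$tstv)
  bases <- c("A", "C", "G", "T")
  seqchar <- apply(leaf, 1, function(r) paste(bases[r], collapse = ""))
  ids <- sprintf("S%03d", seq_along(demeOf))
  aln <- HaplotypeAlignment(stats::setNames(seqchar, ids))
  pm <- PopulationAssignment(
    stats::setNames(sites$pop[demeOf], ids),
    data.frame(pop = sites$pop, lat = sites$lat, lon = sites$lon))
  list(alignment = aln, popmap = pm)
}

#' Simulate diploid microsatellite genotypes on a river metapopulation
#'
#' One independent structured-coalescent genealogy per locus over 2N
#' autosomal gene copies per deme, migrating at the sex-averaged rate
#' \code{(m_f+m_m)/2}; mutations follow the two-phase model (single step
#' with probability \code{p_s}, otherwise a geometric step of mean
#' \code{delta_g}, sign symmetric, reflective floor at one repeat).
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return list(genotypes = \linkS4class{GenotypeMatrix} (with pop slot),
#'   popmap = \linkS4class{PopulationAssignment}).
#' @export
simulateMicrosatellites <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  sites <- config$sites
  d <- nrow(sites)
  nInd <- sites$n_geno
  if (sum(nInd) == 0) stop("no genotypes requested")
  demeOfInd <- rep(seq_len(d), nInd)
  demeOfGene <- rep(demeOfInd, each = 2L)
  mbar <- (config$m_f + config$m_m) / 2
  M <- .migrationMatrix(d, mbar, config$migration_mode,
                        config$edges, sites$pop)
  mm <- config$msat_model
  L <- mm$n_loci
  a1 <- a2 <- matrix(NA_integer_, sum(nInd), L)
  for (l in seq_len(L)) {
    tree <- .coalTree(demeOfGene, rep(2 * config$N, d), M,
                      .historyScale(config$history))
    sizes <- .evolveMicrosat(tree, mm$mu, mm$p_s, mm$delta_g, mm$anc)
    a1[, l] <- sizes[seq(1, length(sizes), by = 2)]
    a2[, l] <- sizes[seq(2, length(sizes), by = 2)]
  }
  ids <- sprintf("G%03d", seq_len(sum(nInd)))
  loci <- sprintf("loc%02d", seq_len(L))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  pop <- stats::setNames(sites$pop[demeOfInd], ids)
  geno <- GenotypeMatrix(a1, a2,
                         stats::setNames(rep(mm$repeat_unit, L), loci),
                         pop = pop)
  pm <- PopulationAssignment(
    pop, data.frame(pop = sites$pop, lat = sites$lat, lon = sites$lon))
  list(genotypes = geno, popmap = pm)
}

#' Study-like synthetic dataset
#'
#' A full synthetic dataset emulating the study design of the motivating
#' system: ten river sampling sites at their published coordinates with 82
#' sequenced and 61 genotyped animals, strong female philopatry and high
#' male mobility (so maternal-marker differentiation exceeds nuclear
#' differentiation), ten dinucleotide microsatellite loci under a two-phase
#' mutation model. Microsatellite sampling uses eight sites (the two
#' smallest sequence-only sites are merged into their river neighbours).
#'
#' @param seed Integer seed.
#' @return list(alignment, popmap, genotypes, msat_popmap, truth) where
#'   \code{truth} records the generating configuration.
#' @export
studyLikeFixture <- function(seed) {
  sites <- data.frame(
    pop = c("IbareMamore", "MiddleMamore", "Bolivar", "ElCorte", "Secure",
            "UpperIbare", "Tijamuchi", "ElAzul", "SanMartin", "Ipurupuru"),
    lat = c(-14.550, -13.445, -12.393, -11.925, -15.333,
            -14.333, -14.450, -11.972, -13.300, -14.302),
    lon = c(-65.003, -65.235, -65.159, -65.054, -65.020,
            -64.900, -65.900, -65.036, -63.417, -65.050),
    n_seq  = c(36, 10, 3, 5, 3, 5, 2, 2, 2, 14),
    n_geno = c(27, 10, 0, 4, 2, 4, 0, 2, 2, 10))
  edges <- data.frame(
    from = c("Secure", "UpperIbare", "Tijamuchi", "Ipurupuru",
             "IbareMamore", "MiddleMamore", "Bolivar", "ElCorte", "ElAzul"),
    to = c("IbareMamore", "IbareMamore", "IbareMamore", "IbareMamore",
           "MiddleMamore", "Bolivar", "ElCorte", "ElAzul", "SanMartin"))
  cfg <- simulationConfig(sites, edges)
  sq <- simulateSequences(cfg, seed)
  ms <- simulateMicrosatellites(cfg, seed + 1L)
  list(alignment = sq$alignment, popmap = sq$popmap,
       genotypes = ms$genotypes, msat_popmap = ms$popmap,
       truth = cfg)
}

# ------------------------------------------------------------------
# fast single-deme SMM/TPM locus, used by the M-ratio equilibrium null
# and as a simulation oracle in tests. Time in units of G generations,
# mutation rate theta/2 per lineage per unit (theta = 2 G mu).
# ------------------------------------------------------------------
.simSMMLocus <- function(n, theta, p_s = 1, delta_g = 3.5) {
  nn <- 2L * n - 1L
  parent <- integer(nn)
  ntime <- numeric(nn)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
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
  blen[nn] <- 0
  nmut <- stats::rpois(nn, theta / 2 * pmax(blen, 0))
  tot <- sum(nmut)
  step <- numeric(nn)
  if (tot > 0) {
    sz <- ifelse(stats::runif(tot) < p_s, 1,
                 stats::rgeom(tot, 1 / max(delta_g - 1, 1e-9)) + 2)
    sgn <- sample(c(-1, 1), tot, replace = TRUE)
    agg <- vapply(split(sz * sgn, factor(rep(seq_len(nn), nmut),
                                         levels = seq_len(nn))), sum, 0)
    step <- unname(agg)
  }
  val <- numeric(nn)
  for (node in (nn - 1L):1L) val[node] <- val[parent[node]] + step[node]
  val[seq_len(n)]
}
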