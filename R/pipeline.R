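#' @include AllClasses.R AllGenerics.R io.R synthetic.R
NULL

# deterministic polynomial rolling hash of a character string (8 hex digits)
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# deterministic stage seed derived from the master seed and stage name
.stageSeed <- function(master, stage) {
  (master + strtoi(substr(.fnv1a(stage), 1, 6), 16L)) %% 2147483647L
}

#' Pipeline configuration
#'
#' @param input NULL to simulate (study-like fixture), or a list with
#'   paths \code{fasta}, \code{popmap}, \code{genepop} (any subset).
#' @param analyses Character vector of stages to run, from
#'   \code{c("seq_diversity", "seq_structure", "msat", "spatial",
#'   "demography", "network")}.
#' @param perms Permutations / randomisations for significance tests.
#' @param mcmc list(demem, batches, iters) for the exact-test chains.
#' @param alpha Significance level for multiple-testing flags.
#' @param n_classes Distance classes for the spatial stage.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param out_dir Output directory (NULL: no files written).
#' @return list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(input = NULL,
                           analyses = c("seq_diversity", "seq_structure",
                                        "msat", "spatial", "demography",
                                        "network"),
                           perms = 1000,
                           mcmc = list(demem = 1000, batches = 10,
                                       iters = 500),
                           alpha = 0.05, n_classes = 5, seed = 1,
                           out_dir = NULL) {
  structure(list(input = input, analyses = analyses, perms = perms,
                 mcmc = mcmc, alpha = alpha, n_classes = n_classes,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Hash of the semantically meaningful pipeline configuration
#' @param config A \code{pipeline_config}.
#' @return 8-hex-digit hash.
#' @export
configHash <- function(config) {
  core <- config[setdiff(names(config), "out_dir")]
  .fnv1a(paste(deparse(core), collapse = ""))
}

#' Run the full multi-marker pipeline
#'
#' Loads (or simulates) the data, then runs the enabled stages in
#' dependency order: sequence diversity and neutrality, sequence
#' differentiation (Hudson statistics, contingency, pairwise exact tests,
#' AMOVA), microsatellite structure (diversity, HWE, F-statistics, Nei
#' distance, exact differentiation, private alleles, assignment),
#' spatial structure (Mantel, correlogram, distogram), microsatellite
#' demography (imbalance index, expansion index, M-ratio, intralocus and
#' interlocus tests) and the median-joining network. Every stage uses a
#' seed derived deterministically from the master seed, so the whole run
#' is reproducible. Results are written as TSV reports when
#' \code{out_dir} is set, stamped with the configuration hash.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Nested list of stage results of class \code{pipeline_result},
#'   with \code{config_hash} and \code{log} (stage timings).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config_hash = configHash(config))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (is.null(config$input)) {
    fx <- studyLikeFixture(.stageSeed(config$seed, "simulate"))
    aln <- fx$alignment; popmap <- fx$popmap
    geno <- fx$genotypes; msatPm <- fx$msat_popmap
  } else {
    aln <- popmap <- geno <- msatPm <- NULL
    if (!is.null(config$input$fasta)) {
      rd <- readFastaWithPopmap(config$input$fasta, config$input$popmap)
      aln <- rd$alignment; popmap <- rd$popmap
    }
    if (!is.null(config$input$genepop)) {
      geno <- readGenepop(config$input$genepop)
      msatPm <- if (!is.null(config$input$msat_popmap))
        readPopmap(config$input$msat_popmap) else NULL
    }
  }
  log$load <- tic() - t0
  on <- function(stage) stage %in% config$analyses
  if (!is.null(aln) && on("seq_diversity")) {
    t0 <- tic()
    res$seq_diversity <- list(
      diversity = diversityStats(aln),
      neutrality = neutralityTests(aln, coalescent_reps = config$perms,
                                   seed = .stageSeed(config$seed, "neutrality")),
      mismatch = mismatchDistribution(aln,
                                      bootstrap_reps = min(config$perms, 200),
                                      seed = .stageSeed(config$seed, "mismatch")))
    log$seq_diversity <- tic() - t0
  }
  if (!is.null(aln) && on("seq_structure")) {
    t0 <- tic()
    het <- hudsonHeterogeneity(aln, popmap, perms = config$perms,
                               seed = .stageSeed(config$seed, "hudson"))
    cont <- haplotypeContingency(aln, popmap,
                                 seed = .stageSeed(config$seed, "contingency"))
    pw <- pairwiseExactTests(aln, popmap, mcmc = config$mcmc,
                             seed = .stageSeed(config$seed, "pairwise"))
    k2p <- kimura2pMatrix(aln, popmap)
    res$seq_structure <- list(heterogeneity = het, contingency = cont,
                              pairwise = pw, k2p = k2p,
                              bonferroni_alpha = config$alpha / pw$npairs)
    log$seq_structure <- tic() - t0
  }
  if (!is.null(geno) && on("msat")) {
    t0 <- tic()
    res$msat <- list(
      diversity = msatDiversity(geno, msatPm),
      hwe = hweTests(geno, msatPm, mcmc = config$mcmc,
                     seed = .stageSeed(config$seed, "hwe")),
      fstats = fStats(geno, msatPm, randomizations = config$perms,
                      seed = .stageSeed(config$seed, "fstats")),
      nei = neiDistance(geno, msatPm),
      exact_genic = exactDifferentiation(geno, msatPm, "genic",
                                         mcmc = config$mcmc,
                                         seed = .stageSeed(config$seed, "genic")),
      private = privateAlleleNm(geno, msatPm))
    log$msat <- tic() - t0
  }
  if (!is.null(aln) && on("spatial")) {
    t0 <- tic()
    geo <- geoDistanceMatrix(popmap)
    pop <- populations(popmap)[sampleIDs(aln)]
    d <- .pairwiseDiffs(aln)
    pops <- rownames(geo)
    gd <- matrix(0, length(pops), length(pops), dimnames = dimnames(geo))
    for (a in seq_along(pops)) for (b in seq_along(pops)) {
      if (a >= b) next
      ia <- which(pop == pops[a]); ib <- which(pop == pops[b])
      gd[a, b] <- gd[b, a] <- mean(d[ia, ib])
    }
    cc <- siteCoordinates(popmap)
    lat <- cc$lat[match(pop, cc$pop)]
    lon <- cc$lon[match(pop, cc$pop)]
    res$spatial <- list(
      mantel = mantelTest(gd, geo, perms = config$perms,
                          seed = .stageSeed(config$seed, "mantel")),
      correlogram = ayCorrelogram(d, lat, lon, n_classes = config$n_classes,
                                  perms = config$perms,
                                  seed = .stageSeed(config$seed, "ay")))
    log$spatial <- tic() - t0
  }
  if (!is.null(geno) && on("demography")) {
    t0 <- tic()
    gw <- gwMRatio(geno)
    res$demography <- list(
      kimmel = kimmelBeta(geno),
      zhivotovsky = zhivotovskySk(geno),
      gw = gw,
      reich_k = reichKTest(geno),
      reich_g = reichGTest(geno, reps = max(200, config$perms / 10),
                           seed = .stageSeed(config$seed, "reich_g")))
    log$demography <- tic() - t0
  }
  if (!is.null(aln) && on("network")) {
    t0 <- tic()
    net <- medianJoiningNetwork(aln)
    root <- names(which.max(net$counts))   # most frequent sampled haplotype
    res$network <- list(network = net,
                        rho = rhoDating(net, root))
    log$network <- tic() - t0
  }
  res$log <- log
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) {
    writeReport(unclass(res)[setdiff(names(res), c("log", "config_hash"))],
                config$out_dir)
    writeLines(c(paste("config_hash", res$config_hash),
                 paste("seed", config$seed),
                 paste("stages", paste(names(log), collapse = " "))),
               file.path(config$out_dir, "run_info.txt"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run", x$config_hash, "- stages:",
      paste(setdiff(names(x), c("config_hash", "log")), collapse = ", "),
      "\n")
  invisible(x)
}
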