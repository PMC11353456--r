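#' @include AllClasses.R
NULL

#' Sample identifiers of a data container
#' @param x A data container.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Number of aligned sites
#' @param x A \linkS4class{HaplotypeAlignment}.
#' @return Integer alignment width.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Population labels per sample
#' @param x A container holding a sample -> population map.
#' @return Named character vector.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Sampling-site coordinates
#' @param x A \linkS4class{PopulationAssignment}.
#' @return data.frame with columns pop, lat, lon.
#' @export
setGeneric("siteCoordinates", function(x) standardGeneric("siteCoordinates"))

#' Locus names
#' @param x A \linkS4class{GenotypeMatrix}.
#' @return Character vector.
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' Per-locus repeat unit (bp)
#' @param x A \linkS4class{GenotypeMatrix}.
#' @return Named integer vector.
#' @export
setGeneric("repeatUnits", function(x) standardGeneric("repeatUnits"))

#' Allele matrices of a genotype container
#' @param x A \linkS4class{GenotypeMatrix}.
#' @param which 1 or 2, which allele of the unordered pair.
#' @return Integer matrix samples x loci (repeat units).
#' @export
setGeneric("alleleMatrix", function(x, which = 1) standardGeneric("alleleMatrix"))

setMethod("sampleIDs", "HaplotypeAlignment", function(x) names(x@seqs))
setMethod("sampleIDs", "PopulationAssignment", function(x) names(x@pop))
setMethod("sampleIDs", "GenotypeMatrix", function(x) rownames(x@a1))

setMethod("nSites", "HaplotypeAlignment",
          function(x) unique(Biostrings::width(x@seqs)))

setMethod("populations", "PopulationAssignment", function(x) x@pop)
setMethod("populations", "GenotypeMatrix", function(x) x@pop)

setMethod("siteCoordinates", "PopulationAssignment", function(x) x@coords)

setMethod("lociNames", "GenotypeMatrix", function(x) colnames(x@a1))
setMethod("repeatUnits", "GenotypeMatrix", function(x) x@repeatUnit)
setMethod("alleleMatrix", "GenotypeMatrix",
          function(x, which = 1) if (which == 1) x@a1 else x@a2)

#' @export
setMethod("length", "HaplotypeAlignment", function(x) length(x@seqs))

setMethod("show", "HaplotypeAlignment", function(object) {
  cat("HaplotypeAlignment:", length(object@seqs), "sequences x",
      nSites(object), "sites\n")
  h <- haplotypeIndex(object)
  cat("  distinct haplotypes:", max(h), "\n")
})

setMethod("show", "PopulationAssignment", function(object) {
  tb <- table(object@pop)
  cat("PopulationAssignment:", length(object@pop), "samples,",
      length(tb), "populations\n")
  print(tb)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@a1), "individuals x",
      ncol(object@a1), "loci\n")
  miss <- mean(is.na(object@a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
})

# ---- internal helpers shared across modules ----

# character matrix view of an alignment (samples x sites)
.alnMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln@seqs), ""))
  rownames(m) <- names(aln@seqs)
  m
}

# columns free of gaps and Ns (complete deletion site set)
.cleanSites <- function(m) {
  which(colSums(m == "-" | m == "N") == 0L)
}

#' Haplotype index of each sequence
#'
#' Assigns each sequence an integer haplotype id; sequences identical at
#' the gap/N-free site set share an id. Ids are ordered by first occurrence.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @return Integer vector, one entry per sample.
#' @export
haplotypeIndex <- function(aln) {
  m <- .alnMatrix(aln)
  keep <- .cleanSites(m)
  key <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  match(key, unique(key))
}

# pairwise difference matrix on the clean site set
.pairwiseDiffs <- function(aln) {
  m <- .alnMatrix(aln)
  keep <- .cleanSites(m)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# permutation p-value convention used everywhere: (exceedances + 1)/(B + 1)
.permP <- function(null, obs, side = c("greater", "less")) {
  side <- match.arg(side)
  ex <- if (side == "greater") sum(null >= obs) else sum(null <= obs)
  (ex + 1) / (length(null) + 1)
}

.checkPopmap <- function(x, popmap) {
  ids <- sampleIDs(x)
  if (!all(ids %in% names(populations(popmap))))
    stop("samples missing from population map: ",
         paste(setdiff(ids, names(populations(popmap))), collapse = ", "))
  populations(popmap)[ids]
}
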