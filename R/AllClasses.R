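#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Aligned haplotype sequences
#'
#' An aligned set of equal-length sequences over \code{A,C,G,T,-,N}, the
#' substrate of every sequence statistic in the package (segregating sites,
#' nucleotide diversity, haplotype identity, Hudson statistics, networks).
#' Backed by a \linkS4class{DNAStringSet}; sample identifiers are the
#' element names and must be unique.
#'
#' @slot seqs A \code{DNAStringSet} of equal width, named by sample.
#' @export
setClass("HaplotypeAlignment", slots = c(seqs = "DNAStringSet"))

setValidity("HaplotypeAlignment", function(object) {
  s <- object@seqs
  if (length(s) == 0L) return("alignment has no sequences")
  ids <- names(s)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("every sequence needs a sample id")
  if (anyDuplicated(ids)) return("sample ids must be unique")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L)
    return("sequences differ in length (alignment error)")
  chars <- unique(strsplit(paste(as.character(s), collapse = ""), "")[[1]])
  bad <- setdiff(chars, ALN_ALPHABET)
  if (length(bad))
    return(paste0("illegal character(s) in alignment: ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a HaplotypeAlignment
#'
#' @param seqs Named character vector of aligned sequences, or a
#'   \code{DNAStringSet}.
#' @param sample_ids Optional ids overriding \code{names(seqs)}.
#' @return A \linkS4class{HaplotypeAlignment}.
#' @export
HaplotypeAlignment <- function(seqs, sample_ids = NULL) {
  if (is.character(seqs)) {
    if (!is.null(sample_ids)) names(seqs) <- sample_ids
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  } else if (!is.null(sample_ids)) {
    names(seqs) <- sample_ids
  }
  new("HaplotypeAlignment", seqs = seqs)
}

#' Sample-to-population map with site geography
#'
#' Maps every sample to a population label and every population to a
#' sampling-site coordinate (decimal degrees, negative = south/west).
#'
#' @slot pop Named character vector: sample id -> population label.
#' @slot coords data.frame with columns \code{pop}, \code{lat}, \code{lon}.
#' @export
setClass("PopulationAssignment",
         slots = c(pop = "character", coords = "data.frame"))

setValidity("PopulationAssignment", function(object) {
  if (is.null(names(object@pop)) || anyDuplicated(names(object@pop)))
    return("pop must be named by unique sample ids")
  cc <- object@coords
  if (!all(c("pop", "lat", "lon") %in% names(cc)))
    return("coords needs columns pop, lat, lon")
  if (!all(unique(object@pop) %in% cc$pop))
    return("every population needs a coordinate row")
  if (anyDuplicated(cc$pop)) return("duplicate population in coords")
  if (!all(is.finite(cc$lat)) || !all(is.finite(cc$lon)))
    return("coordinates must be finite")
  TRUE
})

#' Construct a PopulationAssignment
#'
#' @param pop Named character vector, sample id -> population label.
#' @param coords data.frame with columns \code{pop,lat,lon} (one row per
#'   population).
#' @return A \linkS4class{PopulationAssignment}.
#' @export
PopulationAssignment <- function(pop, coords) {
  coords <- as.data.frame(coords)[, c("pop", "lat", "lon")]
  coords$pop <- as.character(coords$pop)
  new("PopulationAssignment", pop = pop, coords = coords)
}

#' Diploid microsatellite genotypes
#'
#' Individuals by loci, each cell an unordered pair of allele lengths in
#' repeat units (allele size in bp divided by the per-locus repeat unit);
#' missing genotypes are \code{NA}. All demographic tests (M-ratio,
#' imbalance index, expansion index) are defined on repeat counts, hence
#' the internal representation.
#'
#' @slot a1 Integer matrix (samples x loci), first allele, repeat units.
#' @slot a2 Integer matrix, second allele.
#' @slot repeatUnit Named integer vector, bp per repeat, per locus.
#' @slot pop Named character vector sample -> population (may be empty;
#'   analyses can take an explicit \linkS4class{PopulationAssignment}).
#' @export
setClass("GenotypeMatrix",
         slots = c(a1 = "matrix", a2 = "matrix",
                   repeatUnit = "integer", pop = "character"))

setValidity("GenotypeMatrix", function(object) {
  a1 <- object@a1; a2 <- object@a2
  if (!identical(dim(a1), dim(a2))) return("a1/a2 dimensions differ")
  if (is.null(rownames(a1)) || anyDuplicated(rownames(a1)))
    return("samples must be uniquely named")
  if (is.null(colnames(a1)) || anyDuplicated(colnames(a1)))
    return("loci must be uniquely named")
  if (!identical(is.na(a1), is.na(a2)))
    return("half-missing genotypes are not allowed")
  ok1 <- a1[!is.na(a1)]; ok2 <- a2[!is.na(a2)]
  if (length(ok1) && (any(ok1 < 1) || any(ok2 < 1)))
    return("allele lengths must be positive (repeat units)")
  if (!all(colnames(a1) %in% names(object@repeatUnit)))
    return("every locus needs a repeat unit")
  if (length(object@pop) &&
      !all(rownames(a1) %in% names(object@pop)))
    return("pop slot must cover all samples")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param a1,a2 Integer matrices of allele lengths in repeat units
#'   (samples x loci, NA = missing; missingness must agree).
#' @param repeatUnit Named integer vector (bp per repeat) covering all loci.
#' @param pop Optional named character vector sample -> population.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(a1, a2, repeatUnit, pop = character(0)) {
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  # store unordered: smaller allele first
  sw <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  new("GenotypeMatrix", a1 = a1, a2 = a2,
      repeatUnit = vapply(repeatUnit, as.integer, integer(1)),
      pop = pop)
}
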