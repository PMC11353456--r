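#' @include AllClasses.R AllGenerics.R
NULL

#' Read an aligned FASTA together with its population map
#'
#' The popmap CSV must have columns \code{sample,population,lat,lon}; one
#' row per sample (site coordinates repeated). Every FASTA record must
#' appear in the popmap.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param popmap_path Path to the popmap CSV.
#' @return list with elements \code{alignment}
#'   (\linkS4class{HaplotypeAlignment}) and \code{popmap}
#'   (\linkS4class{PopulationAssignment}).
#' @export
readFastaWithPopmap <- function(fasta_path, popmap_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  aln <- new("HaplotypeAlignment", seqs = seqs)
  pm <- readPopmap(popmap_path)
  missing <- setdiff(sampleIDs(aln), names(populations(pm)))
  if (length(missing))
    stop("FASTA records absent from popmap: ",
         paste(missing, collapse = ", "))
  list(alignment = aln, popmap = pm)
}

#' Read a popmap CSV
#'
#' @param path CSV with columns \code{sample,population,lat,lon}.
#' @return A \linkS4class{PopulationAssignment}.
#' @export
readPopmap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("popmap needs columns sample,population,lat,lon")
  pop <- stats::setNames(as.character(df$population), df$sample)
  coords <- unique(df[, c("population", "lat", "lon")])
  names(coords)[1] <- "pop"
  PopulationAssignment(pop, coords)
}

#' Write a popmap CSV
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @param path Output path.
#' @export
writePopmap <- function(popmap, path) {
  cc <- siteCoordinates(popmap)
  pop <- populations(popmap)
  df <- data.frame(sample = names(pop), population = unname(pop),
                   lat = cc$lat[match(pop, cc$pop)],
                   lon = cc$lon[match(pop, cc$pop)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an alignment as FASTA
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param path Output path.
#' @export
writeFastaAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln@seqs, path, width = 70L)
  invisible(path)
}

#' Read diploid microsatellite genotypes in Genepop format
#'
#' Accepts both 2- and 3-digit allele coding (detected from token length);
#' \code{00}/\code{000} marks a missing allele. Allele sizes are divided by
#' the per-locus repeat unit, so the returned container holds repeat
#' counts. Population labels are taken from the name of the last
#' individual in each \code{Pop} block (the Genepop convention), falling
#' back to \code{pop1, pop2, ...}.
#'
#' @param path Genepop file.
#' @param repeat_units Named integer vector (bp per repeat) per locus, or a
#'   single value recycled over all loci.
#' @return A \linkS4class{GenotypeMatrix} with the \code{pop} slot filled.
#' @export
readGenepop <- function(path, repeat_units = 2L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too short")
  body <- lines[-1]                       # first line is a title
  popIdx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(popIdx)) stop("no Pop line found")
  loci_block <- body[seq_len(popIdx[1] - 1)]
  loci <- unlist(strsplit(loci_block, "[,\\s]+"))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (length(repeat_units) == 1L)
    repeat_units <- stats::setNames(rep(as.integer(repeat_units), L), loci)
  if (!all(loci %in% names(repeat_units)))
    stop("repeat_units must cover all loci")

  samples <- character(0); pops <- character(0)
  rows1 <- list(); rows2 <- list()
  popno <- 0L; lastInPop <- integer(0)
  for (k in seq(popIdx[1], length(body))) {
    ln <- body[k]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      popno <- popno + 1L
      lastInPop[popno] <- length(samples)
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("parse error (no comma): ", ln)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("ragged row for ", id, ": ", length(toks), " loci, expected ", L)
    digits <- nchar(toks[1]) / 2
    if (!digits %in% c(2, 3)) stop("allele coding must be 2- or 3-digit")
    x1 <- as.integer(substr(toks, 1, digits))
    x2 <- as.integer(substr(toks, digits + 1, 2 * digits))
    x1[x1 == 0L] <- NA; x2[x2 == 0L] <- NA
    # half-missing is treated as missing
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA; x2[miss] <- NA
    ru <- repeat_units[loci]
    bad <- !is.na(x1) & ((x1 %% ru) != 0L | (x2 %% ru) != 0L)
    if (any(bad))
      stop("allele size not divisible by repeat unit at locus ",
           paste(loci[bad], collapse = ", "), " for ", id)
    samples <- c(samples, id)
    pops <- c(pops, as.character(popno))
    rows1[[length(rows1) + 1]] <- x1 %/% ru
    rows2[[length(rows2) + 1]] <- x2 %/% ru
  }
  lastInPop[popno + 1L] <- length(samples)
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  if (anyDuplicated(samples))
    samples <- make.unique(samples, sep = "_")
  dimnames(a1) <- dimnames(a2) <- list(samples, loci)
  # genepop convention: pop label = last individual's name in the block
  popLabels <- character(popno)
  for (p in seq_len(popno)) {
    last <- lastInPop[p + 1L]
    popLabels[p] <- if (last > lastInPop[p]) samples[last] else paste0("pop", p)
  }
  popLabels <- make.unique(popLabels, sep = "_")
  pop <- stats::setNames(popLabels[as.integer(pops)], samples)
  GenotypeMatrix(a1, a2, repeat_units[loci], pop = pop)
}

#' Write genotypes in Genepop 3-digit format
#'
#' Allele sizes are written back in base pairs (repeat units times the
#' per-locus repeat unit); missing genotypes become \code{000000}.
#'
#' @param geno A \linkS4class{GenotypeMatrix} with populations in its
#'   \code{pop} slot (or supplied via \code{popmap}).
#' @param path Output path.
#' @param popmap Optional \linkS4class{PopulationAssignment} overriding the
#'   \code{pop} slot.
#' @param title Title line.
#' @export
writeGenepop <- function(geno, path, popmap = NULL,
                         title = "riverpopgen genotypes") {
  pop <- if (!is.null(popmap)) .checkPopmap(geno, popmap) else populations(geno)
  if (!length(pop)) stop("no population information to write")
  a1 <- geno@a1; a2 <- geno@a2
  ru <- geno@repeatUnit[colnames(a1)]
  out <- c(title, colnames(a1))
  for (p in unique(pop)) {
    out <- c(out, "Pop")
    for (i in which(pop == p)) {
      g1 <- a1[i, ] * ru; g2 <- a2[i, ] * ru
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      out <- c(out, paste0(rownames(a1)[i], " ,  ",
                           paste(sprintf("%03d%03d", g1, g2), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write analysis result bundles as TSV reports
#'
#' Every table-like element of \code{results} (data.frame or matrix) is
#' written as \code{<name>.tsv}; a \code{summary.txt} collects scalar
#' elements. Output is deterministic: elements are written in sorted name
#' order and numbers formatted with a fixed format.
#'
#' @param results Named list of result bundles; nesting is flattened with
#'   \code{.}-separated names.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(results, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  flat <- .flattenResults(results)
  tables <- flat[vapply(flat, function(x)
    is.data.frame(x) || is.matrix(x), TRUE)]
  scalars <- flat[vapply(flat, function(x)
    is.atomic(x) && !is.matrix(x) && length(x) <= 12, TRUE)]
  paths <- character(0)
  for (nm in sort(names(tables))) {
    p <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv"))
    x <- tables[[nm]]
    if (is.matrix(x)) x <- as.data.frame(x)
    num <- vapply(x, is.numeric, TRUE)
    x[num] <- lapply(x[num], function(v) formatC(v, digits = 6, format = "g"))
    utils::write.table(x, p, sep = "\t", quote = FALSE,
                       row.names = !is.null(rownames(tables[[nm]])) &&
                         !identical(rownames(tables[[nm]]),
                                    as.character(seq_len(nrow(x)))))
    paths <- c(paths, p)
  }
  sp <- file.path(out_dir, "summary.txt")
  con <- file(sp, "w"); on.exit(close(con))
  for (nm in sort(names(scalars))) {
    v <- scalars[[nm]]
    vs <- if (is.numeric(v)) formatC(v, digits = 6, format = "g") else as.character(v)
    writeLines(paste0(nm, "\t", paste(vs, collapse = "\t")), con)
  }
  invisible(c(paths, sp))
}

.flattenResults <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    full <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    el <- x[[nm]]
    if (is.list(el) && !is.data.frame(el)) {
      out <- c(out, .flattenResults(el, full))
    } else {
      out[[full]] <- el
    }
  }
  out
}
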