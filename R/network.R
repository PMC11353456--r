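#' @include AllClasses.R AllGenerics.R
NULL

# Hamming distance matrix between rows of a character matrix
.hamming <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# minimum-spanning-network edges: all inter-component links of minimal
# length encountered while growing components Kruskal-style, relaxed by
# epsilon
.msnEdges <- function(d, epsilon = 0) {
  n <- nrow(d)
  comp <- seq_len(n)
  edges <- NULL
  lens <- sort(unique(d[upper.tri(d)]))
  for (len in lens) {
    idx <- which(d == len & upper.tri(d), arr.ind = TRUE)
    # connect every pair at distance <= current connection length + epsilon
    newly <- idx[comp[idx[, 1]] != comp[idx[, 2]], , drop = FALSE]
    if (!nrow(newly)) next
    keepLen <- d[upper.tri(d)]
    cand <- which(d <= len + epsilon & upper.tri(d), arr.ind = TRUE)
    cand <- cand[comp[cand[, 1]] != comp[cand[, 2]], , drop = FALSE]
    edges <- rbind(edges, cbind(cand, w = d[cand]))
    # merge components
    for (r in seq_len(nrow(cand))) {
      ci <- comp[cand[r, 1]]; cj <- comp[cand[r, 2]]
      comp[comp == cj] <- ci
    }
    if (length(unique(comp)) == 1) break
  }
  unique(edges)
}

# quasi-median (positionwise majority, ties resolved towards the first
# sequence for determinism) of three aligned sequences
.medianSeq <- function(a, b, c) {
  out <- a
  agree_bc <- b == c
  out[agree_bc & (a != b)] <- b[agree_bc & (a != b)]
  out
}

#' Median-joining haplotype network
#'
#' Builds the median-joining network of distinct haplotypes: iterate a
#' minimum-spanning-network construction (with tolerance epsilon), add
#' median (Steiner) consensus sequences of triplets when they reduce the
#' local connection cost, and prune median vectors no longer needed
#' (unsampled nodes of degree below three are removed, their neighbours
#' reconnected). Ties among equal-cost medians are broken by lexicographic
#' sequence order for determinism.
#'
#' @param aln A \linkS4class{HaplotypeAlignment} (samples; haplotypes are
#'   collapsed internally) or a character vector of distinct sequences.
#' @param counts Optional counts per haplotype when \code{aln} is a
#'   character vector.
#' @param epsilon Tolerance of the minimum-spanning-network step.
#' @return list of class \code{mj_network}: \code{seqs} (node sequences),
#'   \code{counts} (0 for median vectors), \code{sampled} (logical),
#'   \code{edges} (data.frame from, to, steps), \code{epsilon}.
#' @export
medianJoiningNetwork <- function(aln, counts = NULL, epsilon = 0) {
  if (is(aln, "HaplotypeAlignment")) {
    hm <- .alnMatrix(aln)
    hm <- hm[, .cleanSites(hm), drop = FALSE]
    key <- apply(hm, 1, paste, collapse = "")
    tb <- table(factor(key, levels = unique(key)))
    seqs <- names(tb)
    counts <- as.integer(tb)
  } else {
    seqs <- aln
    if (is.null(counts)) counts <- rep(1L, length(seqs))
  }
  if (length(seqs) < 2) stop("need >= 2 distinct haplotypes")
  if (length(unique(nchar(seqs))) != 1) stop("haplotypes not aligned")
  labels <- paste0("H", seq_along(seqs))
  sampled <- rep(TRUE, length(seqs))
  mseq <- do.call(rbind, strsplit(seqs, ""))
  repeat {
    d <- .hamming(mseq)
    edges <- .msnEdges(d, epsilon)
    adj <- matrix(FALSE, nrow(mseq), nrow(mseq))
    adj[edges[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    # candidate medians come from triples connected through a common
    # neighbour in the current spanning network; a median is useful when
    # its Steiner cost undercuts the triple's present connection cost
    present <- apply(mseq, 1, paste, collapse = "")
    cand <- character(0); cost <- numeric(0)
    nv <- nrow(mseq)
    for (u in seq_len(nv)) {
      nb <- which(adj[u, ])
      if (length(nb) < 2) next
      prs <- utils::combn(nb, 2)
      for (c2 in seq_len(ncol(prs))) {
        v <- prs[1, c2]; w <- prs[2, c2]
        med <- .medianSeq(mseq[u, ], mseq[v, ], mseq[w, ])
        ms <- paste(med, collapse = "")
        if (ms %in% present) next
        steiner <- sum(mseq[u, ] != med) + sum(mseq[v, ] != med) +
          sum(mseq[w, ] != med)
        lambda <- d[u, v] + d[u, w]     # present connection through u
        if (steiner < lambda) { cand <- c(cand, ms); cost <- c(cost, steiner) }
      }
    }
    if (!length(cand)) break
    # add the minimal-cost medians of this round (epsilon-relaxed),
    # lexicographic order for determinism
    keep <- sort(unique(cand[cost <= min(cost) + epsilon]))
    for (new in keep) {
      mseq <- rbind(mseq, strsplit(new, "")[[1]])
      sampled <- c(sampled, FALSE)
      counts <- c(counts, 0L)
      labels <- c(labels, paste0("mv", sum(!sampled)))
    }
  }
  d <- .hamming(mseq)
  edges <- .msnEdges(d, epsilon)
  # prune unsampled nodes of degree <= 2 (a degree-2 median on a geodesic
  # is redundant: its neighbours are directly connectable at equal cost)
  repeat {
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(mseq))
    drop <- which(!sampled & deg <= 2)
    if (!length(drop)) break
    v <- drop[1]
    nb <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
    edges <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    if (length(nb) == 2) {
      e <- sort(nb)
      if (!any(edges[, 1] == e[1] & edges[, 2] == e[2]))
        edges <- rbind(edges, c(e[1], e[2], d[e[1], e[2]]))
    }
    keep <- setdiff(seq_len(nrow(mseq)), v)
    remap <- match(seq_len(nrow(mseq)), keep)
    mseq <- mseq[keep, , drop = FALSE]
    sampled <- sampled[keep]; counts <- counts[keep]; labels <- labels[keep]
    edges[, 1] <- remap[edges[, 1]]; edges[, 2] <- remap[edges[, 2]]
    d <- .hamming(mseq)
  }
  ed <- data.frame(from = labels[edges[, 1]], to = labels[edges[, 2]],
                   steps = edges[, 3])
  structure(list(seqs = stats::setNames(apply(mseq, 1, paste, collapse = ""),
                                        labels),
                 counts = stats::setNames(counts, labels),
                 sampled = stats::setNames(sampled, labels),
                 edges = ed, epsilon = epsilon),
            class = "mj_network")
}


#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("Median-joining network: %d nodes (%d sampled, %d median vectors), %d edges\n",
              length(x$seqs), sum(x$sampled), sum(!x$sampled), nrow(x$edges)))
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Parsimony cost of a network
#'
#' The total mutational cost of the cheapest subtree of the network that
#' connects every sampled haplotype (median vectors are used only where
#' they shorten the tree): the minimum spanning tree over the network's
#' nodes with unsampled leaves stripped.
#'
#' @param net A \code{mj_network}.
#' @return Total steps of the spanning subtree.
#' @export
networkCost <- function(net) {
  labels <- names(net$seqs)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = labels)
  mst <- igraph::mst(g, weights = net$edges$steps)
  repeat {
    deg <- igraph::degree(mst)
    drop <- names(deg)[deg <= 1 & !net$sampled[names(deg)]]
    if (!length(drop)) break
    mst <- igraph::delete_vertices(mst, drop)
  }
  sum(igraph::E(mst)$steps)
}

#' Rho-statistic dating on a haplotype network
#'
#' rho is the average mutational-step distance from a designated ancestral
#' node to the sampled individuals (haplotype counts as weights), computed
#' over the shortest-path tree from the root. Its standard error follows
#' the branch-weighted estimator sigma^2 = sum over branches of
#' (descendants^2 x length) / n^2. Time is rho times the years represented
#' by one mutation.
#'
#' @param net A \code{mj_network}.
#' @param root Node label of the assumed ancestral haplotype.
#' @param years_per_mutation Years represented by one mutational step. The
#'   default corresponds to a 400-site fragment evolving at 1.5e-8
#'   substitutions/site/year (1/(400 x 1.5e-8) ~ 166,667 years).
#' @return list of class \code{rho_result}: \code{rho, sigma_rho, T,
#'   T_sd, years_per_mutation, n}.
#' @export
rhoDating <- function(net, root, years_per_mutation = 166667) {
  labels <- names(net$seqs)
  if (!root %in% labels) stop("root not present in network")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = labels)
  if (igraph::components(g)$no > 1) stop("network is disconnected")
  sp <- igraph::distances(g, v = root, weights = net$edges$steps)[1, labels]
  n <- sum(net$counts)
  rho <- sum(net$counts * sp) / n
  # shortest-path tree for the variance: parent of each node on a
  # shortest path towards the root (deterministic: first minimal)
  paths <- igraph::shortest_paths(g, from = root, to = labels,
                                  weights = net$edges$steps)$vpath
  # accumulate: branch (parent -> child) carries all sampled descendants
  # reached through it
  desc <- stats::setNames(rep(0, length(labels)), labels)
  blen <- stats::setNames(rep(0, length(labels)), labels)
  for (vi in seq_along(labels)) {
    pth <- names(unlist(paths[[vi]]))
    if (length(pth) < 2) next
    w <- net$counts[labels[vi]]
    for (s in 2:length(pth)) {
      desc[pth[s]] <- desc[pth[s]] + w
      blen[pth[s]] <- sp[pth[s]] - sp[pth[s - 1]]
    }
  }
  sigma2 <- sum(desc^2 * blen) / n^2
  structure(list(rho = rho, sigma_rho = sqrt(sigma2),
                 T = rho * years_per_mutation,
                 T_sd = sqrt(sigma2) * years_per_mutation,
                 years_per_mutation = years_per_mutation, n = n),
            class = "rho_result")
}

#' @export
print.rho_result <- function(x, ...) {
  cat(sprintf("rho dating: rho = %.3f +/- %.3f, T = %.0f +/- %.0f years (%.0f y/mutation, n = %d)\n",
              x$rho, x$sigma_rho, x$T, x$T_sd, x$years_per_mutation, x$n))
  invisible(x)
}

#' Write a network as edge-list TSV and a GML-style text file
#' @param net A \code{mj_network}.
#' @param out_prefix Path prefix; writes \code{<prefix>_edges.tsv} and
#'   \code{<prefix>.gml}.
#' @export
writeNetwork <- function(net, out_prefix) {
  utils::write.table(net$edges, paste0(out_prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(paste0(out_prefix, ".gml"), "w")
  on.exit(close(con))
  writeLines("graph [", con)
  for (i in seq_along(net$seqs)) {
    writeLines(sprintf('  node [ id %d label "%s" count %d sampled %d ]',
                       i, names(net$seqs)[i], net$counts[i],
                       as.integer(net$sampled[i])), con)
  }
  for (r in seq_len(nrow(net$edges))) {
    writeLines(sprintf("  edge [ source %d target %d steps %d ]",
                       match(net$edges$from[r], names(net$seqs)),
                       match(net$edges$to[r], names(net$seqs)),
                       as.integer(net$edges$steps[r])), con)
  }
  writeLines("]", con)
  invisible(out_prefix)
}
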