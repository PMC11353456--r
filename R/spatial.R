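#' @include AllClasses.R AllGenerics.R
#' @importFrom geosphere distHaversine
#' @importFrom igraph graph_from_data_frame distances
NULL

#' Geographic distance matrix between sampling sites
#'
#' Great-circle (haversine) distances in km, or shortest-path distances
#' along a river network given as an edge list with km weights (every site
#' must appear as a network node).
#'
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @param mode "great_circle" or "river_network".
#' @param network data.frame with columns \code{from,to,km} (river mode).
#' @return Symmetric matrix (km), populations in popmap order.
#' @export
geoDistanceMatrix <- function(popmap, mode = c("great_circle", "river_network"),
                              network = NULL) {
  mode <- match.arg(mode)
  cc <- siteCoordinates(popmap)
  P <- nrow(cc)
  d <- matrix(0, P, P, dimnames = list(cc$pop, cc$pop))
  if (mode == "great_circle") {
    for (i in seq_len(P - 1)) for (j in (i + 1):P) {
      d[i, j] <- d[j, i] <- geosphere::distHaversine(
        c(cc$lon[i], cc$lat[i]), c(cc$lon[j], cc$lat[j])) / 1000
    }
  } else {
    if (is.null(network)) stop("river mode needs a network edge list")
    g <- igraph::graph_from_data_frame(
      data.frame(from = network$from, to = network$to),
      directed = FALSE)
    if (!all(cc$pop %in% igraph::V(g)$name))
      stop("site not snapped to a network node: ",
           paste(setdiff(cc$pop, igraph::V(g)$name), collapse = ", "))
    dd <- igraph::distances(g, weights = network$km)
    dd <- dd[cc$pop, cc$pop]
    if (any(!is.finite(dd)))
      stop("unreachable node pair in the river network")
    d <- dd
    dimnames(d) <- list(cc$pop, cc$pop)
  }
  d
}

# great-circle distances (km) between per-sample coordinate rows
.sampleGeoDist <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- geosphere::distHaversine(
      c(lon[i], lat[i]), c(lon[j], lat[j])) / 1000
  d
}

#' Normalized Mantel test
#'
#' Pearson correlation of the off-diagonal upper triangles of two distance
#' matrices (the normalized Mantel statistic), with significance from
#' joint row/column permutations of the second matrix;
#' p = (exceedances+1)/(permutations+1).
#'
#' @param gen_dist,geo_dist Symmetric matrices with zero diagonal.
#' @param perms Number of permutations.
#' @param seed Integer seed.
#' @param alternative "greater" (isolation by distance), "less", or
#'   "two.sided".
#' @param log_geo Log-transform geographic distances (off-diagonal; zero
#'   distances are offset by the smallest positive entry).
#' @return list of class \code{mantel_result}: \code{r, p, perms,
#'   defined}.
#' @export
mantelTest <- function(gen_dist, geo_dist, perms = 10000, seed = 1,
                       alternative = c("greater", "less", "two.sided"),
                       log_geo = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(identical(dim(gen_dist), dim(geo_dist)))
  n <- nrow(gen_dist)
  if (log_geo) {
    off <- geo_dist[upper.tri(geo_dist)]
    eps <- min(off[off > 0])
    geo_dist <- log(pmax(geo_dist, eps))
    diag(geo_dist) <- 0
  }
  ut <- upper.tri(gen_dist)
  x <- gen_dist[ut]
  if (stats::sd(x) == 0 || stats::sd(geo_dist[ut]) == 0)
    return(structure(list(r = NA, p = NA, perms = perms, defined = FALSE),
                     class = "mantel_result"))
  obs <- stats::cor(x, geo_dist[ut])
  set.seed(seed)
  null <- vapply(seq_len(perms), function(b) {
    o <- sample.int(n)
    stats::cor(x, geo_dist[o, o][ut])
  }, 0)
  p <- switch(alternative,
              greater = .permP(null, obs, "greater"),
              less = .permP(null, obs, "less"),
              two.sided = min(1, 2 * min(.permP(null, obs, "greater"),
                                         .permP(null, obs, "less"))))
  structure(list(r = obs, p = p, perms = perms, defined = TRUE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (!x$defined) { cat("Mantel test undefined (constant matrix)\n"); return(invisible(x)) }
  cat(sprintf("Mantel: r = %.4f (r^2 = %.4f), p = %.5f (%d permutations)\n",
              x$r, x$r^2, x$p, x$perms))
  invisible(x)
}

#' Distance-class scheme
#'
#' Builds the ordered class boundaries used by correlograms and
#' distograms. Default boundaries give (approximately) equal pair counts
#' per class; fixed-width boundaries are available. Pairs are assigned to
#' half-open intervals [lo, hi), the last class closed above.
#'
#' @param geo_dist Symmetric geographic distance matrix.
#' @param n_classes Number of classes.
#' @param method "equal_pairs" (quantile boundaries) or "equal_width".
#' @return list of class \code{distance_classes}: \code{breaks} (length
#'   n_classes + 1), \code{n_classes}.
#' @export
distanceClasses <- function(geo_dist, n_classes = 5,
                            method = c("equal_pairs", "equal_width")) {
  method <- match.arg(method)
  v <- geo_dist[upper.tri(geo_dist)]
  breaks <- if (method == "equal_pairs")
    unique(stats::quantile(v, probs = seq(0, 1, length.out = n_classes + 1),
                           names = FALSE))
  else seq(min(v), max(v), length.out = n_classes + 1)
  if (length(breaks) < 2) stop("degenerate distance distribution")
  structure(list(breaks = breaks, n_classes = length(breaks) - 1),
            class = "distance_classes")
}

# class index of each pair (NA = out of range); last class closed
.classOf <- function(v, scheme) {
  b <- scheme$breaks
  idx <- findInterval(v, b, rightmost.closed = TRUE)
  idx[idx < 1 | idx > scheme$n_classes] <- NA
  idx
}

#' Distance-class correlogram of normalized genetic distance
#'
#' The per-class statistic is the mean normalized genetic distance among
#' the pairs whose geographic distance falls in the class: 0 when all
#' individuals in a class are genetically identical, 1 when all are
#' completely dissimilar. The overall statistic V is the variance of the
#' class means. Significance by permutation of individual locations
#' (per-class two-tailed; V upper tail).
#'
#' @param gen_dist Genetic distance matrix (any nonnegative scale; it is
#'   normalized by its maximum so the [0,1] interpretation holds).
#' @param lat,lon Per-individual coordinates (matching rows of gen_dist).
#' @param scheme A \code{\link{distanceClasses}} scheme, or NULL to build
#'   one with \code{n_classes} equal-pair classes.
#' @param n_classes Used when \code{scheme} is NULL.
#' @param perms Number of permutations.
#' @param seed Integer seed.
#' @return list of class \code{ay_correlogram}: \code{Ay, n_pairs, p}
#'   (per class), \code{V, p_V}, \code{breaks}.
#' @export
ayCorrelogram <- function(gen_dist, lat, lon, scheme = NULL, n_classes = 5,
                          perms = 10000, seed = 1) {
  geo <- .sampleGeoDist(lat, lon)
  if (is.null(scheme)) scheme <- distanceClasses(geo, n_classes)
  mx <- max(gen_dist)
  gnorm <- if (mx > 0) gen_dist / mx else gen_dist
  ut <- upper.tri(geo)
  cls <- .classOf(geo[ut], scheme)
  gv <- gnorm[ut]
  ayOf <- function(gvv) vapply(seq_len(scheme$n_classes), function(k) {
    ii <- which(cls == k)
    if (length(ii) < 2) NA_real_ else mean(gvv[ii])
  }, 0)
  obs <- ayOf(gv)
  keep <- !is.na(obs)
  Vobs <- stats::var(obs[keep])
  n <- nrow(geo)
  set.seed(seed)
  lo <- hi <- numeric(scheme$n_classes)
  Vex <- 0
  for (b in seq_len(perms)) {
    o <- sample.int(n)
    sim <- ayOf(gnorm[o, o][ut])
    lo <- lo + (sim <= obs)
    hi <- hi + (sim >= obs)
    if (isTRUE(stats::var(sim[keep]) >= Vobs)) Vex <- Vex + 1
  }
  pcls <- pmin(1, 2 * pmin((lo + 1) / (perms + 1), (hi + 1) / (perms + 1)))
  pcls[!keep] <- NA
  npairs <- vapply(seq_len(scheme$n_classes),
                   function(k) sum(cls == k, na.rm = TRUE), 0L)
  structure(list(Ay = obs, n_pairs = npairs, p = pcls,
                 V = Vobs, p_V = (Vex + 1) / (perms + 1),
                 breaks = scheme$breaks),
            class = "ay_correlogram")
}

#' @export
print.ay_correlogram <- function(x, ...) {
  cat("Distance-class correlogram\n")
  print(data.frame(class = seq_along(x$Ay), Ay = round(x$Ay, 4),
                   pairs = x$n_pairs, p = round(x$p, 4)), row.names = FALSE)
  cat(sprintf("  V = %.5f, p = %.4f\n", x$V, x$p_V))
  invisible(x)
}

# ---- connectivity graphs -------------------------------------------

#' Gabriel graph over sampling sites
#'
#' Sites i and j are joined when no third site k satisfies
#' \code{d(i,k)^2 + d(j,k)^2 <= d(i,j)^2} (great-circle distances); ties
#' broken towards inclusion, deterministic in site order.
#'
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @return data.frame from,to (site labels).
#' @export
gabrielGraph <- function(popmap) {
  cc <- siteCoordinates(popmap)
  d <- .sampleGeoDist(cc$lat, cc$lon)
  P <- nrow(cc)
  out <- list()
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    others <- setdiff(seq_len(P), c(i, j))
    blocked <- length(others) &&
      any(d[i, others]^2 + d[j, others]^2 < d[i, j]^2)
    if (!blocked)
      out[[length(out) + 1]] <- data.frame(from = cc$pop[i], to = cc$pop[j])
  }
  do.call(rbind, out)
}

# incircle predicate: is p inside the circumcircle of (a, b, c)?
.inCircumcircle <- function(a, b, c, p) {
  o <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (abs(o) < 1e-12) return(FALSE)     # degenerate triangle
  if (o < 0) { tmp <- b; b <- c; c <- tmp }
  m <- rbind(c(a[1] - p[1], a[2] - p[2], (a[1]^2 - p[1]^2) + (a[2]^2 - p[2]^2)),
             c(b[1] - p[1], b[2] - p[2], (b[1]^2 - p[1]^2) + (b[2]^2 - p[2]^2)),
             c(c[1] - p[1], c[2] - p[2], (c[1]^2 - p[1]^2) + (c[2]^2 - p[2]^2)))
  det(m) > 1e-12
}

#' Delaunay connectivity over sampling sites
#'
#' Brute-force Delaunay triangulation in the lon/lat plane (adequate for
#' the small extents of a river basin): a triangle is retained when its
#' circumcircle contains no other site. With fewer than three
#' non-collinear sites the minimum spanning tree is returned instead.
#'
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @return data.frame from,to (site labels).
#' @export
delaunayEdges <- function(popmap) {
  cc <- siteCoordinates(popmap)
  P <- nrow(cc)
  pts <- cbind(cc$lon, cc$lat)
  if (P < 2) stop("need >= 2 sites")
  edges <- matrix(FALSE, P, P)
  found <- FALSE
  if (P >= 3) {
    for (i in seq_len(P - 2)) for (j in (i + 1):(P - 1)) for (k in (j + 1):P) {
      others <- setdiff(seq_len(P), c(i, j, k))
      empty <- !length(others) || !any(vapply(others, function(q)
        .inCircumcircle(pts[i, ], pts[j, ], pts[k, ], pts[q, ]), TRUE))
      o <- (pts[j, 1] - pts[i, 1]) * (pts[k, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[k, 1] - pts[i, 1])
      if (empty && abs(o) > 1e-12) {
        edges[i, j] <- edges[j, i] <- TRUE
        edges[i, k] <- edges[k, i] <- TRUE
        edges[j, k] <- edges[k, j] <- TRUE
        found <- TRUE
      }
    }
  }
  if (!found) {                         # collinear or < 3 sites: MST
    d <- .sampleGeoDist(cc$lat, cc$lon)
    g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                             mode = "undirected")
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst, names = FALSE)
    for (r in seq_len(nrow(el)))
      edges[el[r, 1], el[r, 2]] <- edges[el[r, 2], el[r, 1]] <- TRUE
  }
  out <- list()
  for (i in seq_len(P - 1)) for (j in (i + 1):P)
    if (edges[i, j])
      out[[length(out) + 1]] <- data.frame(from = cc$pop[i], to = cc$pop[j])
  do.call(rbind, out)
}

#' Molecular spatial autocorrelation (Moran-type II, Geary-type cc)
#'
#' Codes every allele at every segregating site of the alignment as an
#' indicator variable over individuals, pools numerators and denominators
#' across indicators, and computes Moran's I (II) and Geary's c (cc) for
#' each weight set: either one weight matrix per geographic distance
#' class, or a single connectivity network (Gabriel graph or Delaunay
#' triangulation with crossing-edge elimination) joining sampling sites.
#' Significance by permutation of individuals over locations, with
#' per-class Bonferroni flags at alpha/classes.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param popmap A \linkS4class{PopulationAssignment}.
#' @param connectivity "distance_classes", "gabriel" or "delaunay_pruned".
#' @param scheme Optional \code{\link{distanceClasses}} scheme.
#' @param n_classes Classes when \code{scheme} is NULL.
#' @param perms Number of permutations.
#' @param alpha Familywise level for the Bonferroni flags.
#' @param seed Integer seed.
#' @return list of class \code{aida_result}: data.frame \code{classes}
#'   (class, II, cc, p_II, p_cc, signif_II, signif_cc, n_pairs),
#'   \code{expectation} (-1/(n-1)), \code{connectivity}.
#' @export
aidaAutocorrelation <- function(aln, popmap,
                                connectivity = c("distance_classes",
                                                 "gabriel", "delaunay_pruned"),
                                scheme = NULL, n_classes = 5, perms = 1000,
                                alpha = 0.05, seed = 1) {
  connectivity <- match.arg(connectivity)
  pop <- .checkPopmap(aln, popmap)
  cc0 <- siteCoordinates(popmap)
  lat <- cc0$lat[match(pop, cc0$pop)]
  lon <- cc0$lon[match(pop, cc0$pop)]
  n <- length(pop)
  m <- .alnMatrix(aln)
  keep <- .cleanSites(m)
  m <- m[, keep, drop = FALSE]
  seg <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  if (!length(seg)) stop("no segregating sites")
  # indicator matrix: individuals x (site, allele) indicators, centred
  Z <- NULL
  for (s in seg) {
    als <- unique(m[, s])
    for (al in als) Z <- cbind(Z, as.numeric(m[, s] == al))
  }
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  denom <- sum(Zc^2)
  # weight matrices per class
  geo <- .sampleGeoDist(lat, lon)
  Ws <- list()
  if (connectivity == "distance_classes") {
    if (is.null(scheme)) scheme <- distanceClasses(geo, n_classes)
    for (k in seq_len(scheme$n_classes)) {
      W <- matrix(0, n, n)
      ut <- upper.tri(geo)
      sel <- which(ut & matrix(.classOf(geo, scheme) == k, n, n))
      W[sel] <- 1; W <- W + t(W)
      Ws[[k]] <- W
    }
  } else {
    el <- if (connectivity == "gabriel") gabrielGraph(popmap)
          else delaunayEdges(popmap)
    adj <- matrix(FALSE, nrow(cc0), nrow(cc0),
                  dimnames = list(cc0$pop, cc0$pop))
    for (r in seq_len(nrow(el))) {
      adj[el$from[r], el$to[r]] <- adj[el$to[r], el$from[r]] <- TRUE
    }
    diag(adj) <- TRUE                   # same-site pairs are connected
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (adj[pop[i], pop[j]]) W[i, j] <- W[j, i] <- 1
    Ws[[1]] <- W
  }
  iicc <- function(Zc, denom) {
    vapply(Ws, function(W) {
      Wsum <- sum(W)
      if (Wsum == 0) return(c(II = NA, cc = NA))
      num <- sum(vapply(seq_len(ncol(Zc)), function(c2)
        drop(t(Zc[, c2]) %*% W %*% Zc[, c2]), 0))
      gnum <- sum(vapply(seq_len(ncol(Zc)), function(c2) {
        z <- Zc[, c2]
        sum(W * outer(z, z, function(a, b) (a - b)^2))
      }, 0))
      c(II = n / Wsum * num / denom,
        cc = (n - 1) / (2 * Wsum) * gnum / denom)
    }, c(II = 0, cc = 0))
  }
  obs <- iicc(Zc, denom)
  set.seed(seed)
  loII <- hiII <- loCC <- hiCC <- rep(0, length(Ws))
  for (b in seq_len(perms)) {
    o <- sample.int(n)
    sim <- iicc(Zc[o, , drop = FALSE], denom)
    hiII <- hiII + (sim["II", ] >= obs["II", ])
    loII <- loII + (sim["II", ] <= obs["II", ])
    hiCC <- hiCC + (sim["cc", ] >= obs["cc", ])
    loCC <- loCC + (sim["cc", ] <= obs["cc", ])
  }
  pII <- pmin(1, 2 * pmin((hiII + 1) / (perms + 1), (loII + 1) / (perms + 1)))
  pCC <- pmin(1, 2 * pmin((hiCC + 1) / (perms + 1), (loCC + 1) / (perms + 1)))
  bonf <- alpha / length(Ws)
  classes <- data.frame(class = seq_along(Ws),
                        II = obs["II", ], cc = obs["cc", ],
                        p_II = pII, p_cc = pCC,
                        signif_II = !is.na(pII) & pII < bonf,
                        signif_cc = !is.na(pCC) & pCC < bonf,
                        n_pairs = vapply(Ws, function(W) sum(W) / 2, 0))
  structure(list(classes = classes, expectation = -1 / (n - 1),
                 connectivity = connectivity),
            class = "aida_result")
}

#' @export
print.aida_result <- function(x, ...) {
  cat("Molecular autocorrelation (", x$connectivity, ")\n", sep = "")
  print(x$classes, row.names = FALSE)
  cat(sprintf("  null expectation of II: %.4f\n", x$expectation))
  invisible(x)
}

#' Gregorius genetic distance between frequency vectors
#'
#' \code{d = 0.5 * sum |p_i - q_i|}; 0 for identical vectors, 1 for
#' disjoint supports.
#'
#' @param p,q Frequency vectors over the same haplotype set.
#' @return Distance in [0, 1].
#' @export
gregoriusDistance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

#' Distogram of population genetic distance over distance classes
#'
#' Per-class mean of a population-pair genetic metric (Gregorius distance
#' or proportion of shared haplotypes), with a Monte-Carlo envelope (95
#' percent) from randomising population locations.
#'
#' @param freqs Matrix populations x haplotypes of frequencies (rows sum
#'   to 1).
#' @param lat,lon Per-population coordinates (row order of freqs).
#' @param scheme Optional \code{\link{distanceClasses}}; built with
#'   \code{n_classes} otherwise.
#' @param n_classes Classes when scheme is NULL.
#' @param metric "gregorius" or "shared_haplotypes".
#' @param mc_reps Monte-Carlo replicates for the envelope.
#' @param seed Integer seed.
#' @return list of class \code{distogram_result}: data.frame
#'   \code{classes} (class, value, n_pairs, lower, upper), \code{metric},
#'   \code{breaks}.
#' @export
distogram <- function(freqs, lat, lon, scheme = NULL, n_classes = 5,
                      metric = c("gregorius", "shared_haplotypes"),
                      mc_reps = 10000, seed = 1) {
  metric <- match.arg(metric)
  P <- nrow(freqs)
  if (P < 2) stop("need >= 2 populations")
  gd <- matrix(0, P, P)
  for (a in seq_len(P - 1)) for (b in (a + 1):P) {
    gd[a, b] <- gd[b, a] <- if (metric == "gregorius")
      gregoriusDistance(freqs[a, ], freqs[b, ])
    else {
      ha <- freqs[a, ] > 0; hb <- freqs[b, ] > 0
      sum(ha & hb) / sum(ha | hb)
    }
  }
  geo <- .sampleGeoDist(lat, lon)
  if (is.null(scheme)) scheme <- distanceClasses(geo, n_classes)
  ut <- upper.tri(geo)
  classOf <- .classOf(geo[ut], scheme)
  gv <- gd[ut]
  classMeans <- function(gvv) vapply(seq_len(scheme$n_classes), function(k) {
    ii <- which(classOf == k)
    if (!length(ii)) NA_real_ else mean(gvv[ii])
  }, 0)
  obs <- classMeans(gv)
  set.seed(seed)
  sims <- matrix(NA_real_, mc_reps, scheme$n_classes)
  for (b in seq_len(mc_reps)) {
    o <- sample.int(P)
    sims[b, ] <- classMeans(gd[o, o][ut])
  }
  lower <- apply(sims, 2, stats::quantile, 0.025, na.rm = TRUE, names = FALSE)
  upper <- apply(sims, 2, stats::quantile, 0.975, na.rm = TRUE, names = FALSE)
  npairs <- vapply(seq_len(scheme$n_classes),
                   function(k) sum(classOf == k, na.rm = TRUE), 0L)
  structure(list(classes = data.frame(class = seq_len(scheme$n_classes),
                                      value = obs, n_pairs = npairs,
                                      lower = lower, upper = upper),
                 metric = metric, breaks = scheme$breaks),
            class = "distogram_result")
}

#' Inverse-distance-weighted genetic landscape
#'
#' Places each connectivity-edge midpoint at the mean coordinate of its
#' two sites, assigns it the corresponding pairwise genetic distance, and
#' interpolates a surface on a regular grid with inverse-distance weights
#' \code{w = 1/d^a}; a grid node coinciding with a midpoint takes that
#' midpoint's value exactly.
#'
#' @param lat,lon Coordinates of the entities whose pairwise distances
#'   are interpolated (typically sampling sites).
#' @param gen_dist Matching symmetric genetic distance matrix.
#' @param grid c(nx, ny).
#' @param a IDW exponent.
#' @param edges Optional data.frame from,to (indices or labels matching
#'   \code{rownames(gen_dist)}); defaults to all pairs.
#' @return list of class \code{landscape_grid}: \code{x, y} (grid axes),
#'   \code{z} (ny x nx matrix), \code{midpoints} (data.frame lat, lon,
#'   value), \code{a}.
#' @export
landscapeIdw <- function(lat, lon, gen_dist, grid = c(50, 50), a = 1,
                         edges = NULL) {
  P <- length(lat)
  if (P < 3) stop("need >= 3 sites")
  if (is.null(edges)) {
    idx <- which(upper.tri(gen_dist), arr.ind = TRUE)
    edges <- data.frame(from = idx[, 1], to = idx[, 2])
  } else if (is.character(edges$from)) {
    edges <- data.frame(from = match(edges$from, rownames(gen_dist)),
                        to = match(edges$to, rownames(gen_dist)))
  }
  mids <- data.frame(lat = (lat[edges$from] + lat[edges$to]) / 2,
                     lon = (lon[edges$from] + lon[edges$to]) / 2,
                     value = gen_dist[cbind(edges$from, edges$to)])
  if (nrow(unique(mids[, c("lat", "lon")])) < 2)
    stop("all midpoints coincide")
  xs <- seq(min(mids$lon), max(mids$lon), length.out = grid[1])
  ys <- seq(min(mids$lat), max(mids$lat), length.out = grid[2])
  z <- matrix(NA_real_, grid[2], grid[1])
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    d <- sqrt((mids$lon - xs[ix])^2 + (mids$lat - ys[iy])^2)
    hit <- which(d < 1e-12)
    z[iy, ix] <- if (length(hit)) mids$value[hit[1]]
                 else sum(mids$value / d^a) / sum(1 / d^a)
  }
  structure(list(x = xs, y = ys, z = z, midpoints = mids, a = a),
            class = "landscape_grid")
}
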