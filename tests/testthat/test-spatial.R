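test_that("geographic distances: great-circle and river-network modes", {
  pm <- toyPopmap(c("P1", "P2"), c("a", "b"))
  d <- geoDistanceMatrix(pm)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_true(d["P1", "P2"] > 0)
  # three collinear river nodes at 10 km spacing: d(1,3) = 20
  pm3 <- PopulationAssignment(
    setNames(c("A", "B", "C"), c("x", "y", "z")),
    data.frame(pop = c("A", "B", "C"), lat = c(0, 0.1, 0.2), lon = 0))
  net <- data.frame(from = c("A", "B"), to = c("B", "C"), km = c(10, 10))
  dr <- geoDistanceMatrix(pm3, "river_network", net)
  expect_equal(dr["A", "C"], 20)
  # river distance >= great-circle distance when edges carry true lengths
  set.seed(41)
  for (rep in 1:5) {
    P <- 6
    cc <- data.frame(pop = paste0("S", 1:P),
                     lat = runif(P, -15, -12), lon = runif(P, -66, -64))
    pmr <- PopulationAssignment(setNames(cc$pop, paste0("s", 1:P)), cc)
    gc <- geoDistanceMatrix(pmr)
    # random spanning tree over the sites, edge weights = great-circle km
    ord <- sample(P)
    net <- data.frame(from = cc$pop[ord[-P]], to = cc$pop[ord[-1]])
    net$km <- vapply(seq_len(nrow(net)), function(i)
      gc[net$from[i], net$to[i]], 0)
    rv <- geoDistanceMatrix(pmr, "river_network", net)
    expect_true(all(rv - gc >= -1e-9))
  }
  expect_error(geoDistanceMatrix(pm3, "river_network",
                                 data.frame(from = c("A", "C"),
                                            to = c("B", "Coff"),
                                            km = c(1, 1))),
               "unreachable")
})

test_that("Mantel test: identity, sign, calibration, vegan cross-check", {
  set.seed(42)
  m <- matrix(runif(64), 8); m <- m + t(m); diag(m) <- 0
  mt <- mantelTest(m, m, perms = 200, seed = 1)
  expect_equal(mt$r, 1)
  expect_lt(mt$p, 0.05)
  # anti-correlated construction gives r < 0
  anti <- max(m) - m; diag(anti) <- 0
  expect_lt(mantelTest(anti, m, perms = 100, seed = 2)$r, 0)
  # constant matrix: flagged undefined
  expect_false(mantelTest(matrix(0, 8, 8), m, perms = 10, seed = 1)$defined)
  # r matches the independent implementation in vegan
  g <- m + matrix(rnorm(64, 0, 0.3), 8); g <- (g + t(g)) / 2; diag(g) <- 0
  vg <- vegan::mantel(as.dist(g), as.dist(m), permutations = 99)
  expect_equal(mantelTest(g, m, perms = 99, seed = 3)$r, vg$statistic,
               tolerance = 1e-12)
  # invariance to affine transforms of either matrix
  expect_equal(mantelTest(2 * g + 1 - diag(diag(2 * g + 1)), m,
                          perms = 10, seed = 4)$r,
               mantelTest(g, m, perms = 10, seed = 4)$r)
  # type-I calibration on independent random matrices
  set.seed(43)
  rej <- vapply(1:200, function(r) {
    a <- matrix(runif(400), 20); a <- a + t(a); diag(a) <- 0
    b <- matrix(runif(400), 20); b <- b + t(b); diag(b) <- 0
    mantelTest(a, b, perms = 99, seed = r)$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("distance-class correlogram hits its endpoints and detects clines", {
  set.seed(44)
  n <- 16
  lat <- runif(n, -15, -12); lon <- runif(n, -66, -64)
  # all individuals genetically identical: Ay = 0 everywhere
  z <- matrix(0, n, n)
  ay0 <- ayCorrelogram(z, lat, lon, n_classes = 3, perms = 20, seed = 1)
  expect_true(all(ay0$Ay == 0))
  # all pairs maximally distinct: Ay = 1 everywhere
  one <- matrix(1, n, n); diag(one) <- 0
  ay1 <- ayCorrelogram(one, lat, lon, n_classes = 3, perms = 20, seed = 1)
  expect_true(all(ay1$Ay == 1))
  # Ay invariant to uniform rescaling of the distance matrix
  g <- as.matrix(dist(cbind(lat, lon))); diag(g) <- 0
  a1 <- ayCorrelogram(g, lat, lon, n_classes = 4, perms = 10, seed = 2)
  a2 <- ayCorrelogram(5 * g, lat, lon, n_classes = 4, perms = 10, seed = 2)
  expect_equal(a1$Ay, a2$Ay)
  # monotone cline: genetic distance = geographic distance
  expect_true(all(diff(a1$Ay) > 0))
  # flat under label shuffling
  set.seed(45)
  o <- sample(n)
  aflat <- ayCorrelogram(g[o, o], lat, lon, n_classes = 4,
                         perms = 100, seed = 3)
  expect_gt(aflat$p_V, 0.05)
})

test_that("connectivity graphs are sane on simple configurations", {
  # four sites in a square: Gabriel graph joins the sides, not a diagonal
  # blocked by the other two corners
  pm <- PopulationAssignment(
    setNames(c("A", "B", "C", "D"), paste0("s", 1:4)),
    data.frame(pop = c("A", "B", "C", "D"),
               lat = c(0, 0, 1, 1), lon = c(0, 1, 0, 1)))
  gg <- gabrielGraph(pm)
  key <- paste(gg$from, gg$to)
  expect_true(all(c("A B", "A C", "B D", "C D") %in% key))
  de <- delaunayEdges(pm)
  expect_gte(nrow(de), 4)
  # every Delaunay edge set connects the sites
  g <- igraph::graph_from_data_frame(de, directed = FALSE,
                                     vertices = c("A", "B", "C", "D"))
  expect_equal(igraph::components(g)$no, 1)
})

test_that("molecular autocorrelation matches a double-sum oracle", {
  # two haplotypes across four localities
  h1 <- "AAAA"; h2 <- "TTAA"
  aln <- HaplotypeAlignment(setNames(c(h1, h1, h1, h1, h2, h2),
                                     paste0("s", 1:6)))
  pm <- PopulationAssignment(
    setNames(c("A", "A", "B", "B", "C", "D"), paste0("s", 1:6)),
    data.frame(pop = c("A", "B", "C", "D"),
               lat = c(0, 0.1, 1, 1.1), lon = c(0, 0.1, 1, 1.1)))
  res <- aidaAutocorrelation(aln, pm, "distance_classes", n_classes = 2,
                             perms = 50, seed = 1)
  # oracle: indicators per segregating site and allele, pooled
  m <- riverpopgen:::.alnMatrix(aln)
  seg <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  Z <- NULL
  for (s in seg) for (al in unique(m[, s]))
    Z <- cbind(Z, as.numeric(m[, s] == al))
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  pop <- c("A", "A", "B", "B", "C", "D")
  cc <- data.frame(lat = c(0, 0.1, 1, 1.1), lon = c(0, 0.1, 1, 1.1))
  lat <- cc$lat[match(pop, c("A", "B", "C", "D"))]
  lon <- cc$lon[match(pop, c("A", "B", "C", "D"))]
  geo <- riverpopgen:::.sampleGeoDist(lat, lon)
  sch <- distanceClasses(geo, 2)
  for (k in 1:2) {
    W <- matrix(0, 6, 6)
    ut <- upper.tri(geo)
    cls <- matrix(riverpopgen:::.classOf(geo, sch), 6, 6)
    W[ut & cls == k] <- 1
    W <- W + t(W)
    num <- gnum <- den <- 0
    for (c2 in seq_len(ncol(Zc))) {
      z <- Zc[, c2]
      num <- num + sum(W * outer(z, z))
      gnum <- gnum + sum(W * outer(z, z, function(a, b) (a - b)^2))
      den <- den + sum(z^2)
    }
    expect_equal(res$classes$II[k], 6 / sum(W) * num / den)
    expect_equal(res$classes$cc[k], 5 / (2 * sum(W)) * gnum / den)
  }
  # divergent near patch: short-range II positive, long-range negative
  expect_gt(res$classes$II[1], 0)
  expect_lt(res$classes$II[2], 0)
  expect_equal(res$expectation, -1 / 5)
})

test_that("spatially random haplotypes keep II near its null expectation", {
  set.seed(46)
  n <- 24
  haps <- sample(c("AAAA", "ATAA", "AATA"), n, replace = TRUE)
  aln <- HaplotypeAlignment(setNames(haps, paste0("s", 1:n)))
  pops <- paste0("L", rep(1:6, each = 4))
  pm <- PopulationAssignment(
    setNames(pops, paste0("s", 1:n)),
    data.frame(pop = paste0("L", 1:6),
               lat = runif(6, -15, -12), lon = runif(6, -66, -64)))
  res <- aidaAutocorrelation(aln, pm, "distance_classes", n_classes = 3,
                             perms = 200, seed = 2)
  expect_true(all(res$classes$p_II > 0.05 / 3, na.rm = TRUE))
  # connectivity-network variants run
  resG <- aidaAutocorrelation(aln, pm, "gabriel", perms = 50, seed = 3)
  expect_identical(nrow(resG$classes), 1L)
})

test_that("distograms: Gregorius metric and envelopes", {
  expect_equal(gregoriusDistance(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  expect_equal(gregoriusDistance(c(1, 0), c(1, 0)), 0)
  expect_equal(gregoriusDistance(c(1, 0, 0), c(0, 0.5, 0.5)), 1)
  f <- rbind(c(0.5, 0.5, 0, 0), c(0.25, 0.25, 0.5, 0),
             c(0, 0, 0, 1), c(0.5, 0.5, 0, 0))
  dg <- distogram(f, lat = c(0, 0.2, 1, 1.2), lon = c(0, 0.2, 1, 1.2),
                  n_classes = 2, metric = "gregorius", mc_reps = 100,
                  seed = 1)
  expect_identical(nrow(dg$classes), 2L)
  expect_true(all(dg$classes$value >= 0 & dg$classes$value <= 1))
  # disjoint haplotype sets: shared proportion 0
  dgs <- distogram(f[c(1, 3), ], lat = c(0, 1), lon = c(0, 1),
                   scheme = structure(list(breaks = c(0, 200),
                                           n_classes = 1),
                                      class = "distance_classes"),
                   metric = "shared_haplotypes", mc_reps = 50, seed = 2)
  expect_equal(dgs$classes$value[1], 0)
})

test_that("inverse-distance-weighted landscapes interpolate exactly", {
  # uniform pairwise distance: flat surface
  gd <- matrix(2, 4, 4); diag(gd) <- 0
  lw <- landscapeIdw(lat = c(0, 0, 1, 1), lon = c(0, 1, 0, 1), gd,
                     grid = c(7, 7))
  expect_true(all(abs(lw$z - 2) < 1e-9))
  # node coincident with a midpoint returns that midpoint's value
  gd2 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  lw2 <- landscapeIdw(lat = c(0, 0, 2), lon = c(0, 2, 0), gd2,
                      grid = c(3, 3), a = 1)
  # midpoint of sites 1-2 is at lon 1, lat 0 == grid node (x=1, y=0)
  expect_equal(lw2$z[1, 3], 1)
  # 3-midpoint hand computation at a probe node
  mids <- lw2$midpoints
  probe <- c(lon = lw2$x[2], lat = lw2$y[2])
  d <- sqrt((mids$lon - probe["lon"])^2 + (mids$lat - probe["lat"])^2)
  if (all(d > 1e-12))
    expect_equal(lw2$z[2, 2], sum(mids$value / d) / sum(1 / d))
  expect_error(landscapeIdw(lat = c(0, 1), lon = c(0, 1),
                            matrix(0, 2, 2)), ">= 3")
})
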