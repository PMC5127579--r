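test_that("great-circle distances satisfy closed forms and metric axioms", {
  same <- data.frame(lon = c(10, 10), lat = c(45, 45))
  expect_equal(greatCircleMatrix(same)[1, 2], 0)
  anti <- data.frame(lon = c(0, 180), lat = c(0, 0))
  expect_equal(greatCircleMatrix(anti)[1, 2], pi * 6371, tolerance = 1e-6)
  expect_error(greatCircleMatrix(data.frame(lon = 200, lat = 0)), "longitude")

  set.seed(3)
  pts <- data.frame(lon = runif(100, -180, 180), lat = runif(100, -90, 90))
  d <- greatCircleMatrix(pts)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (rep in 1:200) {                       # triangle inequality, sampled
    ijk <- sample.int(100, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("k-NN networks are unions, row-standardised and handle ties", {
  pts <- data.frame(lon = c(0, 1, 2), lat = c(0, 0, 0))  # collinear
  net <- knnNetwork(pts, k = 1)
  expect_equal(net@adjacency,
               rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))  # union adds 2-3
  expect_equal(rowSums(net@weights), rep(1, 3))

  set.seed(4)
  pts2 <- data.frame(lon = runif(9), lat = runif(9))
  full <- knnNetwork(pts2, k = 8)
  expect_true(all(full@adjacency[upper.tri(full@adjacency)] == 1))
  expect_error(knnNetwork(pts2, k = 9), "k must satisfy")

  dup <- data.frame(lon = c(0, 0, 5), lat = c(0, 0, 0))
  expect_message(knnNetwork(dup, k = 1), "ties broken")
})

test_that("Moran's I reproduces hand computations and the null mean", {
  ring <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(moranI(c(1, -1, 1, -1), ring), -1)   # checkerboard on a ring
  expect_error(moranI(rep(2, 4), ring), "zero variance")

  set.seed(5)
  n <- 10
  W <- matrix(rbinom(n * n, 1, 0.4), n, n); W <- W * t(W); diag(W) <- 0
  x <- rnorm(n)
  perms <- replicate(10000, moranI(x[sample.int(n)], W))
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 3 * sd(perms) / 100)
})

test_that("Moran's I matches the ape implementation", {
  skip_if_not_installed("ape")
  set.seed(6)
  pts <- data.frame(lon = runif(12), lat = runif(12))
  net <- knnNetwork(pts, 3)
  x <- rnorm(12)
  ours <- moranI(x, net)
  apes <- ape::Moran.I(x, net@weights)$observed
  expect_equal(ours, apes, tolerance = 1e-12)
})

test_that("sPCA satisfies its eigen identity and the dense-solve oracle", {
  set.seed(7)
  pts <- data.frame(lon = runif(10, 0, 5), lat = runif(10, 0, 2))
  net <- knnNetwork(pts, 3)
  X <- matrix(runif(10 * 20), 10, 20)
  X <- X / rowSums(X)                        # one 20-allele "locus"
  ft <- new("AlleleFreqTable", freq = X, locusCol = rep("L1", 20),
            alleleCol = as.integer(100 + 1:20),
            copies = matrix(40L, 10, 1, dimnames = list(NULL, "L1")),
            locations = cbind(id = paste0("P", 1:10), name = "x", pts))
  res <- spatialPCA(ft, net)
  lam <- eigenvalues(res)
  # defining identity lambda = var(s) * I(s)
  expect_lt(max(abs(res@varScores * res@moranScores - lam)), 1e-8)
  # independent dense path: eigenvalues of H = X' (L+L')/(2n) X
  Xc <- scale(X, center = TRUE, scale = FALSE)
  L <- net@weights
  H <- t(Xc) %*% ((L + t(L)) / (2 * nrow(X))) %*% Xc
  dense <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  keep <- abs(dense) > 1e-9 * max(abs(dense))
  expect_equal(lam, dense[keep], tolerance = 1e-10)
  # scores are X v with unit loadings
  expect_equal(colSums(alleleLoadings(res)^2), rep(1, ncol(scores(res))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(scores(res), Xc %*% alleleLoadings(res),
               tolerance = 1e-10, ignore_attr = TRUE)
  # sign counts bounded by rank
  expect_lte(sum(lam > 0) + sum(lam < 0), min(nrow(X) - 1, ncol(X)))
})

test_that("a single-column table reduces to lambda = var * I", {
  pts <- data.frame(lon = 1:6, lat = rep(0, 6))
  net <- knnNetwork(pts, 2)
  x <- c(0.1, 0.3, 0.2, 0.6, 0.5, 0.9)
  ft <- new("AlleleFreqTable", freq = cbind(x, 1 - x),
            locusCol = c("L1", "L1"), alleleCol = c(100L, 110L),
            copies = matrix(20L, 6, 1, dimnames = list(NULL, "L1")),
            locations = cbind(id = paste0("P", 1:6), name = "x", pts))
  res <- spatialPCA(ft, net)
  s <- x - mean(x)
  # two mirrored columns: leading component carries the single pattern
  lamTop <- eigenvalues(res)[which.max(abs(eigenvalues(res)))]
  expect_equal(abs(lamTop),
               abs(2 * stats::var(s) * (5 / 6) * moranI(x, net)),
               tolerance = 1e-10)
})

test_that("sPCA on a complete graph is a scaled ordinary PCA", {
  set.seed(8)
  n <- 9
  X <- matrix(runif(n * 6), n, 6)
  X <- X / rowSums(X)
  pts <- data.frame(lon = runif(n), lat = runif(n))
  net <- knnNetwork(pts, n - 1)             # complete graph
  ft <- new("AlleleFreqTable", freq = X, locusCol = rep("L1", 6),
            alleleCol = as.integer(100 + 1:6),
            copies = matrix(20L, n, 1, dimnames = list(NULL, "L1")),
            locations = cbind(id = paste0("P", 1:n), name = "x", pts))
  lam <- sort(eigenvalues(spatialPCA(ft, net)))
  pcaVar <- prcomp(X)$sdev^2                # SS/(n-1)
  lamExp <- sort(-pcaVar[pcaVar > 1e-12 * pcaVar[1]] / n)
  expect_equal(lam, lamExp, tolerance = 1e-8)
})

test_that("the global-structure test flags clines and respects its floor", {
  sp <- syntheticSpec(nLocations = 15, loci = c(LA = 6, LB = 8, LC = 5),
                      nClines = 3, clineAmplitude = 0.4, nFoci = 0,
                      nPerLocation = 60, seed = 12)
  ds <- simulateSTRData(sp)$dataset
  ft <- alleleFrequencies(ds)
  net <- knnNetwork(locationInfo(ds), 4)
  res <- globalStructureTest(ft, net, B = 99, seed = 1)
  expect_equal(res$p, 1 / 100)              # strong cline: minimal p
  expect_gte(res$p, 1 / (res$B + 1))
  expect_error(globalStructureTest(ft, net, B = 50), "at least 99")
})

test_that("global-structure p-values are calibrated without structure", {
  set.seed(13)
  pts <- data.frame(lon = runif(12, 0, 5), lat = runif(12, 0, 2))
  net <- knnNetwork(pts, 3)
  ps <- vapply(1:40, function(s) {
    X <- matrix(runif(12 * 8), 12, 8); X <- X / rowSums(X)
    ft <- new("AlleleFreqTable", freq = X, locusCol = rep("L1", 8),
              alleleCol = as.integer(100 + 1:8),
              copies = matrix(20L, 12, 1, dimnames = list(NULL, "L1")),
              locations = cbind(id = paste0("P", 1:12), name = "x", pts))
    globalStructureTest(ft, net, B = 99, seed = s)$p
  }, 0)
  expect_gt(mean(ps > 0.05), 0.75)
  expect_gt(mean(ps > 0.5), 0.25)
})

test_that("correlograms partition pairs and read clines off a transect", {
  pts <- data.frame(lon = seq(0, 30, length.out = 20), lat = rep(38, 20))
  cg <- moranCorrelogram(pts$lon, pts, B = 199, seed = 1)
  expect_equal(sum(cg$table$nPairs), 20 * 19 / 2)
  expect_true(cg$clinal)                     # I decreasing over classes
  expect_gt(cg$table$moranI[1], 0)
  expect_lt(cg$table$moranI[nrow(cg$table)], 0)
  expect_equal(cg$table$pBonferroni,
               pmin(1, cg$table$p * nrow(cg$table)))
  expect_error(moranCorrelogram(pts$lon, pts, classBounds = c(200, 100)),
               "strictly increasing")
  expect_error(moranCorrelogram(pts$lon, pts, classBounds = c(200, 400)),
               "do not cover")
})

test_that("correlogram p-values stay quiet on spatially random values", {
  pts <- data.frame(lon = seq(0, 30, length.out = 15), lat = rep(38, 15))
  pass <- vapply(1:12, function(s) {
    set.seed(s)
    cg <- moranCorrelogram(rnorm(15), pts, B = 199, seed = s)
    all(cg$table$pBonferroni > 0.05, na.rm = TRUE)
  }, TRUE)
  expect_gte(sum(pass), 9)
})

test_that("Mantel test: identity, exact enumeration, and the vegan oracle", {
  set.seed(14)
  pts <- data.frame(lon = runif(6), lat = runif(6))
  A <- greatCircleMatrix(pts)
  res <- mantelTest(A, A)
  expect_equal(res$r, 1)
  expect_equal(res$method, "exact")
  expect_equal(res$B, factorial(6))

  B <- as.matrix(dist(rnorm(6)))
  ours <- mantelTest(A, B)
  skip_if_not_installed("vegan")
  veg <- vegan::mantel(A, B, permutations = 9999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  se <- sqrt(ours$p * (1 - ours$p) / 9999)
  expect_lt(abs(ours$p - veg$signif), 3 * se + 0.01)

  expect_error(mantelTest(A, matrix(0, 6, 6)), "constant")
  expect_error(mantelTest(A[1:5, 1:5], B), "equal order")
})

test_that("kriging is exact at data points and recovers smooth fields", {
  set.seed(15)
  pts <- data.frame(lon = runif(25, 0, 10), lat = runif(25, 0, 5))
  z <- 0.3 + 0.02 * pts$lon + 0.03 * pts$lat + rnorm(25, 0, 0.001)
  kr <- krigeFrequencySurface(z, pts, gridSize = c(25, 25))
  expect_lt(max(abs(kr$predict(pts$lon, pts$lat) - z)), 1e-6)

  # linear trend recovered inside the hull
  grid <- expand.grid(lon = seq(2, 8, length.out = 8),
                      lat = seq(1, 4, length.out = 8))
  pred <- kr$predict(grid$lon, grid$lat)
  truth <- 0.3 + 0.02 * grid$lon + 0.03 * grid$lat
  expect_lt(sqrt(mean((pred - truth)^2)), 0.01)

  flat <- krigeFrequencySurface(rep(0.4, 25), pts, gridSize = c(10, 10))
  expect_true(all(flat$surface == 0.4))
  expect_error(krigeFrequencySurface(z[1:3], pts[1:3, ]), "at least 4")
})
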