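# Great-circle distances, k-nearest-neighbour networks, Moran's I, spatial
# PCA with global/local eigenvalues, the global-structure permutation test,
# distance-class correlograms and the Mantel test.

EARTH_RADIUS_KM <- 6371

coordsOf <- function(locations) {
  if (is(locations, "STRDataset") || is(locations, "AlleleFreqTable"))
    locations <- locationInfo(locations)
  m <- cbind(lon = locations$lon, lat = locations$lat)
  if (anyNA(m)) stop("missing coordinates")
  if (any(m[, 1] < -180 | m[, 1] > 180)) stop("longitude outside [-180, 180]")
  if (any(m[, 2] < -90 | m[, 2] > 90)) stop("latitude outside [-90, 90]")
  m
}

#' Great-circle distance matrix (km)
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param locations a data.frame with `lon`, `lat` columns, or an
#'   [STRDataset-class] / [AlleleFreqTable-class].
#' @return symmetric matrix of distances in km, zero diagonal.
#' @export
greatCircleMatrix <- function(locations) {
  m <- coordsOf(locations)
  d <- geosphere::distm(m, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000)) / 1000
  dimnames(d) <- NULL
  d
}

#' k-nearest-neighbour spatial network
#'
#' Builds the directed k-NN graph on great-circle distances, symmetrises by
#' union (an edge survives if either endpoint lists the other among its k
#' nearest) and row-standardises the adjacency into the lag operator L.
#' Distance ties (e.g. duplicated coordinates) are broken by location
#' index, with a message.
#'
#' @inheritParams greatCircleMatrix
#' @param k neighbours per node (1 <= k < number of locations).
#' @return a [SpatialNetwork-class].
#' @export
knnNetwork <- function(locations, k) {
  m <- coordsOf(locations)
  n <- nrow(m)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of locations")
  d <- greatCircleMatrix(locations)
  A <- matrix(0, n, n)
  tied <- FALSE
  for (i in seq_len(n)) {
    dd <- d[i, ]; dd[i] <- Inf
    o <- order(dd, seq_len(n))          # ties broken by index
    if (anyDuplicated(dd[o][seq_len(min(k + 1, n - 1))])) tied <- TRUE
    A[i, o[seq_len(k)]] <- 1
  }
  if (tied) message("knnNetwork: distance ties broken by location index")
  A <- pmax(A, t(A))                    # union symmetrisation
  L <- A / rowSums(A)
  new("SpatialNetwork", adjacency = A, weights = L, k = as.integer(k),
      coords = m)
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar
#' x)}{\sum_i (x_i - \bar x)^2}}
#' with \eqn{S_0 = \sum_{ij} w_{ij}}. Under spatial randomness the expected
#' value is \eqn{-1/(n-1)}.
#'
#' @param values numeric vector (>= 2 distinct values).
#' @param weights a [SpatialNetwork-class] (its row-standardised weights are
#'   used) or a non-negative weight matrix with zero diagonal.
#' @return Moran's I (scalar).
#' @export
moranI <- function(values, weights) {
  W <- if (is(weights, "SpatialNetwork")) weights@weights else as.matrix(weights)
  n <- length(values)
  if (nrow(W) != n) stop("weights must be n x n")
  x <- values - mean(values)
  ss <- sum(x^2)
  if (ss == 0) stop("Moran's I undefined: values have zero variance")
  S0 <- sum(W)
  (n / S0) * drop(crossprod(x, W %*% x)) / ss
}

# spatial PCA inner solver via the n x n dual: the nonzero eigenvalues of
# H = X'AX equal those of R A R with R = (XX')^{1/2}. Returns eigenvalues
# (desc) and scores (s = columns); used by both spatialPCA() and the
# global-structure permutation test.
spcaDual <- function(X, A, valuesOnly = FALSE, perm = NULL) {
  n <- nrow(X)
  G <- tcrossprod(X)
  eG <- eigen(G, symmetric = TRUE)
  d <- pmax(eG$values, 0)
  R <- eG$vectors %*% (sqrt(d) * t(eG$vectors))
  Ause <- if (is.null(perm)) A else A[perm, perm]
  B <- R %*% Ause %*% R
  B <- (B + t(B)) / 2
  eB <- eigen(B, symmetric = TRUE, only.values = valuesOnly)
  if (valuesOnly) return(list(values = eB$values))
  list(values = eB$values, R = R, vectors = eB$vectors)
}

#' Spatial principal component analysis of allele frequencies
#'
#' Eigen-decomposes \eqn{H = X^T (L + L^T) X / (2n)}, where X is the
#' column-centred locations x alleles frequency matrix and L the
#' row-standardised network weights. Each component maximises the product
#' of score variance and Moran's I, so positive eigenvalues flag "global"
#' structure (clines: neighbours alike) and negative ones "local" structure
#' (neighbours contrasted). Columns are centred but not scaled (allele
#' frequencies share units).
#'
#' @param freqTable an [AlleleFreqTable-class] (>= 3 locations).
#' @param network a [SpatialNetwork-class] over the same locations.
#' @param tol eigenvalues below `tol * max(|eigenvalue|)` in magnitude are
#'   treated as null space and dropped.
#' @return an [SPCAResult-class]; for every retained component
#'   \eqn{\lambda_k = var(s_k)\, I(s_k)} holds to numerical precision.
#' @export
spatialPCA <- function(freqTable, network, tol = 1e-9) {
  Xr <- freqTable@freq
  n <- nrow(Xr)
  if (n < 3) stop("need at least 3 locations")
  if (nrow(network@weights) != n) stop("network and table disagree on locations")
  X <- scale(Xr, center = TRUE, scale = FALSE)
  L <- network@weights
  A <- (L + t(L)) / (2 * n)
  dual <- spcaDual(X, A)
  lam <- dual$values
  if (max(abs(lam)) == 0) stop("no variation in the frequency table")
  ord <- which(abs(lam) > tol * max(abs(lam)))
  lam <- lam[ord]
  V <- matrix(0, ncol(X), length(ord))
  S <- matrix(0, n, length(ord))
  for (idx in seq_along(ord)) {
    s0 <- dual$R %*% dual$vectors[, ord[idx]]
    v <- crossprod(X, A %*% s0) / lam[idx]
    v <- v / sqrt(sum(v^2))
    V[, idx] <- v
    S[, idx] <- X %*% v
  }
  cn <- paste0("sPC", seq_along(ord))
  dimnames(V) <- list(colnames(Xr), cn)
  dimnames(S) <- list(rownames(Xr), cn)
  varS <- colSums(S^2) / n
  morS <- vapply(seq_along(ord), function(kk) moranI(S[, kk], network), 0)
  new("SPCAResult", eigenvalues = lam, loadings = V, scores = S,
      varScores = varS, moranScores = morS,
      colMeta = data.frame(locus = freqTable@locusCol,
                           allele = formatAllele(freqTable@alleleCol),
                           stringsAsFactors = FALSE),
      network = network)
}

#' Permutation test for global spatial structure
#'
#' Location rows of the (centred) frequency matrix are permuted relative to
#' the network and the largest positive eigenvalue recomputed;
#' \eqn{p = (1 + \#\{\lambda^{max}_{perm} \ge \lambda^{max}_{obs}\})/(B+1)}.
#'
#' @inheritParams spatialPCA
#' @param B permutations (>= 99).
#' @param seed integer seed.
#' @return list with `p`, `obs` (observed largest eigenvalue), `B`.
#' @export
globalStructureTest <- function(freqTable, network, B = 999, seed = 1) {
  if (B < 99) stop("B must be at least 99")
  X <- scale(freqTable@freq, center = TRUE, scale = FALSE)
  n <- nrow(X)
  L <- network@weights
  A <- (L + t(L)) / (2 * n)
  obs <- spcaDual(X, A, valuesOnly = TRUE)$values[1]
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(B)) {
    lam <- spcaDual(X, A, valuesOnly = TRUE, perm = sample.int(n))$values[1]
    if (lam >= obs) ge <- ge + 1L
  }
  list(p = (1 + ge) / (B + 1), obs = obs, B = B)
}

#' Moran correlogram over great-circle distance classes
#'
#' Location pairs are partitioned into distance classes by the given upper
#' bounds; within each class Moran's I is computed with binary weights over
#' the pairs of that class and tested by permutation (two-sided). A
#' Bonferroni-corrected p (times the number of classes, capped at 1) and a
#' "clinal" descriptor (I monotone decreasing over classes) are reported.
#'
#' @param values numeric vector, one value per location.
#' @inheritParams greatCircleMatrix
#' @param classBounds strictly increasing upper bounds in km, covering the
#'   maximum inter-location distance.
#' @param B permutations.
#' @param seed integer seed.
#' @return list with `table` (bound, nPairs, moranI, p, pBonferroni),
#'   `clinal` (logical), `classBounds`.
#' @export
moranCorrelogram <- function(values, locations,
                             classBounds = c(200, 400, 800, 1200, 1600, 3200),
                             B = 10000, seed = 1) {
  if (any(diff(classBounds) <= 0)) stop("class bounds must be strictly increasing")
  d <- greatCircleMatrix(locations)
  n <- length(values)
  if (nrow(d) != n) stop("one value per location required")
  ut <- which(upper.tri(d))
  if (max(d) > classBounds[length(classBounds)])
    stop("class bounds do not cover the maximum distance")
  cls <- findInterval(d[ut], c(0, classBounds), left.open = TRUE)
  cls[cls == 0] <- 1L   # coincident locations fall in the first class
  nc <- length(classBounds)
  pairIdx <- lapply(seq_len(nc), function(cc) {
    w <- ut[cls == cc]
    cbind(row(d)[w], col(d)[w])
  })
  x <- values - mean(values)
  ss <- sum(x^2)
  if (ss == 0) stop("Moran's I undefined: values have zero variance")
  classI <- function(x, ss) vapply(seq_len(nc), function(cc) {
    pr <- pairIdx[[cc]]
    if (nrow(pr) == 0) return(NA_real_)
    (n / (2 * nrow(pr))) * 2 * sum(x[pr[, 1]] * x[pr[, 2]]) / ss
  }, 0)
  Iobs <- classI(x, ss)
  set.seed(seed)
  lo <- hi <- integer(nc)
  for (b in seq_len(B)) {
    xp <- x[sample.int(n)]
    Ip <- classI(xp, ss)
    lo <- lo + (!is.na(Iobs) & Ip <= Iobs)
    hi <- hi + (!is.na(Iobs) & Ip >= Iobs)
  }
  p <- pmin(1, 2 * pmin((1 + lo) / (B + 1), (1 + hi) / (B + 1)))
  p[is.na(Iobs)] <- NA_real_
  tab <- data.frame(bound = classBounds,
                    nPairs = vapply(pairIdx, nrow, 0L),
                    moranI = Iobs, p = p,
                    pBonferroni = pmin(1, p * nc))
  iOK <- Iobs[!is.na(Iobs)]
  list(table = tab, clinal = all(diff(iOK) <= 0) && length(iOK) > 1,
       classBounds = classBounds)
}

# all permutations of 1..n (n <= 7 -> at most 5040)
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- allPerms(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) for (pos in seq_len(n)) {   # insert n at every position
    i <- i + 1L
    out[[i]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangles; significance
#' by jointly permuting rows and columns of the second matrix. One-tailed
#' (positive association). For n <= 7 all n! permutations are enumerated
#' and the p-value is exact; otherwise Monte Carlo with
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\})/(B+1)}.
#'
#' @param matA,matB symmetric matrices of equal order with zero diagonals.
#' @param B Monte Carlo permutations (ignored when enumerating).
#' @param seed integer seed (Monte Carlo only).
#' @return list with `r`, `p`, `method` ("exact" or "monte-carlo"), `B`.
#' @export
mantelTest <- function(matA, matB, B = 9999, seed = 1) {
  matA <- as.matrix(matA); matB <- as.matrix(matB)
  n <- nrow(matA)
  if (!all(dim(matA) == dim(matB)) || n != ncol(matA))
    stop("matrices must be square and of equal order")
  for (M in list(matA, matB)) {
    if (any(diag(M) != 0)) stop("diagonals must be zero")
    if (max(abs(M - t(M))) > 1e-8) stop("matrices must be symmetric")
  }
  ut <- upper.tri(matA)
  a <- matA[ut]
  if (stats::sd(a) == 0 || stats::sd(matB[ut]) == 0)
    stop("Mantel r undefined for a constant matrix")
  rOf <- function(perm) stats::cor(a, matB[perm, perm][ut])
  obs <- rOf(seq_len(n))
  if (n <= 7) {
    rs <- vapply(allPerms(n), rOf, 0)
    list(r = obs, p = mean(rs >= obs - 1e-12), method = "exact",
         B = length(rs))
  } else {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(B)) if (rOf(sample.int(n)) >= obs - 1e-12) ge <- ge + 1L
    list(r = obs, p = (1 + ge) / (B + 1), method = "monte-carlo", B = B)
  }
}
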