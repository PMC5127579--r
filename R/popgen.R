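# Weir & Cockerham (1984) variance components for one locus.
# a1m, a2m: integer vectors of the two allele codes per subject (any labels);
# pop: integer group index 1..r. Returns the per-allele components summed
# over alleles: a (among populations), b (among individuals within
# populations), c (within individuals). Multi-allelic: one component set per
# allele, summed.
wcLocusComponents <- function(a1m, a2m, pop, r) {
  ni <- tabulate(pop, r)
  if (any(ni == 0)) stop("every group needs at least one subject")
  alleles <- sort(unique(c(a1m, a2m)))
  k <- length(alleles)
  i1 <- match(a1m, alleles); i2 <- match(a2m, alleles)
  # allele-copy counts and heterozygote-carrier counts, pops x alleles
  cnt <- matrix(tabulate(pop + r * (i1 - 1L), r * k) +
                tabulate(pop + r * (i2 - 1L), r * k), r, k)
  het <- i1 != i2
  hcnt <- matrix(tabulate(pop[het] + r * (i1[het] - 1L), r * k) +
                 tabulate(pop[het] + r * (i2[het] - 1L), r * k), r, k)
  p <- cnt / (2 * ni)
  h <- hcnt / ni
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(ni * p) / (r * nbar)
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h) / (r * nbar)
  aComp <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  bComp <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cComp <- hbar / 2
  list(a = sum(aComp), b = sum(bComp), c = sum(cComp), k = k)
}

# Multi-locus theta from genotype code matrices (subjects x loci).
wcThetaMatrices <- function(A1, A2, pop, r) {
  if (r < 2) stop("Fst undefined: need at least two groups")
  A <- B <- C <- numeric(ncol(A1))
  for (j in seq_len(ncol(A1))) {
    comp <- wcLocusComponents(A1[, j], A2[, j], pop, r)
    A[j] <- comp$a; B[j] <- comp$b; C[j] <- comp$c
  }
  denom <- sum(A + B + C)
  if (!is.finite(denom) || denom == 0)
    stop("Fst undefined: all groups monomorphic at all loci")
  list(theta = sum(A) / denom, a = A, b = B, c = C)
}

# ReducedDataset objects enter the F-statistic machinery as biallelic
# pseudo-locus genotype datasets.
asGenotypeDataset <- function(dataset) {
  if (is(dataset, "ReducedDataset")) reducedToSTR(dataset) else dataset
}

# Resolve a grouping argument into an integer index per subject.
resolveGrouping <- function(dataset, grouping) {
  if (is.null(grouping)) grouping <- dataset@locationId
  if (!is.null(names(grouping))) {          # location id -> group mapping
    miss <- setdiff(dataset@locations$id, names(grouping))
    if (length(miss)) stop("grouping misses locations: ",
                           paste(miss, collapse = ", "))
    grouping <- unname(grouping[dataset@locationId])
  }
  if (length(grouping) != nSubjects(dataset))
    stop("grouping must give one group per subject (or be a named location map)")
  f <- factor(grouping)
  list(idx = as.integer(f), levels = levels(f))
}

#' Weir-Cockerham Fst
#'
#' Multi-allelic, multi-locus theta of Weir & Cockerham (1984): per allele
#' and locus the variance components a (among groups), b (among individuals
#' within groups) and c (within individuals) are computed and theta is the
#' ratio of summed components, \eqn{\theta = \sum a / \sum (a+b+c)}.
#'
#' @param dataset an [STRDataset-class].
#' @param grouping NULL (group by location), a vector with one group label
#'   per subject, or a named vector mapping location ids to pooled groups.
#' @return list with `fst`, `fis` (Weir-Cockerham small-f), per-locus
#'   components `a`, `b`, `c` (named by locus), `nGroups`.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
weirCockerhamFst <- function(dataset, grouping = NULL) {
  dataset <- asGenotypeDataset(dataset)
  g <- resolveGrouping(dataset, grouping)
  r <- length(g$levels)
  if (r < 2) stop("need at least two groups")
  res <- wcThetaMatrices(dataset@alleles1, dataset@alleles2, g$idx, r)
  bc <- sum(res$b + res$c)
  list(fst = res$theta,
       fis = if (bc > 0) 1 - sum(res$c) / bc else NA_real_,
       a = stats::setNames(res$a, dataset@loci),
       b = stats::setNames(res$b, dataset@loci),
       c = stats::setNames(res$c, dataset@loci),
       nGroups = r)
}

#' Permutation test for Fst
#'
#' Subjects are permuted among groups (group sizes preserved) and theta
#' recomputed; \eqn{p = (1 + \#\{\theta_{perm} \ge \theta_{obs}\})/(B+1)},
#' so p can never fall below 1/(B+1).
#'
#' @inheritParams weirCockerhamFst
#' @param B number of permutations (>= 100).
#' @param seed integer seed for reproducibility.
#' @return as [weirCockerhamFst()] plus `p`, `B`.
#' @export
fstPermutationTest <- function(dataset, grouping = NULL, B = 10000,
                               seed = 1) {
  if (B < 100) stop("B must be at least 100")
  dataset <- asGenotypeDataset(dataset)
  g <- resolveGrouping(dataset, grouping)
  r <- length(g$levels)
  if (r < 2) stop("need at least two groups")
  obs <- wcThetaMatrices(dataset@alleles1, dataset@alleles2, g$idx, r)
  set.seed(seed)
  n <- nSubjects(dataset)
  ge <- 0L
  for (b in seq_len(B)) {
    idx <- g$idx[sample.int(n)]
    th <- tryCatch(
      wcThetaMatrices(dataset@alleles1, dataset@alleles2, idx, r)$theta,
      error = function(e) NA_real_)
    if (!is.na(th) && th >= obs$theta) ge <- ge + 1L
  }
  out <- list(fst = obs$theta, p = (1 + ge) / (B + 1), B = B, nGroups = r)
  out
}

#' Pairwise Fst matrix
#'
#' Weir-Cockerham theta for every pair of pools; symmetric with a zero
#' diagonal. Consistent with [weirCockerhamFst()] called pair by pair.
#'
#' @param dataset an [STRDataset-class].
#' @param pooling NULL (one pool per location) or a named vector mapping
#'   location ids to pool labels (>= 2 pools).
#' @return symmetric numeric matrix of pairwise theta.
#' @export
pairwiseFst <- function(dataset, pooling = NULL) {
  dataset <- asGenotypeDataset(dataset)
  g <- resolveGrouping(dataset, pooling)
  r <- length(g$levels)
  if (r < 2) stop("pooling must define at least two pools")
  M <- matrix(0, r, r, dimnames = list(g$levels, g$levels))
  for (i in 1:(r - 1)) for (j in (i + 1):r) {
    keep <- g$idx %in% c(i, j)
    pop <- ifelse(g$idx[keep] == i, 1L, 2L)
    th <- wcThetaMatrices(dataset@alleles1[keep, , drop = FALSE],
                          dataset@alleles2[keep, , drop = FALSE], pop, 2L)
    M[i, j] <- M[j, i] <- th$theta
  }
  M
}

#' Per-locus, per-location inbreeding coefficients
#'
#' \eqn{F_{IS} = 1 - H_{obs}/H_{exp}} with the sample-size-unbiased
#' expected heterozygosity \eqn{H_{exp} = \frac{2n}{2n-1}(1 - \sum p^2)}.
#' Monomorphic locus x location cells are excluded from the averages and
#' flagged.
#'
#' @param dataset an [STRDataset-class].
#' @return list with `table` (locus, location, hObs, hExp, fis,
#'   monomorphic), `byLocation` and `byLocus` averages over the polymorphic
#'   cells, `mean` (grand mean of `byLocation`), and `nMonomorphic`.
#' @export
estimateFis <- function(dataset) {
  locIds <- dataset@locations$id
  popIdx <- match(dataset@locationId, locIds)
  rows <- list()
  for (j in seq_along(dataset@loci)) {
    for (i in seq_along(locIds)) {
      sel <- popIdx == i
      n <- sum(sel)
      if (n < 2) stop("need at least two subjects per location")
      a1 <- dataset@alleles1[sel, j]; a2 <- dataset@alleles2[sel, j]
      alle <- unique(c(a1, a2))
      mono <- length(alle) < 2
      hObs <- mean(a1 != a2)
      p <- (tabulate(match(a1, alle), length(alle)) +
            tabulate(match(a2, alle), length(alle))) / (2 * n)
      hExp <- (2 * n) / (2 * n - 1) * (1 - sum(p^2))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = dataset@loci[j], location = locIds[i], n = n,
        hObs = hObs, hExp = hExp,
        fis = if (mono) NA_real_ else 1 - hObs / hExp,
        monomorphic = mono, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$monomorphic
  byLocation <- tapply(tab$fis[ok], tab$location[ok], mean)
  byLocus <- tapply(tab$fis[ok], tab$locus[ok], mean)
  list(table = tab,
       byLocation = byLocation[locIds[locIds %in% names(byLocation)]],
       byLocus = byLocus[dataset@loci[dataset@loci %in% names(byLocus)]],
       mean = mean(byLocation),
       nMonomorphic = sum(tab$monomorphic))
}
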