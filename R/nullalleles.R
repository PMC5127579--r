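# EM estimation of the frequency of a non-amplifying (null) allele at one
# locus in one location sample, from the excess of apparent homozygotes.
#
# Model: under Hardy-Weinberg with visible allele frequencies p_1..p_k and a
# hidden null allele of frequency r, an apparent homozygote i/i is either a
# true homozygote (prob p_i^2) or a null carrier i/null (prob 2 p_i r);
# null/null individuals never enter the dataset (incomplete profiles are
# discarded), so the likelihood is conditioned on not being null/null.
#
# E-step: apportion each apparent-homozygote count between the two hidden
# classes, and add the expected number of unobserved null/null individuals
# implied by the truncation (N r^2 / (1 - r^2)). M-step: re-estimate all
# allele frequencies, including r, by gene counting over the completed
# data. The observed-data log-likelihood is non-decreasing across
# iterations.

#' EM estimate of the null-allele frequency
#'
#' @param dataset an [STRDataset-class].
#' @param locus locus name.
#' @param location location id.
#' @param tol convergence tolerance on the change in r (> 0).
#' @param maxIter iteration cap; non-convergence is flagged, with the last
#'   iterate returned.
#' @return list with `r` (null-allele frequency), `p` (visible allele
#'   frequencies, named by label), `logLik` (per-iteration observed-data
#'   log-likelihood), `iterations`, `converged`.
#' @references Dempster AP, Laird NM, Rubin DB (1977) Maximum likelihood
#'   from incomplete data via the EM algorithm. JRSS B 39:1-38.
#' @export
nullAlleleEM <- function(dataset, locus, location, tol = 1e-8,
                         maxIter = 1000) {
  if (tol <= 0) stop("tol must be positive")
  j <- match(locus, dataset@loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  sel <- dataset@locationId == location
  if (!any(sel)) stop("unknown location: ", location)
  a1 <- dataset@alleles1[sel, j]; a2 <- dataset@alleles2[sel, j]
  alle <- sort(unique(c(a1, a2)))
  nullAlleleEMCounts(buildGenotypeCounts(a1, a2, alle), alle, tol, maxIter)
}

buildGenotypeCounts <- function(a1, a2, alle) {
  k <- length(alle)
  D <- matrix(0, k, k)
  i1 <- match(a1, alle); i2 <- match(a2, alle)
  for (i in seq_along(i1)) {
    g <- sort(c(i1[i], i2[i]))
    D[g[1], g[2]] <- D[g[1], g[2]] + 1
  }
  D
}

# Core EM on a genotype count table (upper triangle + diagonal). Exposed
# for constructed-count checks.
nullAlleleEMCounts <- function(D, alle = seq_len(nrow(D)), tol = 1e-8,
                               maxIter = 1000) {
  k <- nrow(D)
  N <- sum(D)
  nHom <- diag(D)
  hetCopies <- rowSums(D + t(D)) - 2 * diag(D)   # copies of each allele in hets
  # start: naive frequencies, small null
  p <- (hetCopies + 2 * nHom) / (2 * N)
  r <- 0.01
  p <- p * (1 - r)
  ll <- numeric(0)
  obsLogLik <- function(p, r) {
    hetTerm <- 0
    for (i in seq_len(k - 1)) for (jj in (i + 1):k)
      if (D[i, jj] > 0) hetTerm <- hetTerm + D[i, jj] * log(2 * p[i] * p[jj])
    sum(nHom * log(p^2 + 2 * p * r)) + hetTerm - N * log(1 - r^2)
  }
  conv <- FALSE
  it <- 0
  while (it < maxIter) {
    it <- it + 1
    ll <- c(ll, obsLogLik(p, r))
    tHom <- ifelse(nHom > 0, nHom * p / (p + 2 * r), 0)  # true homozygotes
    uNull <- nHom - tHom                                  # visible/null carriers
    mNullNull <- N * r^2 / (1 - r^2)                      # truncated class
    copies <- hetCopies + 2 * tHom + uNull
    nullCopies <- sum(uNull) + 2 * mNullNull
    tot <- sum(copies) + nullCopies
    pNew <- copies / tot
    rNew <- nullCopies / tot
    done <- abs(rNew - r) < tol
    p <- pNew; r <- rNew
    if (done) { conv <- TRUE; break }
  }
  ll <- c(ll, obsLogLik(p, r))
  list(r = r, p = stats::setNames(p, formatAllele(alle)), logLik = ll,
       iterations = it, converged = conv)
}
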