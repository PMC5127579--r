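# Exact Hardy-Weinberg test via the Guo & Thompson (1992) switch chain.
#
# The state is the genotype count table with fixed allele counts; its
# conditional probability is pi(table) proportional to 2^h / prod n_ij!
# (h = number of heterozygous individuals). A proposal draws two distinct
# individuals and re-pairs their four alleles one of the two alternative
# ways; the Metropolis ratio combines the pi ratio with the (asymmetric)
# selection probabilities. The exact-test p-value is the chain proportion
# of tables whose conditional probability does not exceed the observed
# table's.

# log pi up to the constant: h*log(2) - sum(lfactorial(n_ij))
hweTableScore <- function(D) {
  h <- sum(D[upper.tri(D)])
  h * log(2) - sum(lfactorial(D[upper.tri(D, diag = TRUE)]))
}

# one switch step; D is a k x k genotype count matrix (upper triangle +
# diagonal used). Returns updated D and score.
hweSwitchStep <- function(D, score) {
  k <- nrow(D)
  ut <- which(upper.tri(D, diag = TRUE))
  cnt <- D[ut]
  c1 <- sample.int(length(ut), 1L, prob = cnt)
  cnt2 <- cnt; cnt2[c1] <- cnt2[c1] - 1L
  c2 <- sample.int(length(ut), 1L, prob = cnt2)
  rc <- arrayInd(ut[c(c1, c2)], c(k, k))
  g1 <- sort(rc[1, ]); g2 <- sort(rc[2, ])      # genotypes (i<=j), (k<=l)
  # the two alternative re-pairings of alleles {g1, g2}
  alt <- list(list(sort(c(g1[1], g2[1])), sort(c(g1[2], g2[2]))),
              list(sort(c(g1[1], g2[2])), sort(c(g1[2], g2[1]))))
  keyOf <- function(pair) paste(sort(c(paste(pair[[1]], collapse = ","),
                                       paste(pair[[2]], collapse = ","))),
                                collapse = ";")
  curKey <- keyOf(list(g1, g2))
  keys <- vapply(alt, keyOf, "")
  alt <- alt[keys != curKey]; keys <- keys[keys != curKey]
  if (length(alt) == 0) return(list(D = D, score = score))  # identity move
  pick <- sample.int(length(alt), 1L)
  wFwd <- if (length(unique(keys)) == 1L) 1 else 0.5
  d1 <- alt[[pick]][[1]]; d2 <- alt[[pick]][[2]]

  at <- function(g) D[g[1], g[2]]
  setAt <- function(M, g, v) { M[g[1], g[2]] <- v; M }
  # pi ratio via sequential remove/add (exact factorial ratios)
  Dn <- D; lr <- 0
  for (g in list(g1, g2)) { lr <- lr + log(Dn[g[1], g[2]]); Dn <- setAt(Dn, g, Dn[g[1], g[2]] - 1L) }
  for (g in list(d1, d2)) { Dn <- setAt(Dn, g, Dn[g[1], g[2]] + 1L); lr <- lr - log(Dn[g[1], g[2]]) }
  dh <- (d1[1] != d1[2]) + (d2[1] != d2[2]) - (g1[1] != g1[2]) - (g2[1] != g2[2])
  lr <- lr + dh * log(2)
  # selection probabilities (unordered pair of individuals)
  selFwd <- if (identical(g1, g2)) at(g1) * (at(g1) - 1) else 2 * at(g1) * at(g2)
  atN <- function(g) Dn[g[1], g[2]]
  selRev <- if (identical(d1, d2)) atN(d1) * (atN(d1) - 1) else 2 * atN(d1) * atN(d2)
  # reverse proposal weight: from Dn, re-pairing {d1,d2} has two
  # alternatives; the move back to {g1,g2} is proposed w.p. wRev
  altRev <- list(list(sort(c(d1[1], d2[1])), sort(c(d1[2], d2[2]))),
                 list(sort(c(d1[1], d2[2])), sort(c(d1[2], d2[1]))))
  keysRev <- vapply(altRev, keyOf, "")
  keysRev <- keysRev[keysRev != keyOf(list(d1, d2))]
  wRev <- if (length(unique(keysRev)) == 1L) 1 else 0.5
  logAcc <- lr + log(selRev * wRev) - log(selFwd * wFwd)
  if (log(stats::runif(1)) < logAcc)
    list(D = Dn, score = score + lr)
  else
    list(D = D, score = score)
}

#' Exact test for Hardy-Weinberg equilibrium (Markov chain)
#'
#' Guo-Thompson switch-chain Monte Carlo over genotype tables with the
#' observed allele counts. The p-value is the proportion of retained chain
#' states whose conditional table probability is less than or equal to the
#' observed one.
#'
#' @param dataset an [STRDataset-class].
#' @param locus locus name.
#' @param location location id.
#' @param steps retained Markov chain steps (>= 1e4; surveys conventionally
#'   use 1e6).
#' @param dememorization burn-in steps discarded before retention.
#' @param seed integer seed.
#' @return list with `p`, `steps`, `obsScore` (log conditional probability
#'   of the observed table up to a constant), `k` (allele count) and
#'   `flag` ("monomorphic" when fewer than 2 alleles segregate, in which
#'   case p = 1).
#' @references Guo SW, Thompson EA (1992) Performing the exact test of
#'   Hardy-Weinberg proportion for multiple alleles. Biometrics 48:361-372.
#' @export
hweExactTest <- function(dataset, locus, location, steps = 1e6,
                         dememorization = 1e5, seed = 1) {
  if (steps < 1e4) stop("steps must be at least 1e4")
  j <- match(locus, dataset@loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  sel <- dataset@locationId == location
  if (!any(sel)) stop("unknown location: ", location)
  a1 <- dataset@alleles1[sel, j]; a2 <- dataset@alleles2[sel, j]
  alle <- sort(unique(c(a1, a2)))
  k <- length(alle)
  if (k < 2)
    return(list(p = 1, steps = 0L, obsScore = NA_real_, k = k,
                flag = "monomorphic"))
  D <- matrix(0L, k, k)
  for (i in seq_along(a1)) {
    g <- sort(c(match(a1[i], alle), match(a2[i], alle)))
    D[g[1], g[2]] <- D[g[1], g[2]] + 1L
  }
  set.seed(seed)
  obs <- hweTableScore(D)
  score <- obs
  le <- 0L
  total <- dememorization + steps
  for (s in seq_len(total)) {
    st <- hweSwitchStep(D, score)
    D <- st$D; score <- st$score
    if (s > dememorization && score <= obs + 1e-7) le <- le + 1L
  }
  list(p = le / steps, steps = as.integer(steps), obsScore = obs, k = k,
       flag = "ok")
}
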