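# Shared fixtures and independent oracles, all built in code.

# A tiny georeferenced dataset: two locations, two loci, microvariants.
tinyDataset <- function() {
  loc <- data.frame(id = c("A", "B"), name = c("Alpha", "Beta"),
                    lon = c(10, 12), lat = c(40, 41),
                    stringsAsFactors = FALSE)
  a1 <- rbind(c("12", "9"), c("12", "9.3"), c("15", "9"), c("12", "8"))
  a2 <- rbind(c("15", "9.3"), c("12", "9.3"), c("15", "9"), c("16", "9"))
  STRDataset(c("L1", "TH01"), a1, a2, paste0("s", 1:4),
             c("A", "A", "B", "B"), loc)
}

# Independent Weir & Cockerham (1984) oracle: plain scalar loops straight
# from the published component formulas, one allele at a time.
wcOracle <- function(genoList) {
  # genoList: per locus, a list of per-deme two-column matrices of alleles
  sumA <- sumB <- sumC <- 0
  for (locus in genoList) {
    r <- length(locus)
    ni <- vapply(locus, nrow, 0)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(unlist(locus)))
    for (al in alleles) {
      p <- h <- numeric(r)
      for (i in seq_len(r)) {
        g <- locus[[i]]
        p[i] <- sum(g == al) / (2 * ni[i])
        h[i] <- sum((g[, 1] == al) != (g[, 2] == al)) / ni[i]
      }
      pbar <- sum(ni * p) / (r * nbar)
      s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h) / (r * nbar)
      aa <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
              (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      bb <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
              ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      sumA <- sumA + aa; sumB <- sumB + bb; sumC <- sumC + cc
    }
  }
  sumA / (sumA + sumB + sumC)
}

# Build an STRDataset from a list of per-deme two-column allele matrices
# (one locus list per element of genoList).
genoListToDataset <- function(genoList) {
  r <- length(genoList[[1]])
  ni <- vapply(genoList[[1]], nrow, 0)
  loc <- data.frame(id = paste0("P", seq_len(r)),
                    name = paste0("Pool ", seq_len(r)),
                    lon = seq_len(r), lat = 0, stringsAsFactors = FALSE)
  a1 <- do.call(cbind, lapply(genoList, function(locus)
    unlist(lapply(locus, function(g) g[, 1]))))
  a2 <- do.call(cbind, lapply(genoList, function(locus)
    unlist(lapply(locus, function(g) g[, 2]))))
  STRDataset(paste0("L", seq_along(genoList)), a1 * 10L, a2 * 10L,
             paste0("s", seq_len(sum(ni))), rep(loc$id, ni), loc)
}

# Exact Hardy-Weinberg test by enumeration of all genotype tables with the
# observed allele counts (small k and n only). Independent of the chain.
hweEnumerate <- function(D) {
  k <- nrow(D)
  counts <- integer(k)
  for (i in 1:k) for (j in i:k) {
    counts[i] <- counts[i] + D[i, j]
    counts[j] <- counts[j] + D[i, j]
  }
  n <- sum(D[upper.tri(D, diag = TRUE)])
  score <- function(M) sum(M[upper.tri(M)]) * log(2) -
    sum(lfactorial(M[upper.tri(M, diag = TRUE)]))
  cells <- which(upper.tri(D, diag = TRUE), arr.ind = TRUE)
  tables <- list()
  rec <- function(M, cellIdx, left) {
    if (cellIdx > nrow(cells)) {
      if (all(left == 0)) tables[[length(tables) + 1L]] <<- M
      return(invisible())
    }
    i <- cells[cellIdx, 1]; j <- cells[cellIdx, 2]
    cap <- if (i == j) min(left[i] %/% 2, n) else min(left[i], left[j])
    for (v in 0:cap) {
      M[i, j] <- v
      l2 <- left
      l2[i] <- l2[i] - v * (if (i == j) 2 else 1)
      if (i != j) l2[j] <- l2[j] - v
      if (all(l2 >= 0)) rec(M, cellIdx + 1L, l2)
    }
  }
  rec(matrix(0L, k, k), 1L, counts)
  sc <- vapply(tables, score, 0)
  lp <- sc - max(sc)
  # multinomial coefficient part: n! constant; table prob ~ exp(score)
  w <- exp(lp)
  pTab <- w / sum(w)
  obs <- score(D)
  sum(pTab[sc <= obs + 1e-9])
}

# Small synthetic spec used across tests (fast to generate).
smallSpec <- function(...) {
  args <- utils::modifyList(
    list(nLocations = 10, loci = c(LA = 4, LB = 6, LC = 5),
         nClines = 2, nFoci = 0, nPerLocation = 20, seed = 42),
    list(...))
  do.call(syntheticSpec, args)
}
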