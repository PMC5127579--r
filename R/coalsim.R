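# Backward-in-time coalescent simulator for split-from-pool demographies,
# used to generate Weir-Cockerham Fst distributions under candidate
# migration rates and score an observed Fst against them.
#
# Conventions (fastsimcoal-style): population sizes are GENE COPIES;
# coalescence follows discrete Wright-Fisher parent sampling among the N(t)
# copies of each population (per-pair probability 1/N); migration and
# pool-exchange rates are backward per-lineage per-generation
# probabilities. Generation-by-generation (discrete) simulation keeps
# time-varying sizes trivial; with all rates <= 0.02 the discretisation
# error is negligible.

#' Split-from-pool demographic model (14 demes)
#'
#' A set of demes splits from a large pool growing at `poolGrowth` per
#' generation; each deme's split time and founding size are drawn uniformly
#' per replicate, the demes grow at `demeGrowth` per generation between
#' their split and the present, exchange gene copies with the pool at fixed
#' sending/receiving rates and exchange migrants among themselves at rate
#' `m` (per-lineage total, destination uniform over the other demes).
#'
#' Deme sizes are drawn at the FOUNDING time (the split) and grow forward
#' to the present, so a deme founded with ~1600 copies 250 generations ago
#' holds ~1.1e5 copies today; the pool size is the present-day value,
#' shrinking backward at its growth rate. The deme-pool exchange is
#' parameterised in the backward (lineage-tracing) convention: the
#' conventional forward rates — demes sending copies to the pool at 1e-3
#' and receiving at 1e-4 per copy per generation — convert to a backward
#' deme-to-pool probability equal to the immigrant fraction (1e-4) and a
#' backward pool-to-deme probability of roughly
#' send x demeSize / poolSize ~ 2e-5 per deme, the defaults here.
#'
#' @param nDemes number of demes.
#' @param m among-deme migration rate (per lineage per generation).
#' @param demeSizeRange uniform range of deme founding sizes (gene copies).
#' @param demeGrowth deme growth rate per generation.
#' @param splitTimeRange uniform range of split times (generations ago).
#' @param poolSize current pool size (gene copies).
#' @param poolGrowth pool growth rate per generation.
#' @param demeToPool backward probability that a deme lineage traces to the
#'   pool (the forward receiving rate).
#' @param poolToDeme backward probability, per deme, that a pool lineage
#'   traces to that deme (the forward sending rate scaled by the
#'   deme/pool size ratio).
#' @param generationTime years per generation (reporting only).
#' @return a [DemographicModel-class].
#' @export
model1Demography <- function(nDemes = 14, m = 0.01,
                             demeSizeRange = c(800, 2400),
                             demeGrowth = 0.017,
                             splitTimeRange = c(224, 276),
                             poolSize = 1e5, poolGrowth = 0.020,
                             demeToPool = 1e-4, poolToDeme = 2e-5,
                             generationTime = 29) {
  new("DemographicModel", nDemes = as.integer(nDemes), m = m,
      demeSizeRange = demeSizeRange, demeGrowth = demeGrowth,
      splitTimeRange = splitTimeRange, poolSize = poolSize,
      poolGrowth = poolGrowth, demeToPool = demeToPool,
      poolToDeme = poolToDeme, joinerTimes = numeric(0), joinerM = 0,
      generationTime = generationTime)
}

#' Split-from-pool model with recently joined demes (17 demes)
#'
#' [model1Demography()] plus `joiner' demes that split from the pool at the
#' given recent times and exchange migrants with the resident demes (and
#' each other) at rate `joinerM`. Joiner sizes, growth and pool exchange
#' follow the resident template. Migration is parameterised per pair as
#' rate/(nDemes - 1), so `joinerM = m` makes the 17-deme migration matrix
#' uniform.
#'
#' @inheritParams model1Demography
#' @param joinerTimes split times of the joiner demes (generations ago).
#' @param joinerM joiner-resident exchange rate (per lineage per
#'   generation, same normalisation as `m`).
#' @return a [DemographicModel-class].
#' @export
model2Demography <- function(nDemes = 14, m = 0.01,
                             joinerTimes = c(96, 96, 18), joinerM = 0.001,
                             ...) {
  mod <- model1Demography(nDemes = nDemes, m = m, ...)
  mod@joinerTimes <- as.numeric(joinerTimes)
  mod@joinerM <- joinerM
  validObject(mod)
  mod
}

#' Constant-size island model
#'
#' d demes of fixed size with symmetric migration and no pool: the
#' equilibrium model with the closed-form expectation
#' \eqn{F_{ST} \approx 1 / (1 + 4 N m (d/(d-1))^2)} (N diploids per deme)
#' used to calibrate the simulator.
#'
#' @param nDemes number of demes.
#' @param size deme size in gene copies.
#' @param m per-lineage total emigration probability per generation.
#' @return a [DemographicModel-class].
#' @export
islandDemography <- function(nDemes = 8, size = 1000, m = 0.002) {
  new("DemographicModel", nDemes = as.integer(nDemes), m = m,
      demeSizeRange = c(size, size), demeGrowth = 0,
      splitTimeRange = c(Inf, Inf), poolSize = 0, poolGrowth = 0,
      demeToPool = 0, poolToDeme = 0, joinerTimes = numeric(0), joinerM = 0,
      generationTime = 29)
}

#' Stepwise mutation model
#'
#' @param mu per-locus mutation rate per copy per generation.
#' @param K number of allele states (reflecting bounds).
#' @param nLoci independent loci per replicate (default 8, the size of a
#'   reduced dataset).
#' @return a [MutationModel-class].
#' @export
mutationModel <- function(mu = 5e-4, K = 20, nLoci = 8) {
  new("MutationModel", mu = mu, K = as.integer(K), nLoci = as.integer(nLoci))
}

# ---- core engine ----------------------------------------------------------

# One coalescent replicate; returns genotype code matrices (individuals x
# loci) and the deme index per individual. Consumes the current RNG stream.
# The generation loop and mutation dropping run in compiled code (same RNG
# stream); this R reference implementation is retained for cross-checking.
simCoalReplicate <- function(model, mutation, sampleSizes,
                             engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  nRes <- model@nDemes
  nJoin <- length(model@joinerTimes)
  D <- nRes + nJoin
  if (length(sampleSizes) == 1L) sampleSizes <- rep(as.integer(sampleSizes), D)
  if (length(sampleSizes) != D)
    stop("need one sample size per deme (residents + joiners)")
  island <- is.infinite(model@splitTimeRange[1])
  if (!island && model@poolSize < 2) stop("split models need a pool")
  if (engine == "R")
    return(simCoalReplicateR(model, mutation, sampleSizes))
  sizes <- stats::runif(D, model@demeSizeRange[1], model@demeSizeRange[2])
  split <- if (island) rep(Inf, D)
           else c(ceiling(stats::runif(nRes, model@splitTimeRange[1],
                                       model@splitTimeRange[2])),
                  ceiling(model@joinerTimes))
  curSizes <- if (island) sizes else sizes * exp(model@demeGrowth * split)
  low <- curSizes < 2 * sampleSizes
  if (any(low)) sizes[low] <- sizes[low] * (2 * sampleSizes / curSizes)[low]
  q1 <- if (nRes > 1) model@m / (nRes - 1) else 0
  q2 <- if (nRes > 1) model@joinerM / (nRes - 1) else 0
  .cppSimReplicate(nRes, nJoin, sizes, split, island,
                   model@poolSize, model@poolGrowth, model@demeGrowth,
                   q1, q2, model@demeToPool, model@poolToDeme,
                   as.integer(sampleSizes),
                   mutation@mu, mutation@K, mutation@nLoci)
}

simCoalReplicateR <- function(model, mutation, sampleSizes) {
  nRes <- model@nDemes
  nJoin <- length(model@joinerTimes)
  D <- nRes + nJoin
  if (length(sampleSizes) == 1L) sampleSizes <- rep(as.integer(sampleSizes), D)
  if (length(sampleSizes) != D)
    stop("need one sample size per deme (residents + joiners)")
  island <- is.infinite(model@splitTimeRange[1])
  # founding size of each deme (gene copies, at its split time); demes grow
  # forward at demeGrowth between founding and the present
  sizes <- stats::runif(D, model@demeSizeRange[1], model@demeSizeRange[2])
  split <- if (island) rep(Inf, D)
           else c(ceiling(stats::runif(nRes, model@splitTimeRange[1],
                                       model@splitTimeRange[2])),
                  ceiling(model@joinerTimes))
  curSizes <- if (island) sizes else sizes * exp(model@demeGrowth * split)
  low <- curSizes < 2 * sampleSizes         # a deme must hold its sample
  if (any(low)) sizes[low] <- sizes[low] * (2 * sampleSizes / curSizes)[low]
  if (!island && model@poolSize < 2) stop("split models need a pool")

  nTips <- 2L * sum(sampleSizes)
  maxN <- 2L * nTips + 2L
  parent <- integer(maxN)
  birth <- numeric(maxN)
  act <- seq_len(nTips)                      # active lineage -> node id
  pop <- rep.int(seq_len(D), 2L * sampleSizes)  # 0 = pool, 1..D demes
  nextNode <- nTips + 1L
  demeAlive <- rep(TRUE, D)
  isJoin <- c(rep(FALSE, nRes), rep(TRUE, nJoin))
  q1 <- if (nRes > 1) model@m / (nRes - 1) else 0       # per-pair, res-res
  q2 <- if (nRes > 1) model@joinerM / (nRes - 1) else 0 # per-pair, joiner
  snd <- model@demeToPool; rcv <- model@poolToDeme
  t <- 0
  while (length(act) > 1L) {
    t <- t + 1
    if (t > 1e6) stop("coalescence did not complete within 1e6 generations")
    if (!island) {
      gone <- which(demeAlive & split <= t)
      if (length(gone)) {
        pop[pop %in% gone] <- 0L
        demeAlive[gone] <- FALSE
      }
    }
    aliveR <- which(demeAlive & !isJoin)
    aliveJ <- which(demeAlive & isJoin)
    nAlive <- length(aliveR) + length(aliveJ)
    k <- length(act)
    # ---- migration: total emigration probability per lineage class ----
    pRes <- q1 * max(length(aliveR) - 1L, 0L) + q2 * length(aliveJ) + snd
    pJoin <- q2 * max(nAlive - 1L, 0L) + snd
    pPool <- rcv * nAlive
    cls <- ifelse(pop == 0L, 0L, ifelse(isJoin[pmax(pop, 1L)], 2L, 1L))
    ptot <- c(pPool, pRes, pJoin)[cls + 1L]
    movers <- which(stats::runif(k) < ptot)
    for (i in movers) {
      d <- pop[i]
      if (d == 0L) {
        dd <- c(aliveR, aliveJ)
        pop[i] <- dd[sample.int(length(dd), 1L)]
      } else if (!isJoin[d]) {
        dest <- c(setdiff(aliveR, d), aliveJ, if (snd > 0) 0L)
        w <- c(rep(q1, length(aliveR) - (d %in% aliveR)),
               rep(q2, length(aliveJ)), if (snd > 0) snd)
        pop[i] <- dest[sample.int(length(dest), 1L, prob = w)]
      } else {
        dest <- c(aliveR, setdiff(aliveJ, d), if (snd > 0) 0L)
        w <- c(rep(q2, length(aliveR) + length(aliveJ) - 1L),
               if (snd > 0) snd)
        pop[i] <- dest[sample.int(length(dest), 1L, prob = w)]
      }
    }
    # ---- coalescence: Wright-Fisher parent sampling within populations ----
    Npool <- if (model@poolSize >= 2) max(2, round(model@poolSize *
                                                   exp(-model@poolGrowth * t))) else 1
    # deme size backward: founding size inflated by the growth still to come
    Ndeme <- if (island) sizes else pmax(2, round(sizes * exp(model@demeGrowth *
                                                              (split - t))))
    Nvec <- c(Npool, Ndeme)[pop + 1L]
    slot <- floor(stats::runif(k) * Nvec)
    key <- pop * (max(Nvec) + 1) + slot
    if (anyDuplicated(key)) {
      grp <- match(key, key)
      cnt <- tabulate(grp, k)
      drop <- integer(0)
      for (g in which(cnt > 1L)) {
        mem <- which(grp == g)
        nd <- nextNode; nextNode <- nextNode + 1L
        parent[act[mem]] <- nd
        birth[nd] <- t
        act[mem[1L]] <- nd
        drop <- c(drop, mem[-1L])
      }
      act <- act[-drop]
      pop <- pop[-drop]
    }
  }
  # ---- drop mutations on the realised genealogy (all loci at once) ----
  nN <- nextNode - 1L
  L <- mutation@nLoci; K <- mutation@K
  idx <- seq_len(nN)
  bl <- numeric(nN)
  hasPar <- parent[idx] > 0L
  bl[hasPar] <- birth[parent[idx][hasPar]] - birth[idx][hasPar]
  nm <- matrix(stats::rpois(nN * L, mutation@mu * bl), nN, L)
  net <- matrix(0L, nN, L)
  nz <- which(nm > 0)
  if (length(nz))
    net[nz] <- 2L * stats::rbinom(length(nz), nm[nz], 0.5) - nm[nz]
  free <- matrix(0L, nN, L)
  for (nd in order(birth[idx], decreasing = TRUE)) {
    pp <- parent[nd]
    if (pp > 0L) free[nd, ] <- free[pp, ] + net[nd, ]
  }
  # fold the free walk into 1..K (reflecting bounds, billiard map)
  start <- (K + 1L) %/% 2L
  y <- start + free[seq_len(nTips), , drop = FALSE]
  P <- 2L * K - 2L
  mm <- (y - 1L) %% P
  st <- matrix(ifelse(mm < K, mm + 1L, 2L * K - 1L - mm), nTips, L)
  odd <- seq(1L, nTips, by = 2L)
  list(a1 = st[odd, , drop = FALSE], a2 = st[odd + 1L, , drop = FALSE],
       popInd = rep.int(seq_len(D), sampleSizes), D = D)
}

#' Simulate one coalescent replicate as an STRDataset
#'
#' Runs the backward simulation for the given demographic and mutation
#' models and returns the sampled diploid genotypes as a dataset (demes
#' become locations laid out on a nominal one-degree transect; allele
#' states are reported as repeat counts 10, 11, ...).
#'
#' @param model a [DemographicModel-class].
#' @param mutation a [MutationModel-class].
#' @param sampleSizes diploids sampled per deme (scalar recycled, or one
#'   value per deme including joiners).
#' @param seed integer seed.
#' @return an [STRDataset-class].
#' @export
simulateReplicate <- function(model, mutation, sampleSizes = 30, seed = 1) {
  set.seed(seed)
  rep1 <- simCoalReplicate(model, mutation, sampleSizes)
  D <- rep1$D
  loci <- sprintf("sim%02d", seq_len(mutation@nLoci))
  lab <- function(stMat) matrix(10L * (stMat + 9L), nrow(stMat), ncol(stMat))
  locs <- data.frame(id = sprintf("D%02d", seq_len(D)),
                     name = c(sprintf("Deme %02d", seq_len(model@nDemes)),
                              if (length(model@joinerTimes))
                                sprintf("Joiner %02d",
                                        seq_along(model@joinerTimes))),
                     lon = seq_len(D) - 1, lat = 0,
                     stringsAsFactors = FALSE)
  STRDataset(loci, lab(rep1$a1), lab(rep1$a2),
             sprintf("I%05d", seq_along(rep1$popInd)),
             locs$id[rep1$popInd], locs)
}

#' Simulated Fst distribution at one migration rate
#'
#' Runs R coalescent replicates, computes the multi-locus Weir-Cockerham
#' theta of each, and (optionally) scores an observed Fst against the
#' distribution with empirical tail probabilities
#' \eqn{p_{lower} = (1 + \#\{\theta_{sim} \le \theta_{obs}\})/(R+1)} (upper
#' analogous; two-sided = 2 min, capped at 1).
#'
#' @inheritParams simulateReplicate
#' @param m among-deme migration rate; overrides `model@m`.
#' @param R replicates (>= 100).
#' @param observed observed Fst to score (NA to skip).
#' @param seed integer seed; the whole distribution is reproducible.
#' @param vary which rate `m` replaces: the among-deme rate (`"m"`) or the
#'   joiner exchange rate (`"joinerM"`).
#' @return an [FstDistribution-class].
#' @export
fstDistribution <- function(model, mutation, sampleSizes = 30,
                            m = model@m, R = 2000, observed = NA_real_,
                            seed = 1, vary = c("m", "joinerM")) {
  if (R < 100) stop("R must be at least 100")
  vary <- match.arg(vary)
  slot(model, vary) <- m
  validObject(model)
  set.seed(seed)
  vals <- numeric(R)
  for (i in seq_len(R)) {
    rep1 <- tryCatch(simCoalReplicate(model, mutation, sampleSizes),
                     error = function(e)
                       stop(sprintf("replicate %d: %s", i, conditionMessage(e))))
    vals[i] <- wcThetaMatrices(rep1$a1, rep1$a2, rep1$popInd, rep1$D)$theta
  }
  pl <- pu <- pt <- NA_real_
  if (!is.na(observed)) {
    pl <- (1 + sum(vals <= observed)) / (R + 1)
    pu <- (1 + sum(vals >= observed)) / (R + 1)
    pt <- min(1, 2 * min(pl, pu))
  }
  new("FstDistribution", m = m, values = vals, observed = observed,
      pLower = pl, pUpper = pu, pTwoSided = pt)
}

#' Sweep migration rates against an observed Fst
#'
#' Simulates an Fst distribution at every rate of the grid, reports the
#' empirical compatibility of the observed value at each ("acceptable" when
#' the two-sided p >= 0.05) and the best-fitting rate (simulated median
#' closest to the observed Fst).
#'
#' @inheritParams fstDistribution
#' @param mGrid vector of rates to sweep.
#' @param observedFst the observed Fst.
#' @return list with `table` (m, median, mean, pLower, pUpper, pTwoSided,
#'   acceptable), `best` (best-fitting rate), `distributions` (list of
#'   [FstDistribution-class]).
#' @export
sweepMigration <- function(model, mutation, sampleSizes = 30,
                           mGrid = c(0, 0.0005, 0.001, 0.0025, 0.005,
                                     0.01, 0.02),
                           R = 2000, observedFst, seed = 1,
                           vary = c("m", "joinerM")) {
  if (!length(mGrid)) stop("mGrid must be non-empty")
  vary <- match.arg(vary)
  dists <- lapply(seq_along(mGrid), function(i)
    fstDistribution(model, mutation, sampleSizes, m = mGrid[i], R = R,
                    observed = observedFst, seed = deriveSeed(seed, paste0("m", i)),
                    vary = vary))
  med <- vapply(dists, function(d) stats::median(d@values), 0)
  tab <- data.frame(m = mGrid, median = med,
                    mean = vapply(dists, function(d) mean(d@values), 0),
                    pLower = vapply(dists, function(d) d@pLower, 0),
                    pUpper = vapply(dists, function(d) d@pUpper, 0),
                    pTwoSided = vapply(dists, function(d) d@pTwoSided, 0),
                    acceptable = vapply(dists, function(d)
                      !is.na(d@pTwoSided) && d@pTwoSided >= 0.05, TRUE))
  list(table = tab, best = mGrid[which.min(abs(med - observedFst))],
       distributions = dists)
}

#' Expected migrant copies per deme per generation
#'
#' \eqn{M = m \times \bar N} with \eqn{\bar N} the mean current deme size
#' in gene copies: the expected number of gene copies emigrating from a
#' deme each generation (linear in m; about 30 at m = 0.02 for sizes
#' uniform on 800-2400).
#'
#' @param model a [DemographicModel-class].
#' @param m migration rate (defaults to the model's).
#' @return expected migrant copies per generation (scalar).
#' @export
migrantCopies <- function(model, m = model@m) {
  m * mean(model@demeSizeRange)
}
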