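test_that("long-isolated demes approach fixation-level Fst", {
  mod <- model1Demography(nDemes = 2, m = 0, demeToPool = 0, poolToDeme = 0,
                          demeSizeRange = c(100, 100), demeGrowth = 0,
                          splitTimeRange = c(3000, 3000), poolSize = 500,
                          poolGrowth = 0)
  mut <- mutationModel(mu = 2e-3, K = 20, nLoci = 6)
  set.seed(1)
  v <- numeric(100)
  for (i in 1:100) {
    r <- strscape:::simCoalReplicate(mod, mut, 20)
    v[i] <- strscape:::wcThetaMatrices(r$a1, r$a2, r$popInd, r$D)$theta
  }
  expect_gt(mean(v), 0.5)
})

test_that("a single deme leaves Fst undefined, with a signal", {
  mod <- islandDemography(nDemes = 1, size = 200, m = 0)
  mut <- mutationModel(mu = 1e-3, K = 10, nLoci = 2)
  set.seed(2)
  r <- strscape:::simCoalReplicate(mod, mut, 10)
  expect_error(strscape:::wcThetaMatrices(r$a1, r$a2, r$popInd, r$D),
               "two groups")
  ds <- simulateReplicate(mod, mut, 10, seed = 2)
  expect_error(weirCockerhamFst(ds), "two groups")
})

test_that("island-model Fst matches the closed form within 25%", {
  mut <- mutationModel(mu = 1e-4, K = 40, nLoci = 12)
  for (Nm in c(1, 5)) {
    m <- Nm / 500                           # 1000 gene copies = 500 diploids
    mod <- islandDemography(nDemes = 8, size = 1000, m = m)
    set.seed(5)
    v <- numeric(40)
    for (i in 1:40) {
      r <- strscape:::simCoalReplicate(mod, mut, 25)
      v[i] <- strscape:::wcThetaMatrices(r$a1, r$a2, r$popInd, r$D)$theta
    }
    cf <- 1 / (1 + 4 * 500 * m * (8 / 7)^2)
    expect_lt(abs(mean(v) - cf) / cf, 0.25)
  }
})

test_that("mean simulated Fst decreases with the migration rate", {
  mut <- mutationModel()
  med <- vapply(c(0.001, 0.0025, 0.005, 0.01), function(mm) {
    set.seed(31)
    v <- numeric(120)
    mod <- model1Demography(m = mm)
    for (i in 1:120) {
      r <- strscape:::simCoalReplicate(mod, mut, 30)
      v[i] <- strscape:::wcThetaMatrices(r$a1, r$a2, r$popInd, r$D)$theta
    }
    mean(v)
  }, 0)
  expect_true(all(diff(med) < 0))
})

test_that("fstDistribution scores observations and is reproducible", {
  mod <- islandDemography(nDemes = 4, size = 400, m = 0.01)
  mut <- mutationModel(mu = 1e-3, K = 15, nLoci = 4)
  d1 <- fstDistribution(mod, mut, sampleSizes = 10, m = 0.01, R = 100,
                        observed = -1, seed = 9)
  expect_equal(d1@pLower, 1 / 101)          # observed below every replicate
  expect_equal(d1@pUpper, 1)
  d2 <- fstDistribution(mod, mut, sampleSizes = 10, m = 0.01, R = 100,
                        observed = -1, seed = 9)
  expect_identical(d1@values, d2@values)    # bit-exact under a fixed seed
  med <- stats::median(d1@values)
  d3 <- fstDistribution(mod, mut, sampleSizes = 10, m = 0.01, R = 100,
                        observed = med, seed = 9)
  expect_gt(d3@pTwoSided, 0.9)              # the median is fully compatible
  expect_error(fstDistribution(mod, mut, R = 50), "at least 100")
})

test_that("migration sweeps report a table row per rate and a best fit", {
  mod <- islandDemography(nDemes = 4, size = 400, m = 0.01)
  mut <- mutationModel(mu = 1e-3, K = 15, nLoci = 4)
  grid <- c(0.002, 0.01, 0.05)
  sw <- sweepMigration(mod, mut, sampleSizes = 10, mGrid = grid, R = 100,
                       observedFst = 0, seed = 3)
  expect_equal(nrow(sw$table), length(grid))
  expect_equal(sw$table$m, grid)
  expect_true(sw$best %in% grid)
  expect_equal(sw$best, grid[which.min(abs(sw$table$median - 0))])
})

test_that("sweeps recover the generating migration rate", {
  # observed Fst generated under the middle rate: the sweep should pick it
  mod <- islandDemography(nDemes = 5, size = 600, m = 0.005)
  mut <- mutationModel(mu = 5e-4, K = 20, nLoci = 8)
  hits <- 0
  for (meta in 1:5) {
    set.seed(400 + meta)
    r <- strscape:::simCoalReplicate(mod, mut, 20)
    obs <- strscape:::wcThetaMatrices(r$a1, r$a2, r$popInd, r$D)$theta
    sw <- sweepMigration(mod, mut, sampleSizes = 20,
                         mGrid = c(0.001, 0.005, 0.025), R = 100,
                         observedFst = obs, seed = 500 + meta)
    if (sw$best == 0.005) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("model 2 differentiation falls as joiner exchange rises", {
  mut <- mutationModel()
  med <- vapply(c(0, 0.01), function(m2) {
    set.seed(77)
    v <- numeric(100)
    mod <- model2Demography(joinerM = m2)
    for (i in 1:100) {
      r <- strscape:::simCoalReplicate(mod, mut, 30)
      v[i] <- strscape:::wcThetaMatrices(r$a1, r$a2, r$popInd, r$D)$theta
    }
    stats::median(v)
  }, 0)
  expect_gt(med[1], med[2])
})

test_that("migrant copies follow M = m x mean deme size", {
  mod <- model1Demography()
  expect_equal(migrantCopies(mod, 0.02), 0.02 * 1600)  # ~ 30 copies
  expect_equal(migrantCopies(mod, 0), 0)
  expect_equal(migrantCopies(mod, 0.01) * 2, migrantCopies(mod, 0.02))
})

test_that("simulateReplicate returns a valid georeferenced dataset", {
  mod <- model2Demography()
  mut <- mutationModel(nLoci = 3)
  ds <- simulateReplicate(mod, mut, sampleSizes = 5, seed = 12)
  expect_s4_class(ds, "STRDataset")
  expect_equal(nLocations(ds), 17)          # 14 residents + 3 joiners
  expect_equal(nSubjects(ds), 17 * 5)
  expect_equal(length(locusNames(ds)), 3)
  expect_true(validObject(ds))
})

test_that("model constructors validate their rates and sizes", {
  expect_error(model1Demography(m = 1.2), "rates")
  expect_error(model1Demography(demeSizeRange = c(1, 10)), "gene copies")
  expect_error(model2Demography(joinerTimes = c(-5, 96, 18)), "positive")
  expect_error(mutationModel(mu = 0.5), "mu")
  expect_error(mutationModel(K = 1), "K")
})
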