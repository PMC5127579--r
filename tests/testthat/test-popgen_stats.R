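test_that("theta matches the independent variance-component oracle exactly", {
  # printed-counts example: 2 demes x 10 diploids, one biallelic locus
  d1 <- cbind(c(1, 1, 1, 1, 1, 1, 2, 2, 1, 2), c(1, 1, 2, 2, 1, 2, 2, 2, 1, 2))
  d2 <- cbind(c(2, 2, 2, 1, 2, 2, 2, 2, 2, 1), c(2, 2, 2, 2, 2, 2, 1, 2, 2, 2))
  genoList <- list(list(d1, d2))
  ds <- genoListToDataset(genoList)
  expect_equal(weirCockerhamFst(ds)$fst, wcOracle(genoList), tolerance = 1e-12)

  # random small instances: 2 demes, 1 locus, <= 4 alleles, <= 6 diploids
  set.seed(1234)
  tested <- 0
  for (rep in 1:300) {
    k <- sample(2:4, 1)
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    g1 <- matrix(sample.int(k, 2 * n1, replace = TRUE), n1)
    g2 <- matrix(sample.int(k, 2 * n2, replace = TRUE), n2)
    gl <- list(list(g1, g2))
    oracle <- wcOracle(gl)
    if (!is.finite(oracle)) next          # both demes monomorphic
    tested <- tested + 1
    expect_equal(weirCockerhamFst(genoListToDataset(gl))$fst, oracle,
                 tolerance = 1e-12)
  }
  expect_gt(tested, 250)
})

test_that("theta hits the fixation and no-differentiation limits", {
  fixed <- list(list(matrix(1L, 8, 2), matrix(2L, 8, 2)))
  expect_equal(weirCockerhamFst(genoListToDataset(fixed))$fst, 1)

  set.seed(2)
  g <- matrix(sample.int(5, 40, replace = TRUE), 20)
  dup <- list(list(g, g))                 # two identical demes
  expect_lte(weirCockerhamFst(genoListToDataset(dup))$fst, 1e-12)

  mono <- list(list(matrix(1L, 4, 2), matrix(1L, 4, 2)))
  expect_error(weirCockerhamFst(genoListToDataset(mono)), "monomorphic")
})

test_that("permutation p-values respect their floor and detect structure", {
  expect_error(fstPermutationTest(tinyDataset(), B = 50), "at least 100")
  fixed <- genoListToDataset(list(list(matrix(1L, 10, 2), matrix(2L, 10, 2))))
  res <- fstPermutationTest(fixed, B = 199, seed = 4)
  expect_equal(res$p, 1 / 200)            # maximal differentiation
  expect_gte(res$p, 1 / (res$B + 1))
})

test_that("permutation p-values are near-uniform under the null", {
  # a fresh unstructured dataset per seed: its permutation p is then one
  # draw from the null distribution of p-values
  ps <- vapply(1:120, function(s) {
    set.seed(s)
    g1 <- matrix(sample.int(4, 24, replace = TRUE), 12)
    g2 <- matrix(sample.int(4, 24, replace = TRUE), 12)
    ds <- genoListToDataset(list(list(g1, g2)))
    fstPermutationTest(ds, B = 199, seed = 1000 + s)$p
  }, 0)
  # discrete uniform on {1/200, ..., 1}: compare via KS; alpha = 0.01
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps > 0.05), 0.80)
})

test_that("pairwise Fst matrix is symmetric, zero-diagonal and consistent", {
  set.seed(11)
  sp <- smallSpec(nLocations = 4, nPerLocation = 15)
  ds <- simulateSTRData(sp)$dataset
  M <- pairwiseFst(ds)
  expect_equal(M, t(M), tolerance = 1e-15)
  expect_true(all(diag(M) == 0))
  ids <- locationInfo(ds)$id
  pair <- weirCockerhamFst(
    ds, grouping = stats::setNames(
      ifelse(ids %in% ids[1], "x", ifelse(ids %in% ids[2], "y", "drop")),
      ids))
  # consistency against the two-group estimator restricted to the pair
  keep <- locationOf(ds) %in% ids[1:2]
  sub <- STRDataset(ds@loci, ds@alleles1[keep, ], ds@alleles2[keep, ],
                    ds@subjectIds[keep], ds@locationId[keep],
                    locationInfo(ds)[1:2, ])
  expect_equal(M[1, 2], weirCockerhamFst(sub)$fst, tolerance = 1e-12)

  g <- matrix(sample.int(4, 20, replace = TRUE), 10)
  ident <- genoListToDataset(list(list(g, g, g)))
  expect_true(all(pairwiseFst(ident)[upper.tri(M[1:3, 1:3])] <= 1e-12))
})

test_that("Fis hits its closed-form limits and flags monomorphic cells", {
  loc <- data.frame(id = "A", name = "A", lon = 0, lat = 0)
  n <- 10
  allHet <- STRDataset("L1", matrix(rep("12", n)), matrix(rep("15", n)),
                       paste0("s", 1:n), rep("A", n), loc)
  est <- estimateFis(allHet)
  expect_equal(est$table$fis[1], 1 - 1 / ((2 * n) / (2 * n - 1) * 0.5))
  expect_lt(est$table$fis[1], 0)

  allHom <- STRDataset("L1", matrix(c(rep("12", 5), rep("15", 5))),
                       matrix(c(rep("12", 5), rep("15", 5))),
                       paste0("s", 1:n), rep("A", n), loc)
  expect_equal(estimateFis(allHom)$table$fis[1], 1)

  mono <- STRDataset("L1", matrix(rep("12", n)), matrix(rep("12", n)),
                     paste0("s", 1:n), rep("A", n), loc)
  em <- estimateFis(mono)
  expect_true(em$table$monomorphic[1])
  expect_equal(em$nMonomorphic, 1)
  expect_true(is.na(em$table$fis[1]))
})

test_that("HWE chain agrees with exact enumeration on small tables", {
  loc <- data.frame(id = "A", name = "A", lon = 0, lat = 0)
  # biallelic with clear heterozygote deficit
  a1 <- c(rep("12", 8), rep("15", 6), rep("12", 2))
  a2 <- c(rep("12", 8), rep("15", 6), rep("15", 2))
  ds <- STRDataset("L1", matrix(a1), matrix(a2), paste0("s", 1:16),
                   rep("A", 16), loc)
  D <- matrix(0L, 2, 2); D[1, 1] <- 8L; D[2, 2] <- 6L; D[1, 2] <- 2L
  exact <- hweEnumerate(D)
  mc <- hweExactTest(ds, "L1", "A", steps = 3e4, dememorization = 3e3,
                     seed = 2)
  se <- sqrt(exact * (1 - exact) / (3e4 / 10))  # conservative ESS
  expect_lt(abs(mc$p - exact), 3 * se + 0.02)

  # three alleles, mixed table
  a1 <- c("10", "10", "11", "12", "10", "11", "12", "10", "11", "12")
  a2 <- c("10", "11", "11", "12", "12", "12", "12", "10", "11", "10")
  ds3 <- STRDataset("L1", matrix(a1), matrix(a2), paste0("s", 1:10),
                    rep("A", 10), loc)
  D3 <- strscape:::buildGenotypeCounts(parseAllele(a1), parseAllele(a2),
                                       sort(unique(parseAllele(c(a1, a2)))))
  # enumeration needs the table in upper-triangular orientation
  exact3 <- hweEnumerate(D3)
  mc3 <- hweExactTest(ds3, "L1", "A", steps = 3e4, dememorization = 3e3,
                      seed = 3)
  se3 <- sqrt(exact3 * (1 - exact3) / (3e4 / 10))
  expect_lt(abs(mc3$p - exact3), 3 * se3 + 0.02)
})

test_that("HWE test flags monomorphic cells with p = 1", {
  loc <- data.frame(id = "A", name = "A", lon = 0, lat = 0)
  mono <- STRDataset("L1", matrix(rep("12", 5)), matrix(rep("12", 5)),
                     paste0("s", 1:5), rep("A", 5), loc)
  res <- hweExactTest(mono, "L1", "A", steps = 1e4)
  expect_equal(res$p, 1)
  expect_equal(res$flag, "monomorphic")
  expect_error(hweExactTest(mono, "L1", "A", steps = 100), "at least 1e4")
})

test_that("HWE p-values are calibrated on equilibrium data", {
  sp <- smallSpec(nLocations = 4, fis = 0, nPerLocation = 40, seed = 55)
  ds <- simulateSTRData(sp)$dataset
  ps <- c()
  for (l in locusNames(ds)) for (loc in locationInfo(ds)$id)
    ps <- c(ps, hweExactTest(ds, l, loc, steps = 1e4,
                             dememorization = 1e3, seed = 9)$p)
  expect_true(all(ps > 0.05 / length(ps)))  # none past Bonferroni
  expect_gt(mean(ps > 0.2), 0.5)            # and generally unremarkable
})

test_that("null-allele EM finds its fixed point on constructed counts", {
  # expected genotype counts under HWE with p = (0.5, 0.4) and r = 0.1,
  # conditioned on no null/null: EM must recover r exactly
  p <- c(0.5, 0.4); r <- 0.1; N <- 1000
  D <- matrix(0, 2, 2)
  D[1, 1] <- N * (p[1]^2 + 2 * p[1] * r) / (1 - r^2)
  D[2, 2] <- N * (p[2]^2 + 2 * p[2] * r) / (1 - r^2)
  D[1, 2] <- N * 2 * p[1] * p[2] / (1 - r^2)
  est <- strscape:::nullAlleleEMCounts(D, c(100L, 110L), tol = 1e-12,
                                       maxIter = 10000)
  expect_lt(abs(est$r - 0.1), 1e-6)
  expect_true(all(diff(est$logLik) > -1e-9))  # monotone likelihood

  # no homozygote excess: r ~ 0
  D0 <- matrix(0, 2, 2)
  D0[1, 1] <- 250; D0[2, 2] <- 250; D0[1, 2] <- 500   # exact HWE, p = 0.5
  est0 <- strscape:::nullAlleleEMCounts(D0, c(100L, 110L), tol = 1e-12,
                                        maxIter = 10000)
  expect_lt(est0$r, 1e-3)
})

test_that("null-allele EM recovers simulated rates and co-varies with Fis", {
  sp <- syntheticSpec(nLocations = 1, loci = c(LA = 6), nClines = 0,
                      nFoci = 0, fis = 0, nullRate = 0.10,
                      nPerLocation = 500, seed = 17)
  ds <- simulateSTRData(sp)$dataset
  est <- nullAlleleEM(ds, "LA", "L01")
  expect_lt(abs(est$r - 0.10), 0.03)
  expect_true(est$converged)

  # heterogeneous null rates across loci -> r-hat and Fis co-vary
  rates <- c(0, 0.02, 0.05, 0.08, 0.11, 0.14)
  sp2 <- syntheticSpec(nLocations = 2, loci = c(A = 5, B = 5, C = 5, D = 5,
                                                E = 5, F = 5),
                       nClines = 0, nFoci = 0, fis = 0, nullRate = rates,
                       nPerLocation = 400, seed = 18)
  ds2 <- simulateSTRData(sp2)$dataset
  fis <- estimateFis(ds2)$table
  rhat <- mapply(function(l, loc) nullAlleleEM(ds2, l, loc)$r,
                 fis$locus, fis$location)
  ok <- !fis$monomorphic
  expect_gt(cor(rhat[ok], fis$fis[ok]), 0.5)
})
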