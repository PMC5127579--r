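# A small clinal survey shared by the reduction tests.
reductionFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- syntheticSpec(nLocations = 15,
                          loci = c(LA = 6, LB = 8, LC = 5, LD = 7),
                          nClines = 2, clineAmplitude = 0.3, nFoci = 0,
                          nPerLocation = 60, seed = 23)
      ds <- simulateSTRData(sp)$dataset
      net <- knnNetwork(locationInfo(ds), 4)
      res <- spatialPCA(alleleFrequencies(ds), net)
      cache <<- list(sp = sp, ds = ds, res = res)
    }
    cache
  }
})

test_that("squared loadings rank correctly and sum to one", {
  fx <- reductionFixture()
  tab <- suppressMessages(squaredLoadings(fx$res, 1))
  expect_equal(sum(tab$loading2), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$loading2) <= 1e-15))
  # independent sort oracle
  raw <- alleleLoadings(fx$res)[, 1]^2
  expect_equal(sort(tab$loading2, decreasing = TRUE),
               unname(sort(raw, decreasing = TRUE)), tolerance = 1e-15)
  expect_error(squaredLoadings(fx$res, 99), "no such component")
  # a unit loading concentrates the ranking on one allele
  one <- fx$res
  one@loadings[, 1] <- 0
  one@loadings[3, 1] <- 1
  tab1 <- suppressMessages(squaredLoadings(one, 1))
  expect_equal(tab1$loading2[1], 1)
  expect_equal(tab1$locus[1], one@colMeta$locus[3])
})

test_that("quantile selection uses the ceiling rule (288 -> 4/8/15/22/29)", {
  ranked <- data.frame(locus = rep("L", 288), allele = as.character(1:288),
                       loading2 = sort(runif(288), decreasing = TRUE))
  sizes <- vapply(c(0.0125, 0.025, 0.05, 0.075, 0.10),
                  function(q) nrow(selectTopQuantile(ranked, q)), 0L)
  expect_identical(sizes, c(4L, 8L, 15L, 22L, 29L))
  expect_equal(nrow(selectTopQuantile(ranked, 1)), 288)
  expect_error(selectTopQuantile(ranked, 0), "positive")
  expect_error(selectTopQuantile(ranked, -0.1), "positive")
})

test_that("dosage recoding counts target alleles and preserves frequencies", {
  loc <- data.frame(id = c("A", "B"), name = c("A", "B"),
                    lon = c(0, 1), lat = c(0, 0))
  ds <- STRDataset("D1S1656",
                   matrix(c("15", "15", "16", "15")),
                   matrix(c("15", "16", "16", "17")),
                   paste0("s", 1:4), c("A", "A", "B", "B"), loc)
  sel <- data.frame(locus = "D1S1656", allele = "15", loading2 = 1)
  red <- recodeDataset(ds, sel)
  expect_identical(unname(red@dosage[, 1]), c(2L, 1L, 0L, 1L))
  expect_error(recodeDataset(ds, data.frame(locus = "D1S1656",
                                            allele = "99")),
               "absent at locus")
  expect_error(recodeDataset(ds, sel[0, ]), "non-empty")

  # pseudo-locus frequency equals the source allele frequency everywhere
  fx <- reductionFixture()
  sel8 <- selectTopQuantile(suppressMessages(squaredLoadings(fx$res, 1)),
                            0.31)   # 8 of 26 alleles
  red8 <- recodeDataset(fx$ds, sel8)
  full <- alleleFrequencies(fx$ds)
  pseudo <- alleleFrequencies(reducedToSTR(red8))
  for (i in seq_len(nrow(sel8))) {
    src <- which(full@locusCol == sel8$locus[i] &
                 full@alleleCol == parseAllele(sel8$allele[i]))
    tgt <- which(pseudo@locusCol == paste(sel8$locus[i], sel8$allele[i],
                                          sep = ":") &
                 pseudo@alleleCol == 2L)
    expect_equal(unname(freqMatrix(pseudo)[, tgt]),
                 unname(freqMatrix(full)[, src]), tolerance = 1e-12)
  }
})

test_that("reduction criteria report shared alleles, multiplicity and Fst gain", {
  fx <- reductionFixture()
  ranked <- suppressMessages(squaredLoadings(fx$res, 1))
  selA <- ranked[1:4, ]
  selB <- ranked[5:8, ]
  crit <- validateReductionCriteria(selA, selB, fx$ds)
  expect_length(crit$sharedAlleles, 0)
  expect_true(crit$pass["a"])
  # identical selections: criterion (a) lists them all
  critSame <- validateReductionCriteria(selA, selA, fx$ds)
  expect_length(critSame$sharedAlleles, 4)
  expect_false(critSame$pass["a"])
  expect_equal(critSame$fst[["reduced1"]], critSame$fst[["reduced2"]])
  # clinal selections enhance structuring over the full panel
  expect_gt(crit$fst[["reduced1"]], crit$fst[["full"]])
})

test_that("top sPC1 alleles recover the designated clinal alleles", {
  hits <- integer(0)
  for (s in 1:20) {
    sp <- syntheticSpec(seed = 1000 + s, nPerLocation = 38)
    ds <- simulateSTRData(sp)$dataset
    net <- knnNetwork(locationInfo(ds), 12)
    res <- spatialPCA(alleleFrequencies(ds), net)
    sel <- selectTopQuantile(suppressMessages(squaredLoadings(res, 1)),
                             0.025)
    truth <- paste(sp@clines$locus, sp@clines$allele, sep = ":")
    hits <- c(hits, sum(paste(sel$locus, sel$allele, sep = ":") %in% truth))
  }
  expect_gte(median(hits), 6)   # >= 6 of 8 selected are true clinal alleles
})

test_that("recoded clinal datasets raise Fst above the full panel", {
  wins <- 0
  for (s in 1:5) {
    sp <- syntheticSpec(seed = 2000 + s, nPerLocation = 38)
    ds <- simulateSTRData(sp)$dataset
    net <- knnNetwork(locationInfo(ds), 12)
    res <- spatialPCA(alleleFrequencies(ds), net)
    sel <- selectTopQuantile(suppressMessages(squaredLoadings(res, 1)),
                             0.025)
    red <- recodeDataset(ds, sel)
    if (weirCockerhamFst(red)$fst > weirCockerhamFst(ds)$fst)
      wins <- wins + 1
  }
  expect_gte(wins, 4)
})
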