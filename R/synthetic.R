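# Synthetic STR surveys with the statistical structure the spatial analysis
# assumes: an elongated east-west transect, longitudinal allele-frequency
# clines, local frequency foci, background inbreeding and (optionally) null
# alleles. The generator is first-class, seeded and fully deterministic.

# Allele labels for a simulated locus: consecutive repeat counts starting at
# 5; designated loci interleave x.2 microvariants (as real compound loci do).
locusLabelSet <- function(K, micro = FALSE) {
  if (!micro) return(10L * (5L + seq_len(K) - 1L))
  n1 <- ceiling(K / 2); n2 <- K - n1
  sort(c(10L * (5L + seq_len(n1) - 1L), 10L * (5L + seq_len(n2) - 1L) + 2L))
}

#' Specify a synthetic STR survey
#'
#' Builds a [SyntheticSpec-class]. The defaults emulate a fine-grained
#' forensic survey of a long east-west transect: 41 locations spread over
#' ~28 degrees of longitude but only ~5 of latitude, 16 loci named after the
#' NGM SElect panel with 9-65 alleles each (288 alleles in total), eight
#' longitudinal clines of total swing 0.15 on eight distinct loci, six local
#' frequency foci, a mild background inbreeding of Fis = 0.012 and no null
#' alleles. Sample sizes default to 38 diploids per location.
#'
#' @param nLocations number of location samples.
#' @param lonRange,latRange transect extent (decimal degrees).
#' @param loci named integer vector: allele count per locus. Defaults to a
#'   16-locus forensic panel with 288 alleles overall.
#' @param clines data.frame(locus, allele, slope, direction) or NULL for the
#'   default set of eight; `allele` is a repeat-count label present at that
#'   locus, `slope` is the maximal frequency change per 1000 km, `direction`
#'   +1 (rising eastward) or -1.
#' @param nClines number of default clines when `clines` is NULL.
#' @param clineAmplitude total frequency swing of each cline.
#' @param foci data.frame(location, locus, allele, bump) or NULL to draw
#'   `nFoci` random foci from the seed; `location` is a location index.
#' @param nFoci,focusBump number and size of default foci.
#' @param fis per-location inbreeding coefficient (recycled).
#' @param nullRate per-locus null-allele frequency (recycled).
#' @param nPerLocation diploids per location (recycled).
#' @param seed integer seed; the whole survey is a deterministic function
#'   of the spec, including this seed.
#' @param baseConcentration Dirichlet concentration of the baseline
#'   frequency vector shared by all locations.
#' @return a [SyntheticSpec-class].
#' @examples
#' sp <- syntheticSpec(nLocations = 5, loci = c(L1 = 4, L2 = 6),
#'                     nClines = 1, nFoci = 0, nPerLocation = 10, seed = 1)
#' sp
#' @export
syntheticSpec <- function(nLocations = 41,
                          lonRange = c(12, 40), latRange = c(36.5, 41.5),
                          loci = NULL, clines = NULL, nClines = 8,
                          clineAmplitude = 0.15,
                          foci = NULL, nFoci = 6, focusBump = 0.08,
                          fis = 0.012, nullRate = 0, nPerLocation = 38,
                          seed = 20160, baseConcentration = 0.8) {
  if (is.null(loci)) {
    loci <- c(D10S1248 = 9, D16S539 = 9, TH01 = 9, D1S1656 = 17, D2S441 = 13,
              D2S1338 = 14, D3S1358 = 12, D8S1179 = 12, D12S391 = 18,
              D18S51 = 20, D19S433 = 16, D21S11 = 25, D22S1045 = 12,
              FGA = 24, vWA = 13, SE33 = 65)
  }
  loci <- unlist(loci)                      # accept a named list (e.g. YAML)
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    stop("'loci' must be a named vector of allele counts")
  microLoci <- c("D21S11", "SE33", "D19S433", "D1S1656")
  labels <- lapply(seq_along(loci), function(j)
    locusLabelSet(loci[[j]], names(loci)[j] %in% microLoci))
  names(labels) <- names(loci)

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  if (is.null(clines)) {
    clLoci <- setdiff(names(loci)[order(-loci)], "SE33")  # many-allele loci carry the clines
    clLoci <- clLoci[seq_len(min(nClines, length(clLoci)))]
    clines <- data.frame(
      locus = clLoci,
      allele = vapply(clLoci, function(l)
        formatAllele(labels[[l]][ceiling(length(labels[[l]]) / 3)]), ""),
      slope = rep(0.1, length(clLoci)),
      direction = rep_len(c(1, -1), length.out = length(clLoci)),
      stringsAsFactors = FALSE)
  }
  if (is.null(foci)) {
    foci <- if (nFoci > 0) data.frame(
      location = sample.int(nLocations, nFoci, replace = TRUE),
      locus = sample(names(loci), nFoci, replace = TRUE),
      allele = NA_character_,   # resolved below, per locus
      bump = focusBump,
      stringsAsFactors = FALSE)
    else data.frame(location = integer(0), locus = character(0),
                    allele = character(0), bump = numeric(0))
    if (nrow(foci))
      foci$allele <- vapply(foci$locus, function(l)
        formatAllele(sample(labels[[l]], 1)), "")
  }
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())

  checkRef <- function(tab, what) {
    bad <- !(tab$locus %in% names(loci))
    if (any(bad)) stop(what, " references unknown locus: ",
                       paste(unique(tab$locus[bad]), collapse = ", "))
    for (i in seq_len(nrow(tab)))
      if (!parseAllele(tab$allele[i]) %in% labels[[tab$locus[i]]])
        stop(sprintf("%s references unknown allele %s at locus %s",
                     what, tab$allele[i], tab$locus[i]))
  }
  checkRef(clines, "cline")
  checkRef(foci, "focus")
  if (nrow(foci) && any(foci$location < 1 | foci$location > nLocations))
    stop("focus references a location index outside the transect")

  new("SyntheticSpec",
      nLocations = as.integer(nLocations),
      lonRange = as.numeric(lonRange), latRange = as.numeric(latRange),
      loci = names(loci), nAlleles = as.integer(loci), alleleLabels = labels,
      clines = clines, clineAmplitude = clineAmplitude, foci = foci,
      fis = as.numeric(fis), nullRate = as.numeric(nullRate),
      nPerLocation = as.integer(nPerLocation), seed = as.integer(seed),
      baseConcentration = baseConcentration)
}

# Eastward position of each location along the transect, in km (plate
# carree; strictly monotone in longitude, which the cline construction
# relies on).
transectKm <- function(lon, lat) {
  (lon - min(lon)) * 111.32 * cos(mean(lat) * pi / 180)
}

#' Generate per-location allele frequency surfaces
#'
#' Every location shares a baseline Dirichlet frequency vector per locus; a
#' designated clinal allele additionally carries a logistic term in the
#' eastward transect position with maximal slope `slope` per 1000 km and
#' total swing `clineAmplitude`; foci add a local bump at one location.
#' Frequencies are renormalised to the simplex per locus x location.
#' Deterministic given the spec (seeded internally).
#'
#' @param spec a [SyntheticSpec-class].
#' @return an [AlleleFreqTable-class] of generating ("true") frequencies,
#'   with the planned gene-copy counts attached.
#' @export
makeFrequencySurfaces <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nLocations
  lon <- seq(spec@lonRange[1], spec@lonRange[2], length.out = n) +
    stats::runif(n, -0.2, 0.2)
  lon <- pmin(pmax(lon, -180), 180)
  lat <- stats::runif(n, spec@latRange[1], spec@latRange[2])
  locations <- data.frame(
    id = sprintf("L%02d", seq_len(n)),
    name = sprintf("Location %02d", seq_len(n)),
    lon = lon, lat = lat, stringsAsFactors = FALSE)
  x <- transectKm(lon, lat) / 1000         # Mm east of the west end
  xmid <- mean(range(x))

  nPer <- rep_len(spec@nPerLocation, n)
  freqCols <- list(); locusCol <- character(0); alleleCol <- integer(0)
  copies <- matrix(2L * nPer, n, length(spec@loci),
                   dimnames = list(locations$id, spec@loci))
  A <- spec@clineAmplitude
  for (j in seq_along(spec@loci)) {
    locus <- spec@loci[j]
    lab <- spec@alleleLabels[[j]]
    K <- length(lab)
    base <- rdirichlet1(rep(spec@baseConcentration, K))
    W <- matrix(base, n, K, byrow = TRUE)
    cl <- spec@clines[spec@clines$locus == locus, , drop = FALSE]
    for (i in seq_len(nrow(cl))) {
      a <- match(parseAllele(cl$allele[i]), lab)
      W[, a] <- W[, a] +
        A * stats::plogis(4 * cl$slope[i] * cl$direction[i] * (x - xmid) / A)
    }
    fo <- spec@foci[spec@foci$locus == locus, , drop = FALSE]
    for (i in seq_len(nrow(fo))) {
      a <- match(parseAllele(fo$allele[i]), lab)
      W[fo$location[i], a] <- W[fo$location[i], a] + fo$bump[i]
    }
    freqCols[[j]] <- W / rowSums(W)
    locusCol <- c(locusCol, rep(locus, K))
    alleleCol <- c(alleleCol, lab)
  }
  freq <- do.call(cbind, freqCols)
  dimnames(freq) <- list(locations$id, freqColNames(locusCol, alleleCol))
  new("AlleleFreqTable", freq = freq, locusCol = locusCol,
      alleleCol = alleleCol, copies = copies, locations = locations)
}

#' Sample diploid genotypes from frequency surfaces
#'
#' Per subject and locus, with probability Fis the two gene copies are
#' identical by descent (a single draw used twice), otherwise they are two
#' independent draws from the local allele frequencies -- which yields
#' exactly the target Fis in expectation. A hidden null allele of frequency
#' `nullRate` is appended to the visible alleles: a null/visible pair is
#' reported as a visible homozygote, and null/null genotypes are resampled
#' (surveys discard incomplete profiles, so the dataset carries no missing
#' data). Deterministic given the spec.
#'
#' @param freqTable an [AlleleFreqTable-class] (typically from
#'   [makeFrequencySurfaces()]).
#' @param spec a [SyntheticSpec-class] supplying `fis`, `nullRate`,
#'   `nPerLocation` and the seed.
#' @return an [STRDataset-class].
#' @export
sampleGenotypes <- function(freqTable, spec) {
  freq <- freqTable@freq
  if (any(freq < -1e-9) ||
      any(abs(vapply(unique(freqTable@locusCol), function(l)
        max(abs(rowSums(freq[, freqTable@locusCol == l, drop = FALSE]) - 1)),
        0)) > 1e-6))
    stop("frequencies are not on the simplex")
  set.seed(spec@seed + 1L)
  nloc <- nrow(freq)
  loci <- unique(freqTable@locusCol)
  nPer <- rep_len(spec@nPerLocation, nloc)
  fis <- rep_len(spec@fis, nloc)
  nullRate <- rep_len(spec@nullRate, length(loci))
  nTot <- sum(nPer)
  a1 <- matrix(0L, nTot, length(loci))
  a2 <- matrix(0L, nTot, length(loci))
  rowOf <- cumsum(c(0L, nPer))
  for (j in seq_along(loci)) {
    lab <- freqTable@alleleCol[freqTable@locusCol == loci[j]]
    r <- nullRate[j]
    for (i in seq_len(nloc)) {
      f <- freq[i, freqTable@locusCol == loci[j]]
      p <- c(f * (1 - r), r)          # states 1..K visible, K+1 null
      K <- length(f)
      ni <- nPer[i]
      ibd <- stats::runif(ni) < fis[i]
      d1 <- sample.int(K + 1L, ni, replace = TRUE, prob = p)
      d2 <- ifelse(ibd, d1, sample.int(K + 1L, ni, replace = TRUE, prob = p))
      repeat {
        bothNull <- d1 > K & d2 > K
        if (!any(bothNull)) break
        nn <- sum(bothNull)
        ibdN <- stats::runif(nn) < fis[i]
        r1 <- sample.int(K + 1L, nn, replace = TRUE, prob = p)
        r2 <- ifelse(ibdN, r1, sample.int(K + 1L, nn, replace = TRUE, prob = p))
        d1[bothNull] <- r1; d2[bothNull] <- r2
      }
      vis1 <- ifelse(d1 > K, d2, d1)   # null/visible reported as visible homozygote
      vis2 <- ifelse(d2 > K, d1, d2)
      rows <- rowOf[i] + seq_len(ni)
      a1[rows, j] <- lab[vis1]
      a2[rows, j] <- lab[vis2]
    }
  }
  locId <- rep(freqTable@locations$id, nPer)
  STRDataset(loci, a1, a2,
             sprintf("S%05d", seq_len(nTot)), locId, freqTable@locations)
}

#' One-call synthetic survey
#'
#' `makeFrequencySurfaces()` followed by `sampleGenotypes()`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `dataset` (an [STRDataset-class]) and
#'   `truth` (the generating [AlleleFreqTable-class]).
#' @export
simulateSTRData <- function(spec) {
  truth <- makeFrequencySurfaces(spec)
  list(dataset = sampleGenotypes(truth, spec), truth = truth)
}

#' Write generator ground truth as JSON
#'
#' Records the generating frequencies, the clinal allele list, per-location
#' Fis and per-locus null rates, for comparison with downstream estimates.
#'
#' @param spec a [SyntheticSpec-class].
#' @param freqTable the matching table from [makeFrequencySurfaces()].
#' @param path output JSON file.
#' @export
writeGroundTruth <- function(spec, freqTable, path) {
  truth <- list(
    seed = spec@seed,
    clines = spec@clines,
    foci = spec@foci,
    fis = rep_len(spec@fis, spec@nLocations),
    null_rate = stats::setNames(rep_len(spec@nullRate, length(spec@loci)),
                                spec@loci),
    locations = freqTable@locations,
    frequencies = as.data.frame(freqTable@freq))
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
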