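#' @import methods
NULL

#' Georeferenced diploid STR genotypes
#'
#' Container for a survey of diploid multi-allelic STR genotypes grouped into
#' georeferenced location samples. Allele labels are stored in canonical
#' integer tenths of a repeat unit (allele 15 is 150, microvariant 15.2 is
#' 152), so microvariants round-trip losslessly through text formats.
#'
#' Every subject is typed at every locus (surveys discard incomplete
#' profiles) and assigned to exactly one location; every location holds at
#' least one subject.
#'
#' @slot loci character vector of locus names, in panel order.
#' @slot alleles1,alleles2 integer matrices (subjects x loci) holding the two
#'   gene copies per genotype in canonical tenths. The pair is unordered;
#'   constructors normalise so that \code{alleles1 <= alleles2}.
#' @slot subjectIds character vector of unique subject identifiers.
#' @slot locationId character vector assigning each subject to a location id.
#' @slot locations data.frame with columns \code{id}, \code{name},
#'   \code{lon}, \code{lat} (decimal degrees).
#'
#' @seealso [readGenepop()], [alleleFrequencies()], [sampleGenotypes()]
#' @export
setClass("STRDataset",
  representation(
    loci = "character",
    alleles1 = "matrix",
    alleles2 = "matrix",
    subjectIds = "character",
    locationId = "character",
    locations = "data.frame"
  )
)

setValidity("STRDataset", function(object) {
  msg <- character(0)
  n <- length(object@subjectIds)
  L <- length(object@loci)
  if (L < 1) msg <- c(msg, "dataset must contain at least one locus")
  if (anyDuplicated(object@loci)) msg <- c(msg, "locus names must be unique")
  for (s in c("alleles1", "alleles2")) {
    a <- slot(object, s)
    if (!is.integer(a)) msg <- c(msg, sprintf("%s must be an integer matrix", s))
    if (!all(dim(a) == c(n, L))) msg <- c(msg, sprintf("%s must be %d x %d", s, n, L))
    if (anyNA(a)) msg <- c(msg, sprintf("missing genotypes in %s are not supported", s))
    else if (length(a) && any(a <= 0)) msg <- c(msg, "allele labels must be positive")
  }
  if (anyDuplicated(object@subjectIds)) msg <- c(msg, "subject ids must be unique")
  if (length(object@locationId) != n) msg <- c(msg, "one location assignment per subject required")
  loc <- object@locations
  need <- c("id", "name", "lon", "lat")
  if (!all(need %in% names(loc))) {
    msg <- c(msg, "locations must have columns id, name, lon, lat")
  } else {
    if (anyDuplicated(loc$id)) msg <- c(msg, "location ids must be unique")
    if (!all(object@locationId %in% loc$id)) msg <- c(msg, "subject assigned to unknown location")
    if (!all(loc$id %in% object@locationId)) msg <- c(msg, "every location needs at least one subject")
    if (any(loc$lon < -180 | loc$lon > 180, na.rm = TRUE)) msg <- c(msg, "longitude outside [-180, 180]")
    if (any(loc$lat < -90 | loc$lat > 90, na.rm = TRUE)) msg <- c(msg, "latitude outside [-90, 90]")
    if (anyNA(loc$lon) || anyNA(loc$lat)) msg <- c(msg, "missing coordinates")
  }
  if (length(msg)) msg else TRUE
})

#' Per-location allele frequency table
#'
#' Relative allele frequencies arranged as locations x (locus, allele)
#' columns, together with the number of gene copies that each locus x
#' location frequency estimate is based on. This is the substrate of the
#' spatial PCA: rows are location samples, columns are alleles pooled over
#' all loci.
#'
#' @slot freq numeric matrix, locations x alleles; within each locus the
#'   frequencies of one row sum to 1.
#' @slot locusCol character vector, locus of each column.
#' @slot alleleCol integer vector, allele label of each column in canonical
#'   tenths.
#' @slot copies integer matrix (locations x loci) of sampled gene copies.
#' @slot locations data.frame as in [STRDataset-class].
#' @export
setClass("AlleleFreqTable",
  representation(
    freq = "matrix",
    locusCol = "character",
    alleleCol = "integer",
    copies = "matrix",
    locations = "data.frame"
  )
)

setValidity("AlleleFreqTable", function(object) {
  msg <- character(0)
  p <- ncol(object@freq)
  if (length(object@locusCol) != p || length(object@alleleCol) != p)
    msg <- c(msg, "column metadata length must match frequency columns")
  if (any(object@freq < -1e-12 | object@freq > 1 + 1e-12))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  for (l in unique(object@locusCol)) {
    s <- rowSums(object@freq[, object@locusCol == l, drop = FALSE])
    if (any(abs(s - 1) > 1e-9))
      msg <- c(msg, sprintf("frequencies at locus %s do not sum to 1", l))
  }
  if (nrow(object@freq) != nrow(object@locations))
    msg <- c(msg, "one frequency row per location required")
  if (length(msg)) msg else TRUE
})

#' Spatial connection network among location samples
#'
#' k-nearest-neighbour graph on great-circle distances, symmetrised by union
#' and row-standardised. The row-standardised matrix \code{L} is the lag
#' operator used by the spatial PCA and Moran's I.
#'
#' @slot adjacency binary symmetric adjacency matrix (no self links).
#' @slot weights row-standardised weight matrix L (rows sum to 1).
#' @slot k integer, the k used to build the graph.
#' @slot coords matrix of (lon, lat) used, one row per node.
#' @export
setClass("SpatialNetwork",
  representation(adjacency = "matrix", weights = "matrix", k = "integer",
                 coords = "matrix")
)

setValidity("SpatialNetwork", function(object) {
  msg <- character(0)
  A <- object@adjacency
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (any(diag(A) != 0)) msg <- c(msg, "self links are not allowed")
  if (!isTRUE(all.equal(A, t(A)))) msg <- c(msg, "adjacency must be symmetric")
  rs <- rowSums(object@weights)
  if (any(abs(rs - 1) > 1e-9 & rs != 0)) msg <- c(msg, "weight rows must sum to 1 (or 0 if isolated)")
  if (length(msg)) msg else TRUE
})

#' Result of a spatial principal component analysis
#'
#' Eigen-decomposition of the spatially lagged covariance
#' \eqn{H = X^T (L + L^T) X / (2n)} of the column-centred frequency matrix
#' X. Components with positive eigenvalues capture "global" structure
#' (neighbouring locations alike, e.g. clines); negative eigenvalues capture
#' "local" structure (neighbouring locations contrasted). For every
#' component the defining identity \eqn{\lambda_k = var(s_k) I(s_k)} holds,
#' with \eqn{s_k = X v_k} the location scores.
#'
#' @slot eigenvalues signed eigenvalues, sorted decreasing.
#' @slot loadings unit-norm allele loadings (columns = components).
#' @slot scores location scores \code{X v} (columns = components).
#' @slot varScores per-component score variance, \code{(1/n) s's}.
#' @slot moranScores per-component Moran's I of the scores on the network.
#' @slot colMeta data.frame with \code{locus}, \code{allele} per allele axis.
#' @slot network the [SpatialNetwork-class] used.
#' @export
setClass("SPCAResult",
  representation(
    eigenvalues = "numeric",
    loadings = "matrix",
    scores = "matrix",
    varScores = "numeric",
    moranScores = "numeric",
    colMeta = "data.frame",
    network = "SpatialNetwork"
  )
)

#' Reduced (biallelic dosage-recoded) dataset
#'
#' The shortlist of (locus, allele) pairs with the largest squared loadings
#' on one spatial principal component, together with the recoding of every
#' genotype as the dosage (0, 1 or 2 copies) of each selected allele against
#' all remaining alleles of the same locus.
#'
#' @slot component which component the selection came from (e.g. "sPC1").
#' @slot q quantile used for the selection.
#' @slot selection data.frame(locus, allele, loading2), ranked.
#' @slot dosage integer matrix (subjects x selected alleles) in {0,1,2}.
#' @slot subjectIds,locationId,locations as in [STRDataset-class].
#' @export
setClass("ReducedDataset",
  representation(
    component = "character",
    q = "numeric",
    selection = "data.frame",
    dosage = "matrix",
    subjectIds = "character",
    locationId = "character",
    locations = "data.frame"
  )
)

setValidity("ReducedDataset", function(object) {
  msg <- character(0)
  if (!all(object@dosage %in% 0:2)) msg <- c(msg, "dosages must be 0, 1 or 2")
  if (ncol(object@dosage) != nrow(object@selection))
    msg <- c(msg, "one dosage column per selected allele required")
  if (length(msg)) msg else TRUE
})

#' Distribution of simulated Fst under a demographic model
#'
#' Weir-Cockerham Fst values from replicate coalescent simulations at one
#' migration rate, plus empirical compatibility P-values of an observed Fst
#' against that distribution.
#'
#' @slot m the among-deme migration rate simulated.
#' @slot values simulated Fst values (length R).
#' @slot observed the observed Fst tested (NA if none supplied).
#' @slot pLower,pUpper,pTwoSided empirical tail probabilities,
#'   \code{(1 + #{sim <= obs}) / (R + 1)} etc.; two-sided = 2 min, capped at 1.
#' @export
setClass("FstDistribution",
  representation(m = "numeric", values = "numeric", observed = "numeric",
                 pLower = "numeric", pUpper = "numeric", pTwoSided = "numeric")
)

#' Demographic model for the coalescent simulator
#'
#' Template family of split-from-pool demographies. A set of demes splits
#' from a large growing pool; between the present and their split times the
#' demes grow exponentially, exchange migrants among themselves at rate
#' \code{m} and with the pool at fixed backward exchange rates. An optional set
#' of recently founded "joiner" demes (model 2) splits from the pool at
#' given times and exchanges migrants with the resident demes at rate
#' \code{joinerM}. A constant-size island model (no pool, no splits) is also
#' expressible for calibration against closed-form expectations.
#'
#' All population sizes are in gene copies (haploid count), migration and
#' exchange rates are backward per-lineage per-generation probabilities,
#' growth rates are per generation.
#'
#' @seealso [model1Demography()], [model2Demography()], [islandDemography()]
#' @export
setClass("DemographicModel",
  representation(
    nDemes = "integer",
    m = "numeric",
    demeSizeRange = "numeric",
    demeGrowth = "numeric",
    splitTimeRange = "numeric",
    poolSize = "numeric",
    poolGrowth = "numeric",
    demeToPool = "numeric",
    poolToDeme = "numeric",
    joinerTimes = "numeric",
    joinerM = "numeric",
    generationTime = "numeric"
  )
)

setValidity("DemographicModel", function(object) {
  msg <- character(0)
  if (object@nDemes < 1) msg <- c(msg, "need at least one deme")
  rates <- c(object@m, object@demeToPool, object@poolToDeme, object@joinerM)
  if (any(rates < 0 | rates >= 1)) msg <- c(msg, "rates must lie in [0, 1)")
  if (any(object@demeSizeRange < 2)) msg <- c(msg, "deme sizes must be >= 2 gene copies")
  if (any(object@splitTimeRange <= 0)) msg <- c(msg, "split times must be positive")
  if (length(object@joinerTimes) && any(object@joinerTimes <= 0))
    msg <- c(msg, "joiner times must be positive")
  if (length(msg)) msg else TRUE
})

#' Stepwise mutation model for simulated STR loci
#'
#' Loci mutate at rate \code{mu} per copy per generation by +/-1 repeat
#' steps, constrained to \code{K} possible allele states with reflecting
#' bounds (a boundary state always steps inward). Loci are independent.
#'
#' @slot mu per-locus mutation rate per generation.
#' @slot K number of allele states (>= 2).
#' @slot nLoci number of loci simulated.
#' @seealso [mutationModel()]
#' @export
setClass("MutationModel",
  representation(mu = "numeric", K = "integer", nLoci = "integer")
)

setValidity("MutationModel", function(object) {
  msg <- character(0)
  if (object@mu <= 0 || object@mu >= 0.01) msg <- c(msg, "mu must lie in (0, 0.01)")
  if (object@K < 2) msg <- c(msg, "K must be >= 2")
  if (object@nLoci < 1) msg <- c(msg, "need at least one locus")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic STR survey
#'
#' Parameters of the synthetic-data generator: an elongated east-west
#' transect of location samples, per-locus allele counts, longitudinal
#' allele-frequency clines, local frequency foci, per-location inbreeding
#' and optional null alleles.
#'
#' @slot nLocations number of location samples.
#' @slot lonRange,latRange transect extent in decimal degrees (lon range
#'   much wider than lat range).
#' @slot loci character vector of locus names.
#' @slot nAlleles integer vector, allele count per locus.
#' @slot clines data.frame(locus, allele, slope, direction): logistic
#'   longitudinal clines; slope in frequency units per 1000 km, direction
#'   +1 eastward / -1 westward.
#' @slot clineAmplitude total frequency swing of each cline.
#' @slot foci data.frame(location, locus, allele, bump): local additive
#'   frequency bumps at single locations.
#' @slot fis per-location inbreeding coefficient (recycled; in (-0.1, 0.1)).
#' @slot nullRate per-locus null-allele frequency (recycled; in [0, 0.15]).
#' @slot nPerLocation diploid sample size per location (recycled).
#' @slot seed base RNG seed of the generator.
#' @slot baseConcentration Dirichlet concentration of baseline frequencies.
#' @slot alleleLabels list of integer-tenths allele labels, one vector per
#'   locus (fixed by the constructor so clines/foci can reference alleles).
#' @seealso [syntheticSpec()], [makeFrequencySurfaces()], [sampleGenotypes()]
#' @export
setClass("SyntheticSpec",
  representation(
    nLocations = "integer",
    lonRange = "numeric",
    latRange = "numeric",
    loci = "character",
    nAlleles = "integer",
    alleleLabels = "list",
    clines = "data.frame",
    clineAmplitude = "numeric",
    foci = "data.frame",
    fis = "numeric",
    nullRate = "numeric",
    nPerLocation = "integer",
    seed = "integer",
    baseConcentration = "numeric"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (object@nLocations < 1) msg <- c(msg, "need at least one location")
  if (length(object@nAlleles) != length(object@loci))
    msg <- c(msg, "one allele count per locus required")
  if (any(object@nAlleles < 2)) msg <- c(msg, "each locus needs >= 2 alleles")
  fisOK <- (object@fis > -0.1 & object@fis < 0.1) | object@fis == 1
  if (!all(fisOK))
    msg <- c(msg, "fis must lie in (-0.1, 0.1) (exactly 1 allowed as a limiting case)")
  if (any(object@nullRate < 0 | object@nullRate > 0.15))
    msg <- c(msg, "null-allele rate must lie in [0, 0.15]")
  if (any(object@nPerLocation < 1)) msg <- c(msg, "need >= 1 subject per location")
  if (length(msg)) msg else TRUE
})
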