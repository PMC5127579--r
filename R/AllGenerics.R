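#' @rdname STRDataset-class
#' @param object,x an object.
#' @export
setGeneric("locusNames", function(x) standardGeneric("locusNames"))

#' @rdname STRDataset-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname STRDataset-class
#' @export
setGeneric("nLocations", function(x) standardGeneric("nLocations"))

#' @rdname STRDataset-class
#' @export
setGeneric("locationInfo", function(x) standardGeneric("locationInfo"))

#' @rdname STRDataset-class
#' @export
setGeneric("locationOf", function(x) standardGeneric("locationOf"))

#' @rdname SPCAResult-class
#' @param x an object.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname SPCAResult-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname SPCAResult-class
#' @export
setGeneric("alleleLoadings", function(x) standardGeneric("alleleLoadings"))

#' @rdname AlleleFreqTable-class
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname AlleleFreqTable-class
#' @export
setGeneric("alleleInfo", function(x) standardGeneric("alleleInfo"))

# ---- accessors ----

#' @rdname STRDataset-class
#' @export
setMethod("locusNames", "STRDataset", function(x) x@loci)

#' @rdname STRDataset-class
#' @export
setMethod("nSubjects", "STRDataset", function(x) length(x@subjectIds))

#' @rdname STRDataset-class
#' @export
setMethod("nLocations", "STRDataset", function(x) nrow(x@locations))

#' @rdname STRDataset-class
#' @export
setMethod("locationInfo", "STRDataset", function(x) x@locations)

#' @rdname STRDataset-class
#' @export
setMethod("locationOf", "STRDataset", function(x) x@locationId)

#' @rdname AlleleFreqTable-class
#' @export
setMethod("locusNames", "AlleleFreqTable", function(x) unique(x@locusCol))

#' @rdname AlleleFreqTable-class
#' @export
setMethod("nLocations", "AlleleFreqTable", function(x) nrow(x@locations))

#' @rdname AlleleFreqTable-class
#' @export
setMethod("locationInfo", "AlleleFreqTable", function(x) x@locations)

#' @rdname AlleleFreqTable-class
#' @export
setMethod("freqMatrix", "AlleleFreqTable", function(x) x@freq)

#' @rdname AlleleFreqTable-class
#' @export
setMethod("alleleInfo", "AlleleFreqTable",
          function(x) data.frame(locus = x@locusCol,
                                 allele = formatAllele(x@alleleCol),
                                 stringsAsFactors = FALSE))

#' @rdname SPCAResult-class
#' @export
setMethod("eigenvalues", "SPCAResult", function(x) x@eigenvalues)

#' @rdname SPCAResult-class
#' @export
setMethod("scores", "SPCAResult", function(x) x@scores)

#' @rdname SPCAResult-class
#' @export
setMethod("alleleLoadings", "SPCAResult", function(x) x@loadings)

# ---- show methods ----

setMethod("show", "STRDataset", function(object) {
  cat(sprintf("STRDataset: %d subjects, %d loci, %d locations\n",
              nSubjects(object), length(object@loci), nLocations(object)))
  cat("  loci:", paste(utils::head(object@loci, 6), collapse = ", "),
      if (length(object@loci) > 6) "..." else "", "\n")
  inv <- alleleInventory(object)
  cat(sprintf("  %d distinct alleles overall\n", nrow(inv)))
})

setMethod("show", "AlleleFreqTable", function(object) {
  cat(sprintf("AlleleFreqTable: %d locations x %d alleles (%d loci)\n",
              nrow(object@freq), ncol(object@freq),
              length(unique(object@locusCol))))
})

setMethod("show", "SpatialNetwork", function(object) {
  cat(sprintf("SpatialNetwork: %d nodes, k = %d, %d undirected edges\n",
              nrow(object@adjacency), object@k, sum(object@adjacency) / 2))
})

setMethod("show", "SPCAResult", function(object) {
  ev <- object@eigenvalues
  cat(sprintf("SPCAResult: %d components (%d global / positive, %d local / negative)\n",
              length(ev), sum(ev > 0), sum(ev < 0)))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(ev, 3), 3), collapse = ", "), "\n")
})

setMethod("show", "ReducedDataset", function(object) {
  cat(sprintf("ReducedDataset (%s, q = %g): %d selected alleles, %d subjects\n",
              object@component, object@q, nrow(object@selection),
              length(object@subjectIds)))
})

setMethod("show", "FstDistribution", function(object) {
  cat(sprintf("FstDistribution: m = %g, R = %d, median Fst = %.4g\n",
              object@m, length(object@values), stats::median(object@values)))
  if (!is.na(object@observed))
    cat(sprintf("  observed %.4g: P(lower) = %.4g, P(upper) = %.4g, two-sided = %.4g\n",
                object@observed, object@pLower, object@pUpper, object@pTwoSided))
})

setMethod("show", "DemographicModel", function(object) {
  kind <- if (is.infinite(object@splitTimeRange[1])) "island (constant size)"
          else if (length(object@joinerTimes)) "split-from-pool + joiners"
          else "split-from-pool"
  cat(sprintf("DemographicModel [%s]: %d demes, m = %g", kind,
              object@nDemes, object@m))
  if (length(object@joinerTimes))
    cat(sprintf(", %d joiners (m2 = %g)", length(object@joinerTimes), object@joinerM))
  cat("\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d locations, %d loci (%d alleles), %d clines, %d foci\n",
              object@nLocations, length(object@loci), sum(object@nAlleles),
              nrow(object@clines), nrow(object@foci)))
})
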