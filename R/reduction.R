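# Reduced-dataset derivation: rank alleles by squared loading on one
# spatial principal component, keep the top quantile, and recode every
# genotype as the dosage of each selected allele against all remaining
# alleles of the same locus.

#' Ranked squared loadings of one spatial component
#'
#' @param spcaResult an [SPCAResult-class].
#' @param component component index (1-based) or name ("sPC1").
#' @return data.frame(locus, allele, loading2) sorted by decreasing squared
#'   loading; ties broken by (locus, allele) lexicographic order (a message
#'   flags ties). Squared loadings of one component sum to 1.
#' @export
squaredLoadings <- function(spcaResult, component = 1) {
  V <- spcaResult@loadings
  if (is.character(component)) component <- match(component, colnames(V))
  if (is.na(component) || component < 1 || component > ncol(V))
    stop("no such component")
  l2 <- V[, component]^2
  tab <- data.frame(locus = spcaResult@colMeta$locus,
                    allele = spcaResult@colMeta$allele,
                    loading2 = l2, stringsAsFactors = FALSE)
  if (anyDuplicated(signif(l2, 12)))
    message("squaredLoadings: ties broken by locus/allele order")
  tab[order(-tab$loading2, tab$locus, tab$allele), , drop = FALSE]
}

#' Select the top quantile of ranked alleles
#'
#' The selection size is \code{ceiling(q * p)} with p the total number of
#' allele columns; on a 288-allele panel the quantiles 1.25, 2.5, 5, 7.5
#' and 10 per cent keep 4, 8, 15, 22 and 29 alleles.
#'
#' @param rankedTable output of [squaredLoadings()].
#' @param q quantile in (0, 1].
#' @return the top rows of `rankedTable` (a selection data.frame).
#' @export
selectTopQuantile <- function(rankedTable, q) {
  if (!is.numeric(q) || q <= 0) stop("q must be positive")
  if (q > 1) stop("q must not exceed 1")
  p <- nrow(rankedTable)
  rankedTable[seq_len(ceiling(q * p)), , drop = FALSE]
}

#' Diagnostics for a pair of reduced-dataset selections
#'
#' Reports the three optimality criteria for reduced datasets derived from
#' two spatial components: (a) independence -- alleles appearing in both
#' selections; (b) internal negative correlation -- loci contributing more
#' than one allele within a selection; (c) improved structuring -- the
#' Weir-Cockerham Fst of each dosage-recoded dataset versus the full
#' dataset. Criteria (a) and (b) are advisory (surveys tolerate limited
#' violations); (c) passes when the reduced Fst exceeds the full one.
#'
#' @param selection1,selection2 selection data.frames (from
#'   [selectTopQuantile()]) for the first and second component.
#' @param dataset the full [STRDataset-class].
#' @param grouping as in [weirCockerhamFst()].
#' @return list with `sharedAlleles` (a), `multiAlleleLoci` (b; per
#'   selection), `fst` (full, reduced1, reduced2) and `pass` (logical per
#'   criterion: a = no shared alleles, b = no multi-allele loci, c =
#'   both reduced Fst > full Fst).
#' @export
validateReductionCriteria <- function(selection1, selection2, dataset,
                                      grouping = NULL) {
  key <- function(s) paste(s$locus, s$allele, sep = ":")
  shared <- intersect(key(selection1), key(selection2))
  multi <- lapply(list(selection1, selection2), function(s)
    names(which(table(s$locus) > 1)))
  fstFull <- weirCockerhamFst(dataset, grouping)$fst
  fstRed <- vapply(list(selection1, selection2), function(s)
    weirCockerhamFst(recodeDataset(dataset, s), grouping)$fst, 0)
  list(sharedAlleles = shared,
       multiAlleleLoci = list(sPC1 = multi[[1]], sPC2 = multi[[2]]),
       fst = c(full = fstFull, reduced1 = fstRed[1], reduced2 = fstRed[2]),
       pass = c(a = length(shared) == 0,
                b = all(lengths(multi) == 0),
                c = all(fstRed > fstFull)))
}

#' Recode genotypes as dosages of selected alleles
#'
#' Every selected (locus, allele) becomes a biallelic pseudo-locus scoring
#' each subject's dosage of the target allele (0, 1 or 2 copies) against
#' all remaining alleles of that locus. Downstream F-statistics operate on
#' these pseudo-loci; the pseudo-locus allele frequency equals the source
#' allele frequency at every location.
#'
#' @param dataset an [STRDataset-class].
#' @param selection data.frame with `locus` and `allele` columns (labels),
#'   e.g. from [selectTopQuantile()].
#' @param component label stored on the result (e.g. "sPC1").
#' @param q quantile stored on the result.
#' @return a [ReducedDataset-class].
#' @export
recodeDataset <- function(dataset, selection, component = "sPC1", q = NA_real_) {
  if (nrow(selection) == 0) stop("selection must be non-empty")
  dos <- matrix(0L, nSubjects(dataset), nrow(selection))
  inv <- alleleInventory(dataset)
  for (i in seq_len(nrow(selection))) {
    j <- match(selection$locus[i], dataset@loci)
    if (is.na(j)) stop("selected locus absent from dataset: ", selection$locus[i])
    a <- parseAllele(selection$allele[i])
    if (!a %in% inv$tenths[inv$locus == selection$locus[i]])
      stop(sprintf("selected allele %s absent at locus %s",
                   selection$allele[i], selection$locus[i]))
    dos[, i] <- (dataset@alleles1[, j] == a) + (dataset@alleles2[, j] == a)
  }
  colnames(dos) <- paste(selection$locus, selection$allele, sep = ":")
  sel <- selection
  if (is.null(sel$loading2)) sel$loading2 <- NA_real_
  new("ReducedDataset", component = component, q = q,
      selection = sel[, c("locus", "allele", "loading2")], dosage = dos,
      subjectIds = dataset@subjectIds, locationId = dataset@locationId,
      locations = dataset@locations)
}

# A ReducedDataset behaves as a set of biallelic pseudo-loci for the
# Weir-Cockerham machinery: dosage 2 -> target/target, 1 -> target/other,
# 0 -> other/other.
setMethod("nSubjects", "ReducedDataset", function(x) length(x@subjectIds))

#' Expand a ReducedDataset into biallelic pseudo-locus genotypes
#'
#' The F-statistic functions accept a [ReducedDataset-class] directly and
#' use this coercion internally.
#'
#' @param x a [ReducedDataset-class].
#' @return an [STRDataset-class] with one biallelic pseudo-locus per
#'   selected allele (codes 2 = target allele, 1 = any other allele).
#' @export
reducedToSTR <- function(x) {
  stopifnot(is(x, "ReducedDataset"))
  a1 <- matrix(1L, nrow(x@dosage), ncol(x@dosage))
  a2 <- a1
  a1[x@dosage == 2L] <- 2L
  a2[x@dosage >= 1L] <- 2L
  STRDataset(colnames(x@dosage), a1, a2, x@subjectIds, x@locationId,
             x@locations)
}
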