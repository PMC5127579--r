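#' Construct an STRDataset from genotype matrices
#'
#' @param loci character vector of locus names.
#' @param alleles1,alleles2 subject x locus matrices of allele labels, as
#'   repeat-count strings ("15", "15.2") or canonical integer tenths. The
#'   pair at each genotype is unordered; it is normalised internally.
#' @param subjectIds character vector of unique subject identifiers.
#' @param locationId character vector mapping each subject to a location id.
#' @param locations data.frame with columns `id`, `name`, `lon`, `lat`.
#' @return an [STRDataset-class] object.
#' @examples
#' loc <- data.frame(id = "A", name = "Alpha", lon = 12, lat = 42)
#' ds <- STRDataset("TH01", matrix("9"), matrix("9.3"), "s1", "A", loc)
#' ds
#' @export
STRDataset <- function(loci, alleles1, alleles2, subjectIds, locationId,
                       locations) {
  loci <- as.character(loci)
  if (length(loci) == 0) stop("dataset must contain at least one locus")
  toTenths <- function(a) {
    m <- if (is.character(a)) matrix(parseAllele(a), nrow(a), ncol(a))
         else matrix(as.integer(a), nrow(a), ncol(a))
    m
  }
  a1 <- toTenths(as.matrix(alleles1))
  a2 <- toTenths(as.matrix(alleles2))
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  locations <- as.data.frame(locations, stringsAsFactors = FALSE)
  locations$id <- as.character(locations$id)
  rownames(locations) <- NULL
  new("STRDataset", loci = loci, alleles1 = a1, alleles2 = a2,
      subjectIds = as.character(subjectIds),
      locationId = as.character(locationId), locations = locations)
}

#' Inventory of distinct alleles per locus
#'
#' @param dataset an [STRDataset-class].
#' @return data.frame with columns `locus`, `allele` (label) and `tenths`
#'   (canonical form), sorted by locus panel order then allele size.
#' @export
alleleInventory <- function(dataset) {
  out <- lapply(seq_along(dataset@loci), function(j) {
    a <- sort(unique(c(dataset@alleles1[, j], dataset@alleles2[, j])))
    data.frame(locus = dataset@loci[j], allele = formatAllele(a),
               tenths = a, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a coordinate sidecar table
#'
#' CSV with header `location_id,name,lon,lat` (`id` accepted for
#' `location_id`), one row per POP block of the companion Genepop file.
#'
#' @param path CSV file path.
#' @return data.frame with columns `id`, `name`, `lon`, `lat`.
#' @export
readCoordinates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "location_id"] <- "id"
  need <- c("id", "name", "lon", "lat")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns location_id,name,lon,lat")
  tab$id <- as.character(tab$id)
  tab[need]
}

popLineRe <- "^[Pp][Oo][Pp]\\s*$"

#' Read a Genepop genotype file into an STRDataset
#'
#' Parses the Genepop 4.x dialect: a title line, locus names (one per line
#' or comma-separated), `POP` separators, and per-subject lines
#' `id , c1 c2 ...` with 2- or 3-digit-per-allele numeric codes.
#' Coordinates come from a sidecar table whose rows map to POP blocks in
#' order.
#'
#' Because Genepop has no native decimal alleles, microvariants use a
#' documented dialect: with `dialect = "tenths"` (the default, used by
#' [writeGenepop()]) each 3-digit code is the canonical tenths form, so
#' `152` is allele 15.2 and `150` is allele 15. With `dialect = "integer"`
#' codes are plain repeat counts (`015` is allele 15), as written by tools
#' without microvariant support. 2-digit codes are always plain integers.
#'
#' @param path Genepop file.
#' @param coordinates data.frame as returned by [readCoordinates()], or a
#'   path to such a CSV. Rows map to POP blocks in file order.
#' @param dialect how to decode 3-digit allele codes (see Details).
#' @return an [STRDataset-class].
#' @export
readGenepop <- function(path, coordinates, dialect = c("tenths", "integer")) {
  dialect <- match.arg(dialect)
  if (is.character(coordinates)) coordinates <- readCoordinates(coordinates)
  lines <- readLines(path)
  if (length(lines) < 3) stop("not a Genepop file: fewer than 3 lines")
  lines <- lines[!grepl("^\\s*$", lines)]
  popAt <- grep(popLineRe, lines)
  if (length(popAt) == 0) stop("not a Genepop file: no POP separator found")
  header <- lines[2:(popAt[1] - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (length(popAt) != nrow(coordinates))
    stop(sprintf("file has %d POP blocks but coordinate table has %d rows",
                 length(popAt), nrow(coordinates)))

  decode <- function(code, lineNo) {
    w <- nchar(code) / 2L
    if (!nchar(code) %in% c(4L, 6L) || grepl("[^0-9]", code))
      stop(sprintf("line %d: malformed allele code '%s'", lineNo, code))
    a <- as.integer(c(substr(code, 1, w), substr(code, w + 1, 2 * w)))
    if (w == 3L && dialect == "tenths") a else a * 10L
  }

  ids <- character(0); locIdx <- integer(0)
  g1 <- list(); g2 <- list()
  bounds <- c(popAt, length(lines) + 1L)
  for (b in seq_along(popAt)) {
    from <- bounds[b] + 1L; to <- bounds[b + 1L] - 1L
    if (from > to) stop(sprintf("POP block %d is empty", b))
    for (i in from:to) {
      parts <- strsplit(lines[i], ",")[[1]]
      if (length(parts) < 2)
        stop(sprintf("line %d: expected 'id , genotypes'", i))
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(codes) != length(loci))
        stop(sprintf("line %d: %d genotype fields for %d loci", i,
                     length(codes), length(loci)))
      ab <- vapply(codes, decode, integer(2), lineNo = i)
      if (any(ab == 0L))
        stop(sprintf("subject %s has a missing genotype (code 0); incomplete profiles are not supported", id))
      ids <- c(ids, id); locIdx <- c(locIdx, b)
      g1[[length(g1) + 1L]] <- ab[1, ]; g2[[length(g2) + 1L]] <- ab[2, ]
    }
  }
  STRDataset(loci,
             matrix(unlist(g1), ncol = length(loci), byrow = TRUE),
             matrix(unlist(g2), ncol = length(loci), byrow = TRUE),
             ids, coordinates$id[locIdx], coordinates)
}

#' Write an STRDataset as a Genepop file
#'
#' Writes the 3-digit-per-allele Genepop dialect; with the default
#' `dialect = "tenths"` codes are canonical tenths (allele 15.2 -> `152`),
#' so a file written here is re-read identically by [readGenepop()].
#' POP blocks follow the order of the location table.
#'
#' @param dataset an [STRDataset-class].
#' @param path output file.
#' @param dialect `"tenths"` (microvariant-safe) or `"integer"` (plain
#'   repeat counts; errors if the dataset contains microvariants).
#' @param title title line (first line of the file).
#' @return `path`, invisibly. A companion coordinate CSV can be written
#'   with [writeCoordinates()].
#' @export
writeGenepop <- function(dataset, path, dialect = c("tenths", "integer"),
                         title = "strscape export") {
  dialect <- match.arg(dialect)
  enc <- function(a) {
    if (dialect == "integer") {
      if (any(a %% 10L != 0L))
        stop("microvariant alleles cannot be encoded in the integer dialect")
      a <- a %/% 10L
    }
    if (any(a > 999L))
      stop("allele label too large for 3-digit Genepop encoding")
    sprintf("%03d", a)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(dataset@loci, con)
  for (loc in dataset@locations$id) {
    writeLines("POP", con)
    rows <- which(dataset@locationId == loc)
    for (i in rows) {
      codes <- paste0(enc(dataset@alleles1[i, ]), enc(dataset@alleles2[i, ]))
      writeLines(paste0(dataset@subjectIds[i], " , ",
                        paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname readCoordinates
#' @param locations data.frame with columns `id`, `name`, `lon`, `lat`
#'   (e.g. from [locationInfo()]).
#' @export
writeCoordinates <- function(locations, path) {
  out <- data.frame(location_id = locations$id, name = locations$name,
                    lon = locations$lon, lat = locations$lat)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-location allele frequencies
#'
#' Counts allele copies per locus and location and divides by the number of
#' gene copies (2 x subjects). The column set is the union of alleles seen
#' anywhere in the dataset, so rows are directly comparable across
#' locations; within each locus every row sums to 1.
#'
#' @param dataset an [STRDataset-class].
#' @return an [AlleleFreqTable-class].
#' @examples
#' loc <- data.frame(id = "A", name = "Alpha", lon = 0, lat = 0)
#' ds <- STRDataset("L1", matrix(c("12", "12")), matrix(c("12", "15")),
#'                  c("s1", "s2"), c("A", "A"), loc)
#' freqMatrix(alleleFrequencies(ds))   # f(12) = 0.75, f(15) = 0.25
#' @export
alleleFrequencies <- function(dataset) {
  inv <- alleleInventory(dataset)
  locIds <- dataset@locations$id
  nloc <- length(locIds)
  popIdx <- match(dataset@locationId, locIds)
  nPer <- tabulate(popIdx, nloc)
  freq <- matrix(0, nloc, nrow(inv))
  copies <- matrix(0L, nloc, length(dataset@loci),
                   dimnames = list(locIds, dataset@loci))
  col0 <- 0L
  for (j in seq_along(dataset@loci)) {
    a <- inv$tenths[inv$locus == dataset@loci[j]]
    k <- length(a)
    idx1 <- match(dataset@alleles1[, j], a)
    idx2 <- match(dataset@alleles2[, j], a)
    cnt <- tabulate(popIdx + nloc * (idx1 - 1L), nloc * k) +
           tabulate(popIdx + nloc * (idx2 - 1L), nloc * k)
    freq[, col0 + seq_len(k)] <- matrix(cnt, nloc, k) / (2 * nPer)
    copies[, j] <- 2L * nPer
    col0 <- col0 + k
  }
  dimnames(freq) <- list(locIds, freqColNames(inv$locus, inv$tenths))
  new("AlleleFreqTable", freq = freq, locusCol = inv$locus,
      alleleCol = as.integer(inv$tenths), copies = copies,
      locations = dataset@locations)
}
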