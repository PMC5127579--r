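# Allele labels: public face is the repeat-count string ("15", "15.2");
# canonical internal form is integer tenths (150, 152), which round-trips
# microvariants losslessly and sorts numerically.

#' Convert allele labels between text and canonical tenths
#'
#' STR alleles are named by repeat count, with microvariants carrying one
#' decimal place (e.g. "15.2" = 15 repeats plus 2 bases). Internally labels
#' are integers in tenths of a repeat: 15 -> 150, 15.2 -> 152.
#'
#' @param x character (or numeric) repeat-count labels for `parseAllele`;
#'   integer tenths for `formatAllele`.
#' @return `parseAllele`: integer vector of canonical tenths.
#'   `formatAllele`: character labels ("15", "15.2").
#' @examples
#' parseAllele(c("15", "15.2"))   # 150 152
#' formatAllele(c(150L, 152L))    # "15" "15.2"
#' @export
parseAllele <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]+(\\.[0-9])?$", x)
  if (!all(ok))
    stop("invalid allele label(s): ", paste(unique(x[!ok]), collapse = ", "))
  v <- as.integer(round(as.numeric(x) * 10))
  if (any(v <= 0)) stop("allele labels must be positive")
  v
}

#' @rdname parseAllele
#' @export
formatAllele <- function(x) {
  x <- as.integer(x)
  whole <- x %/% 10L
  frac <- x %% 10L
  ifelse(frac == 0L, as.character(whole), paste0(whole, ".", frac))
}

# Deterministic per-stage seed derivation: fold a stage label into the
# master seed so each pipeline stage gets an isolated, reproducible stream.
# Kept below 2^31 - 1 (R integers are 32 bit).
deriveSeed <- function(master, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483563
  as.integer((as.numeric(master) %% 2147483563 * 48271 + h) %% 2147483563) + 1L
}

# Dirichlet draw via gamma normalisation.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[] <- 1
  g / sum(g)
}

# Column names of a frequency table: "locus:allele-label".
freqColNames <- function(locus, alleleTenths) {
  paste0(locus, ":", formatAllele(alleleTenths))
}
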