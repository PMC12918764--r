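# Genomic intervals: 0-based half-open [start, end) everywhere inside the
# package. VCF (1-based inclusive) is converted at the I/O boundary only.

#' Normalize a chromosome name
#'
#' Strips a leading `"chr"` prefix so that `"chr11"`, `"Chr11"` and `"11"`
#' all map to `"11"`. The internal convention is prefix-free; output writers
#' re-prefix on request.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  if (any(!nzchar(out))) stop("empty chromosome name after normalization")
  out
}

#' Construct a genomic interval table
#'
#' @param chrom Chromosome names (normalized internally).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @return A `data.table` with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer interval bounds")
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval must satisfy start < end")
  data.table::data.table(chrom = normalize_chrom(chrom), start = start, end = end)
}

interval_length <- function(x) x$end - x$start

# Overlap length of [s1,e1) with [s2,e2); 0 when disjoint.
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Reciprocal overlap of two intervals
#'
#' `min(o / length(a), o / length(b))` where `o` is the overlap in bp;
#' 0 for intervals on different chromosomes. Symmetric; equals 1 iff the
#' intervals are identical.
#'
#' @param a,b Single-row interval tables (or lists with `chrom`, `start`,
#'   `end`). Vectorized over rows when both have equal length.
#' @return Numeric fraction in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  o <- overlap_bp(a$start, a$end, b$start, b$end)
  ro <- pmin(o / (a$end - a$start), o / (b$end - b$start))
  ro[a$chrom != b$chrom] <- 0
  ro
}

#' Parse a region string such as "chr11:100-200-DEL"
#'
#' Accepts `[chr]N:start-end-TYPE` with hyphen or en-dash separators.
#' Coordinates are interpreted as 1-based inclusive (the convention users of
#' VCF-style coordinates expect) and converted to the internal 0-based
#' half-open form.
#'
#' @param text A single region string.
#' @return A list with `chrom`, `start`, `end` (internal convention) and
#'   `type` (`"DEL"` or `"DUP"`).
#' @export
parse_region_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("–", "-", trimws(text))
  m <- regmatches(txt, regexec("^(?:[Cc][Hh][Rr])?([^:[:space:]]+):([0-9]+)-([0-9]+)-([A-Za-z]+)$", txt))[[1]]
  if (length(m) == 0L) stop("cannot parse region string: ", text)
  type <- toupper(m[5])
  if (!type %in% c("DEL", "DUP")) stop("unknown CNV type token: ", m[5])
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (start1 > end1) stop("region start > end in: ", text)
  if (start1 < 1) stop("1-based region start must be >= 1")
  list(chrom = m[2], start = as.integer(start1 - 1), end = as.integer(end1),
       type = type)
}
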