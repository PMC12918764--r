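# The cnv_calls container: one caller's CNV records for one sample, held as
# a data.table with a fixed column set so filter predicates can be vectorized.

# Caller-namespaced quality metrics recognised by the filter rules. Every
# cnv_calls table carries all of them; values the caller does not emit are NA.
CNV_METRIC_COLS <- c("pytorP1", "Q0", "pytorRD", "W", "KS", "max_CW", "TF",
                     "U", "BF", "reads_ratio", "CN", "nt", "QS")

# Callers with a published confidence rule, plus callers that pass through
# unfiltered. apply_caller_filters() refuses anything else.
CALLER_RULES <- c(
  cnvpytor = "cnvpytor", controlfreec = "controlfreec",
  delly = "pass_gt", manta = "pass_gt",
  lumpy = "lumpy", wham = "wham", gridss = "gridss",
  exomedepth = "exomedepth", gatk4 = "gatk4",
  cn.mops = "none", xhmm = "none", ecole = "none",
  cutesv = "none", `svision-pro` = "none", sniffles = "none",
  nanovar = "none", debreak = "none"
)

#' Registered CNV callers
#'
#' @return Character vector of caller identifiers the filter stage accepts.
#' @export
registered_callers <- function() names(CALLER_RULES)

#' Construct a CNV call set
#'
#' Builds the package's central container: a `data.table` of CNV calls from a
#' single caller and sample, sorted by `(chrom, start, end)`, with one row per
#' call and a fixed set of metric columns (missing metrics are `NA`).
#'
#' @param chrom,start,end Interval columns, internal 0-based half-open
#'   convention (see [genomic_interval()]).
#' @param type `"DEL"` or `"DUP"` per call.
#' @param caller Caller identifier (single string).
#' @param sample_id Sample label.
#' @param assembly `"GRCh37"` or `"GRCh38"`.
#' @param genotype Optional genotype strings such as `"0/1"` (`NA` allowed).
#' @param filter Optional semicolon-joined filter-field labels (e.g. `"PASS"`).
#' @param qual Optional numeric QUAL.
#' @param ft Optional per-genotype filter (FORMAT/FT) labels.
#' @param metrics Optional `data.frame`/list of caller metric columns
#'   (subset of `pytorP1, Q0, pytorRD, W, KS, max_CW, TF, U, BF, reads_ratio,
#'   CN, nt, QS`).
#' @return An object of class `cnv_calls` (a `data.table`).
#' @export
cnv_calls <- function(chrom = character(), start = integer(), end = integer(),
                      type = character(), caller = "unknown",
                      sample_id = "sample", assembly = "GRCh38",
                      genotype = NA_character_, filter = NA_character_,
                      qual = NA_real_, ft = NA_character_, metrics = NULL) {
  n <- max(length(chrom), length(start), length(end), length(type))
  if (n > 0L) {
    iv <- genomic_interval(chrom, start, end)
    n <- nrow(iv)
    type <- rep_len(toupper(type), n)
    if (!all(type %in% c("DEL", "DUP"))) stop("type must be DEL or DUP")
    dt <- data.table::data.table(
      chrom = iv$chrom, start = iv$start, end = iv$end, type = type,
      caller = caller, genotype = rep_len(genotype, n),
      filter = rep_len(filter, n), qual = rep_len(as.numeric(qual), n),
      ft = rep_len(ft, n))
  } else {
    dt <- data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      type = character(), caller = character(), genotype = character(),
      filter = character(), qual = numeric(), ft = character())
  }
  for (m in CNV_METRIC_COLS) {
    v <- if (!is.null(metrics) && !is.null(metrics[[m]])) metrics[[m]] else NA_real_
    dt[[m]] <- rep_len(as.numeric(v), nrow(dt))
  }
  data.table::setorder(dt, chrom, start, end)
  data.table::setattr(dt, "sample_id", sample_id)
  data.table::setattr(dt, "assembly", assembly)
  data.table::setattr(dt, "class", c("cnv_calls", class(dt)))
  dt
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("<cnv_calls> %d calls, sample=%s, assembly=%s\n",
              nrow(x), attr(x, "sample_id"), attr(x, "assembly")))
  NextMethod()
}

# Re-attach class/attrs after data.table operations strip them.
as_cnv_calls <- function(dt, template) {
  data.table::setattr(dt, "sample_id", attr(template, "sample_id"))
  data.table::setattr(dt, "assembly", attr(template, "assembly"))
  if (!inherits(dt, "cnv_calls"))
    data.table::setattr(dt, "class", c("cnv_calls", class(dt)))
  dt
}

# Split a semicolon-joined FILTER string into a label set.
filter_labels <- function(filter) {
  if (is.na(filter) || !nzchar(filter)) return(character())
  strsplit(filter, ";", fixed = TRUE)[[1]]
}
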