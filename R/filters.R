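# Caller-specific confidence filters. Each rule is a pure, vectorized
# predicate over a cnv_calls table; thresholds follow each caller's published
# operating point with strict inequalities exactly as printed.

# Missing-metric policy: "lenient" keeps the call with a warning, "strict"
# errors. Controlled via options(cnvcurate.missing_metric = ...).
missing_metric_mode <- function() {
  getOption("cnvcurate.missing_metric", "lenient")
}

# Assemble a filter outcome table: kept iff no rule fired.
filter_outcome <- function(reasons_list) {
  data.table::data.table(
    kept = lengths(reasons_list) == 0L,
    reasons = vapply(reasons_list, paste, character(1), collapse = ";"))
}

# Shared handling of rules whose metric may be absent: in lenient mode a
# missing metric never fires the rule; in strict mode it is an error.
require_metric <- function(x, cols, caller) {
  miss <- vapply(cols, function(cl) any(is.na(x[[cl]])), logical(1))
  if (any(miss)) {
    msg <- sprintf("%s: missing metric(s) %s", caller,
                   paste(cols[miss], collapse = ", "))
    if (missing_metric_mode() == "strict") stop(msg)
    warning(msg, call. = FALSE)
  }
}

collect_reasons <- function(...) {
  conds <- list(...)
  n <- length(conds[[1]]$fire)
  lapply(seq_len(n), function(i) {
    unlist(lapply(conds, function(cn) if (isTRUE(cn$fire[i])) cn$label else NULL))
  })
}

rule <- function(label, fire) list(label = label, fire = fire %in% TRUE)

#' CNVpytor confidence filter
#'
#' Excludes calls with `pytorP1 > 0.05`, or `Q0 > 0.9`, or a normalized read
#' depth in the near-diploid band `0.75 < pytorRD < 1.25` (a depth close to 1
#' is evidence against a real dosage change). The three exclusion conditions
#' combine disjunctively; see the methods vignette for the rationale and the
#' `cnvcurate.pytor_conjunctive` option for the conjunctive alternative.
#'
#' @param calls A [cnv_calls()] table.
#' @return A `data.table` with `kept` (logical) and `reasons` per call.
#' @export
filter_cnvpytor <- function(calls) {
  require_metric(calls, c("pytorP1", "Q0", "pytorRD"), "cnvpytor")
  p1 <- rule("pytorP1", calls$pytorP1 > 0.05)
  q0 <- rule("Q0", calls$Q0 > 0.9)
  rd <- rule("pytorRD", calls$pytorRD > 0.75 & calls$pytorRD < 1.25)
  if (isTRUE(getOption("cnvcurate.pytor_conjunctive", FALSE))) {
    all_fire <- p1$fire & q0$fire & rd$fire
    return(filter_outcome(lapply(all_fire, function(f)
      if (f) c("pytorP1", "Q0", "pytorRD") else character())))
  }
  filter_outcome(collect_reasons(p1, q0, rd))
}

#' ControlFREEC confidence filter
#'
#' Removes calls whose Wilcoxon (`W`) or Kolmogorov-Smirnov (`KS`) test
#' p-value exceeds 0.05.
#'
#' @inheritParams filter_cnvpytor
#' @return Outcome table as in [filter_cnvpytor()].
#' @export
filter_controlfreec <- function(calls) {
  require_metric(calls, c("W", "KS"), "controlfreec")
  filter_outcome(collect_reasons(
    rule("W", calls$W > 0.05),
    rule("KS", calls$KS > 0.05)))
}

#' PASS/genotype filter (delly, Manta)
#'
#' Keeps a call only when both the site FILTER field and the per-genotype
#' filter (FORMAT/FT) carry `PASS`, and the genotype is not `0/0`. A missing
#' genotype is treated as non-`0/0`; a missing FT is treated as `PASS`
#' (both logged in lenient mode).
#'
#' @inheritParams filter_cnvpytor
#' @return Outcome table as in [filter_cnvpytor()].
#' @export
filter_pass_gt <- function(calls) {
  site_pass <- vapply(calls$filter, function(f) "PASS" %in% filter_labels(f),
                      logical(1))
  ft_pass <- is.na(calls$ft) | calls$ft == "PASS"
  if (any(is.na(calls$ft)))
    warning("pass_gt: missing FT treated as PASS", call. = FALSE)
  hom_ref <- !is.na(calls$genotype) & calls$genotype %in% c("0/0", "0|0")
  filter_outcome(collect_reasons(
    rule("site_filter", !site_pass),
    rule("genotype_filter", !ft_pass),
    rule("genotype_0/0", hom_ref)))
}

#' lumpy confidence filter
#'
#' Removes calls with QUAL below 120.
#'
#' @inheritParams filter_cnvpytor
#' @return Outcome table as in [filter_cnvpytor()].
#' @export
filter_lumpy <- function(calls) {
  if (any(is.na(calls$qual))) {
    msg <- "lumpy: missing QUAL"
    if (missing_metric_mode() == "strict") stop(msg)
    warning(msg, call. = FALSE)
  }
  filter_outcome(collect_reasons(rule("qual", calls$qual < 120)))
}

#' Wham confidence filter
#'
#' Removes calls with `max_CW < 0.2`, deletions with fewer than 3 supporting
#' split reads (`TF < 3`), and duplications with fewer than 2 supporting
#' reads (`U < 2`).
#'
#' @inheritParams filter_cnvpytor
#' @return Outcome table as in [filter_cnvpytor()].
#' @export
filter_wham <- function(calls) {
  require_metric(calls, "max_CW", "wham")
  filter_outcome(collect_reasons(
    rule("max_CW", calls$max_CW < 0.2),
    rule("TF", calls$type == "DEL" & calls$TF < 3),
    rule("U", calls$type == "DUP" & calls$U < 2)))
}

#' GRIDSS confidence filter
#'
#' Removes calls carrying the `NO_ASSEMBLY` label in the FILTER field.
#'
#' @inheritParams filter_cnvpytor
#' @return Outcome table as in [filter_cnvpytor()].
#' @export
filter_gridss <- function(calls) {
  fire <- vapply(calls$filter,
                 function(f) "NO_ASSEMBLY" %in% filter_labels(f), logical(1))
  filter_outcome(collect_reasons(rule("NO_ASSEMBLY", fire)))
}

#' ExomeDepth confidence filter
#'
#' Removes calls with Bayes factor `BF < 15`, deletions whose observed over
#' expected read ratio exceeds 0.8, and duplications whose ratio falls below
#' 1.1 (ratios near 1 contradict the called dosage change).
#'
#' @inheritParams filter_cnvpytor
#' @return Outcome table as in [filter_cnvpytor()].
#' @export
filter_exomedepth <- function(calls) {
  require_metric(calls, c("BF", "reads_ratio"), "exomedepth")
  filter_outcome(collect_reasons(
    rule("BF", calls$BF < 15),
    rule("reads_ratio", (calls$type == "DEL" & calls$reads_ratio > 0.8) |
                        (calls$type == "DUP" & calls$reads_ratio < 1.1)))
  )
}

#' GATK4 gCNV quality-score threshold
#'
#' The minimum QS a call must reach, as a function of type, copy-number
#' state and the number of exons spanned (`nt`):
#' deletions at CN 0 need `min(1000, max(400, 10 nt))`, at CN 1
#' `min(1000, max(100, 10 nt))`; duplications need `min(400, max(50, 4 nt))`.
#'
#' @param type `"DEL"` or `"DUP"` (vectorized).
#' @param cn Copy-number state (used for DEL only).
#' @param nt Number of exons the call spans (>= 1).
#' @return Numeric threshold vector; `NA` where the rule does not apply
#'   (DEL with CN outside \{0, 1\}).
#' @export
gatk4_qs_threshold <- function(type, cn, nt) {
  n <- max(length(type), length(cn), length(nt))
  type <- rep_len(type, n); cn <- rep_len(cn, n); nt <- rep_len(nt, n)
  t_del0 <- pmin(1000, pmax(400, 10 * nt))
  t_del1 <- pmin(1000, pmax(100, 10 * nt))
  t_dup <- pmin(400, pmax(50, 4 * nt))
  out <- rep(NA_real_, n)
  out[type == "DUP"] <- t_dup[type == "DUP"]
  out[type == "DEL" & cn == 0] <- t_del0[type == "DEL" & cn == 0]
  out[type == "DEL" & cn == 1] <- t_del1[type == "DEL" & cn == 1]
  out
}

#' GATK4 gCNV confidence filter
#'
#' Removes calls whose QS falls below the exon-count-dependent threshold of
#' [gatk4_qs_threshold()]. Deletions with a copy-number state other than 0 or
#' 1 are outside the rule and kept with a warning.
#'
#' @inheritParams filter_cnvpytor
#' @return Outcome table as in [filter_cnvpytor()].
#' @export
filter_gatk4 <- function(calls) {
  require_metric(calls, c("QS", "nt"), "gatk4")
  thr <- gatk4_qs_threshold(calls$type, calls$CN, calls$nt)
  inapplicable <- calls$type == "DEL" & (is.na(calls$CN) | !calls$CN %in% c(0, 1))
  if (any(inapplicable))
    warning("gatk4: DEL with CN outside {0,1}; QS rule not applied",
            call. = FALSE)
  filter_outcome(collect_reasons(rule("QS", !is.na(thr) & calls$QS < thr)))
}

caller_filter_fun <- function(rule_id) {
  switch(rule_id,
         cnvpytor = filter_cnvpytor, controlfreec = filter_controlfreec,
         pass_gt = filter_pass_gt, lumpy = filter_lumpy, wham = filter_wham,
         gridss = filter_gridss, exomedepth = filter_exomedepth,
         gatk4 = filter_gatk4, none = NULL)
}

#' Apply the caller-specific filter to a call set
#'
#' Dispatches on the call set's caller. Callers without a published
#' confidence rule (cn.mops, xhmm, ECOLE, and the long-read callers cuteSV,
#' SVision-pro, Sniffles, NanoVar, DeBreak) pass through unfiltered.
#'
#' @param calls A [cnv_calls()] table (single caller).
#' @return A list with `kept` (the surviving [cnv_calls()]), `outcome` (the
#'   per-call outcome table) and `report` (a `data.table` of per-rule removal
#'   counts).
#' @export
apply_caller_filters <- function(calls) {
  caller <- unique(calls$caller)
  if (length(caller) == 0L) caller <- "unknown"
  if (length(caller) > 1L) stop("call set mixes callers: ",
                                paste(caller, collapse = ", "))
  if (!caller %in% names(CALLER_RULES))
    stop("unknown caller '", caller, "'; registered callers: ",
         paste(registered_callers(), collapse = ", "))
  fn <- caller_filter_fun(CALLER_RULES[[caller]])
  if (is.null(fn)) {
    outcome <- data.table::data.table(kept = rep(TRUE, nrow(calls)),
                                      reasons = rep("", nrow(calls)))
  } else {
    outcome <- fn(calls)
  }
  kept <- as_cnv_calls(calls[outcome$kept], calls)
  fired <- unlist(strsplit(outcome$reasons[!outcome$kept], ";", fixed = TRUE))
  report <- if (length(fired)) {
    data.table::data.table(caller = caller, rule = names(table(fired)),
                           removed = as.integer(table(fired)))
  } else {
    data.table::data.table(caller = character(), rule = character(),
                           removed = integer())
  }
  list(kept = kept, outcome = outcome, report = report)
}
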