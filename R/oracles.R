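# Deliberately naive reference implementations used by the fixture
# generator and the test suite to compute expected outputs. They transcribe
# each rule literally, use quadratic scans, and share no code with the
# production modules they check.

#' Literal per-caller filter oracle
#'
#' Evaluates one caller's confidence rule on a single call given as a plain
#' list, transcribing each published threshold directly.
#'
#' @param caller Caller identifier.
#' @param x List with whatever fields the caller's rule needs (`type`,
#'   `qual`, `filter`, `ft`, `genotype`, metric values).
#' @return `TRUE` when the call is kept.
#' @export
oracle_filter_kept <- function(caller, x) {
  switch(caller,
    cnvpytor = !(x$pytorP1 > 0.05 || x$Q0 > 0.9 ||
                 (x$pytorRD > 0.75 && x$pytorRD < 1.25)),
    controlfreec = !(x$W > 0.05 || x$KS > 0.05),
    delly = ,
    manta = {
      site <- any(strsplit(x$filter, ";")[[1]] == "PASS")
      ftp <- is.null(x$ft) || is.na(x$ft) || x$ft == "PASS"
      gt_ok <- is.null(x$genotype) || is.na(x$genotype) ||
        !(x$genotype %in% c("0/0", "0|0"))
      site && ftp && gt_ok
    },
    lumpy = !(x$qual < 120),
    wham = !(x$max_CW < 0.2 ||
             (x$type == "DEL" && !is.null(x$TF) && !is.na(x$TF) && x$TF < 3) ||
             (x$type == "DUP" && !is.null(x$U) && !is.na(x$U) && x$U < 2)),
    gridss = !any(strsplit(x$filter, ";")[[1]] == "NO_ASSEMBLY"),
    exomedepth = !(x$BF < 15 ||
                   (x$type == "DEL" && x$reads_ratio > 0.8) ||
                   (x$type == "DUP" && x$reads_ratio < 1.1)),
    gatk4 = {
      thr <- if (x$type == "DUP") min(400, max(50, 4 * x$nt))
             else if (x$CN == 0) min(1000, max(400, 10 * x$nt))
             else if (x$CN == 1) min(1000, max(100, 10 * x$nt))
             else NA_real_
      is.na(thr) || !(x$QS < thr)
    },
    TRUE)
}

#' Transitive-closure clustering oracle
#'
#' Quadratic single-linkage partition: two calls are linked when they share
#' chromosome, type and size bin and both breakpoints lie within
#' `max_dist * max(len_a, len_b)` (or `max_dist` bp when >= 1); clusters are
#' the transitive closure of that relation.
#'
#' @param dt `data.frame`/`data.table` with `chrom`, `start`, `end`, `type`.
#' @param max_dist Breakpoint proximity parameter.
#' @param platform_class `"WGS_LRS"` or `"WES"`.
#' @return Integer cluster id per row (ids ordered by first occurrence).
#' @export
oracle_cluster_ids <- function(dt, max_dist = 0.5,
                               platform_class = "WGS_LRS") {
  n <- nrow(dt)
  if (n == 0L) return(integer())
  len <- dt$end - dt$start
  bin_of <- function(l) {
    if (platform_class == "WGS_LRS") {
      if (l < 500) "SS" else if (l < 5000) "S" else if (l < 100000) "M" else "L"
    } else {
      if (l < 10000) "S" else if (l < 100000) "M" else "L"
    }
  }
  bins <- vapply(len, bin_of, character(1))
  linked <- function(i, j) {
    if (dt$chrom[i] != dt$chrom[j] || dt$type[i] != dt$type[j] ||
        bins[i] != bins[j]) return(FALSE)
    D <- if (max_dist < 1) max_dist * max(len[i], len[j]) else max_dist
    abs(dt$start[i] - dt$start[j]) <= D && abs(dt$end[i] - dt$end[j]) <= D
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && linked(i, j)) {
        old <- max(comp[i], comp[j]); new <- min(comp[i], comp[j])
        comp[comp == old] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' All-pairs region-filter oracle
#'
#' Scans every (CNV, region) pair and flags a CNV for removal when the
#' reciprocal overlap, computed inline, reaches the threshold.
#'
#' @param cnvs,regions Tables with `chrom`, `start`, `end`.
#' @param threshold Reciprocal-overlap cut-off.
#' @return Logical vector: `TRUE` where the CNV is removed.
#' @export
oracle_region_removed <- function(cnvs, regions, threshold = 0.70) {
  vapply(seq_len(nrow(cnvs)), function(i) {
    for (j in seq_len(nrow(regions))) {
      if (cnvs$chrom[i] != regions$chrom[j]) next
      o <- min(cnvs$end[i], regions$end[j]) - max(cnvs$start[i], regions$start[j])
      if (o <= 0) next
      ro <- min(o / (cnvs$end[i] - cnvs$start[i]),
                o / (regions$end[j] - regions$start[j]))
      if (ro >= threshold) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Linear-scan gene-overlap oracle
#'
#' @param genes Gene table with `symbol`, `chrom`, `start`, `end`.
#' @param interval List with `chrom`, `start`, `end`.
#' @return Character vector of overlapped gene symbols.
#' @export
oracle_overlapping_symbols <- function(genes, interval) {
  hit <- genes$chrom == interval$chrom &
    genes$start < interval$end & genes$end > interval$start
  genes$symbol[hit]
}

#' Hand-coded classification band oracle
#'
#' @param total Total evidence points.
#' @return Category string.
#' @export
oracle_band <- function(total) {
  t <- round(total, 2)
  if (t >= 0.99) "Pathogenic"
  else if (t >= 0.90) "Likely pathogenic"
  else if (t <= -0.99) "Benign"
  else if (t <= -0.90) "Likely benign"
  else "VUS"
}
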