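# Blacklist / assembly-gap filtering by reciprocal overlap. Region sets are
# indexed with GenomicRanges; tests verify the indexed queries against a
# brute-force all-pairs oracle.

#' Read a region set from BED
#'
#' @param path BED3 file (additional columns ignored).
#' @param label `"blacklist"` or `"gap"` (free-form accepted).
#' @return A `region_set` list: `label`, `intervals` (`data.table`), `gr`
#'   (`GRanges` index).
#' @export
read_region_bed <- function(path, label = "blacklist") {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          skip = "\t")
  if (ncol(dt) < 3L) stop("region BED needs 3 columns: ", path)
  iv <- genomic_interval(dt[[1]], dt[[2]], dt[[3]])
  data.table::setorder(iv, chrom, start, end)
  region_set(iv, label)
}

#' Construct a region set from an interval table
#'
#' @param intervals `data.table` with `chrom`, `start`, `end` (internal
#'   0-based half-open convention).
#' @param label Region-set label.
#' @return A `region_set` list.
#' @export
region_set <- function(intervals, label = "blacklist") {
  iv <- data.table::as.data.table(intervals)[, c("chrom", "start", "end")]
  data.table::setorder(iv, chrom, start, end)
  gr <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  structure(list(label = label, intervals = iv, gr = gr),
            class = "region_set")
}

#' Filter CNVs against a region set by reciprocal overlap
#'
#' A CNV is removed when its [reciprocal_overlap()] with any single region
#' reaches `threshold`. With `union = TRUE`, the overlap is instead computed
#' against the union of overlapping region bases (a CNV tiled by many small
#' regions can then be removed even if no single region reaches the cut).
#'
#' @param cnvs `data.table` with `chrom`, `start`, `end` (e.g. merged CNVs).
#' @param regions A `region_set`.
#' @param threshold Reciprocal-overlap cut-off in (0, 1\]; default 0.70.
#' @param union Use union-of-regions overlap instead of per-region.
#' @return List with `kept` and `removed` subsets of `cnvs`.
#' @export
filter_by_regions <- function(cnvs, regions, threshold = 0.70, union = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  cnvs <- data.table::as.data.table(cnvs)
  if (nrow(regions$intervals) == 0L) {
    warning("empty region set '", regions$label, "': all CNVs kept",
            call. = FALSE)
    return(list(kept = cnvs, removed = cnvs[0]))
  }
  if (nrow(cnvs) == 0L) return(list(kept = cnvs, removed = cnvs))
  qgr <- GenomicRanges::GRanges(
    cnvs$chrom, IRanges::IRanges(start = cnvs$start + 1L, end = cnvs$end))
  hits <- GenomicRanges::findOverlaps(qgr, regions$gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  remove <- rep(FALSE, nrow(cnvs))
  if (length(qi)) {
    reg <- regions$intervals
    o <- overlap_bp(cnvs$start[qi], cnvs$end[qi], reg$start[si], reg$end[si])
    if (union) {
      len_q <- cnvs$end - cnvs$start
      for (i in unique(qi)) {
        sel <- si[qi == i]
        cov <- IRanges::reduce(IRanges::IRanges(
          start = pmax(reg$start[sel], cnvs$start[i]) + 1L,
          end = pmin(reg$end[sel], cnvs$end[i])))
        ub <- sum(IRanges::width(cov))
        # union overlap fraction of the CNV; region-side fraction uses the
        # union's footprint length
        ulen <- max(reg$end[sel]) - min(reg$start[sel])
        if (min(ub / len_q[i], ub / ulen) >= threshold) remove[i] <- TRUE
      }
    } else {
      ro <- pmin(o / (cnvs$end[qi] - cnvs$start[qi]),
                 o / (reg$end[si] - reg$start[si]))
      for (i in which(ro >= threshold)) remove[qi[i]] <- TRUE
    }
  }
  list(kept = cnvs[!remove], removed = cnvs[remove])
}
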