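# Size- and type-aware ensemble merging. Calls are partitioned by
# (chromosome, type, size bin) and clustered by single linkage under a
# breakpoint-proximity relation; each cluster yields one consensus CNV.

#' Size-bin table for a platform class
#'
#' WGS and long-read data use four bins: SS \[50, 500), S \[500, 5 kb),
#' M \[5 kb, 100 kb), L \[100 kb, Inf). WES data use three: S \[50, 10 kb),
#' M \[10 kb, 100 kb), L \[100 kb, Inf). Bins are half-open so every length
#' >= 50 maps to exactly one bin.
#'
#' @param platform_class `"WGS_LRS"` (short-read WGS and long-read) or
#'   `"WES"`.
#' @return `data.table` with `label`, `lower`, `upper`.
#' @export
size_bins <- function(platform_class = c("WGS_LRS", "WES")) {
  platform_class <- match.arg(platform_class)
  if (platform_class == "WGS_LRS") {
    data.table::data.table(label = c("SS", "S", "M", "L"),
                           lower = c(50, 500, 5000, 100000),
                           upper = c(500, 5000, 100000, Inf))
  } else {
    data.table::data.table(label = c("S", "M", "L"),
                           lower = c(50, 10000, 100000),
                           upper = c(10000, 100000, Inf))
  }
}

#' Assign a CNV length to its size bin
#'
#' @param length CNV length(s) in bp, each >= 50.
#' @param platform_class See [size_bins()].
#' @return Character vector of bin labels.
#' @export
assign_size_bin <- function(length, platform_class = "WGS_LRS") {
  if (any(length < 50)) stop("CNV length below the 50 bp minimum")
  bins <- size_bins(platform_class)
  idx <- vapply(length, function(l) which(l >= bins$lower & l < bins$upper),
                integer(1))
  bins$label[idx]
}

#' Breakpoint compatibility of two calls
#'
#' Two calls on the same chromosome and of the same type are compatible when
#' both breakpoints lie within `D` of each other, where
#' `D = max_dist * max(length(a), length(b))` for a fractional `max_dist`
#' (< 1) or `D = max_dist` bp for an absolute one (>= 1).
#'
#' @param a,b Single-row call/interval tables with `chrom`, `start`, `end`,
#'   and optionally `type`.
#' @param max_dist Breakpoint proximity parameter (default 0.5, fractional).
#' @return Logical.
#' @export
breakpoints_compatible <- function(a, b, max_dist = 0.5) {
  if (a$chrom != b$chrom) return(FALSE)
  if (!is.null(a$type) && !is.null(b$type) && a$type != b$type) return(FALSE)
  D <- if (max_dist < 1) max_dist * max(a$end - a$start, b$end - b$start)
       else max_dist
  abs(a$start - b$start) <= D && abs(a$end - b$end) <= D
}

# Pairwise compatibility matrix for one partition (same chrom/type/bin).
compat_matrix <- function(dt, max_dist) {
  n <- nrow(dt)
  len <- dt$end - dt$start
  D <- if (max_dist < 1) max_dist * outer(len, len, pmax)
       else matrix(max_dist, n, n)
  ds <- abs(outer(dt$start, dt$start, "-"))
  de <- abs(outer(dt$end, dt$end, "-"))
  ds <= D & de <= D
}

# Connected components of a logical adjacency matrix (transitive closure of
# the compatibility relation) via BFS.
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Enforce at most one call per caller in a component: the seed (first call
# in (start, end, caller) order) anchors the cluster; per caller the call
# with the smallest breakpoint distance to the seed stays, the rest are
# re-clustered among themselves.
split_by_caller <- function(dt, max_dist) {
  out <- list()
  work <- data.table::copy(dt)
  while (nrow(work) > 0L) {
    data.table::setorder(work, start, end, caller)
    seed <- work[1]
    d <- abs(work$start - seed$start) + abs(work$end - seed$end)
    pick_idx <- tapply(seq_len(nrow(work)), work$caller,
                       function(ix) ix[which.min(d[ix])])
    pick_idx <- sort(unname(unlist(pick_idx)))
    out[[length(out) + 1L]] <- work[pick_idx]
    work <- work[-pick_idx]
    if (nrow(work) > 0L) {
      adj <- compat_matrix(work, max_dist)
      comp <- components_of(adj)
      clean <- all(vapply(sort(unique(comp)), function(cid)
        anyDuplicated(work$caller[comp == cid]) == 0L, logical(1)))
      if (clean) {
        for (cid in sort(unique(comp)))
          out[[length(out) + 1L]] <- work[comp == cid]
        work <- work[0]
      }
    }
  }
  out
}

#' Cluster filtered calls into consensus CNVs
#'
#' Calls are partitioned by (chromosome, type, size bin); within a partition,
#' single-linkage clustering under [breakpoints_compatible()] groups
#' concordant calls. A cluster holds at most one call per caller; competing
#' same-caller calls seed new clusters. The representative interval takes the
#' per-endpoint median over supporting calls (rounded down).
#'
#' @param calls A [cnv_calls()] table, possibly mixing callers.
#' @param max_dist Breakpoint proximity parameter (see
#'   [breakpoints_compatible()]).
#' @param platform_class See [size_bins()].
#' @return A `data.table` of merged CNVs: `chrom`, `start`, `end`, `type`,
#'   `bin`, `support` (caller count), `callers` (comma list), `members`
#'   (list-column of supporting call tables).
#' @export
cluster_calls <- function(calls, max_dist = 0.5, platform_class = "WGS_LRS") {
  dt <- data.table::as.data.table(calls)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      type = character(), bin = character(), support = integer(),
      callers = character(), members = list()))
  }
  dt$bin <- assign_size_bin(dt$end - dt$start, platform_class)
  data.table::setorder(dt, chrom, type, bin, start, end, caller)
  clusters <- list()
  parts <- split(dt, by = c("chrom", "type", "bin"), drop = TRUE)
  for (key in sort(names(parts))) {
    part <- parts[[key]]
    adj <- compat_matrix(part, max_dist)
    comp <- components_of(adj)
    for (cid in sort(unique(comp))) {
      sub <- part[comp == cid]
      if (anyDuplicated(sub$caller)) {
        clusters <- c(clusters, split_by_caller(sub, max_dist))
      } else {
        clusters[[length(clusters) + 1L]] <- sub
      }
    }
  }
  rows <- lapply(clusters, function(sub) {
    data.table::setorder(sub, start, end, caller)
    data.table::data.table(
      chrom = sub$chrom[1],
      start = as.integer(floor(stats::median(sub$start))),
      end = as.integer(floor(stats::median(sub$end))),
      type = sub$type[1], bin = sub$bin[1],
      support = length(unique(sub$caller)),
      callers = paste(sort(unique(sub$caller)), collapse = ","),
      members = list(sub))
  })
  merged <- data.table::rbindlist(rows)
  data.table::setorder(merged, chrom, start, end, type)
  merged
}

#' Default merge configuration
#'
#' Per (type, size bin) tool set and minimum caller support used by
#' [select_consensus()]. The default admits every registered caller and asks
#' for support from 2 callers in the small bins (SS, S) and 1 in the larger
#' ones (M, L), where individual callers are more reliable.
#'
#' @param platform_class See [size_bins()].
#' @param callers Tool set applied to every (type, bin).
#' @return Nested list: `config[[type]][[bin]] = list(tools, min_support)`.
#' @export
default_merge_config <- function(platform_class = "WGS_LRS",
                                 callers = registered_callers()) {
  bins <- size_bins(platform_class)$label
  per_type <- lapply(bins, function(b) {
    list(tools = callers, min_support = if (b %in% c("SS", "S")) 2L else 1L)
  })
  names(per_type) <- bins
  list(DEL = per_type, DUP = per_type)
}

#' Read a merge configuration from YAML
#'
#' @param path YAML with top-level keys `DEL`/`DUP`, each mapping bin labels
#'   to `tools` (list) and `min_support` (integer).
#' @return Merge config list as in [default_merge_config()].
#' @export
read_merge_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (ty in names(cfg)) for (b in names(cfg[[ty]])) {
    entry <- cfg[[ty]][[b]]
    if (is.null(entry$tools) || length(entry$tools) == 0L)
      stop("merge config ", ty, "/", b, " has an empty tool set")
    cfg[[ty]][[b]]$min_support <- as.integer(entry$min_support %||% 1L)
  }
  cfg
}

#' Select consensus CNVs from merged clusters
#'
#' A merged CNV is kept when the number of its supporting callers that
#' belong to the configured tool set for its (type, bin) reaches the
#' configured minimum support.
#'
#' @param merged Output of [cluster_calls()].
#' @param config Merge configuration (see [default_merge_config()]).
#' @return The kept subset of `merged`.
#' @export
select_consensus <- function(merged, config = default_merge_config()) {
  if (nrow(merged) == 0L) return(merged)
  keep <- vapply(seq_len(nrow(merged)), function(i) {
    ty <- merged$type[i]; b <- merged$bin[i]
    entry <- config[[ty]][[b]]
    if (is.null(entry))
      stop("merge config lacks (", ty, ", ", b, "); configured: ",
           paste(unlist(lapply(names(config), function(t)
             paste(t, names(config[[t]]), sep = "/"))), collapse = ", "))
    supp <- strsplit(merged$callers[i], ",", fixed = TRUE)[[1]]
    length(intersect(supp, entry$tools)) >= entry$min_support
  }, logical(1))
  merged[keep]
}
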