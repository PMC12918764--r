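# One-shot orchestration: per-caller filtering -> ensemble merge ->
# region filtering (short-read platforms) -> per-CNV interpretation, with a
# run manifest recording digests and per-stage counts.

SHORT_READ_PLATFORMS <- c("HD-WGS", "LD-WGS", "WES")
ALL_PLATFORMS <- c(SHORT_READ_PLATFORMS, "PB", "ONT")

platform_class_of <- function(platform) {
  if (platform == "WES") "WES" else "WGS_LRS"
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML path or a list. Schema violations are collected and
#' reported together, not first-failure. Warns when a caller profile is
#' supplied for a caller absent from every merge tool set, or when region
#' files are supplied for a long-read platform (region filters apply to
#' short-read data only).
#'
#' @param config YAML file path or config list with fields `platform`,
#'   `inputs` (list of `vcf`/`bed` + `caller` entries), `resources`
#'   (bundle directory), and optional `merge_config`, `blacklist`, `gaps`,
#'   `rubric`, `max_dist`, `out_dir`.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character()
  if (is.null(config$platform) || !config$platform %in% ALL_PLATFORMS)
    errs <- c(errs, paste0("platform must be one of ",
                           paste(ALL_PLATFORMS, collapse = ", ")))
  if (is.null(config$inputs) || length(config$inputs) == 0L) {
    errs <- c(errs, "at least one input call set is required")
  } else {
    for (i in seq_along(config$inputs)) {
      inp <- config$inputs[[i]]
      f <- inp$vcf %||% inp$bed
      if (is.null(f)) errs <- c(errs, sprintf("input %d: no vcf/bed path", i))
      else if (!file.exists(f)) errs <- c(errs, sprintf("input %d: no such file %s", i, f))
      if (is.null(inp$caller)) errs <- c(errs, sprintf("input %d: no caller", i))
      else if (!inp$caller %in% registered_callers())
        errs <- c(errs, sprintf("input %d: unknown caller '%s'", i, inp$caller))
    }
  }
  if (is.null(config$resources)) errs <- c(errs, "resources directory required")
  else if (!dir.exists(config$resources))
    errs <- c(errs, paste0("no such resources directory: ", config$resources))
  for (f in c("blacklist", "gaps", "merge_config", "rubric")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      errs <- c(errs, paste0("no such file for ", f, ": ", config[[f]]))
  }
  if (length(errs)) stop("invalid run config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  if (!config$platform %in% SHORT_READ_PLATFORMS &&
      (!is.null(config$blacklist) || !is.null(config$gaps)))
    warning("region files supplied for long-read platform ", config$platform,
            ": region filters apply to short-read data only", call. = FALSE)

  mc <- if (!is.null(config$merge_config)) read_merge_config(config$merge_config)
        else default_merge_config(platform_class_of(config$platform))
  tool_universe <- unique(unlist(lapply(mc, function(ty)
    lapply(ty, function(b) b$tools))))
  callers <- vapply(config$inputs, function(i) i$caller, character(1))
  outside <- setdiff(callers, tool_universe)
  if (length(outside))
    warning("caller(s) filtered but absent from every merge tool set: ",
            paste(outside, collapse = ", "), call. = FALSE)
  config$merge_config_parsed <- mc
  config$max_dist <- config$max_dist %||% 0.5
  config$ro_threshold <- config$ro_threshold %||% 0.70
  config$af_threshold <- config$af_threshold %||% 0.01
  class(config) <- "run_config"
  config
}

#' Run the post-calling pipeline
#'
#' Executes filter -> merge -> region-filter -> interpret in fixed order,
#' writing every intermediate and a run manifest to the output directory.
#' Report files carry no timestamps, so reruns on identical inputs are
#' byte-identical; the manifest's `timestamp` field is the only varying
#' output.
#'
#' @param config A `run_config` (or anything [validate_config()] accepts).
#' @param out_dir Output directory (defaults to `config$out_dir`).
#' @return List `report` (interpretation table), `merged` (consensus CNVs),
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pc <- platform_class_of(config$platform)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  bundle <- stage("resources", load_resources(config$resources))
  rubric <- stage("rubric", if (!is.null(config$rubric))
    read_rubric(config$rubric) else default_rubric())

  counts <- list()
  filtered <- list()
  filter_reports <- list()
  for (inp in config$inputs) {
    calls <- stage(paste0("ingest:", inp$caller), {
      prof <- if (!is.null(inp$profile)) read_caller_profile(inp$profile)
              else default_caller_profile(inp$caller)
      if (!is.null(inp$vcf)) read_cnv_vcf(inp$vcf, inp$caller, prof)
      else read_cnv_bed(inp$bed, caller = inp$caller,
                        default_type = inp$default_type)
    })
    res <- stage(paste0("filter:", inp$caller),
                 suppressWarnings(apply_caller_filters(calls)))
    filtered[[inp$caller]] <- res$kept
    filter_reports[[inp$caller]] <- res$report
    counts[[paste0("input_", inp$caller)]] <- nrow(calls)
    counts[[paste0("filtered_", inp$caller)]] <- nrow(res$kept)
    write_calls(res$kept, file.path(out_dir, paste0("filtered_", inp$caller, ".tsv")),
                format = "tsv")
  }
  freport <- data.table::rbindlist(filter_reports)
  data.table::fwrite(freport, file.path(out_dir, "filter_report.tsv"), sep = "\t")

  all_calls <- data.table::rbindlist(filtered)
  merged <- stage("merge", cluster_calls(all_calls, config$max_dist, pc))
  consensus <- stage("consensus",
                     select_consensus(merged, config$merge_config_parsed))
  counts$merged_clusters <- nrow(merged)
  counts$consensus <- nrow(consensus)

  if (config$platform %in% SHORT_READ_PLATFORMS) {
    for (kind in c("blacklist", "gaps")) {
      if (is.null(config[[kind]])) next
      rs <- stage(paste0("regions:", kind),
                  read_region_bed(config[[kind]], kind))
      fr <- stage(paste0("regionfilter:", kind),
                  filter_by_regions(consensus, rs, config$ro_threshold))
      consensus <- fr$kept
      counts[[paste0("after_", kind)]] <- nrow(consensus)
    }
  }
  data.table::fwrite(consensus[, !"members"],
                     file.path(out_dir, "consensus_cnvs.tsv"), sep = "\t")

  rows <- list()
  if (nrow(consensus)) {
    for (i in seq_len(nrow(consensus))) {
      cnv <- consensus[i]
      res <- stage(sprintf("interpret:%s:%d-%d", cnv$chrom, cnv$start, cnv$end),
                   interpret(cnv, bundle, rubric,
                             af_threshold = config$af_threshold,
                             ro_threshold = config$ro_threshold))
      rep <- data.table::copy(res$report)
      rep <- cbind(data.table::data.table(
        chrom = cnv$chrom, start = cnv$start, end = cnv$end, type = cnv$type,
        support = cnv$support, callers = cnv$callers,
        category = res$classification$category,
        total = res$classification$total), rep)
      rows[[length(rows) + 1L]] <- rep
    }
  }
  report <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table()
  data.table::fwrite(report, file.path(out_dir, "interpretation_report.tsv"),
                     sep = "\t")
  counts$interpreted <- nrow(consensus)

  input_files <- unlist(lapply(config$inputs, function(i) i$vcf %||% i$bed))
  manifest <- list(
    tool = "cnvcurate",
    version = as.character(utils::packageVersion("cnvcurate")),
    platform = config$platform,
    input_digests = as.list(tools::md5sum(input_files)),
    stage_counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(report = report, merged = consensus, manifest = manifest)
}
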