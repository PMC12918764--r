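# VCF/BED/TSV ingestion and export. VCF records use symbolic <DEL>/<DUP>
# alleles with INFO END/SVTYPE/SVLEN; per-caller quality metrics live under
# INFO or FORMAT keys declared in a caller profile.

#' Default caller profile
#'
#' A caller profile maps the package's metric names to the VCF INFO/FORMAT
#' keys a given caller writes. The default profile assumes keys equal to the
#' metric names (the dialect the fixture generator emits); real caller
#' dialects are declared in a YAML profile (see [read_caller_profile()]).
#'
#' @param caller Caller identifier.
#' @return A profile list with elements `caller`, `info`, `format`.
#' @export
default_caller_profile <- function(caller) {
  info <- stats::setNames(as.list(CNV_METRIC_COLS), CNV_METRIC_COLS)
  list(caller = caller, info = info, format = list(genotype = "GT", ft = "FT"))
}

#' Read a caller profile from YAML
#'
#' @param path YAML file with keys `caller`, `info` (metric -> INFO key map)
#'   and optional `format` (metric -> FORMAT key map).
#' @return A profile list.
#' @export
read_caller_profile <- function(path) {
  p <- yaml::read_yaml(path)
  if (is.null(p$caller)) stop("caller profile lacks 'caller' field: ", path)
  base <- default_caller_profile(p$caller)
  if (!is.null(p$info)) base$info[names(p$info)] <- p$info
  if (!is.null(p$format)) base$format[names(p$format)] <- p$format
  base
}

# Sanity-scan a VCF body so malformed files fail with a line number before
# being handed to the parser.
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield < 8L]
  if (length(bad)) stop(sprintf("malformed VCF record at line %d of %s", bad[1], path))
  invisible(length(body))
}

#' Read a per-caller CNV call set from VCF
#'
#' Parses symbolic `<DEL>`/`<DUP>` records, converting the 1-based inclusive
#' POS/END convention to the internal 0-based half-open one. Records of other
#' SV types are skipped and counted; records lacking both INFO/END and
#' INFO/SVLEN are skipped as record-level errors. When END is absent,
#' `END = POS + |SVLEN|`.
#'
#' @param path VCF file.
#' @param caller Caller identifier.
#' @param profile Caller profile (default [default_caller_profile()]).
#' @param sample_id,assembly Labels stored on the result.
#' @return A [cnv_calls()] object; attributes `skipped_type` and
#'   `skipped_malformed` carry skip counts.
#' @export
read_cnv_vcf <- function(path, caller, profile = default_caller_profile(caller),
                         sample_id = "sample", assembly = "GRCh38") {
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  empty <- cnv_calls(caller = caller, sample_id = sample_id, assembly = assembly)
  if (n == 0L) {
    data.table::setattr(empty, "skipped_type", 0L)
    data.table::setattr(empty, "skipped_malformed", 0L)
    return(empty)
  }

  svtype <- suppressWarnings(vcfR::extract.info(v, "SVTYPE"))
  alt_type <- ifelse(fix$ALT == "<DEL>", "DEL",
              ifelse(fix$ALT == "<DUP>", "DUP", NA_character_))
  type <- ifelse(!is.na(alt_type), alt_type,
          ifelse(svtype %in% c("DEL", "DUP"), svtype, NA_character_))

  end1 <- suppressWarnings(vcfR::extract.info(v, "END", as.numeric = TRUE))
  svlen <- suppressWarnings(vcfR::extract.info(v, "SVLEN", as.numeric = TRUE))
  pos <- as.numeric(fix$POS)
  end1[is.na(end1)] <- pos[is.na(end1)] + abs(svlen[is.na(end1)])

  keep_type <- !is.na(type)
  keep_coord <- !is.na(end1)
  skipped_type <- sum(!keep_type)
  skipped_malformed <- sum(keep_type & !keep_coord)
  keep <- keep_type & keep_coord

  gt <- ft <- rep(NA_character_, n)
  if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    gt_key <- profile$format$genotype %||% "GT"
    ft_key <- profile$format$ft %||% "FT"
    g <- suppressWarnings(vcfR::extract.gt(v, element = gt_key))
    if (!is.null(g)) gt <- unname(g[, 1])
    f <- tryCatch(suppressWarnings(vcfR::extract.gt(v, element = ft_key)),
                  error = function(e) NULL)
    if (!is.null(f)) ft <- unname(f[, 1])
  }
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  ft[ft %in% "."] <- NA_character_

  metrics <- list()
  for (m in names(profile$info)) {
    key <- profile$info[[m]]
    metrics[[m]] <- suppressWarnings(vcfR::extract.info(v, key, as.numeric = TRUE))
  }
  fmt_metrics <- setdiff(names(profile$format), c("genotype", "ft"))
  for (m in fmt_metrics) {
    g <- tryCatch(suppressWarnings(
      vcfR::extract.gt(v, element = profile$format[[m]], as.numeric = TRUE)),
      error = function(e) NULL)
    if (!is.null(g)) metrics[[m]] <- unname(g[, 1])
  }

  out <- cnv_calls(
    chrom = fix$CHROM[keep], start = pos[keep] - 1, end = end1[keep],
    type = type[keep], caller = caller, sample_id = sample_id,
    assembly = assembly, genotype = gt[keep], filter = fix$FILTER[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])), ft = ft[keep],
    metrics = lapply(metrics, function(x) x[keep]))
  data.table::setattr(out, "skipped_type", skipped_type)
  data.table::setattr(out, "skipped_malformed", skipped_malformed)
  out
}

#' Read a CNV call set from BED
#'
#' BED coordinates are 0-based half-open and kept as-is. A 4th column, when
#' present, carries the per-record type token (`DEL`/`DUP`); otherwise
#' `default_type` applies to every record. Records with `start >= end` are
#' rejected.
#'
#' @param path BED3/BED4 file.
#' @param default_type Type used when column 4 is absent.
#' @param caller,sample_id,assembly Labels stored on the result.
#' @return A [cnv_calls()] object.
#' @export
read_cnv_bed <- function(path, default_type = NULL, caller = "bed",
                         sample_id = "sample", assembly = "GRCh38") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          skip = "\t")
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path)
  type <- if (ncol(dt) >= 4L && !all(is.na(dt[[4]])) && all(toupper(dt[[4]]) %in% c("DEL", "DUP"))) {
    toupper(dt[[4]])
  } else if (!is.null(default_type)) {
    rep(toupper(default_type), nrow(dt))
  } else {
    stop("BED has no type column and no default_type given: ", path)
  }
  bad <- dt[[2]] >= dt[[3]]
  if (any(bad)) stop(sprintf("BED record with start >= end at row %d", which(bad)[1]))
  cnv_calls(chrom = dt[[1]], start = dt[[2]], end = dt[[3]], type = type,
            caller = caller, sample_id = sample_id, assembly = assembly)
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         sub("\\.?0+$", "", sprintf("%.6f", x)))
}

#' Write a CNV call set
#'
#' Supported formats: `"vcf"` (symbolic alleles, INFO END/SVTYPE/SVLEN plus
#' any non-missing metric keys, FORMAT GT:FT), `"bed"` (BED4 with the type in
#' column 4) and `"tsv"` (full table; lossless round trip). Output is sorted
#' and deterministic: no date line is written, so re-writing identical calls
#' is byte-identical.
#'
#' @param calls A [cnv_calls()] object.
#' @param path Output file.
#' @param format One of `"vcf"`, `"bed"`, `"tsv"`.
#' @param chr_prefix Re-prefix chromosome names with `"chr"` on output.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("vcf", "bed", "tsv"),
                        chr_prefix = FALSE) {
  format <- match.arg(format)
  chrom <- if (chr_prefix) paste0("chr", calls$chrom) else calls$chrom
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s", chrom, calls$start, calls$end, calls$type)
    writeLines(lines, path)
  } else if (format == "tsv") {
    dt <- data.table::as.data.table(calls)
    dt$chrom <- chrom
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=cnvcurate",
      '##ALT=<ID=DEL,Description="Deletion">',
      '##ALT=<ID=DUP,Description="Duplication">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
      '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
      '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">')
    used <- CNV_METRIC_COLS[vapply(CNV_METRIC_COLS,
                                   function(m) any(!is.na(calls[[m]])), logical(1))]
    for (m in used) {
      hdr <- c(hdr, sprintf(
        '##INFO=<ID=%s,Number=1,Type=Float,Description="Caller metric %s">', m, m))
    }
    hdr <- c(hdr,
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=FT,Number=1,Type=String,Description="Genotype filter">',
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", attr(calls, "sample_id") %||% "sample", sep = "\t"))
    body <- character(nrow(calls))
    if (nrow(calls) > 0L) {
      for (i in seq_len(nrow(calls))) {
        r <- calls[i]
        info <- sprintf("END=%d;SVTYPE=%s;SVLEN=%d", r$end, r$type, r$end - r$start)
        for (m in used) {
          if (!is.na(r[[m]])) info <- paste0(info, ";", m, "=", fmt_num(r[[m]]))
        }
        gt <- if (is.na(r$genotype)) "./." else r$genotype
        ft <- if (is.na(r$ft)) "." else r$ft
        body[i] <- paste(chrom[i], r$start + 1L, ".", "N",
                         paste0("<", r$type, ">"),
                         if (is.na(r$qual)) "." else fmt_num(r$qual),
                         if (is.na(r$filter)) "." else r$filter,
                         info, "GT:FT", paste(gt, ft, sep = ":"), sep = "\t")
      }
    }
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read back a TSV written by [write_calls()]
#'
#' @param path TSV file.
#' @param sample_id,assembly Labels stored on the result.
#' @return A [cnv_calls()] object.
#' @export
read_cnv_tsv <- function(path, sample_id = "sample", assembly = "GRCh38") {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  cnv_calls(chrom = dt$chrom, start = dt$start, end = dt$end, type = dt$type,
            caller = dt$caller, sample_id = sample_id, assembly = assembly,
            genotype = dt$genotype, filter = dt$filter, qual = dt$qual,
            ft = dt$ft, metrics = dt[, intersect(CNV_METRIC_COLS, names(dt)),
                                     with = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
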