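# Local annotation resources: gene models with constraint and dosage
# annotations, ClinGen-style dosage regions, curated variants, and population
# CNV frequencies. All tables are plain TSV/BED with a mandatory schema
# version line; interval queries go through GenomicRanges indexes.

SCHEMA_TAG <- "#cnvcurate_schema"
SCHEMA_VERSION <- "1"

GENE_COLS <- c("symbol", "chrom", "start", "end", "strand", "exon_starts",
               "exon_ends", "cds_start", "cds_end", "mane", "family",
               "disease_assoc", "pLI", "oe_upper", "hi_index",
               "clingen_hi", "clingen_ts")
DOSAGE_KINDS <- c("HI_region", "TS_region", "benign_loss_region",
                  "benign_gain_region")

check_schema_line <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, SCHEMA_TAG))
    stop("missing schema version line in ", basename(path))
  ver <- strsplit(first, "[\t ]+")[[1]][2]
  if (!identical(ver, SCHEMA_VERSION))
    stop("unsupported schema version '", ver, "' in ", basename(path))
}

read_schema_tsv <- function(path, required) {
  check_schema_line(path)
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE,
                          na.strings = c("NA", "."))
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop(basename(path), " lacks column(s): ", paste(missing, collapse = ", "))
  dt
}

parse_pos_list <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

make_gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
}

#' Load an annotation resource bundle
#'
#' Reads and validates the four tables of a bundle directory:
#' `genes.tsv` (one transcript per gene: coordinates, exon structure, CDS,
#' MANE flag, gene family, OMIM-derived disease association, gnomAD pLI and
#' o/e upper bound, DECIPHER HI index, ClinGen HI/TS scores),
#' `dosage_regions.bed` (ClinGen-style HI/TS and benign regions),
#' `curated_variants.tsv` (ClinVar-style null and last-exon variants) and
#' `population_cnvs.tsv` (population CNVs with allele frequency and source).
#' Every table starts with a `#cnvcurate_schema 1` version line; coordinates
#' are 0-based half-open.
#'
#' @param bundle_dir Directory holding the four tables.
#' @return A `resource_bundle` object.
#' @export
load_resources <- function(bundle_dir) {
  paths <- file.path(bundle_dir, c("genes.tsv", "dosage_regions.bed",
                                   "curated_variants.tsv",
                                   "population_cnvs.tsv"))
  for (p in paths) if (!file.exists(p))
    stop("resource bundle is missing ", basename(p))

  genes <- read_schema_tsv(paths[1], GENE_COLS)
  genes$chrom <- normalize_chrom(genes$chrom)
  if (anyDuplicated(genes$symbol))
    stop("duplicate gene symbol in genes.tsv: ",
         genes$symbol[duplicated(genes$symbol)][1])
  for (i in seq_len(nrow(genes))) {
    es <- parse_pos_list(genes$exon_starts[i])
    ee <- parse_pos_list(genes$exon_ends[i])
    ok <- length(es) == length(ee) && all(es < ee) &&
      (length(es) < 2L || all(es[-1] >= ee[-length(ee)])) &&
      es[1] >= genes$start[i] && ee[length(ee)] <= genes$end[i]
    if (!ok) stop("malformed exon structure in genes.tsv row ", i)
    if (!is.na(genes$cds_start[i]) &&
        (genes$cds_start[i] < es[1] || genes$cds_end[i] > ee[length(ee)]))
      stop("CDS outside exon span in genes.tsv row ", i)
  }
  bad_pli <- which(!is.na(genes$pLI) & (genes$pLI < 0 | genes$pLI > 1))
  if (length(bad_pli)) stop("pLI out of [0,1] in genes.tsv row ", bad_pli[1])

  check_schema_line(paths[2])
  dosage <- data.table::fread(paths[2], sep = "\t", skip = 1L, header = FALSE,
                              col.names = c("chrom", "start", "end", "kind", "label"))
  dosage$chrom <- normalize_chrom(dosage$chrom)
  bad <- which(!dosage$kind %in% DOSAGE_KINDS)
  if (length(bad)) stop("unknown dosage kind '", dosage$kind[bad[1]],
                        "' in dosage_regions.bed row ", bad[1])

  variants <- read_schema_tsv(paths[3], c("gene", "chrom", "pos", "consequence",
                                          "pathogenicity", "in_last_exon"))
  variants$chrom <- normalize_chrom(variants$chrom)
  vg <- match(variants$gene, genes$symbol)
  if (anyNA(vg)) stop("curated variant references unknown gene: ",
                      variants$gene[which(is.na(vg))[1]])
  outside <- which(variants$pos < genes$start[vg] | variants$pos >= genes$end[vg])
  if (length(outside))
    stop("curated variant outside its gene span, row ", outside[1])

  popcnv <- read_schema_tsv(paths[4], c("chrom", "start", "end", "type", "af",
                                        "source"))
  popcnv$chrom <- normalize_chrom(popcnv$chrom)
  if (nrow(popcnv) && any(popcnv$af < 0 | popcnv$af > 1))
    stop("population CNV allele frequency out of [0,1]")

  structure(list(
    genes = genes,
    gene_gr = make_gr(genes$chrom, genes$start, genes$end),
    dosage = dosage,
    dosage_gr = make_gr(dosage$chrom, dosage$start, dosage$end),
    variants = variants,
    popcnv = popcnv,
    popcnv_gr = make_gr(popcnv$chrom, popcnv$start, popcnv$end)
  ), class = "resource_bundle")
}

#' @export
print.resource_bundle <- function(x, ...) {
  cat(sprintf(paste0("<resource_bundle> %d genes, %d dosage regions, ",
                     "%d curated variants, %d population CNVs\n"),
              nrow(x$genes), nrow(x$dosage), nrow(x$variants), nrow(x$popcnv)))
  invisible(x)
}

# Classify how a CNV overlaps a gene span on genomic coordinates, then map
# the genomic side through strand to the transcript 5'/3' side.
overlap_kind <- function(cnv_start, cnv_end, g_start, g_end, strand) {
  if (cnv_start <= g_start && cnv_end >= g_end) return("complete")
  if (cnv_start > g_start && cnv_end < g_end) return("internal")
  left <- cnv_start <= g_start   # CNV covers the gene's genomic-left end
  if (strand == "+") {
    if (left) "partial_5prime" else "partial_3prime"
  } else {
    if (left) "partial_3prime" else "partial_5prime"
  }
}

#' Genes overlapping an interval
#'
#' @param bundle A `resource_bundle`.
#' @param interval List/table with `chrom`, `start`, `end` (internal
#'   convention).
#' @return `data.table` of overlapping gene rows with an extra
#'   `overlap_kind` column (`complete`, `internal`, `partial_5prime`,
#'   `partial_3prime`).
#' @export
overlapping_genes <- function(bundle, interval) {
  q <- make_gr(normalize_chrom(interval$chrom), interval$start, interval$end)
  hits <- GenomicRanges::findOverlaps(q, bundle$gene_gr)
  idx <- sort(S4Vectors::subjectHits(hits))
  g <- bundle$genes[idx]
  if (nrow(g)) {
    g$overlap_kind <- vapply(seq_len(nrow(g)), function(i)
      overlap_kind(interval$start, interval$end, g$start[i], g$end[i],
                   g$strand[i]), character(1))
  } else {
    g$overlap_kind <- character()
  }
  g
}

#' Gene count with family collapsing
#'
#' Counts protein-coding genes overlapping the interval. A gene family with
#' two or more overlapped members, none of which is disease-associated,
#' contributes a single unit, so that locally duplicated families do not
#' inflate the count; every other gene contributes one.
#'
#' @inheritParams overlapping_genes
#' @return Integer collapsed gene count.
#' @export
count_genes <- function(bundle, interval) {
  g <- overlapping_genes(bundle, interval)
  if (nrow(g) == 0L) return(0L)
  no_fam <- is.na(g$family) | g$family == ""
  n <- sum(no_fam)
  for (fam in unique(g$family[!no_fam])) {
    members <- g[!no_fam & g$family == fam]
    if (nrow(members) >= 2L && !any(members$disease_assoc)) {
      n <- n + 1L
    } else {
      n <- n + nrow(members)
    }
  }
  as.integer(n)
}

#' Predicted haploinsufficiency of a gene
#'
#' A gene is predicted haploinsufficient when its gnomAD pLI is at least
#' 0.9, the upper bound of the observed/expected LoF confidence interval is
#' below 0.35, and its DECIPHER HI index is at most 10 (percent). Missing
#' values make the prediction `FALSE`.
#'
#' @param gene One or more gene rows (with `pLI`, `oe_upper`, `hi_index`).
#' @return Logical vector.
#' @export
predicted_hi <- function(gene) {
  out <- !is.na(gene$pLI) & !is.na(gene$oe_upper) & !is.na(gene$hi_index) &
    gene$pLI >= 0.9 & gene$oe_upper < 0.35 & gene$hi_index <= 10
  out
}

#' Established dosage-sensitive elements hit by a CNV
#'
#' For a deletion, returns ClinGen HI genes (HI score 3), HI regions and
#' benign-loss regions the CNV overlaps; for a duplication, the TS and
#' benign-gain analogues. Each hit reports the fraction of the established
#' element covered by the CNV.
#'
#' @param bundle A `resource_bundle`.
#' @param interval CNV interval (`chrom`, `start`, `end`).
#' @param cnv_type `"DEL"` or `"DUP"`.
#' @return `data.table`: `element` (symbol or region label), `class`
#'   (`gene`, `region`, `benign_region`), `kind`, `chrom`, `start`, `end`,
#'   `fraction` (of the element covered).
#' @export
dosage_hits <- function(bundle, interval, cnv_type) {
  stopifnot(cnv_type %in% c("DEL", "DUP"))
  score_col <- if (cnv_type == "DEL") "clingen_hi" else "clingen_ts"
  region_kind <- if (cnv_type == "DEL") "HI_region" else "TS_region"
  benign_kind <- if (cnv_type == "DEL") "benign_loss_region" else "benign_gain_region"
  chrom <- normalize_chrom(interval$chrom)

  g <- overlapping_genes(bundle, interval)
  g <- g[!is.na(g[[score_col]]) & g[[score_col]] == 3]
  rows <- list()
  if (nrow(g)) {
    o <- overlap_bp(interval$start, interval$end, g$start, g$end)
    rows[[1]] <- data.table::data.table(
      element = g$symbol, class = "gene", kind = score_col,
      chrom = g$chrom, start = g$start, end = g$end,
      fraction = o / (g$end - g$start))
  }
  d <- bundle$dosage[bundle$dosage$chrom == chrom &
                     bundle$dosage$kind %in% c(region_kind, benign_kind)]
  if (nrow(d)) {
    o <- overlap_bp(interval$start, interval$end, d$start, d$end)
    d <- d[o > 0]; o <- o[o > 0]
    if (nrow(d)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        element = d$label,
        class = ifelse(d$kind == benign_kind, "benign_region", "region"),
        kind = d$kind, chrom = d$chrom, start = d$start, end = d$end,
        fraction = o / (d$end - d$start))
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(
      element = character(), class = character(), kind = character(),
      chrom = character(), start = integer(), end = integer(),
      fraction = numeric()))
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, class, element)
  out
}

#' Maximum population allele frequency of a CNV
#'
#' Among population CNVs of the same type with reciprocal overlap of at
#' least `ro_threshold`, returns the maximum allele frequency and its
#' source database.
#'
#' @param bundle A `resource_bundle`.
#' @param cnv List/row with `chrom`, `start`, `end`, `type`.
#' @param ro_threshold Reciprocal-overlap cut-off for a frequency match.
#' @return List `frequency` (numeric or `NA`) and `source` (or `NA`).
#' @export
max_population_frequency <- function(bundle, cnv, ro_threshold = 0.70) {
  p <- bundle$popcnv
  if (nrow(p) == 0L) return(list(frequency = NA_real_, source = NA_character_))
  chrom <- normalize_chrom(cnv$chrom)
  cand <- p[p$chrom == chrom & p$type == cnv$type]
  if (nrow(cand) == 0L) return(list(frequency = NA_real_, source = NA_character_))
  o <- overlap_bp(cnv$start, cnv$end, cand$start, cand$end)
  ro <- pmin(o / (cnv$end - cnv$start), o / (cand$end - cand$start))
  cand <- cand[ro >= ro_threshold]
  if (nrow(cand) == 0L) return(list(frequency = NA_real_, source = NA_character_))
  best <- which.max(cand$af)
  list(frequency = cand$af[best], source = cand$source[best])
}
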