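# Synthetic fixtures: caller VCFs with threshold-straddling records,
# a toy annotation bundle, and clustering scenarios — each paired with
# expected outputs computed by the naive oracles in oracles.R, never by the
# modules under test. The toy genome is 2 chromosomes of 10 Mb, small
# enough that every test is sub-second.

# Minimal VCF text writer used only by the generator, kept independent of
# the package's own write_calls().
fixture_vcf_text <- function(records, sample = "FIX") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cnvcurate-fixtures",
           '##ALT=<ID=DEL,Description="Deletion">',
           '##ALT=<ID=DUP,Description="Duplication">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length">')
  keys <- unique(unlist(lapply(records, function(r) names(r$info))))
  for (k in keys) hdr <- c(hdr, sprintf(
    '##INFO=<ID=%s,Number=1,Type=Float,Description="metric">', k))
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=FT,Number=1,Type=String,Description="Genotype filter">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- vapply(records, function(r) {
    info <- sprintf("END=%d;SVTYPE=%s;SVLEN=%d", r$end1, r$type,
                    r$end1 - r$pos1 + 1L)
    for (k in names(r$info))
      info <- paste0(info, ";", k, "=", format(r$info[[k]], scientific = FALSE))
    paste(r$chrom, r$pos1, r$id, "N", paste0("<", r$type, ">"),
          r$qual %||% ".", r$filter %||% "PASS", info,
          "GT:FT", paste(r$gt %||% "0/1", r$ft %||% "PASS", sep = ":"),
          sep = "\t")
  }, character(1))
  c(hdr, body)
}

# Allocate non-overlapping fixture intervals along chromosome 1.
fixture_slots <- function(n, len = 1000L, gap = 10000L, offset = 100000L) {
  starts <- offset + (seq_len(n) - 1L) * (len + gap)
  data.table::data.table(pos1 = starts + 1L, end1 = starts + len)
}

#' Generate per-caller fixture VCFs with known filter outcomes
#'
#' For every caller with a confidence rule, writes a VCF whose records sit
#' below, at, and above each published threshold (boundaries included), plus
#' an `expected_filters.tsv` table giving the kept/removed outcome of each
#' record as computed by the literal rule oracle [oracle_filter_kept()].
#'
#' @param out_dir Output directory.
#' @param seed Seed (fixes record order; regeneration is byte-identical).
#' @return Invisibly, the expected-outcome `data.table` (`caller`, `id`,
#'   `type`, `kept`).
#' @export
generate_caller_vcfs <- function(out_dir, seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list()
  add <- function(caller, type = "DEL", info = list(), qual = NULL,
                  filter = "PASS", gt = "0/1", ft = "PASS") {
    specs[[length(specs) + 1L]] <<- list(caller = caller, type = type,
                                         info = info, qual = qual,
                                         filter = filter, gt = gt, ft = ft)
  }
  for (p1 in c(0.04, 0.05, 0.06)) for (rd in c(0.5, 0.75, 1.0, 1.25, 1.3))
    add("cnvpytor", info = list(pytorP1 = p1, Q0 = 0.2, pytorRD = rd))
  for (q0 in c(0.85, 0.9, 0.95))
    add("cnvpytor", info = list(pytorP1 = 0.01, Q0 = q0, pytorRD = 0.4))
  for (w in c(0.04, 0.05, 0.06)) for (ks in c(0.04, 0.05, 0.06))
    add("controlfreec", info = list(W = w, KS = ks))
  for (f in c("PASS", "LowQual")) for (ftv in c("PASS", "LowGQ"))
    for (g in c("0/1", "0/0", "1/1"))
      add("delly", filter = f, ft = ftv, gt = g)
  for (q in c(100, 119, 120, 121, 500)) add("lumpy", qual = q)
  for (cw in c(0.19, 0.2, 0.3)) for (tf in c(2, 3, 4))
    add("wham", type = "DEL", info = list(max_CW = cw, TF = tf))
  for (u in c(1, 2, 3))
    add("wham", type = "DUP", info = list(max_CW = 0.3, U = u))
  for (f in c("PASS", "NO_ASSEMBLY", "NO_ASSEMBLY;PASS", "LowQual"))
    add("gridss", filter = f)
  for (bf in c(14, 15, 16)) for (rr in c(0.7, 0.8, 0.9))
    add("exomedepth", type = "DEL", info = list(BF = bf, reads_ratio = rr))
  for (rr in c(1.0, 1.1, 1.2))
    add("exomedepth", type = "DUP", info = list(BF = 20, reads_ratio = rr))
  for (nt in c(1, 10, 40, 70, 150)) for (cn in c(0, 1)) {
    thr <- min(1000, max(if (cn == 0) 400 else 100, 10 * nt))
    for (qs in c(thr - 1, thr, thr + 1))
      add("gatk4", type = "DEL", info = list(QS = qs, CN = cn, nt = nt))
  }
  for (nt in c(1, 10, 40, 70, 150, 200)) {
    thr <- min(400, max(50, 4 * nt))
    for (qs in c(thr - 1, thr, thr + 1))
      add("gatk4", type = "DUP", info = list(QS = qs, CN = 3, nt = nt))
  }

  callers <- unique(vapply(specs, function(s) s$caller, character(1)))
  expected <- list()
  for (cl in callers) {
    recs <- Filter(function(s) s$caller == cl, specs)
    slots <- fixture_slots(length(recs))
    vcf_recs <- lapply(seq_along(recs), function(i) {
      s <- recs[[i]]
      list(chrom = "1", pos1 = slots$pos1[i], end1 = slots$end1[i],
           id = sprintf("%s_%03d", cl, i), type = s$type, info = s$info,
           qual = s$qual, filter = s$filter, gt = s$gt, ft = s$ft)
    })
    writeLines(fixture_vcf_text(vcf_recs),
               file.path(out_dir, paste0(cl, ".vcf")))
    kept <- vapply(seq_along(recs), function(i) {
      s <- recs[[i]]
      x <- c(s$info, list(type = s$type, qual = s$qual, filter = s$filter,
                          gt = s$gt, ft = s$ft, genotype = s$gt))
      oracle_filter_kept(cl, x)
    }, logical(1))
    expected[[cl]] <- data.table::data.table(
      caller = cl, id = sprintf("%s_%03d", cl, seq_along(recs)),
      type = vapply(recs, function(s) s$type, character(1)), kept = kept)
  }
  exp_dt <- data.table::rbindlist(expected)
  data.table::fwrite(exp_dt, file.path(out_dir, "expected_filters.tsv"),
                     sep = "\t")
  invisible(exp_dt)
}

fixture_gene_row <- function(symbol, chrom, start, end, strand = "+",
                             exon_starts, exon_ends, cds_start = NA,
                             cds_end = NA, mane = TRUE, family = NA,
                             disease = FALSE, pLI = NA, oe = NA, hi = NA,
                             chi = NA, cts = NA) {
  data.table::data.table(
    symbol = symbol, chrom = chrom, start = start, end = end, strand = strand,
    exon_starts = paste(exon_starts, collapse = ","),
    exon_ends = paste(exon_ends, collapse = ","),
    cds_start = cds_start, cds_end = cds_end, mane = mane, family = family,
    disease_assoc = disease, pLI = pLI, oe_upper = oe, hi_index = hi,
    clingen_hi = chi, clingen_ts = cts)
}

# A simple multi-exon gene: n_exon exons of exon_len bp spaced 4 kb apart.
simple_gene <- function(symbol, chrom, start, n_exon = 3L, exon_len = 500L,
                        ...) {
  es <- start + (seq_len(n_exon) - 1L) * 4000L
  ee <- es + exon_len
  fixture_gene_row(symbol, chrom, start, ee[n_exon], exon_starts = es,
                   exon_ends = ee, cds_start = es[1] + 100L,
                   cds_end = ee[n_exon] - 100L, ...)
}

#' Generate the toy annotation resource bundle
#'
#' Writes a bundle with roughly 30 genes on a 2 x 10 Mb toy genome:
#' established HI and TS genes with full exon/CDS models and curated null
#' variants, a gene whose last exon carries a pathogenic variant, gene
#' families with and without a disease-associated member, eight genes at the
#' corners of the predicted-HI cut-offs (pLI 0.9, o/e upper 0.35, HI index
#' 10), HI/TS and benign dosage regions, and population CNVs at allele
#' frequencies 0.0001, 0.001, 0.02, 0.03 and 0.05. Returns hand-traceable
#' expected answers computed by the naive oracles.
#'
#' @param out_dir Bundle directory to create.
#' @param seed Seed (generation is deterministic given the seed).
#' @return Invisibly, a list of expected answers (`phi_truth`,
#'   `family_counts`, `toy_cnvs`).
#' @export
generate_resource_bundle <- function(out_dir, seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- list()
  # Established HI gene, LoF disease mechanism (curated null variants below).
  genes[[1]] <- fixture_gene_row(
    "HIGENE1", "1", 1000000L, 1016500L, "+",
    exon_starts = c(1000000L, 1004000L, 1008000L, 1012000L, 1016000L),
    exon_ends = c(1000500L, 1004500L, 1008500L, 1012500L, 1016500L),
    cds_start = 1000100L, cds_end = 1016400L, disease = TRUE,
    pLI = 0.99, oe = 0.10, hi = 2, chi = 3)
  # Second HI gene with a 99 bp (in-frame) internal exon, no curated
  # variants: exercises the in-frame / <=10% branch of the LoF tree.
  genes[[2]] <- fixture_gene_row(
    "HIGENE2", "1", 1100000L, 1116500L, "+",
    exon_starts = c(1100000L, 1104000L, 1108000L, 1112000L, 1116000L),
    exon_ends = c(1100500L, 1104099L, 1108500L, 1112500L, 1116500L),
    cds_start = 1100100L, cds_end = 1116400L, disease = TRUE,
    pLI = 0.98, oe = 0.12, hi = 3, chi = 3)
  # Ordinary gene with no dosage or constraint annotation (VUS fixture).
  genes[[3]] <- simple_gene("GENE1", "1", 2000000L, n_exon = 2L)
  genes[[3]]$end <- 2010000L
  # Families: FAMA has no disease member (collapses), FAMB has one.
  for (i in 1:3) genes[[length(genes) + 1L]] <-
    simple_gene(paste0("FAMA", i), "1", 3000000L + (i - 1L) * 15000L,
                family = "FAMA")
  for (i in 1:3) genes[[length(genes) + 1L]] <-
    simple_gene(paste0("FAMB", i), "1", 3100000L + (i - 1L) * 15000L,
                family = "FAMB", disease = (i == 2L))
  # Predicted-HI corner genes: all 8 combinations around the cut-offs.
  corners <- expand.grid(pLI = c(0.89, 0.9), oe = c(0.34, 0.35),
                         hi = c(10, 11))
  for (i in seq_len(nrow(corners))) genes[[length(genes) + 1L]] <-
    simple_gene(paste0("PHI", i), "1", 4000000L + (i - 1L) * 100000L,
                pLI = corners$pLI[i], oe = corners$oe[i], hi = corners$hi[i])
  # HI gene whose last exon carries an established pathogenic variant.
  genes[[length(genes) + 1L]] <- simple_gene("LEGENE", "1", 5000000L,
                                             n_exon = 4L, disease = TRUE,
                                             chi = 3)
  # Established TS gene on chromosome 2.
  genes[[length(genes) + 1L]] <- simple_gene("TSGENE1", "2", 1000000L,
                                             n_exon = 4L, disease = TRUE,
                                             cts = 3)
  genes[[length(genes)]]$end <- 1020000L
  # Genes inside the benign regions.
  genes[[length(genes) + 1L]] <- simple_gene("BGG1", "2", 2045000L)
  genes[[length(genes) + 1L]] <- simple_gene("BGG2", "2", 2070000L)
  genes[[length(genes) + 1L]] <- simple_gene("BLG1", "2", 3040000L)
  # Disease gene for breakpoint-in-gene duplication cases.
  genes[[length(genes) + 1L]] <- simple_gene("DISG1", "2", 5000000L,
                                             disease = TRUE)
  # Gene just outside the benign loss region (benign-overlap-plus-genes case).
  genes[[length(genes) + 1L]] <- simple_gene("BLEDGE", "2", 3110000L)
  # Dense block of 60 unannotated genes for the gene-count bands.
  for (i in 1:60) genes[[length(genes) + 1L]] <-
    simple_gene(sprintf("DENSE%02d", i), "2", 6000000L + (i - 1L) * 20000L)
  gene_dt <- data.table::rbindlist(genes)
  data.table::setorder(gene_dt, chrom, start)

  dosage <- data.table::data.table(
    chrom = c("1", "2", "2", "2"),
    start = c(6000000L, 4000000L, 2000000L, 3000000L),
    end = c(6050000L, 4050000L, 2100000L, 3100000L),
    kind = c("HI_region", "TS_region", "benign_gain_region",
             "benign_loss_region"),
    label = c("HIREG1", "TSREG1", "BENGAIN1", "BENLOSS1"))
  data.table::setorder(dosage, chrom, start)

  variants <- data.table::data.table(
    gene = c("HIGENE1", "HIGENE1", "HIGENE1", "LEGENE", "GENE1"),
    chrom = c("1", "1", "1", "1", "1"),
    pos = c(1004100L, 1008200L, 1012300L, 5012200L, 2004100L),
    consequence = c("nonsense", "frameshift", "splicing", "nonsense",
                    "other"),
    pathogenicity = c("pathogenic", "pathogenic", "pathogenic",
                      "pathogenic", "benign"),
    in_last_exon = c(FALSE, FALSE, FALSE, TRUE, FALSE))

  popcnv <- data.table::data.table(
    chrom = c("2", "1", "1", "1", "1"),
    start = c(2040000L, 2000000L, 7000000L, 7000050L, 7000100L),
    end = c(2060000L, 2010000L, 7010000L, 7010050L, 7010100L),
    type = c("DUP", "DEL", "DEL", "DEL", "DEL"),
    af = c(0.05, 0.001, 0.02, 0.03, 0.0001),
    source = c("gnomAD_controls", "DGV", "gnomAD_controls", "DECIPHER",
               "DECIPHER"))

  write_schema_table <- function(dt, path, header = TRUE) {
    tmp <- tempfile()
    data.table::fwrite(dt, tmp, sep = "\t", col.names = header, na = "NA",
                       quote = FALSE)
    writeLines(c(paste(SCHEMA_TAG, SCHEMA_VERSION, sep = "\t"),
                 readLines(tmp)), path)
    unlink(tmp)
  }
  write_schema_table(gene_dt, file.path(out_dir, "genes.tsv"))
  write_schema_table(dosage, file.path(out_dir, "dosage_regions.bed"),
                     header = FALSE)
  write_schema_table(variants, file.path(out_dir, "curated_variants.tsv"))
  write_schema_table(popcnv, file.path(out_dir, "population_cnvs.tsv"))

  # Expected answers, computed by literal transcription (not the modules).
  phi_truth <- data.table::data.table(
    symbol = paste0("PHI", seq_len(nrow(corners))),
    pLI = corners$pLI, oe_upper = corners$oe, hi_index = corners$hi,
    expected = corners$pLI >= 0.9 & corners$oe < 0.35 & corners$hi <= 10)
  family_counts <- list(
    fama_only = list(interval = list(chrom = "1", start = 3000000L,
                                     end = 3040000L), expected = 1L),
    famb_only = list(interval = list(chrom = "1", start = 3100000L,
                                     end = 3140000L), expected = 3L),
    no_family = list(interval = list(chrom = "1", start = 4000000L,
                                     end = 4250000L), expected = 3L))
  toy_cnvs <- data.table::data.table(
    name = c("pathogenic_del", "benign_dup", "vus_del"),
    chrom = c("1", "2", "1"),
    start = c(995000L, 2040000L, 2000000L),
    end = c(1025000L, 2060000L, 2010000L),
    type = c("DEL", "DUP", "DEL"),
    expected_total = c(1.0, -2.0, 0.0),
    expected_category = c("Pathogenic", "Benign", "VUS"))
  ans <- list(phi_truth = phi_truth, family_counts = family_counts,
              toy_cnvs = toy_cnvs)
  data.table::fwrite(toy_cnvs, file.path(out_dir, "expected_toy_cnvs.tsv"),
                     sep = "\t")
  invisible(ans)
}

#' Generate randomized clustering scenarios with oracle partitions
#'
#' Each scenario plants 1-4 well-separated consensus CNVs and perturbs the
#' breakpoints per caller: perturbations within 20% of the length stay
#' mergeable under the default 0.5 breakpoint-distance fraction, and a
#' fraction of calls are displaced beyond it to seed singletons. The
#' expected partition comes from the transitive-closure oracle
#' [oracle_cluster_ids()].
#'
#' @param seed Seed.
#' @param n_scenarios Number of scenarios.
#' @param platform_class See [size_bins()].
#' @return List of scenarios, each a list with `calls` (a `data.table`) and
#'   `expected` (oracle cluster ids).
#' @export
generate_cluster_scenarios <- function(seed = 1L, n_scenarios = 20L,
                                       platform_class = "WGS_LRS") {
  set.seed(seed)
  callers <- c("cnvpytor", "delly", "lumpy", "wham", "manta")
  lens <- c(120L, 800L, 20000L, 150000L)
  out <- vector("list", n_scenarios)
  for (s in seq_len(n_scenarios)) {
    k <- sample(1:4, 1)
    rows <- list()
    for (i in seq_len(k)) {
      chrom <- sample(c("1", "2"), 1)
      base <- 1000000L + i * 3000000L
      len <- sample(lens, 1)
      type <- sample(c("DEL", "DUP"), 1)
      ncall <- sample(1:4, 1)
      cls <- sample(callers, ncall)
      for (j in seq_len(ncall)) {
        far <- stats::runif(1) < 0.2 && j > 1L
        f <- if (far) stats::runif(1, 0.8, 1.2) else stats::runif(1, -0.15, 0.15)
        off <- as.integer(round(f * len))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = chrom, start = base + off, end = base + len + off,
          type = type, caller = cls[j])
      }
    }
    calls <- data.table::rbindlist(rows)
    out[[s]] <- list(calls = calls,
                     expected = oracle_cluster_ids(calls, 0.5, platform_class))
  }
  out
}

#' The three hand-traced end-to-end CNV fixtures
#'
#' A full deletion of an established HI gene (Pathogenic, +1.0), a common
#' duplication contained in a benign gain region (Benign, -2.0), and a
#' deletion of a single unremarkable gene (VUS, 0), matching the toy bundle
#' written by [generate_resource_bundle()].
#'
#' @return `data.table` of the three CNVs with `expected_total` and
#'   `expected_category`.
#' @export
toy_cnv_fixtures <- function() {
  data.table::data.table(
    name = c("pathogenic_del", "benign_dup", "vus_del"),
    chrom = c("1", "2", "1"),
    start = c(995000L, 2040000L, 2000000L),
    end = c(1025000L, 2060000L, 2010000L),
    type = c("DEL", "DUP", "DEL"),
    expected_total = c(1.0, -2.0, 0.0),
    expected_category = c("Pathogenic", "Benign", "VUS"))
}
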