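# Semiquantitative ACMG/ClinGen scoring of CNVs. Evidence criteria, their
# point weights and the classification bands are data (inst/extdata/
# rubric.yaml); this file implements the decision logic that picks which
# criteria fire for a given CNV against the loaded annotation resources.

#' Read a scoring rubric
#'
#' @param path Rubric YAML (criterion ids with section, applicability,
#'   default/min/max points; classification bands; gene-count bands;
#'   LoF-strength point map).
#' @return A `rubric` list.
#' @export
read_rubric <- function(path) {
  r <- yaml::read_yaml(path)
  stopifnot(!is.null(r$criteria), !is.null(r$bands))
  for (arm in c("loss", "gain")) {
    secs <- sort(unique(vapply(
      Filter(function(cr) cr$applies %in% c(arm, "both"), r$criteria),
      function(cr) as.integer(cr$section), integer(1))))
    if (!all(1:5 %in% secs))
      stop("rubric lacks section(s) for the ", arm, " arm")
  }
  for (id in names(r$criteria)) {
    cr <- r$criteria[[id]]
    if (cr$default < cr$min || cr$default > cr$max)
      stop("rubric criterion ", id, ": default outside [min,max]")
  }
  class(r) <- "rubric"
  r
}

#' The shipped default rubric
#'
#' @return A `rubric` list (see [read_rubric()]).
#' @export
default_rubric <- function() {
  read_rubric(system.file("extdata", "rubric.yaml", package = "cnvcurate"))
}

# One evidence item; points default to the rubric's default for the id.
evidence_item <- function(rubric, id, points = NULL, rationale = "",
                          auto = TRUE) {
  cr <- rubric$criteria[[id]]
  if (is.null(cr)) stop("unknown rubric criterion: ", id)
  if (is.null(points)) points <- cr$default
  if (points < cr$min - 1e-9 || points > cr$max + 1e-9)
    stop(sprintf("points %.2f outside rubric range [%.2f, %.2f] for %s",
                 points, cr$min, cr$max, id))
  data.table::data.table(criterion = id, points = as.numeric(points),
                         section = as.integer(cr$section),
                         rationale = rationale, auto = auto)
}

empty_evidence <- function() {
  data.table::data.table(criterion = character(), points = numeric(),
                         section = integer(), rationale = character(),
                         auto = logical())
}

#' Section 1: genomic content
#'
#' Fires 1A (continue scoring) when the CNV overlaps at least one
#' protein-coding gene or an established dosage-sensitive region, and 1B
#' otherwise; a 1B call skips the dosage and gene-count sections.
#'
#' @param cnv List/row with `chrom`, `start`, `end`, `type`.
#' @param bundle A `resource_bundle`.
#' @param rubric A `rubric`.
#' @return One-row evidence table.
#' @export
evaluate_section1 <- function(cnv, bundle, rubric = default_rubric()) {
  pre <- if (cnv$type == "DEL") "L" else "G"
  genes <- overlapping_genes(bundle, cnv)
  hits <- dosage_hits(bundle, cnv, cnv$type)
  important <- nrow(genes) > 0L || any(hits$class %in% c("gene", "region"))
  if (important) {
    evidence_item(rubric, paste0(pre, "1A"),
                  rationale = sprintf("%d protein-coding gene(s), %d dosage element(s)",
                                      nrow(genes), sum(hits$class != "benign_region")))
  } else {
    evidence_item(rubric, paste0(pre, "1B"),
                  rationale = "no protein-coding genes or functionally important elements")
  }
}

# Pick the established-element evidence for a deletion. Priority: complete
# overlap of an HI element, then partial overlaps (5'/3'/intragenic), then
# benign-region containment, then predicted HI.
#' Section 2 for copy-number losses
#'
#' Evaluates established haploinsufficient genes/regions, benign loss
#' regions, and predicted haploinsufficiency, in that priority order.
#' Intragenic deletions of an HI gene are routed through
#' [assess_pvs1_loss()].
#'
#' @inheritParams evaluate_section1
#' @return Evidence table (zero or one row).
#' @export
evaluate_section2_loss <- function(cnv, bundle, rubric = default_rubric()) {
  stopifnot(cnv$type == "DEL")
  hits <- dosage_hits(bundle, cnv, "DEL")
  genes <- overlapping_genes(bundle, cnv)
  est <- hits[hits$class %in% c("gene", "region")]
  benign <- hits[hits$class == "benign_region"]

  if (nrow(est)) {
    conflict <- if (nrow(benign))
      "; note: also overlaps a benign loss region (established HI takes priority)" else ""
    full <- est[est$fraction >= 1]
    if (nrow(full)) {
      return(evidence_item(rubric, "L2A",
        rationale = paste0("complete overlap of established HI element(s): ",
                           paste(full$element, collapse = ", "), conflict)))
    }
    part <- est[1]
    if (part$class == "region") {
      return(evidence_item(rubric, "L2B",
        rationale = paste0("partial overlap of established HI region ",
                           part$element, conflict)))
    }
    g <- genes[genes$symbol == part$element][1]
    kind <- g$overlap_kind
    if (kind == "internal") {
      pvs1 <- assess_pvs1_loss(cnv, g, bundle)
      pts <- rubric$pvs1_points[[pvs1$strength]]
      return(evidence_item(rubric, "L2E", points = pts,
        rationale = sprintf("intragenic deletion in HI gene %s; LoF strength %s (%s)%s",
                            g$symbol, pvs1$strength,
                            paste(pvs1$path, collapse = " > "), conflict)))
    }
    if (kind == "partial_5prime") {
      coding <- !is.na(g$cds_start) &&
        overlap_bp(cnv$start, cnv$end, g$cds_start, g$cds_end) > 0
      return(evidence_item(rubric, "L2C",
        points = if (coding) 0.90 else 0,
        rationale = sprintf("5' partial overlap of HI gene %s (%scoding sequence involved)%s",
                            g$symbol, if (coding) "" else "no ", conflict)))
    }
    # 3' partial overlap: weight depends on last-exon involvement and
    # curated pathogenic variants there
    d3 <- pvs1_3prime_weight(cnv, g, bundle)
    return(evidence_item(rubric, "L2D", points = d3$points,
      rationale = paste0("3' partial overlap of HI gene ", g$symbol, "; ",
                         d3$why, conflict)))
  }

  if (nrow(benign)) {
    reg <- benign[which.max(benign$fraction)]
    contained <- cnv$start >= reg$start && cnv$end <= reg$end
    extra <- genes[!(genes$start >= reg$start & genes$end <= reg$end)]
    if (contained) {
      return(evidence_item(rubric, "L2F",
        rationale = paste0("contained within established benign loss region ",
                           reg$element)))
    }
    if (nrow(extra)) {
      return(evidence_item(rubric, "L2G",
        rationale = sprintf("overlaps benign loss region %s but includes %d additional gene(s)",
                            reg$element, nrow(extra))))
    }
    return(evidence_item(rubric, "L2F",
      rationale = paste0("covered by established benign loss region ",
                         reg$element, " (no additional genes)")))
  }

  if (nrow(genes) && any(predicted_hi(genes))) {
    hi <- genes$symbol[predicted_hi(genes)]
    return(evidence_item(rubric, "L2H",
      rationale = paste0("predicted HI gene(s): ", paste(hi, collapse = ", "))))
  }
  empty_evidence()
}

# Transcript-direction exon bookkeeping for the LoF tree.
exon_model <- function(gene) {
  es <- parse_pos_list(gene$exon_starts)
  ee <- parse_pos_list(gene$exon_ends)
  ord <- if (gene$strand == "+") order(es) else order(-es)
  list(starts = es[ord], ends = ee[ord], strand = gene$strand,
       cds_start = gene$cds_start, cds_end = gene$cds_end)
}

# Coding bases of each exon (transcript order) and of the CNV overlap.
coding_overlap <- function(em, cnv_start, cnv_end) {
  cs <- pmax(em$starts, em$cds_start)
  ce <- pmin(em$ends, em$cds_end)
  coding_len <- pmax(0L, ce - cs)
  del <- overlap_bp(cnv_start, cnv_end, cs, ce)
  del[coding_len == 0L] <- 0L
  list(coding_len = coding_len, deleted = del)
}

#' Loss-of-function assessment of an intragenic deletion
#'
#' Walks a decision tree over the gene's exon model: (i) does the deletion
#' remove coding bases; (ii) does the removal shift the reading frame
#' (deleted coding bases not a multiple of 3); (iii) is the resulting
#' premature termination predicted to trigger nonsense-mediated decay (the
#' first affected coding base lies upstream of the last exon-exon junction
#' minus 50 nt, in transcript coordinates); (iv) for NMD-escaping or
#' in-frame removals, strength steps down with the fraction of protein
#' removed (>10% strong, otherwise moderate), upgraded to strong when
#' curated pathogenic variants lie in or downstream of the removed region
#' (including last-exon pathogenic variants). Full (very strong) weight
#' requires an NMD-competent frameshift in a gene whose disease mechanism is
#' loss of function (disease-associated with curated null variants).
#'
#' @param cnv CNV row (`chrom`, `start`, `end`).
#' @param gene One gene row from the resource bundle.
#' @param bundle A `resource_bundle`.
#' @return List `strength` (`very_strong`, `strong`, `moderate`,
#'   `supporting`, `none`) and `path` (trace of tree nodes).
#' @export
assess_pvs1_loss <- function(cnv, gene, bundle) {
  if (is.na(gene$cds_start) || is.na(gene$cds_end))
    return(list(strength = "none", path = "no_cds_annotation"))
  em <- exon_model(gene)
  co <- coding_overlap(em, cnv$start, cnv$end)
  total_cds <- sum(co$coding_len)
  removed <- sum(co$deleted)
  if (removed == 0L)
    return(list(strength = "none", path = "no_coding_exon_loss"))
  path <- "coding_exons_removed"

  sym <- gene$symbol
  vars <- bundle$variants[bundle$variants$gene == sym]
  nullvars <- vars[vars$consequence %in% c("nonsense", "frameshift", "splicing") &
                   vars$pathogenicity == "pathogenic"]
  lof_mechanism <- isTRUE(gene$disease_assoc) && nrow(nullvars) > 0L

  frameshift <- (removed %% 3L) != 0L
  # transcript (CDS) coordinate of the last exon-exon junction and of the
  # first affected coding base
  ncod <- co$coding_len
  cum <- cumsum(ncod)
  last_junction <- if (length(ncod) >= 2L) cum[length(ncod) - 1L] else 0L
  affected <- which(co$deleted > 0L)
  first_ex <- affected[1]
  before <- if (first_ex > 1L) cum[first_ex - 1L] else 0L
  cs <- max(em$starts[first_ex], em$cds_start)
  ce <- min(em$ends[first_ex], em$cds_end)
  within <- if (em$strand == "+") max(0L, cnv$start - cs) else max(0L, ce - cnv$end)
  first_affected_cds <- before + within

  if (frameshift) {
    path <- c(path, "frameshift")
    nmd <- last_junction > 0L && first_affected_cds < (last_junction - 50L)
    if (nmd) {
      path <- c(path, "nmd_competent")
      if (lof_mechanism)
        return(list(strength = "very_strong", path = c(path, "lof_mechanism")))
      return(list(strength = "strong", path = c(path, "lof_mechanism_unproven")))
    }
    path <- c(path, "nmd_escape")
  } else {
    path <- c(path, "in_frame")
  }

  # altered region in genomic coordinates: the deletion itself when
  # in-frame; on a frameshift everything downstream to the transcript end
  # is altered, and last-exon pathogenic variants also count
  if (frameshift) {
    region_start <- if (em$strand == "+") cnv$start else gene$start
    region_end <- if (em$strand == "+") gene$end else cnv$end
    pathvars <- vars[vars$pathogenicity == "pathogenic" &
                     (vars$in_last_exon |
                      (vars$pos >= region_start & vars$pos < region_end))]
  } else {
    pathvars <- vars[vars$pathogenicity == "pathogenic" &
                     vars$pos >= cnv$start & vars$pos < cnv$end]
  }
  if (nrow(pathvars)) {
    return(list(strength = "strong",
                path = c(path, "pathogenic_variants_in_altered_region")))
  }
  frac <- removed / total_cds
  if (frac > 0.10)
    return(list(strength = "strong", path = c(path, "gt10pct_protein_removed")))
  list(strength = "moderate", path = c(path, "le10pct_protein_removed"))
}

# 3' partial-overlap weighting: only 3'UTR -> 0; last coding exon involved
# with curated pathogenic variants there -> 0.90; other exons too -> 0.90;
# last exon only, no such variants -> 0.30.
pvs1_3prime_weight <- function(cnv, gene, bundle) {
  if (is.na(gene$cds_start))
    return(list(points = 0, why = "no CDS annotation"))
  em <- exon_model(gene)
  co <- coding_overlap(em, cnv$start, cnv$end)
  if (sum(co$deleted) == 0L)
    return(list(points = 0, why = "only 3' UTR involved"))
  affected <- which(co$deleted > 0L)
  nexon <- length(em$starts)
  last_only <- identical(affected, nexon)
  sym <- gene$symbol
  vars <- bundle$variants[bundle$variants$gene == sym]
  last_path <- vars[vars$in_last_exon & vars$pathogenicity == "pathogenic"]
  if (!last_only)
    return(list(points = 0.90, why = "coding exons beyond the last exon removed"))
  if (nrow(last_path))
    return(list(points = 0.90,
                why = "last exon removed; established pathogenic variants in last exon"))
  list(points = 0.30, why = "last exon removed; no established pathogenic variants there")
}

#' Section 2 for copy-number gains
#'
#' Mirrors the loss arm over triplosensitive and benign-gain elements:
#' complete overlap of an established TS gene/region scores +1.0, strict
#' containment in a benign gain region -1.0, partial TS overlap 0.
#' Intragenic and breakpoint-in-gene duplications take conservative
#' 0-point criteria because tandem status and insertion site are unknown
#' from a call set alone.
#'
#' @inheritParams evaluate_section1
#' @return Evidence table (zero or one row).
#' @export
evaluate_section2_gain <- function(cnv, bundle, rubric = default_rubric()) {
  stopifnot(cnv$type == "DUP")
  hits <- dosage_hits(bundle, cnv, "DUP")
  genes <- overlapping_genes(bundle, cnv)
  est <- hits[hits$class %in% c("gene", "region")]
  benign <- hits[hits$class == "benign_region"]

  if (nrow(est)) {
    full <- est[est$fraction >= 1]
    if (nrow(full)) {
      return(evidence_item(rubric, "G2A",
        rationale = paste0("complete overlap of established TS element(s): ",
                           paste(full$element, collapse = ", "))))
    }
    return(evidence_item(rubric, "G2B",
      rationale = paste0("partial overlap of established TS element ",
                         est$element[1])))
  }
  if (nrow(benign)) {
    reg <- benign[which.max(benign$fraction)]
    contained <- cnv$start >= reg$start && cnv$end <= reg$end
    extra <- genes[!(genes$start >= reg$start & genes$end <= reg$end)]
    if (contained) {
      return(evidence_item(rubric, "G2C",
        rationale = paste0("contained within established benign gain region ",
                           reg$element)))
    }
    if (nrow(extra)) {
      return(evidence_item(rubric, "G2D",
        rationale = sprintf("overlaps benign gain region %s but includes %d additional gene(s)",
                            reg$element, nrow(extra))))
    }
    return(evidence_item(rubric, "G2C",
      rationale = paste0("covered by established benign gain region ",
                         reg$element, " (no additional genes)")))
  }
  internal <- genes[genes$overlap_kind == "internal"]
  if (nrow(internal)) {
    return(evidence_item(rubric, "G2I", points = 0,
      rationale = paste0("intragenic duplication of ", internal$symbol[1],
                         "; tandem status and reading frame unknown")))
  }
  brk <- genes[genes$overlap_kind %in% c("partial_5prime", "partial_3prime") &
               genes$disease_assoc]
  if (nrow(brk)) {
    return(evidence_item(rubric, "G2L",
      rationale = paste0("one breakpoint within disease-associated gene ",
                         brk$symbol[1], "; insertion site unknown")))
  }
  empty_evidence()
}

#' Section 3: gene count
#'
#' Applies the rubric's gene-count bands to the family-collapsed count of
#' protein-coding genes ([count_genes()]): losses score 0 / +0.45 / +0.90 at
#' 0-24 / 25-34 / >=35 genes, gains at 0-34 / 35-49 / >=50.
#'
#' @inheritParams evaluate_section1
#' @return One-row evidence table.
#' @export
evaluate_section3 <- function(cnv, bundle, rubric = default_rubric()) {
  n <- count_genes(bundle, cnv)
  arm <- if (cnv$type == "DEL") "loss" else "gain"
  pre <- if (cnv$type == "DEL") "L" else "G"
  b <- rubric$gene_count_bands[[arm]]
  id <- if (n >= b$high) paste0(pre, "3C")
        else if (n >= b$mid) paste0(pre, "3B")
        else paste0(pre, "3A")
  evidence_item(rubric, id,
                rationale = sprintf("%d protein-coding gene(s) after family collapsing", n))
}

#' Section 4: population frequency
#'
#' Fires the common-variation criterion (-1.0) when the CNV matches a
#' population CNV of the same type at reciprocal overlap >= `ro_threshold`
#' with allele frequency >= `af_threshold`. All other Section 4 criteria are
#' user-supplied (see [merge_user_evidence()]).
#'
#' @inheritParams evaluate_section1
#' @param af_threshold Common-variant allele-frequency cut-off (default 1%).
#' @param ro_threshold Reciprocal-overlap cut-off for a frequency match.
#' @return Evidence table (zero or one row).
#' @export
evaluate_section4_frequency <- function(cnv, bundle, rubric = default_rubric(),
                                        af_threshold = 0.01,
                                        ro_threshold = 0.70) {
  m <- max_population_frequency(bundle, cnv, ro_threshold)
  if (is.na(m$frequency) || m$frequency < af_threshold) return(empty_evidence())
  id <- if (cnv$type == "DEL") "L4O" else "G4O"
  evidence_item(rubric, id,
                rationale = sprintf("common population CNV: AF %.4g in %s",
                                    m$frequency, m$source))
}

#' Merge engine evidence with user-supplied evidence
#'
#' User items (e.g. de novo status, segregation, case reports) are validated
#' against the rubric and unioned with the automatic items; a user item for
#' a criterion the engine scored replaces the automatic one, with the
#' overridden value recorded in the rationale.
#'
#' @param auto_items Evidence table from the engine.
#' @param user_items List of lists with `criterion`, optional `points`,
#'   optional `rationale`.
#' @param rubric A `rubric`.
#' @return Combined evidence table.
#' @export
merge_user_evidence <- function(auto_items, user_items,
                                rubric = default_rubric()) {
  if (length(user_items) == 0L) return(auto_items)
  out <- data.table::copy(auto_items)
  for (u in user_items) {
    item <- evidence_item(rubric, u$criterion, points = u$points,
                          rationale = u$rationale %||% "user-supplied",
                          auto = FALSE)
    prev <- out$criterion == u$criterion
    if (any(prev)) {
      item$rationale <- sprintf("%s (overrides automatic %.2f)",
                                item$rationale, out$points[prev][1])
      out <- out[!prev]
    }
    out <- rbind(out, item)
  }
  out
}

#' Classify a CNV from its evidence total
#'
#' Sums the evidence points and maps the total onto the rubric's five bands:
#' >= 0.99 Pathogenic, 0.90-0.98 Likely pathogenic, -0.89-0.89 VUS,
#' -0.98 to -0.90 Likely benign, <= -0.99 Benign.
#'
#' @param evidence Evidence table.
#' @param rubric A `rubric`.
#' @return List `total`, `category`, `evidence`.
#' @export
classify <- function(evidence, rubric = default_rubric()) {
  total <- if (nrow(evidence)) sum(evidence$points) else 0
  b <- rubric$bands
  eps <- 1e-9
  category <-
    if (total >= b$pathogenic - eps) "Pathogenic"
    else if (total >= b$likely_pathogenic - eps) "Likely pathogenic"
    else if (total <= b$benign + eps) "Benign"
    else if (total <= b$likely_benign + eps) "Likely benign"
    else "VUS"
  list(total = round(total, 2), category = category, evidence = evidence)
}

#' Interpret one CNV end to end
#'
#' Runs Section 1 (content), Section 2 (dosage sensitivity, per type),
#' Section 3 (gene count) and Section 4 (population frequency), merges any
#' user-supplied evidence and classifies the total. A Section 1 "no content"
#' outcome skips Sections 2-3.
#'
#' @param cnv List/row with `chrom`, `start`, `end`, `type`.
#' @param bundle A `resource_bundle`.
#' @param rubric A `rubric`.
#' @param user_evidence Optional list of user items (see
#'   [merge_user_evidence()]).
#' @param af_threshold,ro_threshold See [evaluate_section4_frequency()].
#' @return List `classification` (see [classify()]) and `report` (one row
#'   per evidence item plus a summary row).
#' @export
interpret <- function(cnv, bundle, rubric = default_rubric(),
                      user_evidence = NULL, af_threshold = 0.01,
                      ro_threshold = 0.70) {
  s1 <- evaluate_section1(cnv, bundle, rubric)
  items <- s1
  if (endsWith(s1$criterion[1], "A")) {
    s2 <- if (cnv$type == "DEL") evaluate_section2_loss(cnv, bundle, rubric)
          else evaluate_section2_gain(cnv, bundle, rubric)
    s3 <- evaluate_section3(cnv, bundle, rubric)
    items <- rbind(items, s2, s3)
  }
  s4 <- evaluate_section4_frequency(cnv, bundle, rubric, af_threshold,
                                    ro_threshold)
  items <- rbind(items, s4)
  items <- merge_user_evidence(items, user_evidence, rubric)
  cls <- classify(items, rubric)
  report <- data.table::copy(items)
  report <- rbind(report, data.table::data.table(
    criterion = "TOTAL", points = cls$total, section = NA_integer_,
    rationale = cls$category, auto = TRUE))
  list(classification = cls, report = report)
}
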