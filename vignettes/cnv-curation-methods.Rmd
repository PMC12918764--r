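---
title: "Methods: ensemble CNV curation and semiquantitative interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble CNV curation and semiquantitative interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcurate)
```

# Overview

`cnvcurate` implements the post-calling half of a germline CNV analysis
workflow. Its input is the output of one or more CNV callers (VCF with
symbolic `<DEL>`/`<DUP>` alleles, or BED); its output is a consensus call
set in which each CNV carries a five-tier clinical classification
(Pathogenic, Likely pathogenic, VUS, Likely benign, Benign) with an
itemised evidence report. Four stages run in fixed order:

1. **Caller-specific filtering** — per-caller confidence rules remove
   low-confidence calls.
2. **Size- and type-aware ensemble merging** — concordant calls from
   different callers are clustered into consensus CNVs.
3. **Region filtering** — consensus CNVs falling in blacklist or
   assembly-gap regions are removed (short-read platforms only).
4. **Semiquantitative interpretation** — each CNV is scored under the
   ACMG/ClinGen evidence framework against local annotation tables.

Coordinates are 0-based half-open everywhere inside the package; the VCF
boundary converts the 1-based inclusive POS/END convention on the way in
and out. A single internal convention removes the usual class of
off-by-one defects; the choice of the BED convention internally makes BED
I/O the identity.

# Caller-specific filters

Each supported caller has a published operating point below which its
calls are predominantly artifacts. The rules are pure predicates over a
call's metrics, with strict inequalities exactly as printed by each
caller's authors:

| Caller | Removal condition |
|---|---|
| CNVpytor | `pytorP1 > 0.05`, or `Q0 > 0.9`, or `0.75 < pytorRD < 1.25` |
| ControlFREEC | `W > 0.05` or `KS > 0.05` |
| delly, Manta | site FILTER or FORMAT/FT not `PASS`, or genotype `0/0` |
| lumpy | `QUAL < 120` |
| Wham | `max_CW < 0.2`; DEL with `TF < 3`; DUP with `U < 2` |
| GRIDSS | `NO_ASSEMBLY` in FILTER |
| ExomeDepth | `BF < 15`; DEL ratio `> 0.8`; DUP ratio `< 1.1` |
| GATK4 gCNV | `QS` below `min(1000, max(400, 10nt))` (DEL, CN 0), `min(1000, max(100, 10nt))` (DEL, CN 1), `min(400, max(50, 4nt))` (DUP) |

cn.mops, xhmm, ECOLE and the long-read callers (cuteSV, SVision-pro,
Sniffles, NanoVar, DeBreak) have no published rule here and pass through
unfiltered.

Two readings of the CNVpytor rule are possible, because its conditions
are listed with commas. We combine them **disjunctively**, with the two
`pytorRD` bounds forming a single band condition: a normalized read depth
between 0.75 and 1.25 is close to diploid and therefore evidence
*against* a real dosage change. A conjunctive combination would almost
never fire (a call cannot have suspicious P1, Q0 and near-diploid depth
be required simultaneously for removal to be useful), and the band
reading matches what the depth metric means. The conjunctive alternative
remains available via `options(cnvcurate.pytor_conjunctive = TRUE)`.

Missing metrics are handled by a global policy:
`options(cnvcurate.missing_metric = "lenient")` (default) keeps the call
with a warning, `"strict"` raises an error. Caller output dialects vary
across versions, so a hard failure by default would make the filter
stage brittle for no safety gain — a kept low-quality call is still
subject to ensemble support requirements downstream.

# Ensemble merging

Callers differ systematically in sensitivity by CNV size, type and
breakpoint resolution, so merging is stratified: calls are partitioned
by chromosome, type (DEL/DUP) and size bin before any clustering.
The bins are half-open so that every length maps to exactly one bin:

* WGS and long-read: SS [50, 500), S [500, 5 kb), M [5 kb, 100 kb), L [100 kb, ∞)
* WES: S [50, 10 kb), M [10 kb, 100 kb), L [100 kb, ∞)

Within a partition, two calls are *breakpoint-compatible* when both
start and end differ by at most `D = max_dist × max(len_a, len_b)`.
The default `max_dist = 0.5` is interpreted as a **fraction of the larger
variant's length** — half a base pair would be a degenerate absolute
distance — and values ≥ 1 are taken as absolute base pairs, so both
semantics are available. Clusters are the single-linkage (transitive)
closure of this relation, computed with a deterministic seed order
(sorted by start, end, then caller id) so results are independent of
input order.

A cluster may contain at most one call per caller. When a caller
contributes several compatible calls, the one with the smallest
breakpoint distance (|Δstart| + |Δend|) to the cluster seed is retained
and the others are re-clustered among themselves. The representative
interval of a cluster is the per-endpoint median of its supporting calls,
rounded down — a median is robust to one caller's outlier breakpoints,
whereas designating a "best" caller would import that caller's biases.

Consensus selection is configuration-driven: for each (type, bin) a tool
set and a minimum support count decide whether a cluster is kept. The
optimal per-bin tool sets are a property of the calling cohort and
platform, so they ship as an editable YAML rather than hard-coded
constants. The default admits all registered callers with minimum
support 2 in the small bins (SS, S), where individual callers are noisy,
and 1 in M and L, where single-caller calls are reliable.

# Region filtering

Blacklist and assembly-gap regions produce recurrent artifactual calls in
short-read data. A consensus CNV is removed when its **reciprocal
overlap** — `min(o/len_cnv, o/len_region)` for overlap `o` — with any
single region reaches 0.70 (inclusive, the conventional reading of a
"70% reciprocal overlap" cut-off). Overlap is evaluated per region, not
against the union of regions: a CNV tiled by many small regions none of
which reaches the cut-off is kept, matching the per-region phrasing of
the rule; `union = TRUE` enables the union-based alternative. The filter
applies only to short-read platform classes (HD-WGS, LD-WGS, WES);
supplying region files for a long-read run produces a warning and no
filtering.

# Annotation resources

The interpretation engine queries four plain-TSV/BED tables (bundle
directory, schema version line mandatory): a gene table (one transcript
per gene — the MANE transcript when flagged, else the longest — with exon
structure, CDS, gene family, OMIM-derived disease association, gnomAD
pLI, o/e upper bound, DECIPHER HI index, ClinGen HI/TS scores), a dosage
region table (HI/TS and benign regions), a curated variant table
(ClinVar-style null variants and last-exon pathogenic variants) and a
population CNV table with allele frequencies (gnomAD controls, DGV,
DECIPHER). Producing these tables from the live databases is an ETL
concern outside the package; the shipped generator writes toy bundles
with the same schema.

Gene counting collapses families: a family with ≥ 2 overlapped members,
none disease-associated, counts as one unit, so locally expanded gene
families do not inflate the gene-count evidence. Predicted
haploinsufficiency requires all three of pLI ≥ 0.9, o/e upper bound
< 0.35 and HI index ≤ 10% — boundary directions exactly as printed by the
sources of those metrics. Population-frequency matching requires the same
CNV type and reciprocal overlap ≥ 0.70 (the same cut-off as region
filtering, applied symmetrically; the matching rule is configurable
because upstream databases do not fix one).

# Semiquantitative interpretation

Evidence criteria, their point weights, the gene-count bands and the
classification bands are **data** (`inst/extdata/rubric.yaml`), encoding
the ClinGen semiquantitative framework; point revisions are a data edit,
not a code change. The engine automates what a call set and local
annotation can support:

* **Section 1** — genomic content: protein-coding genes or established
  dosage-sensitive regions present (1A, continue) or absent (1B, 0
  points; sections 2–3 are skipped and scoring continues with the
  population-frequency arm).
* **Section 2 (loss)** — in priority order: complete overlap of an
  established HI gene/region (+1.0); partial overlaps weighted by side
  (5' with coding sequence involved 0.90; 3' depending on last-exon
  content and known last-exon pathogenic variants 0.30–0.90); intragenic
  deletions routed through the loss-of-function tree below; containment
  in a benign loss region (−1.0) or benign overlap with additional genes
  (0); otherwise predicted-HI genes (+0.15).
* **Section 2 (gain)** — mirror image over TS and benign-gain elements;
  intragenic and breakpoint-in-gene duplications receive conservative 0
  points because tandem status and insertion site are unknown from a
  call set alone.
* **Section 3** — family-collapsed gene count: losses 0 / +0.45 / +0.90
  at 0–24 / 25–34 / ≥ 35 genes; gains at 0–34 / 35–49 / ≥ 50.
* **Section 4** — population frequency: a match at allele frequency
  ≥ 1% scores −1.0. The 1% cut-off is the conventional "common variant"
  threshold and is configurable (`af_threshold`); the upstream databases
  name no single value. All other Section 4 criteria, and all of
  Section 5 (de novo status, segregation, family history), are
  user-supplied through `merge_user_evidence()`; a user item for a
  criterion the engine scored replaces the automatic item with
  provenance retained.

When several criteria in one section could fire, the highest-priority
(largest-|points|) applicable criterion is taken and the alternatives are
noted in the rationale; emitting both would double-count one observation.

The total maps onto five bands: ≥ 0.99 Pathogenic, 0.90–0.98 Likely
pathogenic, −0.89–0.89 VUS, −0.98–−0.90 Likely benign, ≤ −0.99 Benign.
Band comparisons use a 10⁻⁹ tolerance so that sums of decimal point
values (e.g. 0.45 + 0.45) land in the intended band despite binary
floating point.

## Loss-of-function decision tree

For an intragenic deletion of an established HI gene the engine walks a
PVS1-style tree on the gene's exon model:

1. No coding bases removed → no LoF evidence.
2. Removed coding bases not a multiple of 3 → frameshift. The premature
   termination is approximated by the transcript coordinate of the first
   affected coding base; if it lies more than 50 nt upstream of the last
   exon–exon junction the transcript is predicted to undergo
   nonsense-mediated decay. NMD-competent frameshifts score *very
   strong* (0.90) when the gene's disease mechanism is loss of function
   (disease-associated with curated null variants), else *strong*.
3. In-frame or NMD-escaping removals: *strong* when curated pathogenic
   variants lie in the altered region (the deletion itself when
   in-frame; the deletion plus everything downstream, including
   last-exon pathogenic variants, on a frameshift), else *strong* when
   more than 10% of the protein is removed, else *moderate*.

Strengths map to points very strong 0.90 / strong 0.45 / moderate 0.30 /
supporting 0.15. Finer sub-branches of automated PVS1 tools (splice-site
micro-anatomy, alternative-transcript rescue) require annotation this
package does not ingest and are deliberately out of scope.

# Synthetic fixtures and what passing tests show

The generator (`generate_caller_vcfs()`, `generate_resource_bundle()`,
`generate_cluster_scenarios()`) fabricates every input the pipeline
consumes on a toy genome of 2 chromosomes × 10 Mb, chosen so the whole
suite runs in seconds. Expected outputs are computed at generation time
by naive oracles (literal rule transcription, quadratic transitive
closure, all-pairs overlap scans, a hand-coded band table) that share no
code with the modules under test. Every published threshold appears in
at least one fixture below, at, and above its boundary; the predicted-HI
cut-offs are planted at all eight corners; the three golden CNVs
(a full HI-gene deletion, a common benign-region duplication, a
single-gene deletion) are hand-traced to +1.0 / −2.0 / 0.0.

What this does *not* show: fixtures do not emulate real caller error
profiles, breakpoint uncertainty distributions, segmental-duplication
artifacts, or the content of the live annotation databases. Passing
tests demonstrate that the rules, the merge algebra and the scoring
arithmetic are implemented exactly as specified — not that the
thresholds themselves are optimal for any particular cohort.

Problem sizes used by the test and acceptance runs — ~120
threshold-straddling filter records, 100 randomized merge scenarios,
1,000 random interval pairs, a 200-CNV region-filter fixture — were
chosen as the smallest sets that still exercise every rule branch and
boundary.

# Degenerate inputs and tie-breaks

* Records lacking both END and SVLEN are skipped and counted; END is
  reconstructed as `POS + |SVLEN|` when absent.
* A cluster's representative uses `floor()` of the median, keeping
  integer coordinates.
* An empty region set keeps all CNVs with a warning rather than failing
  a run.
* DEL calls with a copy-number state outside {0, 1} are outside the
  GATK4 rule and kept with a warning.
* Genes without CDS annotation yield no LoF evidence rather than an
  error.
* Single-base intervals (`chrX:5-5-DEL` in the region-string syntax) are
  valid.

# Known limitations

* Breakend (BND) notation, inversions and insertions are not
  interpreted; only symbolic DEL/DUP calls are in scope.
* Multi-sample VCFs contribute only their first sample.
* The gain arm cannot distinguish tandem from inserted duplications, so
  intragenic gains are scored conservatively at 0 points.
* Section 4 automation is limited to population frequency; clinical
  case-level criteria require user-supplied evidence.
* The shipped per-bin tool sets and minimum supports are sensible
  defaults, not cohort-calibrated optima.
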