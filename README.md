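# cnvcurate

Post-calling curation and clinical interpretation of germline copy number
variant (CNV) call sets, for analysts who run several CNV callers on the
same sample and need one defensible, classified call set at the end.

Individual CNV callers differ sharply in sensitivity by variant size,
type and breakpoint resolution, and their raw output carries
caller-specific artifact modes. `cnvcurate` takes per-caller call sets
(VCF with symbolic `<DEL>`/`<DUP>` alleles, or BED) and runs four stages:

1. **Caller-specific filtering** — published per-caller confidence rules
   (e.g. CNVpytor `pytorP1 > 0.05` / `Q0 > 0.9` / near-diploid read
   depth; lumpy `QUAL < 120`; ExomeDepth `BF < 15`; the GATK4 gCNV
   exon-count-dependent QS thresholds `min(1000, max(400, 10nt))` etc.).
2. **Size- and type-aware ensemble merging** — calls are partitioned by
   chromosome, type and size bin (SS/S/M/L for WGS and long reads,
   S/M/L for WES), then single-linkage clustered: calls *a*, *b* merge
   when both breakpoints differ by at most
   `0.5 × max(len_a, len_b)`. Each cluster yields one consensus CNV
   (per-endpoint median) with caller support counted against a
   configurable per-bin tool set.
3. **Region filtering** — consensus CNVs with reciprocal overlap
   `min(o/len_a, o/len_b) ≥ 0.70` against any blacklist or assembly-gap
   region are removed (short-read platforms).
4. **ACMG/ClinGen semiquantitative interpretation** — each CNV is scored
   against local annotation tables (dosage-sensitive genes and regions,
   gene constraint pLI / o/e / HI index, curated null variants,
   population CNV frequencies): evidence points per criterion are
   summed and the total banded into Pathogenic (≥ 0.99), Likely
   pathogenic (0.90–0.98), VUS (−0.89–0.89), Likely benign
   (−0.98–−0.90), Benign (≤ −0.99). Intragenic deletions run through a
   PVS1-style loss-of-function tree (reading frame, the NMD 50-nt rule,
   fraction of protein removed, last-exon pathogenic variants).

A synthetic-fixture generator fabricates caller VCFs, an annotation
bundle and merge scenarios with oracle-computed expected outputs, so the
entire pipeline is testable offline.

## Worked example

```r
library(cnvcurate)

# toy inputs: annotation bundle + three callers reporting the same CNVs
bundle_dir <- tempfile(); generate_resource_bundle(bundle_dir, seed = 1)
run_dir <- tempfile(); dir.create(run_dir)
toys <- toy_cnv_fixtures()
inputs <- lapply(c("delly", "lumpy", "manta"), function(cl) {
  calls <- cnv_calls(chrom = toys$chrom, start = toys$start, end = toys$end,
                     type = toys$type, caller = cl, genotype = "0/1",
                     filter = "PASS", qual = 500, ft = "PASS")
  f <- file.path(run_dir, paste0(cl, ".vcf"))
  write_calls(calls, f, "vcf")
  list(vcf = f, caller = cl)
})

res <- run_pipeline(list(platform = "HD-WGS", inputs = inputs,
                         resources = bundle_dir,
                         out_dir = file.path(run_dir, "out")))
res$report[res$report$criterion == "TOTAL",
           c("chrom", "start", "end", "type", "support", "category", "total")]
#>     chrom   start     end   type support   category total
#>    <char>   <int>   <int> <char>   <int>     <char> <num>
#> 1:      1  995000 1025000    DEL       3 Pathogenic     1
#> 2:      1 2000000 2010000    DEL       3        VUS     0
#> 3:      2 2040000 2060000    DUP       3     Benign    -2
```

Three consensus CNVs, each supported by all three callers. The first
deletes an established haploinsufficient gene completely (+1.0 →
Pathogenic); the second covers one gene with no dosage, constraint or
frequency evidence (0 → VUS); the duplication sits inside an established
benign gain region (−1.0) and matches a population CNV at 5% allele
frequency (−1.0), totalling −2.0 → Benign. The per-criterion rows of
`res$report` give each evidence item with its points and rationale.

Single CNVs can be interpreted directly:

```r
bundle <- load_resources(bundle_dir)
r <- parse_region_string("chr1:995001-1025000-DEL")
interpret(r, bundle)$classification
#> $total      [1] 1
#> $category   [1] "Pathogenic"
```

A thin command line wraps the same functions
(`exec/cnvcurate ingest|filter|merge|regionfilter|interpret|run|fixtures`).

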