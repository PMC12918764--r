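# Semiquantitative CNV scoring rubric (ClinGen-style), editable data.
# Points are evidence weights; the classification is banded on their sum.
version: 1
bands:
  pathogenic: 0.99          # total >= 0.99
  likely_pathogenic: 0.90   # 0.90 <= total <= 0.98
  likely_benign: -0.90      # -0.98 <= total <= -0.90
  benign: -0.99             # total <= -0.99
gene_count_bands:
  loss: {mid: 25, high: 35}   # 0-24 -> 0, 25-34 -> 0.45, >=35 -> 0.90
  gain: {mid: 35, high: 50}   # 0-34 -> 0, 35-49 -> 0.45, >=50 -> 0.90
pvs1_points: {very_strong: 0.90, strong: 0.45, moderate: 0.30, supporting: 0.15, none: 0}
criteria:
  # ---- Section 1: genomic content ----
  L1A: {section: 1, applies: loss, default: 0, min: 0, max: 0,
        description: "Contains protein-coding genes or known functionally important elements"}
  L1B: {section: 1, applies: loss, default: 0, min: 0, max: 0,
        description: "Does not contain protein-coding genes or known functionally important elements"}
  G1A: {section: 1, applies: gain, default: 0, min: 0, max: 0,
        description: "Contains protein-coding genes or known functionally important elements"}
  G1B: {section: 1, applies: gain, default: 0, min: 0, max: 0,
        description: "Does not contain protein-coding genes or known functionally important elements"}
  # ---- Section 2 (loss): established / predicted dosage sensitivity ----
  L2A: {section: 2, applies: loss, default: 1.0, min: 0, max: 1.0,
        description: "Complete overlap of an established haploinsufficient gene or region"}
  L2B: {section: 2, applies: loss, default: 0, min: 0, max: 0,
        description: "Partial overlap of an established haploinsufficient region"}
  L2C: {section: 2, applies: loss, default: 0.90, min: 0, max: 0.90,
        description: "Partial overlap of the 5' end of an established haploinsufficient gene"}
  L2D: {section: 2, applies: loss, default: 0.30, min: 0, max: 0.90,
        description: "Partial overlap of the 3' end of an established haploinsufficient gene"}
  L2E: {section: 2, applies: loss, default: 0, min: 0, max: 0.90,
        description: "Intragenic deletion in an established haploinsufficient gene (LoF assessment)"}
  L2F: {section: 2, applies: loss, default: -1.0, min: -1.0, max: 0,
        description: "Completely contained within an established benign loss region"}
  L2G: {section: 2, applies: loss, default: 0, min: 0, max: 0,
        description: "Overlaps an established benign loss region but includes additional protein-coding genes"}
  L2H: {section: 2, applies: loss, default: 0.15, min: 0, max: 0.15,
        description: "Involves at least one predicted haploinsufficient gene (pLI/LOEUF/HI index)"}
  # ---- Section 2 (gain): triplosensitivity ----
  G2A: {section: 2, applies: gain, default: 1.0, min: 0, max: 1.0,
        description: "Complete overlap of an established triplosensitive gene or region"}
  G2B: {section: 2, applies: gain, default: 0, min: 0, max: 0,
        description: "Partial overlap of an established triplosensitive gene or region"}
  G2C: {section: 2, applies: gain, default: -1.0, min: -1.0, max: 0,
        description: "Completely contained within an established benign gain region"}
  G2D: {section: 2, applies: gain, default: 0, min: 0, max: 0,
        description: "Overlaps an established benign gain region but includes additional protein-coding genes"}
  G2I: {section: 2, applies: gain, default: 0, min: 0, max: 0.90,
        description: "Both breakpoints within the same gene (intragenic duplication, effect uncertain)"}
  G2L: {section: 2, applies: gain, default: 0, min: 0, max: 0,
        description: "One breakpoint within a disease-associated gene, insertion site unknown"}
  # ---- Section 3: gene count ----
  L3A: {section: 3, applies: loss, default: 0, min: 0, max: 0,
        description: "0-24 protein-coding genes"}
  L3B: {section: 3, applies: loss, default: 0.45, min: 0.45, max: 0.45,
        description: "25-34 protein-coding genes"}
  L3C: {section: 3, applies: loss, default: 0.90, min: 0.90, max: 0.90,
        description: "35 or more protein-coding genes"}
  G3A: {section: 3, applies: gain, default: 0, min: 0, max: 0,
        description: "0-34 protein-coding genes"}
  G3B: {section: 3, applies: gain, default: 0.45, min: 0.45, max: 0.45,
        description: "35-49 protein-coding genes"}
  G3C: {section: 3, applies: gain, default: 0.90, min: 0.90, max: 0.90,
        description: "50 or more protein-coding genes"}
  # ---- Section 4: population and clinical evidence ----
  L4O: {section: 4, applies: loss, default: -1.0, min: -1.0, max: 0,
        description: "Overlap with common population variation"}
  G4O: {section: 4, applies: gain, default: -1.0, min: -1.0, max: 0,
        description: "Overlap with common population variation"}
  L4A: {section: 4, applies: loss, default: 0.30, min: 0, max: 0.90,
        description: "Reported proband with highly specific, consistent phenotype (user-supplied)"}
  L4B: {section: 4, applies: loss, default: 0.30, min: 0, max: 0.90,
        description: "Reported proband with consistent but nonspecific phenotype (user-supplied)"}
  L4D: {section: 4, applies: loss, default: -0.30, min: -0.90, max: 0,
        description: "Case-control or population evidence against pathogenicity (user-supplied)"}
  G4A: {section: 4, applies: gain, default: 0.30, min: 0, max: 0.90,
        description: "Reported proband with highly specific, consistent phenotype (user-supplied)"}
  G4B: {section: 4, applies: gain, default: 0.30, min: 0, max: 0.90,
        description: "Reported proband with consistent but nonspecific phenotype (user-supplied)"}
  G4D: {section: 4, applies: gain, default: -0.30, min: -0.90, max: 0,
        description: "Case-control or population evidence against pathogenicity (user-supplied)"}
  # ---- Section 5: inheritance and family history (user-supplied) ----
  "5A": {section: 5, applies: both, default: 0.45, min: 0, max: 0.45,
         description: "De novo occurrence with consistent, specific phenotype"}
  "5B": {section: 5, applies: both, default: 0.30, min: 0, max: 0.30,
         description: "De novo occurrence with nonspecific phenotype"}
  "5C": {section: 5, applies: both, default: 0.15, min: 0, max: 0.45,
         description: "Segregation among affected family members"}
  "5D": {section: 5, applies: both, default: -0.30, min: -0.45, max: 0,
         description: "Non-segregation with phenotype"}
  "5E": {section: 5, applies: both, default: -0.30, min: -0.45, max: 0,
         description: "Inherited from an unaffected parent"}
  "5F": {section: 5, applies: both, default: 0, min: -0.15, max: 0.15,
         description: "Inheritance information unavailable or uninformative"}
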