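# pedcns

Consensus somatic calling and molecular subtyping for pediatric CNS tumor
cohorts.

Pediatric brain tumors are the leading disease-related cause of death in
children, and most cohorts collected over the last decade lack the
molecular subtype labels that modern WHO classifications require. `pedcns`
reimplements, as a tested and reusable R package, the downstream
somatic-analysis layer used to characterize such cohorts: multi-caller
consensus SNV/indel calling with hotspot rescue, reciprocal-overlap
consensus copy-number calling, arm/cytoband/gene-level focal copy-number
resolution, tumor mutation burden and hypermutation classes, pairwise
mutation co-occurrence, gene-fusion artifact filtering and prioritization,
expression-matrix collapsing with cohort z-scores, germline sex inference,
and a rule-based molecular-subtyping engine aligned with the WHO 2016
classification. It is written for computational biologists who need these
analyses on their own cohorts, or who need a fully synthetic, truth-known
test bed for pipelines whose real inputs sit behind controlled access.

## The methods in brief

* **Consensus SNVs.** Callers disagree on representation, so
  multi-nucleotide variants are first decomposed into consecutive SNVs;
  a call is consensus iff the exact tuple
  (chromosome, position, ref, alt, sample) appears in all three callers
  (strelka2, mutect2, lancet; a fourth caller's calls are ignored).
  Non-hotspot calls with normal depth ≤ 7 or gnomAD AF > 0.001 are removed
  as germline-like; calls matching a curated hotspot database (by protein
  position, splice HGVSp, or indel range) are rescued from *any* single
  caller into a separate hotspot set. TERT promoter positions
  chr5:1,295,113 (C228T) and chr5:1,295,135 (C250T) are annotated and
  count as hotspots.
* **Consensus CNVs.** After per-caller filters (Control-FREEC p < 0.01,
  Manta PASS, any caller file with > 2,500 segments dropped), two callers'
  same-direction segments form a consensus region when they overlap
  reciprocally by ≥ 50% or the smaller is > 90% covered; the emitted span
  is the intersection. Same-direction regions within 10 kb merge; regions
  ≥ 50% inside exclusion lists (telomeres, centromeres, …) or shorter than
  3 kb are removed.
* **TMB.** `TMB = n coding consensus SNVs / Mb of effectively surveyed
  genome`, the denominator being the intersection of the callers' regions
  with coding sequence; tumors with TMB > 10 are hypermutant and > 100
  ultra-hypermutant (strict inequalities).
* **Co-occurrence.** For each gene pair, the score is `I · (−log10 P)`
  with P from the two-sided Fisher exact test and I = +1 when the odds
  ratio exceeds 1 (co-occurrence), −1 otherwise (exclusivity); q values
  are Benjamini–Hochberg.
* **Fusions.** In-frame/frameshift calls with ≥ 1 junction read, an
  expressed partner (TPM > 1), and spanning − junction ≤ 10 survive;
  promiscuous partners (> 5 fusion partners in a sample) are removed, and
  the prioritized set is the union of both-caller calls, fusions recurrent
  in a broad histology (> 2 samples), and histology-specific fusions.
* **Subtyping.** Per-histology rule lists (HGG/DMG, LGG/GNT/SEGA,
  embryonal, ependymoma, craniopharyngioma, neurocytoma, Ewing sarcoma,
  medulloblastoma classifier consensus) consume SNV, CNV, fusion,
  expression-z and clinical evidence; TP53 status (activated / lost /
  other) is integrated into HGG labels, e.g. `DMG, H3 K28, TP53 loss`.

Because the cohorts these methods were designed for live behind controlled
access, the package ships a seeded synthetic-cohort generator
(`cohort_config()`, `generate_cohort()`, `simulate_multicaller_*()`) that
emulates every input — three SNV callers with representation differences
and germline-like contaminants, three CNV callers with boundary jitter,
two fusion-caller dialects with per-rule artifact classes, expression
matrices with multi-mapped symbols and planted marker genes — with known
truth, down to a "rule-coverage" roster that exercises every subtyping
branch.

## Worked example

```r
library(pedcns)
library(dplyr)

# 1. classify the published per-specimen TMB values
tmb <- hypermutant_tmb_table()
tmb$category <- classify_hypermutation(tmb$tmb)
count(tmb, category)
#> # A tibble: 3 × 2
#>   category              n
#>   <chr>             <int>
#> 1 hypermutant           3
#> 2 normal                4
#> 3 ultra-hypermutant     4

# 2. run the full pipeline on a synthetic rule-coverage cohort
res <- run_synthetic_pipeline(cohort_config(mode = "rule-coverage", seed = 1))
res$integrated_histology |>
  filter(sample_type == "tumor") |>
  select(sample_id, pathology_diagnosis, molecular_subtype) |>
  head(8)
#> # A tibble: 8 × 3
#>   sample_id pathology_diagnosis molecular_subtype
#>   <chr>     <chr>               <chr>
#> 1 BS_001    High-grade glioma   DMG, H3 K28
#> 2 BS_002    High-grade glioma   DMG, H3 K28, BRAF V600E
#> 3 BS_003    High-grade glioma   HGG, H3 G35
#> 4 BS_004    High-grade glioma   HGG, IDH
#> 5 BS_005    High-grade glioma   HGG, BRAF V600E
#> 6 BS_006    High-grade glioma   HGG, H3 wild type
#> 7 BS_007    High-grade glioma   DMG, H3 K28, TP53 activated
#> 8 BS_008    High-grade glioma   DMG, H3 K28, TP53 loss
```

The first block reproduces the published hypermutation tally: 4
ultra-hypermutant and 3 hypermutant specimens among the 11 listed. The
second runs every stage — consensus SNV (18 calls), consensus CNV (5
segments), fusion prioritization (11 fusions) — and labels all 47 planted
tumors in 100% agreement with the generator's truth.

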