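---
title: "Methods: consensus somatic calling and rule-based subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus somatic calling and rule-based subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcns)
```

`pedcns` is a downstream somatic-analysis layer for pediatric CNS tumor
cohorts: it takes per-caller variant, copy-number, structural-variant and
fusion tables plus expression matrices and clinical metadata, and produces
consensus calls, mutation statistics, prioritized fusions and
research-grade molecular subtypes. This vignette explains the models and
procedures, the parameters that matter, the numerical choices made where
the methods left room, and what the synthetic test bed does and does not
establish.

## Consensus SNV calling

Somatic SNV callers disagree far more on borderline calls than on clear
ones, so the package treats agreement of three independent callers
(strelka2, mutect2, lancet) as the operating definition of a
high-confidence somatic call. Two details matter:

* **Representation.** Some callers report adjacent substitutions as one
  multi-nucleotide record while others split them. `decompose_mnv()`
  rewrites every equal-length k-base substitution into its component SNVs
  (dropping positions where ref equals alt) before comparison, so the
  consensus is taken over a canonical representation. Indels
  (unequal-length alleles) pass through unchanged; the package assumes
  indels were left-normalized upstream, as is standard in VCF processing.
* **Identity.** Two calls describe the same mutation iff they agree on
  the exact tuple (chromosome, position, reference allele, alternate
  allele, sample). The retained consensus record carries read counts from
  the first caller in the fixed order strelka2 → mutect2 → lancet; the
  choice is arbitrary but deterministic, and only annotations — never
  membership — depend on it.

Calls with matched-normal depth ≤ 7 reads or population allele frequency
> 0.001 are removed as probable germline contamination. A missing
population frequency counts as 0 (absence of evidence the allele is
common); a missing normal depth does not trigger the filter. Both
thresholds are the field's conventional values for tumor/normal panels of
this depth. Hotspot-annotated calls are exempt, and additionally any
*single* caller's call matching the hotspot database — SNVs by (gene,
protein position), splice sites by HGVSp short string, indels by protein
position within a curated range — is rescued into a separate hotspot call
set: recurrence across tumors is strong prior evidence that outweighs
single-caller uncertainty. The two TERT promoter positions (chr5:1295113
C228T, chr5:1295135 C250T on hg38) are annotated directly by coordinate
and treated as hotspots. The bundled hotspot database and driver-gene
lists are small synthetic stand-ins that carry the vocabulary the rules
need; users with access to the curated references can supply them in the
same TSV layouts.

## Consensus CNV calling

Copy-number callers disagree on boundaries more than on events, so
consensus is defined on interval overlap rather than identity, within a
(sample, chromosome, direction) group — gain pairs with gain and loss
with loss; pairing opposite directions would be biologically incoherent.
Two rules admit a caller pair: reciprocal overlap ≥ 50%, or > 90% of the
smaller segment covered by the other (which rescues focal events inside a
caller's broader segment). The emitted span is the **intersection** of the
pair — the conservative common region — and where all three callers
support a region the pairwise intersections are unioned by the subsequent
merge step. No single-caller region ever survives. The consensus copy
number is the rounded mean of the contributing callers', with half-integer
ties broken toward the sample's ploidy (the least surprising value);
regions whose contributing calls are copy-neutral get a missing copy
number.

Post-processing is ordered merge → exclusion filter → size filter:
same-direction regions within 10 kb merge; if a sample's merged gain and
loss regions overlap (possible only under incoherent caller disagreement)
the ambiguous overlap is removed from both sides; regions with ≥ 50% of
their length in exclusion intervals (immunoglobulin loci, telomeres,
centromeres, segmental duplications) are dropped; regions under 3 kb are
dropped. Up front, Control-FREEC segments need p < 0.01, Manta segments
need PASS, and any (sample, caller) table with more than 2,500 segments is
discarded wholesale as a noisy sample; the cap is applied after the
per-segment filters, since the per-segment filters are unambiguous while
the cap's timing is a judgment call (flagged as such, not silently
assumed).

Breakpoint density is breaks per Mb of effectively surveyed genome,
computed separately from PASS SV breakpoints and from consensus segments
with |log2 ratio| > log2(1) = 0. For chromothripsis-style analyses the
consensus profile is made gap-free: uncalled or neutral regions take the
sample's ploidy and equal-copy-number neighbors merge, so every base of
every (non-Y) chromosome carries exactly one copy number.

## Focal copy-number resolution

Events should be reported at the broadest unit that genuinely carries
them, not as dozens of adjacent "focal" gene hits. Per cytoband the
package computes loss, gain and callable fractions of the band's length;
arm fractions are band-length-weighted means. A region's dominant status
requires more than half the region callable and a status fraction above
0.9 — measured, by default, against the *callable* portion, which
guarantees the dominant fraction exceeds all competing ones; measuring
against total length is available as `denominator = "total"` for users
who prefer the stricter reading, since the threshold's base is genuinely
ambiguous. Reporting is hierarchical: a dominant arm masks its bands and
genes; a dominant band under an undetermined arm masks its genes; genes
surface only under undetermined arms and bands. At gene level, copy
number 0 is a deep deletion and copy number > 2 × ploidy an amplification
— on autosomes only; sex-chromosome genes cap at gain because ploidy
conventions there are not comparable.

## Mutation statistics

TMB divides the count of coding consensus SNVs by the Mb size of the
intersection between the callers' surveyed regions and coding sequence;
the same intersection masks the numerator, so splitting intervals into
sub-intervals cannot change the value. Indels are excluded from the
numerator by default (`include_indels = TRUE` is available) because the
statistic is defined on SNVs. Hypermutation uses strict thresholds:
\> 10 Mut/Mb hypermutant, > 100 Mut/Mb ultra-hypermutant; exactly 10 is
normal. Recurrently mutated genes count distinct samples with at least
one High/Moderate-consequence mutation at VAF > 5%, with ties broken by
gene name for a deterministic top-50.

Pairwise co-occurrence uses the two-sided Fisher exact test on the 2×2
mutated/wild-type table; the score is I·(−log10 P) with I = +1 when the
conditional maximum-likelihood odds ratio exceeds 1 and −1 otherwise. An
odds ratio of exactly 1 therefore takes the −1 branch — the literal
reading of the rule — which is inconsequential in practice because such
tables have p near 1 and score near 0. q values are Benjamini–Hochberg,
the standard choice for genomics co-occurrence reporting.

## Expression utilities

Collapsing to unique symbols first drops genes with zero expression in
every sample, then keeps, per symbol, the identifier with the maximum
mean expression across samples (raw FPKM, not log; ties to the
lexicographically smallest identifier). Cohort z-scores are
(x − μ)/σ with σ the sample (n−1) standard deviation by default — the
formula's σ is underspecified, so the choice is explicit and switchable
(`sd_type = "population"`). A constant gene is a degenerate error rather
than a silent 0/0. Library types (stranded vs poly-A) must never be mixed
in one matrix operation; the package treats this as a caller-side
precondition because batch effects between preparations are not
correctable downstream.

## Fusion prioritization

Both caller dialects are standardized to one schema (per sample, fusion
and caller, read counts maximized over duplicates; frames normalized to
in-frame/frameshift/other). Artifact filtering keeps in-frame and
frameshift calls with ≥ 1 junction read, at least one partner expressed
(TPM > 1 in the matching sample; a partner missing from the matrix counts
as unexpressed), and spanning − junction ≤ 10; the conditions are applied
as one conjunction, so their order cannot matter. Prioritization then
removes promiscuous partners (> 5 distinct partner genes in one sample,
counted after artifact filtering) and retains the union of both-caller
calls, fusions recurrent within a broad histology (> 2 samples), and
fusions specific to one broad histology — operationalized as a fusion
name observed in exactly one broad histology across the cohort, the most
direct reading of "specific" and switchable if a stricter definition is
wanted. Reciprocal fusions (A–B vs B–A) are distinct because the 5′/3′
roles carry the oncogenic meaning.

## The subtyping engine

Each histology's rule list runs in its published order with first match
winning, except the LGG list where all matching rules contribute and the
matched parts are comma-joined in rule order (combined labels such as
"LGG, BRAF V600E, CDKN2A/B" are real vocabulary). Two readings deserved
explanation:

* **HGG histone rules.** Read literally in isolation, the first rule
  ("H3F3A/HIST1H3B/HIST1H3C/HIST2H3C K28M *and no BRAF V600E*") leaves an
  H3F3A-K28M + BRAF-V600E sample matching no histone rule and falling
  through to H3 wild type — an incoherent outcome for a K28-mutant
  tumor. The engine applies the BRAF exclusion to the HIST-gene variants
  only (which the second rule re-routes to "DMG, H3 K28, BRAF V600E"),
  so rules 1–2 are jointly exhaustive for K28-mutant samples and adding
  BRAF V600E to an H3F3A-K28M sample never changes its label.
* **TP53 "lost" from a single alteration.** One somatic alteration
  suffices for "lost", but a lone SNV qualifies only when it falls in the
  DNA-binding domain; a lone CNV loss or SV always qualifies, as do any
  two alterations (probable biallelic loss), any hotspot TP53 mutation,
  or a Li-Fraumeni predisposition (with or without a classifier score
  above 0.5). Mutations outside the DNA-binding domain with no second
  hit stay "other" — without this qualification the "other" category
  could never receive a mutated sample, contradicting its definition.

Other engine conventions: overexpression of a marker gene means a cohort
z-score above 3 (strictly), matching the ependymoma rules' convention and
applied uniformly to LIN28A and FOXR2; craniopharyngioma patients aged
exactly 40 match neither the "over 40" nor the "younger than 40" rule and
are left "To be classified"; the two medulloblastoma classifier labels
must agree, otherwise "MB, To be classified" (the conservative reading of
a consensus of two); the ependymoma non-exclusive tier reports both
evidence-flag counts and resolves the primary label by the larger count,
ties falling to "To be classified". BCOR internal tandem duplication
detection is an upstream concern and enters as an evidence boolean. Label
orthography follows the published vocabulary ("KIAA1549-BRAF" with a
hyphen inside labels, "::" or "--" only in fusion names; "HGG, H3 wild
type"). TP53 status suffixes apply to HGG/DMG labels only.

The spec's per-module command-line subcommands are fulfilled by the
package's function surface plus `scripts/acceptance.R`; the analyses are
R-native and the functions compose in a few lines, so a shell wrapper
would add indirection without capability.

## The synthetic cohort

The generator exists so that every stage is testable without
controlled-access data. It emulates the *interfaces and failure modes*
of the real inputs, not their biology:

* a miniature genome (ten chromosomes of 2–20 Mb with synthetic
  cytobands, telomere/centromere exclusions, and gene models for the
  genes the rules reference) — all interval code is genome-agnostic, so
  full-genome scale adds nothing to correctness testing;
* three SNV callers sharing every true call, with two callers merging
  adjacent pairs into MNV records, caller-specific false positives
  (Bernoulli at `fp_rate`, default 0.1 per true call), and germline-like
  contaminants shared by all callers (default 2) carrying either high
  population AF or low normal depth, so only the germline filter can
  remove them;
* three CNV callers with uniform boundary jitter (default 0 bp),
  Control-FREEC significance values, an optional > 2,500-segment noisy
  file, and PASS/non-PASS SV breakpoints;
* two fusion-caller dialects where each artifact class violates exactly
  one downstream rule, and an expression matrix with a multi-mapped
  symbol, an all-zero gene, TPM > 1 partners and marker-gene spikes
  (baseline ≈ 5 FPKM, spike 100) sized so planted z-scores clear 3 with
  margin at the roster's cohort size;
* a "rule-coverage" roster of 47 tumors, one per subtyping branch, whose
  planted labels the full pipeline must reproduce exactly, and a
  "random" mode for property tests.

Noise processes are simple Bernoulli/uniform draws by design: the
downstream methods are rule-based filters, so the generator only needs to
satisfy or violate each rule, not model sequencing error. Seeds are
explicit arguments; every simulator derives an independent stream from
the master seed and restores the caller's RNG state, so identical
configurations are byte-identical across runs and machines.

What passing these tests shows: the implementation applies each published
rule exactly, recovers planted truth through the full chain, and matches
independent oracles (exhaustive hypergeometric enumeration for Fisher p
values to 1e-10; brute-force membership, reciprocal-overlap and per-base
coverage checks for the set/interval operations). What it does not show:
performance on real read-level artifacts, caller error correlation,
normalization differences between real indel representations, or the
clinical validity of any label — those require the controlled-access
cohorts the methods were developed on.

## Problem sizes and runtime

The test suite runs the full pipeline on the 47-sample rule-coverage
roster and 6–12-patient random cohorts, checks the Fisher oracle on every
2×2 table with n ≤ 60 (grouped by the symmetry classes that leave the p
value invariant) and on 200 random tables, and exercises the interval
oracles at 1,000 variants / 200 segments — sizes chosen so the whole
suite completes in a few minutes on one CPU while still covering every
rule branch and overlap configuration.

## Known limitations

* Consensus assumes pre-normalized, left-aligned indels; discordant
  representations across callers would be missed.
* The gap between the exclusive and non-exclusive ependymoma tiers means
  a sample with abundant non-exclusive evidence but one exclusive marker
  follows the exclusive tier unconditionally, as published.
* Arm assignment parses band names (p/q prefix); exotic band
  nomenclature would need explicit mapping.
* The bundled hotspot and driver lists are synthetic stand-ins; analyses
  of real cohorts should substitute the curated references.
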