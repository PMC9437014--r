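---
title: "Methods: integrated genetic and biochemical triage for IMD gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated genetic and biochemical triage for IMD gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpanel)
```

## The diagnostic problem

Inherited metabolic disorders (IMDs) are individually rare but collectively
common, frequently treatable, and notoriously slow to diagnose. A targeted
gene panel covering the recurrent and treatable metabolic diseases, combined
with *reflex* biochemical testing — automatically measuring the relevant
enzyme activity or biomarker whenever a candidate genotype of matching
inheritance is found — shortens that path: the biochemical phenotype either
corroborates the genotype (supporting a pathogenic classification) or
contradicts it (excluding candidates, or revealing that two heterozygous
variants sit on the same allele). `metpanel` implements this workflow as a
deterministic, testable pipeline: variant triage, inheritance matching,
reflex assay interpretation, five-class classification, and case reporting,
plus a seeded cohort simulator so that every stage can be exercised end to
end without patient data.

## The panel knowledge base

A panel configuration (YAML; JSON schema in `inst/schema/`) declares:

* **Gene entries** — one per (gene, disease): transcript, exon count,
  inheritance mode (`AR`, `AD`, `XL`), disease, one of 18 metabolic
  categories, a treatability flag, and linked assay ids. A gene may carry
  several disease entries (e.g. distinct AR and AD phenotypes); each entry
  is matched independently.
* **Assay records** — 25 in the packaged panel: enzyme activities (always
  pathologic *below* their reference interval) and biomarkers (pathologic
  in either direction, e.g. lyso-Gb1 accumulating in Gaucher disease,
  ceruloplasmin depressed in Wilson disease).
* **Thresholds** — the numeric cut-offs of the workflow, with defaults:
  SNV rarity gate MAF < 1% (external and internal healthy-cohort
  frequencies combined by maximum, absent values counting as 0), CNV gate
  MAF < 2%, dbscSNV ADA/RF splice cut-off 0.6, minimum heterozygous-CNV
  span 3 exons ("more than 2"), and the specimen QC gate of 99.5% target
  coverage at ≥ 20×.

The packaged configuration is a *surrogate*: the true proprietary panel
content is not public. It contains 199 real gene entries — every gene
needed by the worked examples carries its usual inheritance mode and
plausible assay links — padded with 7 entries marked `placeholder: true`
to reach the full 206 symbols. Reference intervals are synthetic but
realistically scaled; nothing downstream depends on placeholder biology,
and tests never touch it.

## Variant triage

SNVs/indels are retained when not previously classified (likely) benign
and at least one criterion fires: (1) prior internal P/LP/VUS
classification; (2) previously unclassified; (3) rare with high/moderate
predicted impact; (4) externally asserted disease-causing; (5) both splice
scores above 0.6. Two readings required a decision:

* **Criterion (2) is rarity-gated.** Taken literally, "unclassified"
  retains every novel common benign variant; in a semi-automated workflow
  the human reviewer absorbs those, but an automated tool needs a
  defensible gate. We apply the same rarity test as criterion (3), without
  the impact requirement; `c2_literal = TRUE` restores the literal reading.
* **Benign exclusion dominates.** A prior LB/B classification discards the
  variant even when external databases assert it disease-causing — the
  internal curation is the more recent, reviewed judgement.

CNVs are retained when rare and either homozygous deletions (any span) or
heterozygous deletions/duplications spanning ≥ 3 exons. The span cut-off
is a *screening* heuristic reflecting the detection algorithm's validated
sensitivity for ≥ 3-exon events; a CNV already confirmed by qPCR, MLPA or
CMA (`confirmed_by` set) is therefore retained regardless of span (the MAF
gate still applies). This is what allows a confirmed two-exon deletion —
e.g. exons 2–3 of *DBT* in the maple-syrup-urine-disease worked example —
to contribute to a diagnosis. Retained heterozygous CNVs are always
flagged for orthogonal confirmation; homozygous deletions need none.
Multi-gene CNVs are retained when any constituent panel gene passes and
mark the case *syndromic*: a contiguous-gene dosage lesion (e.g. a
whole-arm trisomy) is reportable on one heterozygous copy irrespective of
the single-disease inheritance mode.

## Inheritance matching and reflex testing

Alleles are counted over all retained variants of a gene entry: hom = 2,
each het = 1, hemi = 1; SNV and CNV alleles combine, so a heterozygous SNV
plus a heterozygous exon deletion forms a potential compound heterozygote
of unknown phase (`comp_het_phase_unknown`). AR requires 2 alleles, AD
requires 1, XL requires a hemizygous male or homozygous female; X-linked
entries carry a per-disease `female_het_reportable` flag (default off,
set e.g. for *GLA* and *OTC*) rather than a rigid XLR/XLD split, which the
workflow does not need. A hemizygous call in a female, or on an autosome,
is a data-consistency error. Single heterozygous AR candidates do not
trigger reflex testing by default (`reflex_single_het` overrides, for
laboratories that do work up carrier-level findings).

Each eligible gene entry orders its linked assays once (shared assays are
deduplicated). A measurement is called against the reference bound in the
assay's pathologic direction with a symmetric grey zone of ±10% of that
bound (configurable): beyond the bound by more than the band →
*pathologic*; on the safe side by more than the band → *normal*; inside —
including exactly at the bound — *borderline*. The grey zone exists
because "borderline" is clinically real but rarely given a numeric
definition; 10% is a conservative default for DBS fluorimetry/LC-MS
assays, and the calls are monotone in the measured value by construction.

## Classification and reporting

The pre-biochemistry base class uses a deliberately small, transparent
rule subset: curated assertions are honored; exon deletions are P and
duplications LP; a rare LoF variant in an LoF-mechanism gene is LP;
everything else retained by triage starts as VUS. The full 28-criterion
ACMG apparatus is out of scope — the goal is a faithful, auditable
automatic stand-in for the expert review step.

Biochemical evidence then moves classifications at most one step:

* **Pathologic** → functional evidence for; VUS upgrade to LP unless the
  variant carries contradictory evidence (it stays VUS — these are the
  reported inconclusive cases with pathologic biochemistry).
* **Normal enzyme activity** → the gene product demonstrably works; phase
  of a compound heterozygote is inferred *cis*, and non-curated candidates
  become non-reportable. Curated P/LP findings are never silently dropped:
  they stay in the report flagged `biochem_discordant`, and the case is
  issued *unclear* rather than positive.
* **Normal biomarker only** → weaker, indirect evidence: a VUS stays
  reportable with recommendations `parental_testing` and
  `biomarker_followup`. This asymmetry between direct enzyme readout and
  downstream biomarker is what separates the two narrated
  two-missense-VUS patterns: normal *TPP1* enzyme excludes (cis), normal
  lyso-Gb1 with *PSAP* variants does not.
* **Borderline** → no class change, `biomarker_followup` recommended.

Reports are *positive* (a reportable P/LP finding with
inheritance-consistent genotype and no contradicting normal result),
*unclear* (best reportable finding VUS, or a discordant P/LP), or
*negative*. Single-het P/LP findings in AR diseases are carrier findings:
they move to the report's `excluded` audit trail (reason `carrier_only`)
and do not set the status, whereas a single-het VUS is "at least
partially" phenotype-compatible and reports unclear — mirroring how such
cases are communicated clinically. Findings are ordered by class, then
genotype, then gene symbol, and JSON report output is byte-stable. The
decision table is total (an enumerated test covers every combination of
class × biochemical call × eligibility × reportability) and enforces two
structural zeros in the biochemistry-by-status cross-tabulation:
(pathologic, negative) and (normal, positive) are impossible for any
parameter setting.

## The cohort simulator

`generate_cohort()` draws fully reproducible cohorts with ground truth.
Its defaults are the emulated study conditions, fixed once:

* region mix Africa 33%, Asia 30%, Europe 24%, Latin America 6%,
  Middle East 6%, North America 1%;
* consanguinity unknown for 50% of cases and 61% among known (≈ 30.4% of
  all cases); family history unknown for 76.7%, 84.4% positive among known;
* diagnosable prevalence (`true_positive_rate`) 0.37; 94% of causal
  lesions SNVs; 85% of CNV lesions deletions (forced to 0-copy deletions
  on the male X, where a single copy exists);
* a disease spectrum peaking at Gaucher disease, Niemann-Pick A/B, MPS I,
  phenylketonuria and Wilson disease with a long tail over the panel;
* assay sensitivity and specificity 1.0 by default (the ISO-accredited
  DBS assays are treated as definitive; both are parameters);
* among non-diagnosable cases: 24% carry an uncertain VUS-level finding
  (single-het VUS, biomarker-normal compound-het VUS, or
  conflicting-evidence VUS with pathologic biochemistry), 0.8% carry a
  splice-score candidate excluded by a normal enzyme, and 30% of all cases
  carry an incidental common variant that triage must discard;
* onset documented for 10.2% of cases; onset ages, ages at testing and the
  onset-to-diagnosis gap are log-normal (gap mean ≈ 2 years, capped at
  20; onset mean ≈ 1 year) — the shapes are a modelling choice, exposed
  as code, since only summary statistics of such cohorts are ever printed.

Continuous annotations are rounded at generation (MAFs to 5 decimals,
scores to 3, ages to 2) so that the emitted plain-text fixtures (VCF, CNV
TSV, biochemistry TSV, metadata TSV per case) round-trip exactly through
the package's readers.

What the simulator deliberately does **not** model: sequencing reads and
coverage profiles, annotation errors, population structure in allele
frequencies, phenotype (HPO) content, multi-gene CNVs, and
mitochondrial/Y variants. Passing tests therefore demonstrate the
*decision logic* under clean annotations, not robustness to noisy
upstream calling.

## Numerical and degenerate-input choices

* Rounding of printed percentages is half-up at the printed precision
  (`percent()`), the convention of clinical summary tables; a small
  epsilon guards against binary-representation artefacts at exact halves.
* All rarity gates are strict inequalities (`< 1%`, `< 2%`, `> 0.6`,
  `> 2 exons`), matching their verbal definitions; boundary tests pin the
  semantics at ±ε.
* Absent annotations are `NA`, never 0; they count as 0 only inside the
  explicit MAF maxima.
* Duplicate input variants are deduplicated by
  (chrom, pos, ref, alt, zygosity) before triage; duplicate assay orders
  collapse.
* Empty inputs are valid everywhere: a case with no variants yields a
  well-formed negative report; empty report sets yield all-zero tables.
* Specimen QC is evaluated per case and recorded on the report; the
  pipeline still classifies a failing specimen (the gate is a laboratory
  re-run trigger, not a reporting rule).

## Problem sizes

The shipped test-suite and acceptance runs use cohorts of 2,000–5,000
simulated cases for the stochastic properties (yield recovery against
exact binomial quantiles, cross-tab structural zeros, goodness-of-fit of
region and disease frequencies at α = 0.01) and a 3,720-case cohort for
the end-to-end summary run — sizes at which the binomial intervals are
tight enough to be meaningful while a full run stays interactive.

## Known limitations

* The ACMG rule subset cannot distinguish LP from P for novel LoF
  variants, and never outputs LB/B for novel variants — triage has already
  removed them.
* Phenotype overlap is recorded but not scored; "explaining the
  phenotype" is approximated by an eligible genotype in a panel disease.
* Phase inference uses biochemistry only; parental segregation results
  are accepted as evidence input but never computed.
* The surrogate panel's treatability flags and reference intervals are
  configuration choices, not curated clinical content; cohort-level
  treatable fractions computed on simulated data reflect those flags.
* XL inheritance is modelled with a single reportability flag for
  heterozygous females; X-inactivation biology is out of scope.
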