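---
title: "Methods: secondary-findings triage in population cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secondary-findings triage in population cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sftriage)
```

# The problem

Population sequencing programs screen the ACMG secondary-findings gene
catalog (v3.1, 78 genes) for variants a clinician should act on even
though they were not the reason for sequencing. Turning a multisample VCF
into defensible per-participant findings requires a chain of small,
individually unremarkable decisions — allele decomposition, variant
normalization, transcript choice, evidence thresholds, inheritance-aware
reporting — whose composition is easy to get subtly wrong and hard to
audit after the fact. This package implements that chain as a deterministic
rules engine with an explicit reason trail per variant, and pairs it with
a cohort simulator so every branch is testable without access to any
restricted dataset.

# The classification model

Variants surviving a strict cohort rarity gate (minor allele frequency
< 2%, computed from the cohort's own AC/AN after decomposition) and not
annotated Benign/Likely Benign are assigned to exactly one list, in fixed
precedence order:

| list | rule |
|------|------|
| P1 | ClinVar P/LP **and** HGMD DM |
| P2 | ClinVar P/LP, no HGMD entry, review stars ≥ 2 |
| LP1 | LOF consequence (nonsense, frameshift, splice site, in-frame indel), PVS1 *Very Strong*, impact HIGH, cohort and gnomAD MAF < 0.1%, LOF-mechanism gene |
| LP2 | missense; ClinVar VUS/conflicting or novel; cohort and gnomAD MAF < 0.1%; > 1 carrier; REVEL > 0.7; cancer/cardiovascular gene; carriers show matching disease evidence; external verdict P/LP |
| pVUS | as LP2 but the external verdict is not P/LP |

Everything else is `rejected` (benign or common) or `unclassified`. Three
interactions deserve spelling out because they are where independent
implementations diverge:

* **ClinVar/HGMD conflicts.** A ClinVar P/LP variant with a non-DM HGMD
  entry is excluded from *both* P sub-lists and is not forwarded to the
  LP/pVUS rules (those require VUS/conflicting/novel ClinVar status, and
  we treat the conflict as disqualifying for LP1 as well); it ends
  `unclassified`. A ClinVar P/LP variant with *no* HGMD entry and fewer
  than two stars, by contrast, falls through and may still qualify as LP1
  on its own merits.
* **Novelty** means absent from all four of dbSNP, gnomAD, ClinVar and
  HGMD. A variant absent from ClinVar but present in dbSNP is neither a
  reported VUS nor novel, so it is ineligible for LP2/pVUS.
* **gnomAD-absent counts as rare.** Treating a missing gnomAD frequency as
  failing the rarity filter would exclude every novel variant and
  contradict the LP2 definition, which explicitly includes them.

All threshold comparisons are strict in the direction stated: `< 2%`,
`< 0.1%`, `> 0.7`, "more than one carrier", stars `>= 2`. REVEL exactly
0.7 therefore does not qualify, and MAF exactly 0.1% does not pass. The
thresholds live in `sft_thresholds()` and are echoed into every run
report; they are parameters of record, not knobs to tune per run.

## The phenotype-evidence gate

LP2/pVUS require that carriers show disease evidence matching the gene's
category: at least two carriers with cardiovascular or
hypercholesterolemia evidence for cardiovascular genes, at least one
carrier with personal/family cancer evidence for cancer genes (the
stricter of two possible readings — two *evidenced* carriers rather than
two carriers of whom any is evidenced — switchable via
`select_candidates(rule=)`). This gate depends only on genotypes,
phenotypes and the catalog, never on classification output, so the
apparent circularity (classification needs evidence, evidence needs
carriers of classified variants) dissolves: candidate evidence flags are
computed first and fed into the classifier.

Evidence derivation is a logical OR over questionnaire/laboratory
components: CVD = abnormal ECG, self-reported heart disease,
revascularization, or parental/sibling heart disease; cancer = personal or
parental cancer history, tumor surgery, or screening below the
sex-specific recommended age; familial hypercholesterolemia = diagnosis or
LDL at/above a threshold (default 4.9 mmol/L, the conventional severe
hypercholesterolemia cut; the boundary is inclusive and documented because
the source criteria say only "high LDL").

# Reportability and prevalence

ACMG reporting is inheritance-aware: P/LP variants in dominant or
semidominant genes are reportable in heterozygotes; recessive genes only
for biallelic participants. Without phase information, two distinct
heterozygous P/LP variants in the same gene are treated as biallelic and
flagged `phase_unknown` — the same compromise the underlying cohort data
forces. Heterozygous single-variant carriers in recessive genes are
`carrier_only`: not reportable under ACMG, but tallied separately because
in consanguineous populations their reproductive risk is the headline
finding. pVUS is never reportable. X-linked genes are treated like
dominant ones; no hemizygous logic is modeled (and none of the planted
test data exercises it).

Prevalence uses the one-proportion z-interval (Wald),
`p ± z·sqrt(p(1−p)/n)` clamped to [0, 1], because that is the named test
of record for such cohort frequencies; a Wilson score interval
(`prop.test` without continuity correction) is available where small
numerators make Wald coverage poor. Percentages print with half-up
rounding by default; a truncation mode exists because published tables mix
both conventions (for instance a variant share printed as 57% where 87/151
rounds to 58%), and the formatter, not the counts, absorbs that
inconsistency.

# Association testing

Candidate LP2/pVUS variants are tested with a two-sided Fisher exact test
on the carrier × evidence 2×2 table over phenotyped participants. The
p-value is the sum of hypergeometric probabilities no larger than the
observed table's (with the customary 1 + 1e−7 tie tolerance); the odds
ratio is the conditional maximum-likelihood estimate with its exact CI
from `fisher.test`, matching the statistical environment such analyses
standardize on — a deliberate choice over the sample cross-product OR
(available as an option), because zero-cell tables then yield a finite
informative bound on one side rather than 0/∞, which is how published
one-bound CIs like "OR = 117.8, 95% CI = 1.5" arise. Tables with a zero
margin are returned as `untestable`, never silently as p = 1. Raw
p-values are starred; a Benjamini–Hochberg column is emitted alongside for
transparency but never alters the stars, mirroring screening practice.

# Numerical and representational choices

* **Normalization** trims shared trailing bases, left-aligns indels
  through repeat context by extending with reference bases whenever an
  allele would empty, then trims shared leading bases to the single
  anchor. The result is the unique minimal representation at the smallest
  position; the operation is idempotent and is tested against an
  exhaustive search over all equivalent representations in a window.
  Without a reference sequence, trimming still happens but indels are not
  shifted (warning) — left-alignment needs flanking bases.
* **Decomposition** emits one biallelic record per ALT; a sample's dosage
  for ALT k counts its alleles equal to k, other ALT alleles counting as
  reference for that record. AN counts all called alleles at the original
  site, keeping MAF comparable across the decomposed records. Spanning
  deletions (`*`) are dropped and logged.
* **Missingness.** A genotype with any missing allele is treated as wholly
  missing, so AN = 2 × (called samples) holds exactly; a site with AN = 0
  is dropped and logged. Half-calls like `./1` are a convention no
  upstream source specifies; treating them as missing is the conservative
  choice and is stated here rather than buried in code.
* **Transcript selection** is a pure, order-insensitive function: MANE if
  flagged (two MANE rows for one variant is a data error), else best
  consequence rank from a severity table frozen into the package (so
  results cannot drift with an external release), then longest transcript,
  then smallest transcript id. "Longest" is whatever length the annotation
  producer supplies — CDS versus full transcript is their call, not ours.
* **Ploidy.** Autosomal diploid throughout; haploid calls are doubled with
  a warning.

# What the simulator emulates — and what it does not

`sim_config()` defines the study conditions: 2000 participants by default,
inbreeding coefficient F = 0.0625 (the first-cousin-offspring value, a
realistic cohort-wide figure for a population where a majority of parents
are consanguineous), genotypes drawn per variant from
q² + Fq(1−q) / 2q(1−q)(1−F) / (1−q)² + Fq(1−q), and 40 planted variants
covering every truth class plus adversarial near-misses (each one field
away from a rule boundary: impact MODERATE, PVS1 Moderate, REVEL 0.65 and
exactly 0.70, a single carrier, a ClinVar/HGMD conflict, an
evidence-suppressed missense, a non-LOF-mechanism gene). Rare truth
classes plant their carriers deterministically within allele-count bounds
that keep the class's rarity guarantee at any seed; common/benign classes
draw from the inbreeding-adjusted Hardy–Weinberg model. Phenotypes give
each evidence domain a baseline prevalence p₀ (CVD 0.10, cancer 0.05, FH
0.05) and carriers of an OR-planted variant the odds p₀/(1−p₀)·OR.

Deliberate unrealism, so that passing tests mean what they claim:
baseline LDL is truncated below the diagnostic threshold (the composite FH
flag then has exactly prevalence p₀ among non-carriers); LP2/pVUS variants
force their minimum number of evidenced carriers so truth-label recovery
is deterministic rather than probabilistic (the odds-ratio recovery study
uses a separate configuration without forcing); variants are drawn without
linkage disequilibrium; a single cohort-wide F replaces pedigree
structure; no sequencing error or quality model exists beyond planted
non-PASS decoys. Consequently the end-to-end tests demonstrate rule
correctness and plumbing integrity on data whose generative model is
known — they say nothing about annotation quality, caller error modes, or
population stratification in real cohorts.

A note on small cohorts: at 500 participants (1000 alleles) no variant can
sit strictly below the 0.1% rarity ceiling, so the demonstration bundle
plants only P/benign/common classes; the rare LP/pVUS classes need the
full-size configuration. This is arithmetic, not a tuning choice.

# Problem sizes used by the test suite

Chosen as the smallest sizes at which each check is sharp: the
classification oracle sweep covers ~42,000 evidence combinations; the
Fisher oracle enumerates every 2×2 table with margins ≤ 30 and anchors a
200-table subsample against `fisher.test`; normalization checks 1000
seeded random indels in repeat contexts against exhaustive equivalence
search; the inbreeding simulator is checked at n = 100,000 per (q, F)
pair within 3 binomial standard deviations; planted-OR coverage uses 200
replicates at n = 5000 with ≥ 30 carriers; the end-to-end cohort is
n = 2000 with 40 planted variants.

# Known limitations

CNVs and structural variants are out of scope, as are re-derivations of
any upstream annotation (VEP consequences, PVS1 strength, REVEL, external
verdicts are inputs, with versions recorded as provenance only). The
compound-heterozygote rule is phase-unaware by design and will overcall
biallelic status when two variants are in cis. X-linked reportability is
simplified to dominant-like. The Wald interval undercovers for very small
numerators — use the Wilson option there. Association testing applies no
multiplicity correction to its star tiers (the BH column is advisory),
matching the screening character of the analysis rather than confirmatory
practice.
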