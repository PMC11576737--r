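# sftriage

Inheritance-aware triage of **secondary findings** — pathogenic variants in
medically actionable genes discovered incidentally in cohort sequencing —
for population-scale multisample VCFs, built around the ACMG SF v3.1
catalog of 78 actionable genes. It is written for groups running
whole-genome cohorts (in particular consanguineous populations, where
excess homozygosity makes recessive actionable variants matter) who need a
reproducible, testable rules engine rather than a one-off analysis script.

## What it computes

Starting from a multisample VCF, a per-transcript annotation table
(ClinVar-style significance and review stars, HGMD-style class, VEP-style
consequence/impact/MANE, REVEL, PVS1 strength, an external combinatory
verdict, gnomAD-style AF), the gene catalog and an optional participant
phenotype table, the pipeline:

1. trims the VCF to catalog genes, keeps `FILTER = PASS` sites, decomposes
   multi-allelic records, and normalizes each variant to its minimal
   left-aligned representation;
2. computes cohort allele statistics (AC, AN, MAF = min(AC/AN, 1 − AC/AN))
   and applies a strict global rarity gate (cohort MAF < 2%);
3. selects one transcript per variant: MANE if flagged, else the most
   severe consequence by the packaged severity ranking, ties broken by
   transcript length, then lexicographic transcript id;
4. assigns each variant to exactly one list:
   - **P1** — ClinVar P/LP and HGMD DM (conflicting ClinVar/HGMD
     annotations are excluded from P entirely);
   - **P2** — ClinVar P/LP, no HGMD entry, ≥ 2 review gold stars;
   - **LP1** — rare (cohort and gnomAD MAF < 0.1%) high-impact
     loss-of-function variants with PVS1 *Very Strong*, in genes where LOF
     is a known disease mechanism;
   - **LP2** — rare missense variants (ClinVar VUS/conflicting or novel)
     with REVEL > 0.7, more than one carrier, matching cardiovascular or
     cancer evidence among carriers, and an external P/LP verdict;
   - **pVUS** — as LP2 but lacking the external P/LP verdict;
   - `rejected` (benign or common) or `unclassified` otherwise;
5. identifies genotype-positive participants (GPPs) and applies the ACMG
   reportability rule: dominant/semidominant carriers are reportable;
   recessive genes only for homozygotes or compound heterozygotes
   (phase-unaware, flagged); heterozygous single-variant carriers in
   recessive genes are flagged `carrier_only`;
6. estimates prevalences with the one-proportion z-interval
   p ± z·√(p(1−p)/n) (Wilson score optional) and summarizes variants and
   GPPs per gene and disease category;
7. tests carrier–phenotype association for candidate LP2/pVUS variants
   with a two-sided Fisher exact test, reporting the conditional-MLE odds
   ratio with its exact CI and significance stars
   (\*p<0.05, \*\*p<0.01, \*\*\*p<0.001, \*\*\*\*p<0.0001).

A seeded simulator (`sim_config()`, `write_fixture_bundle()`) generates
complete synthetic cohorts — genotypes under Hardy–Weinberg with an
inbreeding coefficient F (hom-alt probability q² + Fq(1−q)), annotations
spanning every classification branch including one-field-off near-misses,
and phenotypes with planted carrier odds ratios — so the whole pipeline is
exercisable without access-restricted cohort data.

## Worked example

```r
library(sftriage)
bundle <- write_fixture_bundle(demo_config(seed = 42L), "demo")
report <- run_pipeline("demo/config.yaml", out_dir = "demo/out")
print(report)
#> Secondary-findings triage report
#>   cohort: 500 participants
#>   variants: P1 4 | P2 2 | LP1 0 | LP2 0 | pVUS 0 | rejected 6 | unclassified 0
#>   distinct GPPs: 17 (reportable 10, AR carrier-only 7)
#>   reportable prevalence: 10 / 500 = 2% (95% CI 0.77-3.23%, wald)
```

Of the 12 planted variants, the 6 pathogenic ones (4 P1, 2 P2) are
recovered and the benign/common ones rejected; 17 participants carry at
least one listed variant, of whom 10 meet the ACMG reporting bar (dominant
carriers plus one recessive homozygote) and 7 are heterozygous carriers of
recessive-disease alleles — reported separately because they matter for
reproductive counselling but not for ACMG disclosure. Prevalence
arithmetic works the same on real tallies:

```r
print(prevalence(509, 14392))
#> 509 / 14392 = 3.5% (95% CI 3.23-3.84%, wald)
```

The full-size default configuration (`sim_config()`, n = 2000, 40 planted
variants) exercises every branch: multi-allelic sites, spanning-deletion
alleles, padded and right-shifted indel representations, a compound
heterozygote, adversarial near-misses, and off-gene / non-PASS decoys.

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","sftriage",package="sftriage"))') \
    simulate --out demo --seed 42 --demo
```

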