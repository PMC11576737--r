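Package: sftriage
Title: Secondary-Findings Triage of Actionable Variants in Population Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inheritance-aware triage of cohort variants in the ACMG
    secondary-findings (SF v3.1) actionable-gene catalog. Reads a
    multisample VCF, decomposes multi-allelic sites, left-aligns and
    trims variant representations, selects one transcript annotation per
    variant (MANE, then consequence severity, then length), and assigns
    each variant to a Pathogenic (P1/P2), Likely Pathogenic (LP1/LP2) or
    pVUS list using ClinVar-style significance and review stars,
    HGMD-style classes, PVS1 strength, REVEL scores and an external
    combinatory verdict. Counts genotype-positive participants, applies
    ACMG reportability rules (dominant carriers; biallelic recessive),
    estimates carrier prevalence with one-proportion confidence
    intervals, and tests carrier-phenotype association with Fisher's
    exact test. A seeded simulator generates self-consistent synthetic
    cohorts (genotypes with excess homozygosity under an inbreeding
    coefficient, annotations spanning every classification branch, and
    phenotypes with planted odds ratios) so the whole pipeline is
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
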