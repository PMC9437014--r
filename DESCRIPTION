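Package: metpanel
Title: Integrated Genetic and Biochemical Triage for Inherited Metabolic
    Disorder Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated diagnostic workflow for inherited metabolic
    disorders (IMDs) on a targeted next-generation-sequencing gene panel.
    Implements the SNV filter cascade and exon-level CNV selection rules
    against a panel knowledge base (genes, diseases, inheritance modes,
    linked biochemical assays), inheritance-aware reflex enzymatic and
    biomarker testing, biochemistry-informed five-class (ACMG-style)
    variant classification, and positive/unclear/negative case reporting.
    Ships a seeded synthetic-cohort simulator with ground truth and
    cohort-level analytics (diagnostic yield by stratum, variant-type
    breakdowns, biochemistry cross-tabulation, diagnostic-odyssey
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
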