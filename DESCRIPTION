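Package: couplescreen
Title: Carrier Screening of Couples for Autosomal Recessive Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-panel and exome-based carrier screening for couples at
    increased risk for severe autosomal recessive disease. Filters annotated
    parental variants to rare, potentially deleterious candidates, intersects
    the two partners at gene level to nominate recessive risk genes (shared
    heterozygous variants or potential compound heterozygotes in offspring),
    classifies variants with the ACMG/AMP evidence-combining rules, decides
    eligibility for prenatal or preimplantation genetic diagnosis, confirms
    candidates by cosegregation in affected children, and reports Mendelian
    recurrence risks. Includes a deterministic 13-couple demonstration cohort
    and a consanguinity-aware couple simulator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
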