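# couplescreen

Carrier screening of couples at increased risk for severe autosomal
recessive (AR) disease. Many lethal childhood disorders are recessive: both
parents are healthy heterozygous carriers, the recurrence risk is 25% in
every pregnancy, and affected children often die before a molecular
diagnosis is made — leaving the couple without the biallelic genotype that
prenatal diagnosis (PND) or preimplantation genetic diagnosis (PGD)
requires. `couplescreen` implements the *parent-first* strategy for such
couples: sequence the two healthy partners, and look for genes in which
both carry a qualifying heterozygous variant.

The package is aimed at diagnostic/bioinformatics teams evaluating this
screening design: it ships the complete decision pipeline plus a synthetic
cohort and a consanguinity-aware simulator so every stage is testable
without access to patient data.

## The screen

For each partner, annotated variants are filtered to
*rare* — every reported population allele frequency (dbSNP, ESP, ExAC)
below 1%, or an HGMD/ClinVar disease-causing assertion; absence from all
databases counts as rare —
*of qualifying consequence* — non-synonymous coding or splice-site,
including small indels and exon-level deletions — and
*predicted deleterious* — loss-of-function outright, otherwise CADD ≥ 20
or at least two damaging in-silico votes.

The couple's retained heterozygous variants are then intersected at gene
level. A gene is nominated when

- both partners carry the **identical** variant (normalized
  `chrom:pos:ref:alt`, or `gene:exon` for exon deletions): the offspring can
  be homozygous (`shared_hom`); or
- the partners carry **different** variants in the same gene: the offspring
  can be compound heterozygous, one allele from each parent, so trans phase
  holds by construction (`compound_het`).

Each candidate allele is classified on the five-tier scale by the ACMG/AMP
evidence-combining rules (PVS/PS/PM/PP vs BA/BS/BP codes; contradictions
and insufficient evidence → Class 3/VUS). PND/PGD eligibility requires
Class ≥ 4 on *both* alleles; Class 3–5 findings are reportable to the
couple. Where DNA from an affected child or fetus exists, candidates are
checked for cosegregation (affected child homozygous / carrying both
alleles → confirmed). Mendelian recurrence risks are exact: 25% for AR with
two carrier parents; 50% for a male pregnancy with a carrier mother of an
X-linked condition.

The simulator models background variant sharing between partners with
kinship coefficient φ: each maternal variant of population frequency *p* is
also carried by the partner with probability φ + (1 − φ)·2p(1 − p), so the
expected number of shared genes is n·[φ + (1 − φ)·Σ w·2p(1 − p)] plus any
planted candidates — about 4 shared genes for a first-cousin couple
(φ = 1/16) with 64 effectively private rare variants.

## Worked example

Build the bundled 13-couple demonstration cohort (reconstructed from
published per-family results; 8 consanguineous, 5 non-consanguineous
couples) and screen one couple:

```r
library(couplescreen)
dir <- tempfile()
build_table1_fixture(dir)
rep <- screen_couple_files(file.path(dir, "family02", "mother.vcf"),
                           file.path(dir, "family02", "father.vcf"),
                           couple_id = "family02")
rep
#> Couple screening report: family02 (wes mode, consanguinity: unknown)
#>   COQ2     compound_het Class 5/4  eligible for PND/PGD  coseg: unavailable
#>   tier: class45_match
```

The mother carries a COQ2 frameshift (Class 5, pathogenic), the father a
COQ2 missense variant (Class 4, likely pathogenic): their child can be
compound heterozygous for primary coenzyme-Q10 deficiency, and because both
alleles are Class ≥ 4 the couple is eligible for prenatal/preimplantation
diagnosis. Screening the whole cohort:

```r
res <- run_cohort(dir)
res$summary
#> Cohort of 13 couples
#>   likely causative (Class 4/5, eligible):  5/13 (38%)
#>   novel candidate (Class 3, reportable):   2/13 (15%)
#>   no finding:                              6/13 (46%)
#>   confirmed in an affected child:          4
```

Five couples get an actionable Class-4/5 candidate, two get a reportable
Class-3 candidate in a gene without an established disease entry, and in
four families the candidate genotype is confirmed in an affected child
(homozygous CTSD, ACADVL and PALLD; compound-heterozygous APAF1).

Recurrence risks for counseling:

```r
recurrence_risk("AR", both_parents_carriers = TRUE)                    # 0.25
recurrence_risk("XL_maternal", fetus_sex = "male", mother_carrier = TRUE) # 0.5
```

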