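---
title: "Parent-first carrier screening for severe recessive disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-first carrier screening for severe recessive disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplescreen)
```

## The problem and the design

Couples who have lost one or more children (or pregnancies) to a severe
undiagnosed condition frequently face an autosomal recessive (AR) disease:
both partners are healthy heterozygous carriers and every future pregnancy
carries a 25% risk. Prenatal diagnosis (PND) and preimplantation genetic
diagnosis (PGD) require a firmly established biallelic genotype — but DNA
from the affected child is often unavailable by the time the family seeks
counseling.

The *parent-first* design sequenced here inverts the usual diagnostic
route: sequence the two healthy parents, filter each partner's variants to
rare, potentially deleterious heterozygous calls, and nominate genes in
which **both** partners carry a qualifying variant. Such a gene predicts a
recessive risk genotype in offspring by construction:

* the identical variant in both partners → the child can be **homozygous**;
* different variants in the same gene → the child can be **compound
  heterozygous**, necessarily in trans because each parent contributes one
  allele — no read-based phasing is ever needed.

This design cannot see de novo dominant events, X-linked variants
transmitted through the mother are a separate (maternal-only) report, and
the yield depends heavily on consanguinity, which raises the background
rate of shared heterozygous variants.

## The filter cascade

Each parent's records pass three predicates (`filter_parent_variants()`);
all three must hold and the call must be heterozygous:

1. **Rarity** (`is_rare`): every population allele frequency *present*
   among dbSNP/ESP/ExAC is `< maf_threshold`, **or** the variant carries an
   HGMD/ClinVar disease-causing assertion (the assertion overrides
   frequency — known pathogenic founder alleles may exceed 1%). The
   frequency test is conjunctive over *present* sources: a variant common
   in any one database is excluded even if absent from the others, while a
   variant listed nowhere is retained — absence from databases is exactly
   how novel pathogenic alleles present. Missingness is therefore encoded
   as absence (`NA`), never as 0.
2. **Consequence** (`is_candidate_consequence`): non-synonymous coding or
   splice-site classes, including small indels, plus exon-level deletions.
3. **Deleteriousness** (`is_predicted_deleterious`): nonsense, frameshift
   and exon-deletion events qualify outright (loss-of-function shortcut —
   a frameshift with no CADD score must not be discarded); otherwise
   CADD ≥ `cadd_cutoff` or at least `min_tool_votes` damaging calls among
   SIFT/PolyPhen/splice prediction.

Defaults: `maf_threshold = 0.01` (the conventional carrier-screening
cutoff), `cadd_cutoff = 20` (phred scale: top 1% of possible
substitutions; every retained missense variant in the demonstration cohort
scores ≥ 23.1, so 20 is conservative for it), `min_tool_votes = 2`
(a single in-silico tool is weak evidence). All three are configuration
(`filter_params()`, YAML-loadable), not code.

Homozygous parental calls are excluded — the screen targets unaffected
carriers — but with a warning rather than silently, since a homozygous hit
in a severe-disease gene deserves a manual look. Both partners' variants
must pass the cascade independently before a gene can be nominated; a gene
where only one partner's variant survives is not reported (the stricter of
the two possible readings of the design).

## Candidate genes and classification

`match_couple()` intersects the two filtered sets at gene level under the
identity `chrom:pos:ref:alt` after normalization (`normalize_variant()`:
shared-base trimming plus left-alignment across repeat context, the
standard truncate-and-extend algorithm). HGVS strings are carried for
display only — they are transcript-relative, and the same physical variant
can legitimately print two different HGVS forms. Exon-level deletions match
by `(gene, exon)` label; two *different* exon deletions in one gene fall
through to the compound branch flagged low-confidence, since without
breakpoints they may be one allele.

Each candidate allele is classified 1–5 by the ACMG/AMP evidence-combining
rules (`combine_evidence()`): counts of very-strong/strong/moderate/
supporting pathogenic codes are weighed against stand-alone/strong/
supporting benign codes, with simultaneous pathogenic and benign matches
collapsing to Class 3 (uncertain), as does an empty evidence set. The
engine deliberately takes evidence codes as *input* (VCF `ACMG` INFO key
or a sidecar TSV): deriving codes from raw annotations is clinical
judgment, and the optional conveniences never override explicit codes.

Policy, applied per candidate:

* **eligible for PND/PGD**: both alleles Class ≥ 4;
* **reportable**: both alleles Class ≥ 3;
* couple tier: `class45_match` if any candidate is eligible, else
  `class3_candidate` if any candidate is reportable, else `no_finding`.

## Cosegregation and recurrence risk

Where material from children exists, `check_cosegregation()` compares each
child's genotype with the candidate's predicted risk genotype. One affected
child with the matching genotype suffices for confirmation (the design
regularly has exactly one testable sample); an *unaffected* child with the
risk genotype marks the candidate inconsistent; an affected child carrying
only one allele marks it carrier-only — the gene is not causal in that
child, which is itself informative. No affected child with material →
unavailable.

`recurrence_risk()` is Mendelian-exact: AR with two carrier parents →
0.25 regardless of fetal sex; maternally inherited X-linked with a carrier
mother → 0.5 for a male fetus, 0 for a female under full recessivity, and
0.25 marginally when sex is unknown (this last value is a package choice:
the counseling sources only state the male and female cases). De novo
mutation and germline mosaicism are ignored throughout, matching the
counseling framing.

## The demonstration cohort

`build_table1_fixture()` writes a fully deterministic 13-couple cohort
(8 consanguineous) reconstructed from published per-family screening
results: every printed variant with its transcript, HGVS, genotypes, CADD
score and class; child genotypes where printed; and per-family decoy
variants each engineered to fail **exactly one** filter predicate, so a
filtering regression is attributable to a named predicate. Points worth
knowing:

* Genomic coordinates are synthetic placeholders (gene-indexed spacing) —
  the source prints HGVS, not coordinates; the identity logic is
  coordinate-based and does not care.
* Evidence codes are *reconstructed* to reproduce the printed classes
  (e.g. a frameshift absent from databases: `{PVS1, PM2}` → Class 4); the
  source prints classes, not codes.
* One variant is described with two conflicting HGVS forms in different
  parts of the source; the per-family-table form is encoded and the
  manifest records the discrepancy rather than reconciling it.
* The cohort reproduces the published partition — 5 couples with eligible
  Class-4/5 candidates, 2 with Class-3 novel-candidate genes, 6 with no
  finding, 4 confirmed in an affected child — and `scripts/acceptance.R`
  recomputes exactly that from scratch.

## The simulator

`simulate_couple()` generates couples with known ground truth. Each of
`n_background_variants` maternal rare heterozygous variants (frequency
drawn from a configurable spectrum; every simulated variant passes the
filter cascade by construction) is shared identically by the partner with
probability φ + (1 − φ)·2p(1 − p): identity by descent at the kinship
coefficient φ, plus chance co-carriage at the heterozygote frequency.
Variants are independent — no linkage blocks — because the quantity of
interest is the *expected count* of shared genes, for which per-variant
independence is exact, not haplotype realism. The closed form
(`expected_shared_genes()`)

n·[φ + (1 − φ)·Σ w·2p(1 − p)] + planted candidates

gives 4.0 for φ = 1/16 (first cousins), n = 64, p → 0 — the regime of a
consanguineous exome screen, where a handful of shared genes per couple is
expected background. The defaults (n = 64, φ = 1/16, p = 0.001) encode
that regime; no parameter set is claimed to be any particular study's.
Kinship itself comes from standard path counting
(`kinship_coefficient()`): (1/2)^L per connecting loop, 1/16 for first
cousins, 1/8 for double first cousins.

What passing simulator-based tests shows: the pipeline recovers every
planted candidate and its false-positive rate equals the engineered
background-sharing rate. What it does not show: behaviour under realistic
exome-wide consequence/frequency spectra, annotation noise, or linked
variants — real data differ there, and the demonstration cohort (hand-built
edge cases) covers only the printed families.

## Numerical and interface choices

* Coordinates are 1-based VCF convention end to end; indels carry the
  anchor base. One convention everywhere avoids off-by-one identity
  failures at the matching step.
* The VCF writer emits INFO keys in a fixed order and fixed numeric
  formatting, so equal record sets are byte-identical on disk; the
  simulator and fixture builder are deterministic given a seed.
* Multi-allelic sites are split one record per alternate allele, zygosity
  per allele from its GT copy count.
* Normalization without reference context trims shared bases only (it
  cannot left-shift); with context it reaches the canonical leftmost
  representation, verified against a brute-force placement oracle.
* Ties among multiple candidates in one couple are broken by gene symbol
  order in reports; ranking beyond class/eligibility is presentation, not
  method.
* Verification scale, chosen so that each check is decisive at desk scale:
  the ACMG combiner is checked exhaustively against an independently coded
  rule table over all 256 evidence sets of up to four codes from a reduced
  vocabulary; the filter and matcher are checked against brute-force
  per-record/all-pairs oracles on 100–200-record random fixtures over
  several seeds; planted-candidate recovery runs over 100 seeds; and the
  shared-gene closed form is checked by a 2000-replicate Monte Carlo within
  three standard errors.

## Limitations

The screen inherits the design's blind spots: de novo dominant disease,
regulatory and deep-intronic variants, repeat expansions, and genes absent
from the panel in panel mode. Phenotype match — which real counseling
weighs alongside variant class — is not modeled; eligibility here is
class-based only. The ACMG engine implements the combining table, not the
full criterion-strength modulation debate. CNV support is limited to
whole-exon deletion/duplication labels, without breakpoint logic.
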