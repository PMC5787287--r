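# ---------------------------------------------------------------------------
# Demonstration cohort: 13 carrier couples (8 consanguineous, 5 not)
# reconstructed from a published targeted-NGS carrier screen. Variant
# descriptors (gene, transcript, HGVS, genotypes, CADD, class, child
# genotypes) follow the printed per-family results; genomic coordinates are
# synthetic placeholders (gene-indexed spacing on two contigs) because the
# publication prints HGVS only, and ACMG evidence codes are reconstructed so
# that the rule engine reproduces the printed classes. Families without a
# finding carry decoy variants, each designed to fail exactly one filter
# predicate.
# ---------------------------------------------------------------------------

FIXTURE_GENE_INDEX <- c(
  CTSD = 1, FTCD = 2, NAGA = 3, COQ2 = 4, ACADVL = 5, UNC13D = 6,
  BRAT1 = 7, PALLD = 8, APAF1 = 9,
  TTN = 20, OBSCN = 21, MUC16 = 22, PLEC = 23, AHNAK = 24, SYNE1 = 25,
  FLG = 26, DNAH5 = 27, USH2A = 28, LAMA5 = 29, RYR3 = 30)

fixture_pos <- function(gene, slot = 1L) {
  idx <- FIXTURE_GENE_INDEX[[gene]]
  if (is.null(idx)) stop("no synthetic coordinate for gene ", gene)
  as.integer(idx * 100000L + slot * 100L)
}

# One fixture variant, expanded to records for the carrying samples.
fx_var <- function(gene, carriers, ref, alt, consequence, kind,
                   transcript = "", hgvs_c = "", hgvs_p = "",
                   exon = NA_character_, cadd = NA_real_,
                   acmg = NA_character_, slot = 1L, chrom = "1",
                   maf_dbsnp = NA_real_, maf_esp = NA_real_,
                   maf_exac = NA_real_, sift_del = NA, pph2_dam = NA,
                   splice_dam = NA, zygosity = "het") {
  recs <- record_columns()
  for (s in carriers) {
    recs <- rbind(recs, variant_record(
      chrom = chrom, pos = fixture_pos(gene, slot), ref = ref, alt = alt,
      gene = gene, transcript = transcript, hgvs_c = hgvs_c,
      hgvs_p = hgvs_p, consequence = consequence, kind = kind, exon = exon,
      sample_id = s, zygosity = zygosity, maf_dbsnp = maf_dbsnp,
      maf_esp = maf_esp, maf_exac = maf_exac, cadd = cadd,
      sift_del = sift_del, pph2_dam = pph2_dam, splice_dam = splice_dam,
      acmg = acmg))
  }
  recs
}

# Decoy builders: each fails exactly one named predicate of the cascade.
decoy_common <- function(gene, slot = 9L) {          # fails is_rare
  fx_var(gene, c("mother", "father"), "A", "C", "missense", "snv",
         hgvs_c = "c.100A>C", cadd = 30, maf_exac = 0.05,
         sift_del = TRUE, pph2_dam = TRUE, slot = slot)
}
decoy_synonymous <- function(gene, slot = 8L) {      # fails consequence
  fx_var(gene, c("mother", "father"), "G", "A", "synonymous", "snv",
         hgvs_c = "c.300G>A", cadd = 25, slot = slot)
}
decoy_benign <- function(gene, slot = 7L) {          # fails deleteriousness
  fx_var(gene, c("mother", "father"), "T", "G", "missense", "snv",
         hgvs_c = "c.500T>G", cadd = 3, sift_del = FALSE,
         pph2_dam = FALSE, slot = slot)
}
decoy_single_parent <- function(gene, slot = 6L, parent = "mother") {
  fx_var(gene, parent, "C", "A", "missense", "snv",  # fails couple overlap
         hgvs_c = "c.700C>A", cadd = 28, sift_del = TRUE,
         pph2_dam = TRUE, slot = slot)
}
decoy_hom <- function(gene, slot = 5L, parent = "mother") {
  fx_var(gene, parent, "A", "T", "missense", "snv",  # fails zygosity (hom)
         hgvs_c = "c.900A>T", cadd = 28, zygosity = "hom", slot = slot)
}

standard_decoys <- function(genes = c("TTN", "OBSCN", "MUC16", "PLEC")) {
  rbind(decoy_common(genes[1]), decoy_synonymous(genes[2]),
        decoy_benign(genes[3]), decoy_single_parent(genes[4]))
}

#' Definitions of the 13-couple demonstration cohort
#'
#' Returns the in-memory definition of each family: consanguinity, parental
#' variant records (real findings plus per-predicate decoys), child
#' observations, and the expected screening outcome used by the manifest.
#'
#' @return named list of family definitions (`family01` ... `family13`).
#' @keywords internal
table1_families <- function() {
  fam <- list()

  # Family 1: first cousins; three deceased children with early epileptic
  # encephalopathy. Exome-tier screen: shared frameshift in CTSD (Class 4,
  # child homozygous), shared FTCD missense (Class 4, third child only
  # heterozygous -> FTCD not causal in that child), shared NAGA missense
  # kept as Class 3 and not used for prenatal testing.
  fam$family01 <- list(
    consanguinity = "first_cousins",
    wes = TRUE,
    parents = rbind(
      fx_var("CTSD", c("mother", "father"), "A", "AC", "frameshift",
             "indel", transcript = "NM_001909", hgvs_c = "c.268_269insC",
             hgvs_p = "p.(Gln90Profs*50)", acmg = "PVS1,PM2"),
      fx_var("FTCD", c("mother", "father"), "G", "A", "missense", "snv",
             transcript = "NM_001320412", hgvs_c = "c.530G>A",
             hgvs_p = "p.(Gly177Glu)", cadd = 25.8, acmg = "PS1,PM2"),
      fx_var("NAGA", c("mother", "father"), "G", "A", "missense", "snv",
             transcript = "NM_000262", hgvs_c = "c.973G>A",
             hgvs_p = "p.(Glu325Lys)", cadd = 24, acmg = "PM2,PP3"),
      standard_decoys()),
    children = data.frame(
      sample_id = c("child1", "child2", "child3"),
      affected = c(TRUE, TRUE, TRUE),
      sex = c("F", "M", "M"),
      material = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE),
    child_genotypes = rbind(
      fx_var("CTSD", "child3", "A", "AC", "frameshift", "indel",
             transcript = "NM_001909", hgvs_c = "c.268_269insC",
             zygosity = "hom"),
      fx_var("FTCD", "child3", "G", "A", "missense", "snv",
             transcript = "NM_001320412", hgvs_c = "c.530G>A",
             zygosity = "het"),
      fx_var("NAGA", "child3", "G", "A", "missense", "snv",
             transcript = "NM_000262", hgvs_c = "c.973G>A",
             zygosity = "het")),
    expected = list(tier = "class45_match", confirmed = TRUE,
                    genes = c("CTSD", "FTCD", "NAGA")))

  # Family 2: non-consanguineous; fatal congenital lactic acidosis.
  # Compound-heterozygous COQ2: maternal frameshift (Class 5), paternal
  # missense (Class 4). No material from the deceased child.
  fam$family02 <- list(
    consanguinity = "none",
    wes = FALSE,
    parents = rbind(
      fx_var("COQ2", "mother", "CT", "C", "frameshift", "indel",
             transcript = "NM_015697", hgvs_c = "c.1197delT",
             hgvs_p = "p.(Asn401Ilefs*15)", cadd = 23.7,
             acmg = "PVS1,PS3,PM2", slot = 1L),
      fx_var("COQ2", "father", "C", "T", "missense", "snv",
             transcript = "NM_015697", hgvs_c = "c.764C>T",
             hgvs_p = "p.(Pro255Leu)", cadd = 29, acmg = "PS1,PM2",
             slot = 2L),
      standard_decoys(c("AHNAK", "SYNE1", "FLG", "DNAH5"))),
    children = data.frame(sample_id = "child1", affected = TRUE,
                          sex = "F", material = FALSE,
                          stringsAsFactors = FALSE),
    child_genotypes = record_columns(),
    expected = list(tier = "class45_match", confirmed = FALSE,
                    genes = "COQ2"))

  # Family 3: first cousins; sudden infant death with hypertrophic
  # cardiomyopathy. Shared ACADVL missense (Class 4) confirmed homozygous
  # in the deceased son. (The source reports this variant with two
  # different HGVS descriptions; the per-family table form is used here.)
  fam$family03 <- list(
    consanguinity = "first_cousins",
    wes = FALSE,
    parents = rbind(
      fx_var("ACADVL", c("mother", "father"), "T", "C", "missense", "snv",
             transcript = "NM_001033859", hgvs_c = "c.1274T>C",
             hgvs_p = "p.(L425P)", cadd = 27.4, acmg = "PS3,PM2"),
      standard_decoys(c("USH2A", "LAMA5", "RYR3", "TTN"))),
    children = data.frame(sample_id = "child1", affected = TRUE,
                          sex = "M", material = TRUE,
                          stringsAsFactors = FALSE),
    child_genotypes = fx_var("ACADVL", "child1", "T", "C", "missense",
                             "snv", transcript = "NM_001033859",
                             hgvs_c = "c.1274T>C", zygosity = "hom"),
    expected = list(tier = "class45_match", confirmed = TRUE,
                    genes = "ACADVL"))

  # Family 4: first cousins; fatal hemophagocytic lymphohistiocytosis.
  # Shared UNC13D splice-donor variant (Class 4). No material from the
  # affected daughter; the healthy son is wildtype.
  fam$family04 <- list(
    consanguinity = "first_cousins",
    wes = FALSE,
    parents = rbind(
      fx_var("UNC13D", c("mother", "father"), "G", "T", "splice_site",
             "snv", transcript = "NM_199242", hgvs_c = "c.2447+1G>T",
             hgvs_p = "p.?", cadd = 27.4, splice_dam = TRUE,
             acmg = "PVS1,PM2"),
      standard_decoys(c("OBSCN", "PLEC", "MUC16", "SYNE1"))),
    children = data.frame(
      sample_id = c("child1", "child2"),
      affected = c(TRUE, FALSE),
      sex = c("F", "M"),
      material = c(FALSE, TRUE),
      stringsAsFactors = FALSE),
    child_genotypes = fx_var("UNC13D", "child2", "G", "T", "splice_site",
                             "snv", transcript = "NM_199242",
                             hgvs_c = "c.2447+1G>T", zygosity = "absent"),
    expected = list(tier = "class45_match", confirmed = FALSE,
                    genes = "UNC13D"))

  # Family 5: multiply consanguineous; lethal neurodegenerative disease.
  # Shared BRAT1 missense (Class 4); no DNA from the deceased child.
  fam$family05 <- list(
    consanguinity = "multiple_first_cousins",
    wes = FALSE,
    parents = rbind(
      fx_var("BRAT1", c("mother", "father"), "G", "A", "missense", "snv",
             transcript = "NM_152743", hgvs_c = "c.1280G>A",
             hgvs_p = "p.(Arg427Gln)", cadd = 32,
             acmg = "PM1,PM2,PP2,PP3"),
      standard_decoys(c("FLG", "DNAH5", "AHNAK", "USH2A"))),
    children = data.frame(sample_id = "child1", affected = TRUE,
                          sex = "M", material = FALSE,
                          stringsAsFactors = FALSE),
    child_genotypes = record_columns(),
    expected = list(tier = "class45_match", confirmed = FALSE,
                    genes = "BRAT1"))

  # Families 6, 8, 9, 10, 11, 12: no shared qualifying variants. Decoys
  # only, each failing exactly one predicate (family 6 additionally carries
  # a homozygous maternal decoy, excluded with a warning).
  no_finding <- function(consang, children, genes) {
    list(consanguinity = consang, wes = FALSE,
         parents = standard_decoys(genes),
         children = children, child_genotypes = record_columns(),
         expected = list(tier = "no_finding", confirmed = FALSE,
                         genes = character(0)))
  }
  fam$family06 <- no_finding("none",
    data.frame(sample_id = "child1", affected = TRUE, sex = "F",
               material = FALSE, stringsAsFactors = FALSE),
    c("TTN", "AHNAK", "USH2A", "FLG"))
  fam$family06$parents <- rbind(fam$family06$parents, decoy_hom("RYR3"))

  # Family 7: first cousins; three children lost to severe lissencephaly.
  # Shared heterozygous exon 1 deletion of PALLD (no established disease
  # entry -> Class 3), homozygous in the first affected child; the healthy
  # child does not carry the deletion.
  fam$family07 <- list(
    consanguinity = "first_cousins",
    wes = TRUE,
    parents = rbind(
      fx_var("PALLD", c("mother", "father"), "", "", "other_noncoding",
             "exon_cnv", transcript = "NM_001166108", exon = "exon1",
             acmg = "PM2"),
      standard_decoys(c("MUC16", "RYR3", "LAMA5", "OBSCN"))),
    children = data.frame(
      sample_id = c("child1", "child2", "child3", "child4"),
      affected = c(TRUE, TRUE, TRUE, FALSE),
      sex = c("F", "M", "M", "F"),
      material = c(TRUE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE),
    child_genotypes = rbind(
      fx_var("PALLD", "child1", "", "", "other_noncoding", "exon_cnv",
             transcript = "NM_001166108", exon = "exon1",
             zygosity = "hom"),
      fx_var("PALLD", "child4", "", "", "other_noncoding", "exon_cnv",
             transcript = "NM_001166108", exon = "exon1",
             zygosity = "absent")),
    expected = list(tier = "class3_candidate", confirmed = TRUE,
                    genes = "PALLD"))

  fam$family08 <- no_finding("consanguineous",
    data.frame(sample_id = "child1", affected = TRUE, sex = "F",
               material = FALSE, stringsAsFactors = FALSE),
    c("PLEC", "SYNE1", "DNAH5", "MUC16"))
  fam$family09 <- no_finding("none",
    data.frame(sample_id = c("child1", "child2"), affected = c(TRUE, TRUE),
               sex = c("M", "F"), material = c(FALSE, FALSE),
               stringsAsFactors = FALSE),
    c("OBSCN", "USH2A", "TTN", "AHNAK"))
  fam$family10 <- no_finding("consanguineous",
    data.frame(stringsAsFactors = FALSE, sample_id = character(),
               affected = logical(), sex = character(),
               material = logical()),
    c("LAMA5", "FLG", "SYNE1", "RYR3"))
  fam$family11 <- no_finding("none",
    data.frame(sample_id = c("child1", "child2", "child3"),
               affected = c(TRUE, TRUE, TRUE), sex = c("F", "M", "M"),
               material = c(FALSE, FALSE, FALSE), stringsAsFactors = FALSE),
    c("DNAH5", "MUC16", "PLEC", "USH2A"))
  fam$family12 <- no_finding("consanguineous",
    data.frame(sample_id = "child1", affected = TRUE, sex = "F",
               material = FALSE, stringsAsFactors = FALSE),
    c("SYNE1", "TTN", "OBSCN", "FLG"))

  # Family 13: non-consanguineous; two anencephalic miscarriages. Panel
  # negative; exome tier found compound-heterozygous APAF1 missense
  # variants (novel candidate gene, Class 3 each), confirmed compound
  # heterozygous in both affected fetuses. Not eligible for PGD.
  fam$family13 <- list(
    consanguinity = "none",
    wes = TRUE,
    parents = rbind(
      fx_var("APAF1", "mother", "C", "G", "missense", "snv",
             transcript = "NM_181861", hgvs_c = "c.1350C>G",
             hgvs_p = "p.(Cys450Trp)", cadd = 23.1, acmg = "PM2,PP3",
             slot = 1L),
      fx_var("APAF1", "father", "C", "G", "missense", "snv",
             transcript = "NM_181861", hgvs_c = "c.3127C>G",
             hgvs_p = "p.(His1043Asp)", cadd = 25.7, acmg = "PM2,PP3",
             slot = 2L),
      standard_decoys(c("RYR3", "LAMA5", "USH2A", "DNAH5"))),
    children = data.frame(
      sample_id = c("fetus1", "fetus2"),
      affected = c(TRUE, TRUE),
      sex = c("U", "U"),
      material = c(TRUE, TRUE),
      stringsAsFactors = FALSE),
    child_genotypes = rbind(
      fx_var("APAF1", c("fetus1", "fetus2"), "C", "G", "missense", "snv",
             transcript = "NM_181861", hgvs_c = "c.1350C>G",
             zygosity = "het", slot = 1L),
      fx_var("APAF1", c("fetus1", "fetus2"), "C", "G", "missense", "snv",
             transcript = "NM_181861", hgvs_c = "c.3127C>G",
             zygosity = "het", slot = 2L)),
    expected = list(tier = "class3_candidate", confirmed = TRUE,
                    genes = "APAF1"))

  fam
}

#' Build the 13-couple demonstration cohort on disk
#'
#' Writes one directory per family (`family01` ... `family13`) containing
#' `mother.vcf`, `father.vcf`, `children.vcf` (where any child was
#' genotyped), `pedigree.tsv` and `evidence.tsv`, plus a top-level
#' `manifest.json` recording the expected screening outcome of every family
#' and the reconstruction caveats (synthetic coordinates, reconstructed
#' evidence codes, a transcript-level discrepancy in the source's
#' description of the ACADVL variant that is deliberately not reconciled).
#' Fully deterministic: repeated builds are byte-identical.
#'
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
build_table1_fixture <- function(dir) {
  fams <- table1_families()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    cohort = "demo_table1",
    n_couples = length(fams),
    notes = c(
      "Synthetic cohort reconstructed from printed per-family results; raw sequencing data were never deposited.",
      "Genomic coordinates are deterministic placeholders (gene-indexed spacing); variant identity in the source is HGVS-based.",
      "ACMG evidence codes are reconstructed so the combining rules reproduce the printed classes; the source prints classes only.",
      "The ACADVL variant is described inconsistently in the source (c.1274T>C p.(L425P) in the per-family table vs c.1436T>C p.(Pro479Leu) in the text); the table form is encoded and the discrepancy is not silently reconciled.",
      "Family 2's second-pregnancy fetus (compound heterozygous on prenatal testing) is not encoded as a cosegregation sample: confirmation counts follow the deceased-child column."),
    families = list())
  for (id in names(fams)) {
    f <- fams[[id]]
    fdir <- file.path(dir, id)
    dir.create(fdir, showWarnings = FALSE)
    write_annotated_vcf(f$parents[f$parents$sample_id == "mother", ,
                                  drop = FALSE],
                        file.path(fdir, "mother.vcf"))
    write_annotated_vcf(f$parents[f$parents$sample_id == "father", ,
                                  drop = FALSE],
                        file.path(fdir, "father.vcf"))
    if (nrow(f$child_genotypes) > 0)
      write_annotated_vcf(f$child_genotypes,
                          file.path(fdir, "children.vcf"))
    ped <- rbind(
      data.frame(sample_id = c("mother", "father"),
                 role = c("mother", "father"), affected = 0L,
                 sex = c("F", "M"), material = 1L,
                 stringsAsFactors = FALSE),
      if (nrow(f$children) > 0)
        data.frame(sample_id = f$children$sample_id, role = "child",
                   affected = as.integer(f$children$affected),
                   sex = f$children$sex,
                   material = as.integer(f$children$material),
                   stringsAsFactors = FALSE))
    utils::write.table(ped, file.path(fdir, "pedigree.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ev <- f$parents[!is.na(f$parents$acmg), , drop = FALSE]
    ev_tab <- unique(data.frame(variant = variant_key(ev),
                                codes = ev$acmg, stringsAsFactors = FALSE))
    utils::write.table(ev_tab, file.path(fdir, "evidence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$families[[id]] <- list(
      consanguinity = f$consanguinity,
      consanguineous = f$consanguinity != "none",
      wes = f$wes,
      expected_tier = f$expected$tier,
      expected_confirmed = f$expected$confirmed,
      expected_genes = as.list(f$expected$genes))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
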