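# Builders shared across the test files. All fixtures are constructed in
# code at test time; nothing binary is stored.

CONSEQ_POOL <- c("missense", "missense", "nonsense", "frameshift",
                 "inframe_indel", "splice_site", "synonymous",
                 "other_noncoding")

# A single record with carrier-screen-friendly defaults: rare heterozygous
# missense SNV with a damaging CADD score.
mk_rec <- function(gene = "CTSD", pos = 1000L, ref = "A", alt = "G",
                   sample_id = "mother", zygosity = "het",
                   consequence = "missense", kind = "snv", cadd = 25,
                   ...) {
  variant_record(chrom = "1", pos = pos, ref = ref, alt = alt, gene = gene,
                 consequence = consequence, kind = kind,
                 sample_id = sample_id, zygosity = zygosity, cadd = cadd,
                 ...)
}

# Random annotated records with a mix of passing and failing annotation
# profiles, for the property-style filter/matcher tests.
random_records <- function(n, sample_id = "mother", n_genes = 12,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- function(vals, p_na = 0.4) {
    x <- sample(vals, 1)
    if (stats::runif(1) < p_na) NA else x
  }
  do.call(rbind, lapply(seq_len(n), function(i) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T", "AT", "GC"), ref), 1)
    variant_record(
      chrom = "1", pos = i * 10L, ref = ref, alt = alt,
      gene = sprintf("G%02d", sample.int(n_genes, 1)),
      consequence = sample(CONSEQ_POOL, 1),
      kind = if (nchar(ref) == 1 && nchar(alt) == 1) "snv" else "indel",
      sample_id = sample_id,
      zygosity = sample(c("het", "het", "het", "hom", "absent"), 1),
      maf_dbsnp = pick(c(0, 0.001, 0.02, 0.2)),
      maf_esp = pick(c(0, 0.001, 0.05)),
      maf_exac = pick(c(0.0001, 0.005, 0.03)),
      hgmd_dm = stats::runif(1) < 0.1,
      clinvar_patho = stats::runif(1) < 0.1,
      cadd = pick(c(2, 10, 21, 35), p_na = 0.3),
      sift_del = pick(c(TRUE, FALSE)),
      pph2_dam = pick(c(TRUE, FALSE)),
      splice_dam = pick(c(TRUE, FALSE), p_na = 0.7))
  }))
}

# Cached on-disk demonstration cohort shared by the fixture/report tests.
fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "table1_fixture")
      build_table1_fixture(dir)
    }
    dir
  }
})

fam_path <- function(id, file) file.path(fixture_dir(), id, file)

screen_family <- function(id, with_children = TRUE) {
  ped <- fam_path(id, "pedigree.tsv")
  kids <- fam_path(id, "children.vcf")
  screen_couple_files(
    fam_path(id, "mother.vcf"), fam_path(id, "father.vcf"),
    couple_id = id,
    pedigree_path = if (with_children && file.exists(ped)) ped else NULL,
    children_vcf = if (with_children && file.exists(kids)) kids else NULL)
}
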