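test_that("biallelic records round-trip through the annotated VCF dialect", {
  recs <- rbind(
    mk_rec(gene = "CTSD", pos = 100L, ref = "A", alt = "AC",
           consequence = "frameshift", kind = "indel", cadd = NA,
           hgvs_c = "c.268_269insC", acmg = "PVS1,PM2"),
    mk_rec(gene = "FTCD", pos = 200L, ref = "G", alt = "A", cadd = 25.8,
           maf_exac = 0.0001, sift_del = TRUE, pph2_dam = FALSE),
    mk_rec(gene = "NAGA", pos = 300L, ref = "G", alt = "A",
           hgmd_dm = TRUE, clinvar_patho = TRUE),
    variant_record(chrom = "1", pos = 400L, gene = "PALLD",
                   consequence = "other_noncoding", kind = "exon_cnv",
                   exon = "exon1", sample_id = "mother",
                   zygosity = "het"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_annotated_vcf(recs, path)
  back <- read_annotated_vcf(path, "mother")
  expect_equal(nrow(back), 4L)
  expect_true(all(back$zygosity == "het"))
  # writer sorts by coordinate; compare field-for-field in that order
  ord <- order(recs$chrom, recs$pos)
  expected <- recs[ord, ]
  rownames(expected) <- rownames(back) <- NULL
  expect_equal(back, expected)
  # a second round trip is the identity exactly
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_annotated_vcf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("multi-allelic lines split into one record per alt allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="c">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "1\t500\t.\tC\tG,T\t.\t.\tGENE=COQ2;CSQ=missense\tGT\t1/2",
    "1\t600\t.\tA\tG,T\t.\t.\tGENE=BRAT1;CSQ=missense\tGT\t2/2"),
    path)
  recs <- read_annotated_vcf(path, "S1")
  # enumerating the 1/2 line by hand: alt G carries one allele (het), alt T
  # carries one allele (het); the 2/2 line: alt G zero copies, alt T two
  expect_equal(nrow(recs), 4L)
  line1 <- recs[recs$pos == 500, ]
  expect_setequal(line1$alt, c("G", "T"))
  expect_true(all(line1$zygosity == "het"))
  line2 <- recs[recs$pos == 600, ]
  expect_equal(line2$zygosity[line2$alt == "G"], "absent")
  expect_equal(line2$zygosity[line2$alt == "T"], "hom")
  # allele-count conservation: copies across split records = GT arity
  copies <- c(het = 1L, hom = 2L, absent = 0L)
  expect_equal(sum(copies[line1$zygosity]), 2L)
  expect_equal(sum(copies[line2$zygosity]), 2L)
})

test_that("format errors are reported with the offending line number", {
  path <- withr::local_tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="c">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"))
  writeLines(c(header, "1\t100\t.\tA\tT\t.\t.\tCSQ=missense\tGT\t0/1"),
             path)
  expect_error(read_annotated_vcf(path, "S1"),
               "missing mandatory INFO key GENE at line 6")
  writeLines(c(header, "1\t100\t.\tA\tT\t.\t.\tGENE=X;CSQ=weird\tGT\t0/1"),
             path)
  expect_error(read_annotated_vcf(path, "S1"), "unknown consequence")
  writeLines(c(header, "1\t100\t.\tA\tT\t.\t.\tGENE=X;CSQ=missense\tGT\t0/1"),
             path)
  expect_error(read_annotated_vcf(path, "missing_sample"), "not present")
})

test_that("record invariants are enforced", {
  expect_error(mk_rec(ref = "A", alt = "A"), "ref == alt")
  expect_error(mk_rec(pos = 0L), "pos")
  expect_error(mk_rec(consequence = "nonsense_mediated"), "consequence")
  expect_error(mk_rec(maf_exac = 1.5), "maf_exac")
  expect_error(variant_record(chrom = "1", pos = 10L, gene = "PALLD",
                              consequence = "other_noncoding",
                              kind = "exon_cnv", sample_id = "m",
                              zygosity = "het"),
               "exon label")
})

test_that("normalization trims to minimal form and is idempotent", {
  # SNV passes through unchanged
  snv <- mk_rec(pos = 100L, ref = "A", alt = "T")
  expect_equal(normalize_variant(snv), snv)
  # exon-CNV passes through unchanged
  cnv <- variant_record(chrom = "1", pos = 400L, gene = "PALLD",
                        consequence = "other_noncoding", kind = "exon_cnv",
                        exon = "exon1", sample_id = "m", zygosity = "het")
  expect_equal(normalize_variant(cnv), cnv)
  # shared trailing base is trimmed: CTT>CT at 100 becomes CT>C at 100
  del <- mk_rec(pos = 100L, ref = "CTT", alt = "CT", kind = "indel",
                consequence = "frameshift")
  norm <- normalize_variant(del)
  expect_equal(norm[, c("pos", "ref", "alt")],
               data.frame(pos = 100L, ref = "CT", alt = "C"))
  # idempotent
  expect_equal(normalize_variant(norm), norm)
})

test_that("deletions left-align across repeat context like the brute-force
           oracle", {
  # context: GACTTTTTGC starting at position 95; a one-base T deletion
  # anywhere in the T run is the same event
  context <- "GACTTTTTGC"
  start <- 95L
  for (pos in 98:101) {
    del <- mk_rec(pos = pos, ref = "TT", alt = "T", kind = "indel",
                  consequence = "frameshift")
    norm <- normalize_variant(del, context = context, context_start = start)
    oracle <- oracle_left_align_deletion(context, start, pos, "TT", "T")
    expect_equal(norm$pos, oracle$pos)
    expect_equal(norm$ref, oracle$ref)
    expect_equal(norm$alt, oracle$alt)
  }
  # non-minimal input reaches the same normal form
  fat <- mk_rec(pos = 97L, ref = "CTTT", alt = "CTT", kind = "indel",
                consequence = "frameshift")
  norm_fat <- normalize_variant(fat, context = context,
                                context_start = start)
  oracle_fat <- oracle_left_align_deletion(context, start, 97L, "CTTT",
                                           "CTT")
  expect_equal(norm_fat$pos, oracle_fat$pos)
  expect_equal(norm_fat$ref, oracle_fat$ref)
  # idempotent after left alignment too
  expect_equal(normalize_variant(norm_fat, context, start), norm_fat)
})

test_that("normalization is idempotent on random indels", {
  set.seed(11)
  for (i in 1:50) {
    base <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    ref <- paste(base[1:sample(2:5, 1)], collapse = "")
    alt <- paste(base[1:sample(1:5, 1)], collapse = "")
    if (ref == alt) next
    rec <- mk_rec(pos = 50L, ref = ref, alt = alt, kind = "indel",
                  consequence = "inframe_indel")
    once <- normalize_variant(rec)
    expect_equal(normalize_variant(once), once)
  }
})
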