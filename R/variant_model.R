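# Consequence and kind vocabularies used throughout the pipeline.
CONSEQUENCES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                  "splice_site", "synonymous", "other_noncoding")
VARIANT_KINDS <- c("snv", "indel", "exon_cnv")
ZYGOSITIES <- c("het", "hom", "absent")

# Fixed INFO key order of the annotated-VCF dialect; the writer emits keys
# in exactly this order so identical record sets give byte-identical files.
INFO_KEYS <- c("GENE", "TRANSCRIPT", "HGVSC", "HGVSP", "CSQ", "EXON",
               "MAF_DBSNP", "MAF_ESP", "MAF_EXAC", "HGMD_DM", "CLNSIG_PATHO",
               "CADD", "SIFT_DEL", "PPH2_DAM", "SPLICE_DAM", "ACMG")

record_columns <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), gene = character(), transcript = character(),
    hgvs_c = character(), hgvs_p = character(), consequence = character(),
    kind = character(), exon = character(), sample_id = character(),
    zygosity = character(), maf_dbsnp = numeric(), maf_esp = numeric(),
    maf_exac = numeric(), hgmd_dm = logical(), clinvar_patho = logical(),
    cadd = numeric(), sift_del = logical(), pph2_dam = logical(),
    splice_dam = logical(), acmg = character(),
    stringsAsFactors = FALSE
  )
}

#' Construct a table of annotated variant records
#'
#' One row per (sample, variant, alt allele). This flat table is the working
#' currency of the whole pipeline: a `SeqVariant` (coordinates, alleles, gene,
#' transcript, HGVS strings, consequence, kind), a genotype call
#' (`sample_id`, `zygosity`) and an annotation bundle (population allele
#' frequencies, database assertions, prediction scores, optional ACMG
#' evidence codes) live together in each row.
#'
#' Missing annotation values are `NA`, which is distinct from zero: a variant
#' with no frequency entry in any database is *unobserved*, not known to be
#' absent, and the rarity filter treats it as rare.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position (VCF convention; indels carry the anchor base).
#' @param ref,alt reference / alternate allele strings; empty for exon-level
#'   copy-number records, which are identified by (`gene`, `exon`) instead.
#' @param gene HGNC gene symbol (required).
#' @param transcript transcript accession, e.g. `"NM_001909"`.
#' @param hgvs_c,hgvs_p coding / protein HGVS strings (display metadata only;
#'   never used as a match key).
#' @param consequence one of `r paste(CONSEQUENCES, collapse = ", ")`.
#' @param kind one of `snv`, `indel`, `exon_cnv`.
#' @param exon affected-exon label for `exon_cnv` records.
#' @param sample_id sample the genotype call belongs to.
#' @param zygosity one of `het`, `hom`, `absent`.
#' @param maf_dbsnp,maf_esp,maf_exac population allele frequencies in
#'   \[0, 1\], `NA` when the variant is not listed in that source.
#' @param hgmd_dm,clinvar_patho logical: asserted disease-causing in
#'   HGMD / ClinVar.
#' @param cadd CADD phred score, `NA` when unavailable.
#' @param sift_del,pph2_dam,splice_dam logical predictions (deleterious /
#'   damaging / splice-affecting), `NA` when the tool gave no call.
#' @param acmg comma-separated ACMG/AMP evidence codes, `NA` when unset.
#' @return a `data.frame` with one row per record, validated.
#' @export
#' @examples
#' variant_record(chrom = "1", pos = 100L, ref = "A", alt = "T",
#'                gene = "CTSD", consequence = "missense", kind = "snv",
#'                sample_id = "mother", zygosity = "het", cadd = 25)
variant_record <- function(chrom, pos, ref = "", alt = "", gene,
                           transcript = "", hgvs_c = "", hgvs_p = "",
                           consequence, kind, exon = NA_character_,
                           sample_id, zygosity,
                           maf_dbsnp = NA_real_, maf_esp = NA_real_,
                           maf_exac = NA_real_, hgmd_dm = FALSE,
                           clinvar_patho = FALSE, cadd = NA_real_,
                           sift_del = NA, pph2_dam = NA, splice_dam = NA,
                           acmg = NA_character_) {
  rec <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), transcript = as.character(transcript),
    hgvs_c = as.character(hgvs_c), hgvs_p = as.character(hgvs_p),
    consequence = as.character(consequence), kind = as.character(kind),
    exon = as.character(exon), sample_id = as.character(sample_id),
    zygosity = as.character(zygosity),
    maf_dbsnp = as.numeric(maf_dbsnp), maf_esp = as.numeric(maf_esp),
    maf_exac = as.numeric(maf_exac),
    hgmd_dm = as.logical(hgmd_dm), clinvar_patho = as.logical(clinvar_patho),
    cadd = as.numeric(cadd), sift_del = as.logical(sift_del),
    pph2_dam = as.logical(pph2_dam), splice_dam = as.logical(splice_dam),
    acmg = as.character(acmg), stringsAsFactors = FALSE
  )
  validate_records(rec)
}

#' Validate a record table
#'
#' Checks the structural invariants of the record table: vocabulary
#' membership of `consequence`, `kind` and `zygosity`; positions >= 1;
#' `ref != alt` for sequence variants; present allele frequencies in
#' \[0, 1\]; exon-CNV records carrying a gene and exon label instead of
#' alleles.
#'
#' @param records a record `data.frame` (see [variant_record()]).
#' @return `records`, invisibly unchanged, or an error.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(names(record_columns()), names(records))
  if (length(missing_cols))
    stop("record table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0) return(invisible(records))
  bad <- function(cond, msg) if (any(cond)) stop(msg, " (rows ",
    paste(utils::head(which(cond), 5), collapse = ","), ")", call. = FALSE)
  bad(!records$consequence %in% CONSEQUENCES, "unknown consequence")
  bad(!records$kind %in% VARIANT_KINDS, "unknown variant kind")
  bad(!records$zygosity %in% ZYGOSITIES, "unknown zygosity")
  bad(is.na(records$pos) | records$pos < 1L, "pos must be >= 1")
  bad(is.na(records$gene) | records$gene == "", "gene symbol required")
  seqv <- records$kind %in% c("snv", "indel")
  bad(seqv & records$ref == records$alt, "ref == alt for sequence variant")
  bad(seqv & (records$ref == "" | records$alt == ""),
      "empty allele for sequence variant")
  bad(records$kind == "exon_cnv" &
        (is.na(records$exon) | records$exon == ""),
      "exon_cnv record needs an exon label")
  for (col in c("maf_dbsnp", "maf_esp", "maf_exac")) {
    v <- records[[col]]
    bad(!is.na(v) & (v < 0 | v > 1), paste(col, "outside [0, 1]"))
  }
  invisible(records)
}

#' Variant identity keys
#'
#' The identity under which "the same variant" is decided when intersecting
#' the two partners: `chrom:pos:ref:alt` after normalization for sequence
#' variants, `gene:exon` for exon-level copy-number events. HGVS strings are
#' transcript-dependent and deliberately excluded from the key.
#'
#' @param records a record table.
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(records) {
  ifelse(records$kind == "exon_cnv",
         paste("cnv", records$gene, records$exon, sep = ":"),
         paste(records$chrom, records$pos, records$ref, records$alt,
               sep = ":"))
}

#' Normalize a sequence variant to its minimal left-aligned form
#'
#' Trims bases shared between `ref` and `alt` (trailing first, then leading,
#' always retaining the VCF anchor base for indels) and, when a reference
#' context is supplied, left-shifts indels across repeat tracts to the
#' left-most equivalent placement. SNVs already minimal and exon-CNV records
#' pass through unchanged. Idempotent.
#'
#' @param records a record table of variants to normalize.
#' @param context optional reference context: a single string of reference
#'   bases covering the region around the indel.
#' @param context_start 1-based position of the first base of `context`.
#' @return the record table with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variant <- function(records, context = NULL, context_start = 1L) {
  if (nrow(records) == 0) return(records)
  for (i in seq_len(nrow(records))) {
    if (records$kind[i] == "exon_cnv") next
    norm <- normalize_one(records$pos[i], records$ref[i], records$alt[i],
                          context, context_start)
    records$pos[i] <- norm$pos
    records$ref[i] <- norm$ref
    records$alt[i] <- norm$alt
  }
  records
}

normalize_one <- function(pos, ref, alt, context = NULL, context_start = 1L) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  ctx <- if (is.null(context)) NULL else strsplit(context, "")[[1]]
  # truncate shared trailing bases; when one allele empties, extend both to
  # the left from the reference context (this is what shifts an indel
  # leftward across a repeat tract)
  while (length(r) > 0 && length(a) > 0 &&
         r[length(r)] == a[length(a)] &&
         !(length(r) == 1 && length(a) == 1)) {
    if (length(r) == 1 || length(a) == 1) {
      prev_i <- pos - context_start  # context index of the base before pos
      if (is.null(ctx) || prev_i < 1 || prev_i > length(ctx)) break
      r <- c(ctx[prev_i], r[-length(r)])
      a <- c(ctx[prev_i], a[-length(a)])
      pos <- pos - 1L
    } else {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
  }
  # trim shared leading bases, keeping one anchor base for indels
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# ---- annotated-VCF dialect -------------------------------------------------

vcf_header_lines <- function(sample_ids) {
  c("##fileformat=VCFv4.2",
    "##source=couplescreen",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="HGNC gene symbol">',
    '##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description="Transcript accession">',
    '##INFO=<ID=HGVSC,Number=1,Type=String,Description="Coding HGVS">',
    '##INFO=<ID=HGVSP,Number=1,Type=String,Description="Protein HGVS">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=EXON,Number=1,Type=String,Description="Affected exon label (CNV records)">',
    '##INFO=<ID=MAF_DBSNP,Number=1,Type=Float,Description="Allele frequency, dbSNP138">',
    '##INFO=<ID=MAF_ESP,Number=1,Type=Float,Description="Allele frequency, Exome Variant Server">',
    '##INFO=<ID=MAF_EXAC,Number=1,Type=Float,Description="Allele frequency, ExAC">',
    '##INFO=<ID=HGMD_DM,Number=0,Type=Flag,Description="HGMD disease-causing assertion">',
    '##INFO=<ID=CLNSIG_PATHO,Number=0,Type=Flag,Description="ClinVar pathogenic assertion">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">',
    '##INFO=<ID=SIFT_DEL,Number=1,Type=Integer,Description="SIFT deleterious (0/1)">',
    '##INFO=<ID=PPH2_DAM,Number=1,Type=Integer,Description="PolyPhen-2 damaging (0/1)">',
    '##INFO=<ID=SPLICE_DAM,Number=1,Type=Integer,Description="Splice prediction damaging (0/1)">',
    '##INFO=<ID=ACMG,Number=1,Type=String,Description="Comma-separated ACMG/AMP evidence codes">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

fmt_num <- function(x) {
  # fixed numeric formatting so identical data are byte-identical on disk
  formatC(x, format = "g", digits = 10)
}

info_string <- function(rec) {
  parts <- character(0)
  add <- function(key, val) {
    if (length(val) == 1 && !is.na(val) && val != "")
      parts[[length(parts) + 1]] <<- paste0(key, "=", val)
  }
  add("GENE", rec$gene)
  add("TRANSCRIPT", rec$transcript)
  add("HGVSC", rec$hgvs_c)
  add("HGVSP", rec$hgvs_p)
  add("CSQ", rec$consequence)
  add("EXON", rec$exon)
  if (!is.na(rec$maf_dbsnp)) add("MAF_DBSNP", fmt_num(rec$maf_dbsnp))
  if (!is.na(rec$maf_esp)) add("MAF_ESP", fmt_num(rec$maf_esp))
  if (!is.na(rec$maf_exac)) add("MAF_EXAC", fmt_num(rec$maf_exac))
  if (isTRUE(rec$hgmd_dm)) parts[[length(parts) + 1]] <- "HGMD_DM"
  if (isTRUE(rec$clinvar_patho)) parts[[length(parts) + 1]] <- "CLNSIG_PATHO"
  if (!is.na(rec$cadd)) add("CADD", fmt_num(rec$cadd))
  if (!is.na(rec$sift_del)) add("SIFT_DEL", as.integer(rec$sift_del))
  if (!is.na(rec$pph2_dam)) add("PPH2_DAM", as.integer(rec$pph2_dam))
  if (!is.na(rec$splice_dam)) add("SPLICE_DAM", as.integer(rec$splice_dam))
  add("ACMG", rec$acmg)
  paste(parts, collapse = ";")
}

zygosity_gt <- c(het = "0/1", hom = "1/1", absent = "0/0")

#' Write a record table as an annotated VCF
#'
#' Emits the pipeline's VCF 4.2 dialect with INFO keys in a fixed order, so
#' identical record sets produce byte-identical files. Multiple samples may
#' be written to one file; a variant absent from a sample's rows is written
#' as genotype `0/0` for that sample. Exon-CNV records are written with
#' symbolic ALT `<DEL>`.
#'
#' @param records record table; may contain several `sample_id`s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(records, path) {
  validate_records(records)
  samples <- unique(records$sample_id)
  key <- variant_key(records)
  ord <- order(records$chrom, records$pos, records$ref, records$alt, key)
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  lines <- vcf_header_lines(samples)
  for (k in unique(key)) {
    rows <- records[key == k, , drop = FALSE]
    rec <- rows[1, , drop = FALSE]
    is_cnv <- rec$kind == "exon_cnv"
    gts <- vapply(samples, function(s) {
      z <- rows$zygosity[rows$sample_id == s]
      if (length(z) == 0) "0/0" else zygosity_gt[[z[1]]]
    }, character(1))
    lines <- c(lines, paste(c(
      rec$chrom, rec$pos, ".",
      if (is_cnv) "N" else rec$ref,
      if (is_cnv) "<DEL>" else rec$alt,
      ".", ".", info_string(rec), "GT", gts), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_info <- function(info) {
  out <- list()
  if (is.na(info) || info == "" || info == ".") return(out)
  for (part in strsplit(info, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", part, fixed = TRUE)
    if (eq > 0) {
      out[[substr(part, 1, eq - 1)]] <- substr(part, eq + 1, nchar(part))
    } else {
      out[[part]] <- TRUE  # Flag key
    }
  }
  out
}

info_num <- function(info, key) {
  v <- info[[key]]
  if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
}

info_lgl01 <- function(info, key) {
  v <- info[[key]]
  if (is.null(v)) NA else v == "1"
}

info_chr <- function(info, key, default = "") {
  v <- info[[key]]
  if (is.null(v)) default else v
}

#' Read an annotated VCF for one sample
#'
#' Parses the pipeline's annotated-VCF dialect and returns one record per
#' (variant, alt allele) for the requested sample. Multi-allelic lines are
#' split into one record per alternate allele, with the sample's zygosity for
#' each allele derived from its GT allele counts (2 copies = `hom`, 1 =
#' `het`, 0 or missing = `absent`). Symbolic `<DEL>` ALT alleles with an
#' `EXON` INFO key become exon-CNV records.
#'
#' @param path VCF file path.
#' @param sample_id sample column to read genotypes from.
#' @return a validated record table (see [variant_record()]).
#' @export
read_annotated_vcf <- function(path, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (!sample_id %in% colnames(gt))
    stop("sample '", sample_id, "' not present in ", path)
  n_header <- sum(startsWith(readLines(path), "#"))
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    line_no <- n_header + i
    info <- parse_info(fix[i, "INFO"])
    if (is.null(info[["GENE"]]))
      stop("missing mandatory INFO key GENE at line ", line_no, " of ", path)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gt_str <- sub(":.*$", "", gt[i, sample_id])
    alleles <- suppressWarnings(
      as.integer(strsplit(gt_str, "[/|]")[[1]]))
    is_cnv <- any(alts == "<DEL>") && !is.null(info[["EXON"]])
    csq <- info_chr(info, "CSQ", if (is_cnv) "other_noncoding" else "")
    if (!csq %in% CONSEQUENCES)
      stop("unknown consequence '", csq, "' at line ", line_no, " of ", path)
    recs <- lapply(seq_along(alts), function(a) {
      n_copies <- sum(alleles == a, na.rm = TRUE)
      zyg <- if (n_copies >= 2) "hom" else if (n_copies == 1) "het"
             else "absent"
      variant_record(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = if (is_cnv) "" else fix[i, "REF"],
        alt = if (is_cnv) "" else alts[a],
        gene = info[["GENE"]],
        transcript = info_chr(info, "TRANSCRIPT"),
        hgvs_c = info_chr(info, "HGVSC"),
        hgvs_p = info_chr(info, "HGVSP"),
        consequence = csq,
        kind = if (is_cnv) "exon_cnv"
               else if (nchar(fix[i, "REF"]) == 1L &&
                        nchar(alts[a]) == 1L) "snv" else "indel",
        exon = info_chr(info, "EXON", NA_character_),
        sample_id = sample_id, zygosity = zyg,
        maf_dbsnp = info_num(info, "MAF_DBSNP"),
        maf_esp = info_num(info, "MAF_ESP"),
        maf_exac = info_num(info, "MAF_EXAC"),
        hgmd_dm = isTRUE(info[["HGMD_DM"]]),
        clinvar_patho = isTRUE(info[["CLNSIG_PATHO"]]),
        cadd = info_num(info, "CADD"),
        sift_del = info_lgl01(info, "SIFT_DEL"),
        pph2_dam = info_lgl01(info, "PPH2_DAM"),
        splice_dam = info_lgl01(info, "SPLICE_DAM"),
        acmg = info_chr(info, "ACMG", NA_character_))
    })
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, c(list(record_columns()), out))
  rownames(res) <- NULL
  validate_records(res)
  res
}
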