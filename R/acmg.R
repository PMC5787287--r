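# ACMG/AMP evidence-code vocabulary (Richards et al. 2015 combining rules).
ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4),
                paste0("PM", 1:6),
                paste0("PP", 1:5),
                "BA1",
                paste0("BS", 1:4),
                paste0("BP", 1:7))

parse_evidence <- function(codes) {
  if (length(codes) == 1 && (is.na(codes) || codes == ""))
    return(character(0))
  codes <- unlist(strsplit(codes, "[,;+[:space:]]+"))
  codes <- toupper(codes[codes != ""])
  unknown <- setdiff(codes, ACMG_CODES)
  if (length(unknown))
    stop("unknown ACMG evidence code(s): ", paste(unknown, collapse = ", "))
  unique(codes)
}

#' Combine ACMG/AMP evidence codes into a five-tier class
#'
#' Implements the published evidence-combining rules: counts of very-strong
#' (PVS1), strong (PS1-4), moderate (PM1-6) and supporting (PP1-5)
#' pathogenic criteria are weighed against stand-alone (BA1), strong (BS1-4)
#' and supporting (BP1-7) benign criteria. When a pathogenic and a benign
#' combination are met simultaneously the evidence is contradictory and the
#' variant is uncertain (Class 3); an empty or insufficient evidence set is
#' likewise Class 3.
#'
#' Classes: 1 benign, 2 likely benign, 3 uncertain significance (VUS),
#' 4 likely pathogenic, 5 pathogenic.
#'
#' @param codes character vector of evidence codes, or a single
#'   comma-separated string (e.g. `"PVS1,PM2"`); `NA`/empty means no
#'   evidence.
#' @return integer class in 1..5, with class `"pathogenicity_class"` label
#'   attribute dropped — a plain integer for easy comparison.
#' @export
#' @examples
#' combine_evidence("PVS1,PM2")        # 4, likely pathogenic
#' combine_evidence(c("PVS1", "PS1"))  # 5, pathogenic
#' combine_evidence(character(0))      # 3, uncertain
combine_evidence <- function(codes) {
  codes <- parse_evidence(codes)
  pvs <- sum(codes == "PVS1")
  ps <- sum(grepl("^PS[1-4]$", codes))
  pm <- sum(grepl("^PM[1-6]$", codes))
  pp <- sum(grepl("^PP[1-5]$", codes))
  ba <- sum(codes == "BA1")
  bs <- sum(grepl("^BS[1-4]$", codes))
  bp <- sum(grepl("^BP[1-7]$", codes))

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs == 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp == 1) || bp >= 2

  patho_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (patho_side && benign_side) return(3L)  # contradictory -> uncertain
  if (pathogenic) return(5L)
  if (likely_pathogenic) return(4L)
  if (benign) return(1L)
  if (likely_benign) return(2L)
  3L
}

#' Classify every variant record by its attached evidence codes
#'
#' @param records a record table whose `acmg` column carries comma-separated
#'   evidence codes (`NA` = no evidence, classified uncertain).
#' @return integer vector of classes, one per record.
#' @export
classify_records <- function(records) {
  if (nrow(records) == 0) return(integer(0))
  vapply(records$acmg, combine_evidence, integer(1), USE.NAMES = FALSE)
}

#' Eligibility of a candidate pair of variants for prenatal diagnosis / PGD
#'
#' Prenatal diagnosis or preimplantation genetic diagnosis requires a firmly
#' established causative genotype: both the maternal and the paternal allele
#' of a candidate must be likely pathogenic or pathogenic (Class 4 or 5).
#'
#' @param class_maternal,class_paternal integer classes in 1..5.
#' @return `TRUE` iff both classes are >= 4.
#' @export
eligible_for_action <- function(class_maternal, class_paternal) {
  stopifnot(class_maternal %in% 1:5, class_paternal %in% 1:5)
  class_maternal >= 4 && class_paternal >= 4
}

#' Reportability of a class to the couple
#'
#' Variants of uncertain significance and above (Class 3-5) are reported to
#' the couple; benign and likely benign variants are not.
#'
#' @param class integer class in 1..5 (vectorized).
#' @return logical.
#' @export
reportable <- function(class) {
  stopifnot(all(class %in% 1:5))
  class >= 3
}

#' Read an evidence sidecar table
#'
#' Tab-separated file with columns `variant` (an identity key as produced by
#' [variant_key()]) and `codes` (comma-separated ACMG evidence codes), used
#' to attach evidence to records when the VCF itself carries no `ACMG` INFO
#' key.
#'
#' @param path TSV file path.
#' @return named character vector: key -> codes.
#' @export
read_evidence_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("variant", "codes") %in% names(tab)))
    stop("evidence file must have columns 'variant' and 'codes': ", path)
  stats::setNames(tab$codes, tab$variant)
}

#' Attach sidecar evidence codes to a record table
#'
#' Explicit codes already present in the records' `acmg` column are never
#' overridden.
#'
#' @param records a record table.
#' @param evidence named vector from [read_evidence_tsv()].
#' @return the record table with `acmg` filled in where matched.
#' @export
attach_evidence <- function(records, evidence) {
  key <- variant_key(records)
  hit <- is.na(records$acmg) & key %in% names(evidence)
  records$acmg[hit] <- unname(evidence[key[hit]])
  records
}
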