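#' Filter parameters for the per-parent variant cascade
#'
#' @param maf_threshold retain a variant only if every population allele
#'   frequency that *is* reported for it (dbSNP, ESP, ExAC) lies below this
#'   fraction; a variant absent from all three sources counts as rare.
#'   Default 0.01 (the conventional 1% carrier-screening cutoff).
#' @param cadd_cutoff CADD phred score at or above which a variant counts as
#'   predicted deleterious. Default 20, the conventional "top 1% of possible
#'   substitutions" threshold.
#' @param min_tool_votes number of in-silico tools (SIFT, PolyPhen, splice
#'   predictor) that must call a variant damaging for it to count as
#'   predicted deleterious when the CADD branch does not apply. One of 1, 2
#'   or 3; default 2.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(maf_threshold = 0.01, cadd_cutoff = 20,
                          min_tool_votes = 2L) {
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1,
            maf_threshold > 0, maf_threshold < 1,
            is.numeric(cadd_cutoff), length(cadd_cutoff) == 1,
            cadd_cutoff > 0,
            min_tool_votes %in% c(1L, 2L, 3L))
  structure(list(maf_threshold = maf_threshold, cadd_cutoff = cadd_cutoff,
                 min_tool_votes = as.integer(min_tool_votes)),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat("Filter parameters: MAF <", x$maf_threshold,
      "| CADD >=", x$cadd_cutoff,
      "| tool votes >=", x$min_tool_votes, "\n")
  invisible(x)
}

#' Read filter parameters from a YAML configuration file
#'
#' Recognised keys: `maf_threshold`, `cadd_cutoff`, `min_tool_votes`; any
#' missing key falls back to the default.
#'
#' @param path YAML file path.
#' @return a `filter_params` object.
#' @export
read_filter_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("maf_threshold", "cadd_cutoff", "min_tool_votes")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown filter configuration key(s): ",
         paste(unknown, collapse = ", "))
  defaults <- filter_params()
  do.call(filter_params, utils::modifyList(unclass(defaults),
                                           cfg[names(cfg) %in% known]))
}

#' Rarity predicate
#'
#' A variant is rare when every population allele frequency present for it
#' (dbSNP, ESP, ExAC) is below `maf_threshold`, or when it carries a
#' disease-causing assertion in HGMD or ClinVar (the assertion overrides
#' frequency). A variant listed in none of the sources is rare: absence from
#' the databases is how novel variants look.
#'
#' @param records a record table.
#' @param params a [filter_params()] object.
#' @return logical vector, one element per record.
#' @export
is_rare <- function(records, params = filter_params()) {
  mafs <- cbind(records$maf_dbsnp, records$maf_esp, records$maf_exac)
  below <- mafs < params$maf_threshold
  all_present_below <- apply(below, 1, function(x) all(x, na.rm = TRUE))
  asserted <- records$hgmd_dm | records$clinvar_patho
  as.logical(all_present_below | asserted)
}

#' Qualifying-consequence predicate
#'
#' Keeps non-synonymous coding and splice-site variants, including small
#' indels, and exon-level copy-number events; synonymous and other
#' non-coding classes are excluded.
#'
#' @inheritParams is_rare
#' @return logical vector.
#' @export
is_candidate_consequence <- function(records) {
  records$consequence %in% c("missense", "nonsense", "frameshift",
                             "inframe_indel", "splice_site") |
    records$kind == "exon_cnv"
}

#' Deleteriousness predicate
#'
#' Nonsense and frameshift variants and exon-level deletions count as
#' deleterious outright (loss-of-function shortcut; no score needed). Any
#' other variant counts when its CADD phred score reaches `cadd_cutoff`, or
#' when at least `min_tool_votes` of the SIFT / PolyPhen / splice-prediction
#' calls are damaging. A non-LoF variant with no score and no tool call is
#' not deleterious.
#'
#' @inheritParams is_rare
#' @return logical vector.
#' @export
is_predicted_deleterious <- function(records, params = filter_params()) {
  lof <- records$consequence %in% c("nonsense", "frameshift") |
    records$kind == "exon_cnv"
  cadd_hit <- !is.na(records$cadd) & records$cadd >= params$cadd_cutoff
  votes <- rowSums(cbind(records$sift_del, records$pph2_dam,
                         records$splice_dam), na.rm = TRUE)
  lof | cadd_hit | votes >= params$min_tool_votes
}

#' The per-parent filter cascade
#'
#' Retains exactly the heterozygous records that are rare, of qualifying
#' consequence and predicted deleterious, in input order. Homozygous calls
#' are dropped with a warning: the screen targets unaffected carrier
#' parents, for whom a homozygous hit in a severe recessive gene is either
#' an annotation artifact or a benign allele, but worth a look. Idempotent.
#'
#' @param records record table for one sample.
#' @param params a [filter_params()] object.
#' @return the retained record table.
#' @export
filter_parent_variants <- function(records, params = filter_params()) {
  if (nrow(records) == 0) return(records)
  if (length(unique(records$sample_id)) > 1)
    stop("filter_parent_variants expects records from a single sample")
  hom <- records$zygosity == "hom"
  if (any(hom))
    warning(sum(hom), " homozygous parental call(s) excluded from carrier ",
            "matching (", paste(unique(records$gene[hom]), collapse = ", "),
            ")", call. = FALSE)
  keep <- records$zygosity == "het" &
    is_rare(records, params) &
    is_candidate_consequence(records) &
    is_predicted_deleterious(records, params)
  records[keep, , drop = FALSE]
}
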