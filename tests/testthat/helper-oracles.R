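# Independent oracles used by the property-style tests. Each is coded
# directly from first principles (per-record loops, literal rule rows,
# brute-force enumeration) and never calls the implementation it checks.

# Per-record filter oracle: evaluates the three predicates independently
# on scalar values.
oracle_filter <- function(records, maf_threshold = 0.01, cadd_cutoff = 20,
                          min_tool_votes = 2) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    mafs <- c(r$maf_dbsnp, r$maf_esp, r$maf_exac)
    present <- mafs[!is.na(mafs)]
    rare <- (length(present) == 0 || all(present < maf_threshold)) ||
      isTRUE(r$hgmd_dm) || isTRUE(r$clinvar_patho)
    csq_ok <- r$consequence %in% c("missense", "nonsense", "frameshift",
                                   "inframe_indel", "splice_site") ||
      r$kind == "exon_cnv"
    lof <- r$consequence %in% c("nonsense", "frameshift") ||
      r$kind == "exon_cnv"
    votes <- sum(c(isTRUE(r$sift_del), isTRUE(r$pph2_dam),
                   isTRUE(r$splice_dam)))
    del <- lof || (!is.na(r$cadd) && r$cadd >= cadd_cutoff) ||
      votes >= min_tool_votes
    keep[i] <- r$zygosity == "het" && rare && csq_ok && del
  }
  records[keep, , drop = FALSE]
}

# Brute-force couple matcher oracle: double loop over all cross-parent
# variant pairs, grouped by gene. Returns the set of (gene, mode) strings.
oracle_match_modes <- function(mother, father) {
  key <- function(r) {
    if (r$kind == "exon_cnv") paste("cnv", r$gene, r$exon)
    else paste(r$chrom, r$pos, r$ref, r$alt)
  }
  out <- character(0)
  for (i in seq_len(nrow(mother))) {
    for (j in seq_len(nrow(father))) {
      m <- mother[i, ]
      f <- father[j, ]
      if (m$gene != f$gene) next
      if (key(m) == key(f)) {
        out <- c(out, paste(m$gene, "shared_hom"))
      } else {
        out <- c(out, paste(m$gene, "compound_het"))
      }
    }
  }
  sort(unique(out))
}

# Literal ACMG/AMP rule-table oracle: one logical per published row.
oracle_acmg <- function(codes) {
  cnt <- function(set) sum(codes %in% set)
  PVS <- cnt("PVS1")
  PS <- cnt(c("PS1", "PS2", "PS3", "PS4"))
  PM <- cnt(c("PM1", "PM2", "PM3", "PM4", "PM5", "PM6"))
  PP <- cnt(c("PP1", "PP2", "PP3", "PP4", "PP5"))
  BA <- cnt("BA1")
  BS <- cnt(c("BS1", "BS2", "BS3", "BS4"))
  BP <- cnt(c("BP1", "BP2", "BP3", "BP4", "BP5", "BP6", "BP7"))
  pathogenic_rows <- c(
    PVS >= 1 && PS >= 1,                 # (i)(a)
    PVS >= 1 && PM >= 2,                 # (i)(b)
    PVS >= 1 && PM == 1 && PP == 1,      # (i)(c)
    PVS >= 1 && PP >= 2,                 # (i)(d)
    PS >= 2,                             # (ii)
    PS == 1 && PM >= 3,                  # (iii)(a)
    PS == 1 && PM == 2 && PP >= 2,       # (iii)(b)
    PS == 1 && PM == 1 && PP >= 4)       # (iii)(c)
  likely_pathogenic_rows <- c(
    PVS == 1 && PM == 1,                 # (i)
    PS == 1 && (PM == 1 || PM == 2),     # (ii)
    PS == 1 && PP >= 2,                  # (iii)
    PM >= 3,                             # (iv)
    PM == 2 && PP >= 2,                  # (v)
    PM == 1 && PP >= 4)                  # (vi)
  benign_rows <- c(BA >= 1, BS >= 2)
  likely_benign_rows <- c(BS == 1 && BP == 1, BP >= 2)
  p_side <- any(pathogenic_rows) || any(likely_pathogenic_rows)
  b_side <- any(benign_rows) || any(likely_benign_rows)
  if (p_side && b_side) return(3L)
  if (any(pathogenic_rows)) return(5L)
  if (any(likely_pathogenic_rows)) return(4L)
  if (any(benign_rows)) return(1L)
  if (any(likely_benign_rows)) return(2L)
  3L
}

# Applies a (pos, ref, alt) replacement to a reference context string.
apply_to_context <- function(context, context_start, pos, ref, alt) {
  i <- pos - context_start + 1
  stopifnot(substr(context, i, i + nchar(ref) - 1) == ref)
  paste0(substr(context, 1, i - 1), alt,
         substr(context, i + nchar(ref), nchar(context)))
}

# Brute-force left-shift oracle for deletions: enumerates every anchored
# placement of a deletion of the same length inside the context, keeps the
# placements whose mutated sequence equals the observed one, and returns
# the left-most.
oracle_left_align_deletion <- function(context, context_start, pos, ref,
                                       alt) {
  target <- apply_to_context(context, context_start, pos, ref, alt)
  d <- nchar(ref) - nchar(alt)
  stopifnot(d > 0)
  best <- NULL
  for (p in rev(seq(context_start, context_start + nchar(context) - d - 1))) {
    i <- p - context_start + 1
    cand_ref <- substr(context, i, i + d)
    cand_alt <- substr(context, i, i)
    mutated <- apply_to_context(context, context_start, p, cand_ref,
                                cand_alt)
    if (mutated == target)
      best <- list(pos = p, ref = cand_ref, alt = cand_alt)
  }
  best
}
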