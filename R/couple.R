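#' Construct a candidate gene
#'
#' @param gene HGNC symbol.
#' @param mode `"shared_hom"` (both partners carry the identical variant;
#'   offspring can be homozygous) or `"compound_het"` (different variants in
#'   the same gene; offspring can be compound heterozygous).
#' @param maternal,paternal record tables of the participating variants.
#' @param low_confidence logical flag, set for compound events built from
#'   distinct exon-level deletions in one gene, where the two events may in
#'   truth be one allele.
#' @return an object of class `candidate_gene`.
#' @export
candidate_gene <- function(gene, mode, maternal, paternal,
                           low_confidence = FALSE) {
  stopifnot(mode %in% c("shared_hom", "compound_het"),
            nrow(maternal) >= 1, nrow(paternal) >= 1,
            all(maternal$gene == gene), all(paternal$gene == gene))
  mk <- variant_key(maternal)
  pk <- variant_key(paternal)
  if (mode == "shared_hom") {
    if (!any(mk %in% pk))
      stop("shared_hom candidate without an identity-equal variant pair")
  } else {
    if (any(mk %in% pk))
      stop("compound_het candidate with an identity-equal variant pair")
  }
  structure(list(
    gene = gene, mode = mode,
    maternal = maternal, paternal = paternal,
    offspring_risk_genotype = if (mode == "shared_hom") "homozygous"
                              else "compound_heterozygous",
    low_confidence = isTRUE(low_confidence)),
    class = "candidate_gene")
}

#' @export
print.candidate_gene <- function(x, ...) {
  lab <- function(r) paste(unique(ifelse(r$hgvs_c != "", r$hgvs_c,
                                         variant_key(r))), collapse = "+")
  cat(sprintf("%s [%s]%s  maternal: %s | paternal: %s\n", x$gene, x$mode,
              if (x$low_confidence) " (low confidence)" else "",
              lab(x$maternal), lab(x$paternal)))
  invisible(x)
}

#' Nominate autosomal-recessive candidate genes for a couple
#'
#' The core intersection step of the screen. Both inputs are the filtered
#' heterozygous record sets of the two partners. For every gene carried by
#' both partners the matcher emits
#' \itemize{
#'   \item one `shared_hom` candidate per variant that is identity-equal
#'     (normalized `chrom:pos:ref:alt`, or `gene:exon` for exon deletions)
#'     in both partners — the offspring can be homozygous; and
#'   \item one `compound_het` candidate when the partners additionally (or
#'     only) carry non-identical variants in that gene — the offspring can
#'     be compound heterozygous, one allele from each parent, so trans phase
#'     holds by construction and no phasing is needed.
#' }
#' Genes carried by only one partner are never emitted. The candidate list
#' is symmetric in the two parents and sorted by gene symbol.
#'
#' Exon-level copy-number records are matched by their (gene, exon) label:
#' an identical deletion in both partners gives a `shared_hom` candidate;
#' distinct deletions in one gene give a `compound_het` candidate flagged
#' low-confidence.
#'
#' @param mother,father filtered record tables (see
#'   [filter_parent_variants()]).
#' @return list of `candidate_gene` objects, sorted by gene.
#' @export
match_couple <- function(mother, father) {
  mother <- normalize_variant(mother)
  father <- normalize_variant(father)
  seqm <- mother[mother$kind != "exon_cnv", , drop = FALSE]
  seqf <- father[father$kind != "exon_cnv", , drop = FALSE]
  out <- c(match_by_key(seqm, seqf, cnv = FALSE),
           match_cnv(mother, father))
  out[order(vapply(out, function(c) paste(c$gene, c$mode), character(1)))]
}

#' Match exon-level copy-number events between partners
#'
#' @param mother,father record tables; only `exon_cnv` rows are considered.
#' @return list of `candidate_gene` objects.
#' @export
match_cnv <- function(mother, father) {
  cm <- mother[mother$kind == "exon_cnv", , drop = FALSE]
  cf <- father[father$kind == "exon_cnv", , drop = FALSE]
  match_by_key(cm, cf, cnv = TRUE)
}

match_by_key <- function(mother, father, cnv = FALSE) {
  genes <- intersect(unique(mother$gene), unique(father$gene))
  out <- list()
  for (g in sort(genes)) {
    m <- mother[mother$gene == g, , drop = FALSE]
    f <- father[father$gene == g, , drop = FALSE]
    mk <- variant_key(m)
    fk <- variant_key(f)
    for (k in sort(intersect(mk, fk))) {
      out[[length(out) + 1]] <- candidate_gene(
        g, "shared_hom",
        m[mk == k, , drop = FALSE][1, , drop = FALSE],
        f[fk == k, , drop = FALSE][1, , drop = FALSE])
    }
    # compound branch: the offspring can inherit two *different* variants,
    # one per parent; exists iff the couple carries >= 2 distinct variants
    # in the gene. Shared variants already have their own shared_hom
    # candidate, so compound lists prefer each parent's private variants
    # and fall back to shared ones (kept disjoint) only when a side has
    # none of its own.
    shared <- intersect(mk, fk)
    m_only <- setdiff(mk, fk)
    f_only <- setdiff(fk, mk)
    if (length(unique(c(mk, fk))) >= 2) {
      if (length(m_only) == 0 && length(f_only) == 0) {
        s <- sort(shared)
        msel <- s[1]
        fsel <- s[-1]
      } else if (length(m_only) == 0) {
        msel <- shared
        fsel <- f_only
      } else if (length(f_only) == 0) {
        msel <- m_only
        fsel <- shared
      } else {
        msel <- m_only
        fsel <- f_only
      }
      out[[length(out) + 1]] <- candidate_gene(
        g, "compound_het",
        m[mk %in% msel, , drop = FALSE],
        f[fk %in% fsel, , drop = FALSE],
        low_confidence = cnv)
    }
  }
  out
}
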