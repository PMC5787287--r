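#' Construct a child/fetus observation
#'
#' @param child_id sample identifier.
#' @param affected logical disease status.
#' @param genotypes record table of the child's genotype calls at the
#'   candidate variants (empty when no material was available).
#' @param material_available logical; when `FALSE`, `genotypes` must be
#'   empty.
#' @return an object of class `child_observation`.
#' @export
child_observation <- function(child_id, affected, genotypes = NULL,
                              material_available = !is.null(genotypes) &&
                                nrow(genotypes) > 0) {
  if (is.null(genotypes)) genotypes <- record_columns()
  if (!material_available && nrow(genotypes) > 0)
    stop("child ", child_id,
         ": genotypes supplied but material_available is FALSE")
  structure(list(child_id = child_id, affected = isTRUE(affected),
                 genotypes = genotypes,
                 material_available = isTRUE(material_available)),
            class = "child_observation")
}

candidate_keys <- function(candidate) {
  unique(c(variant_key(candidate$maternal), variant_key(candidate$paternal)))
}

# Genotype of one child at a candidate: "risk" (matches the offspring risk
# genotype), "carrier" (one allele), "noncarrier", or "untyped".
child_candidate_genotype <- function(candidate, child) {
  gt <- child$genotypes
  keys <- variant_key(gt)
  extra <- setdiff(keys[gt$gene == candidate$gene], candidate_keys(candidate))
  if (length(extra))
    stop("child ", child$child_id, " genotyped at variant(s) absent from ",
         "the ", candidate$gene, " candidate: ",
         paste(extra, collapse = ", "))
  gt <- gt[keys %in% candidate_keys(candidate), , drop = FALSE]
  if (nrow(gt) == 0) return("untyped")
  keys <- variant_key(gt)
  if (candidate$mode == "shared_hom") {
    z <- gt$zygosity[match(candidate_keys(candidate)[1], keys)]
    if (is.na(z)) return("untyped")
    switch(z, hom = "risk", het = "carrier", absent = "noncarrier")
  } else {
    mat <- any(keys %in% variant_key(candidate$maternal) &
                 gt$zygosity != "absent")
    pat <- any(keys %in% variant_key(candidate$paternal) &
                 gt$zygosity != "absent")
    if (mat && pat) "risk" else if (mat || pat) "carrier" else "noncarrier"
  }
}

#' Check a candidate gene for cosegregation with disease in children
#'
#' Compares each child's genotype at the candidate's variants with the
#' genotype predicted to cause disease (homozygous for a shared variant;
#' carrying both alleles for a compound-heterozygous candidate).
#'
#' Overall status: `confirmed` when at least one *affected* child carries
#' the risk genotype; `inconsistent` when an *unaffected* child carries it;
#' `carrier_only` when affected children were genotyped but none carries
#' the risk genotype; `unavailable` when no affected child had material.
#' A single affected child with a matching genotype suffices for
#' confirmation.
#'
#' @param candidate a `candidate_gene`.
#' @param children list of [child_observation()] objects.
#' @return an object of class `cosegregation_result`: list with `candidate`,
#'   `status` and `per_child` (named character vector of per-child calls:
#'   `affected_genotype`, `carrier`, `noncarrier`, `no_material`).
#' @export
check_cosegregation <- function(candidate, children) {
  per_child <- character(0)
  confirmed <- FALSE
  inconsistent <- FALSE
  any_affected_typed <- FALSE
  for (child in children) {
    stopifnot(inherits(child, "child_observation"))
    if (!child$material_available) {
      per_child[child$child_id] <- "no_material"
      next
    }
    g <- child_candidate_genotype(candidate, child)
    if (g == "untyped") {
      per_child[child$child_id] <- "no_material"
      next
    }
    per_child[child$child_id] <- switch(g, risk = "affected_genotype",
                                        carrier = "carrier",
                                        noncarrier = "noncarrier")
    if (child$affected) {
      any_affected_typed <- TRUE
      if (g == "risk") confirmed <- TRUE
    } else if (g == "risk") {
      inconsistent <- TRUE
    }
  }
  status <- if (inconsistent) "inconsistent"
            else if (confirmed) "confirmed"
            else if (any_affected_typed) "carrier_only"
            else "unavailable"
  structure(list(candidate = candidate, status = status,
                 per_child = per_child),
            class = "cosegregation_result")
}

#' @export
print.cosegregation_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %s\n", x$candidate$gene, x$candidate$mode, x$status))
  if (length(x$per_child))
    for (id in names(x$per_child))
      cat("  ", id, ": ", x$per_child[[id]], "\n", sep = "")
  invisible(x)
}

#' Mendelian recurrence risk for a future pregnancy
#'
#' Exact Mendelian risks for the two inheritance patterns the screen
#' addresses. An autosomal-recessive candidate with both parents
#' heterozygous carriers gives a 1/4 risk of an affected conceptus in every
#' pregnancy, independent of fetal sex. A maternally inherited X-linked
#' candidate with a carrier mother gives a 1/2 risk for a male pregnancy
#' and (under full recessivity) zero risk of an affected female; with fetal
#' sex unknown the marginal risk is 1/4. Any non-carrier configuration
#' gives zero (de novo and mosaic contributions are ignored).
#'
#' @param inheritance `"AR"` or `"XL_maternal"`.
#' @param fetus_sex `"male"`, `"female"` or `"unknown"`.
#' @param both_parents_carriers logical (AR mode).
#' @param mother_carrier logical (XL mode).
#' @return numeric probability in \{0, 0.25, 0.5\}.
#' @export
#' @examples
#' recurrence_risk("AR", both_parents_carriers = TRUE)           # 0.25
#' recurrence_risk("XL_maternal", fetus_sex = "male",
#'                 mother_carrier = TRUE)                        # 0.5
recurrence_risk <- function(inheritance = c("AR", "XL_maternal"),
                            fetus_sex = c("unknown", "male", "female"),
                            both_parents_carriers = FALSE,
                            mother_carrier = FALSE) {
  inheritance <- match.arg(inheritance)
  fetus_sex <- match.arg(fetus_sex)
  if (inheritance == "AR") {
    if (isTRUE(both_parents_carriers)) 0.25 else 0
  } else {
    if (!isTRUE(mother_carrier)) return(0)
    switch(fetus_sex, male = 0.5, female = 0, unknown = 0.25)
  }
}

#' Interpret a fetal genotype at a candidate gene
#'
#' @param candidate a `candidate_gene`.
#' @param fetus a [child_observation()] with genotypes at the candidate's
#'   variants.
#' @return one of `"unaffected_noncarrier"`, `"carrier"`,
#'   `"affected_genotype"`.
#' @export
fetal_genotype_interpretation <- function(candidate, fetus) {
  g <- child_candidate_genotype(candidate, fetus)
  if (g == "untyped")
    stop("fetus ", fetus$child_id, " not genotyped at the ",
         candidate$gene, " candidate")
  switch(g, risk = "affected_genotype", carrier = "carrier",
         noncarrier = "unaffected_noncarrier")
}
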