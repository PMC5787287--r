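#' Read a pedigree sidecar table
#'
#' Tab-separated file with columns `sample_id`, `role`
#' (`mother`/`father`/`child`/`fetus`), `affected` (0/1), `sex` (M/F/U),
#' `material` (0/1).
#'
#' @param path TSV file path.
#' @return data.frame with logical `affected` and `material` columns.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("sample_id", "role", "affected", "sex", "material")
  miss <- setdiff(need, names(ped))
  if (length(miss))
    stop("pedigree file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!all(ped$role %in% c("mother", "father", "child", "fetus")))
    stop("pedigree file ", path, ": unknown role value")
  ped$affected <- ped$affected == 1
  ped$material <- ped$material == 1
  ped
}

#' Build child observations from a children VCF and a pedigree
#'
#' @param children_vcf path to the multi-sample children VCF, or `NULL`
#'   when no child was genotyped.
#' @param pedigree data.frame from [read_pedigree()].
#' @return list of [child_observation()] objects, one per pedigree row with
#'   role `child` or `fetus`.
#' @export
read_children <- function(children_vcf, pedigree) {
  kids <- pedigree[pedigree$role %in% c("child", "fetus"), , drop = FALSE]
  lapply(seq_len(nrow(kids)), function(i) {
    id <- kids$sample_id[i]
    gts <- NULL
    if (kids$material[i] && !is.null(children_vcf) &&
        file.exists(children_vcf)) {
      all_gt <- read_annotated_vcf(children_vcf, id)
      gts <- all_gt
    }
    child_observation(id, affected = kids$affected[i], genotypes = gts,
                      material_available = kids$material[i])
  })
}

#' Screen one couple for autosomal-recessive candidate genes
#'
#' Runs the full per-couple pipeline: optional panel restriction, the
#' per-parent filter cascade, gene-level intersection of the partners,
#' ACMG/AMP classification of each candidate's maternal and paternal
#' alleles, the Class-4/5 eligibility rule for prenatal/preimplantation
#' diagnostics, and (when children are supplied) cosegregation against
#' affected-child genotypes.
#'
#' When a panel with inheritance annotations is used, X-linked genes are
#' excluded from the couple intersection (which is specific to autosomal
#' recessive inheritance) and maternal heterozygous X-linked records are
#' returned separately in `$xl_maternal`.
#'
#' @param mother,father record tables for the two partners (e.g. from
#'   [read_annotated_vcf()]).
#' @param couple_id identifier for the couple.
#' @param panel optional `gene_panel`; `NULL` means exome (WES) mode, no
#'   restriction.
#' @param params a [filter_params()] object.
#' @param children list of [child_observation()] objects (may be empty).
#' @param consanguinity free-text consanguinity label for the report.
#' @param evidence optional named vector of sidecar ACMG evidence codes
#'   (see [read_evidence_tsv()]), attached where the records carry none.
#' @return an object of class `couple_report`: list with `couple_id`,
#'   `consanguinity`, `mode` (`"panel"`/`"wes"`), `candidates` (list of
#'   `candidate_gene`), `classes` (data.frame: gene, mode, class_m,
#'   class_f, eligible, reportable, coseg_status), `cosegregation` (list of
#'   `cosegregation_result`), `xl_maternal` (record table) and
#'   `summary_tier` (`class45_match` / `class3_candidate` / `no_finding`).
#' @export
screen_couple <- function(mother, father, couple_id = "couple",
                          panel = NULL, params = filter_params(),
                          children = list(), consanguinity = "unknown",
                          evidence = NULL) {
  mode <- if (is.null(panel)) "wes" else "panel"
  xl_maternal <- record_columns()
  if (!is.null(panel)) {
    mother <- restrict_to_panel(mother, panel)
    father <- restrict_to_panel(father, panel)
    xl <- panel_xl_genes(panel)
    if (length(xl)) {
      xl_maternal <- mother[mother$gene %in% xl &
                              mother$zygosity == "het", , drop = FALSE]
      xl_maternal <- filter_parent_variants(xl_maternal, params)
      mother <- mother[!mother$gene %in% xl, , drop = FALSE]
      father <- father[!father$gene %in% xl, , drop = FALSE]
    }
  }
  if (!is.null(evidence)) {
    mother <- attach_evidence(mother, evidence)
    father <- attach_evidence(father, evidence)
  }
  fm <- filter_parent_variants(mother, params)
  ff <- filter_parent_variants(father, params)
  candidates <- match_couple(fm, ff)

  coseg <- lapply(candidates, check_cosegregation, children = children)
  classes <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    cm <- max(classify_records(cand$maternal))
    cf <- max(classify_records(cand$paternal))
    data.frame(gene = cand$gene, mode = cand$mode,
               class_m = cm, class_f = cf,
               eligible = eligible_for_action(cm, cf),
               reportable = reportable(cm) && reportable(cf),
               coseg_status = coseg[[i]]$status,
               stringsAsFactors = FALSE)
  }))
  if (is.null(classes))
    classes <- data.frame(gene = character(), mode = character(),
                          class_m = integer(), class_f = integer(),
                          eligible = logical(), reportable = logical(),
                          coseg_status = character(),
                          stringsAsFactors = FALSE)
  tier <- if (any(classes$eligible)) "class45_match"
          else if (any(classes$reportable)) "class3_candidate"
          else "no_finding"
  structure(list(couple_id = couple_id, consanguinity = consanguinity,
                 mode = mode, params = params, candidates = candidates,
                 classes = classes, cosegregation = coseg,
                 xl_maternal = xl_maternal, summary_tier = tier),
            class = "couple_report")
}

#' Screen a couple directly from files
#'
#' Thin file-level wrapper around [screen_couple()]: reads the two parental
#' VCFs, an optional panel, an optional pedigree plus children VCF and an
#' optional evidence sidecar, and optionally writes the TSV/JSON report
#' pair.
#'
#' @param mother_vcf,father_vcf annotated VCF paths.
#' @param couple_id identifier for the couple.
#' @param panel_path optional panel file (panel mode); `NULL` = WES mode.
#' @param pedigree_path optional pedigree TSV.
#' @param children_vcf optional children VCF (needs `pedigree_path`).
#' @param evidence_path optional evidence sidecar TSV.
#' @param config_path optional filter-parameter YAML.
#' @param consanguinity free-text label for the report.
#' @param out_prefix when non-`NULL`, write `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return a `couple_report`.
#' @export
screen_couple_files <- function(mother_vcf, father_vcf,
                                couple_id = "couple", panel_path = NULL,
                                pedigree_path = NULL, children_vcf = NULL,
                                evidence_path = NULL, config_path = NULL,
                                consanguinity = "unknown",
                                out_prefix = NULL) {
  params <- if (is.null(config_path)) filter_params()
            else read_filter_config(config_path)
  panel <- if (is.null(panel_path)) NULL else load_panel(panel_path)
  mother <- read_annotated_vcf(mother_vcf, "mother")
  father <- read_annotated_vcf(father_vcf, "father")
  children <- list()
  if (!is.null(pedigree_path)) {
    ped <- read_pedigree(pedigree_path)
    children <- read_children(children_vcf, ped)
  }
  evidence <- if (is.null(evidence_path)) NULL
              else read_evidence_tsv(evidence_path)
  report <- screen_couple(mother, father, couple_id = couple_id,
                          panel = panel, params = params,
                          children = children,
                          consanguinity = consanguinity,
                          evidence = evidence)
  if (!is.null(out_prefix)) write_couple_report(report, out_prefix)
  report
}

report_table <- function(report) {
  cls <- report$classes
  n <- nrow(cls)
  hgvs_or_key <- function(r) {
    lab <- ifelse(r$hgvs_c != "" & !is.na(r$hgvs_c), r$hgvs_c,
                  variant_key(r))
    paste(lab, collapse = "+")
  }
  data.frame(
    couple_id = rep(report$couple_id, n),
    gene = cls$gene, mode = cls$mode,
    maternal_variant = vapply(report$candidates,
                              function(c) hgvs_or_key(c$maternal),
                              character(1)),
    paternal_variant = vapply(report$candidates,
                              function(c) hgvs_or_key(c$paternal),
                              character(1)),
    class_m = cls$class_m, class_f = cls$class_f,
    eligible = cls$eligible, coseg_status = cls$coseg_status,
    tier = rep(report$summary_tier, n),
    stringsAsFactors = FALSE)
}

#' Write a couple report as TSV and JSON
#'
#' The two files carry the same records: one row/object per candidate gene
#' with the fixed column set `couple_id, gene, mode, maternal_variant,
#' paternal_variant, class_m, class_f, eligible, coseg_status, tier`.
#'
#' @param report a `couple_report`.
#' @param out_prefix output path prefix.
#' @return the table written, invisibly.
#' @export
write_couple_report <- function(report, out_prefix) {
  tab <- report_table(report)
  utils::write.table(tab, paste0(out_prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(couple_id = report$couple_id,
         consanguinity = report$consanguinity,
         mode = report$mode, summary_tier = report$summary_tier,
         candidates = tab),
    paste0(out_prefix, ".json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(tab)
}

#' @export
print.couple_report <- function(x, ...) {
  cat("Couple screening report: ", x$couple_id,
      " (", x$mode, " mode, consanguinity: ", x$consanguinity, ")\n",
      sep = "")
  if (nrow(x$classes) == 0) {
    cat("  no candidate genes\n")
  } else {
    for (i in seq_len(nrow(x$classes))) {
      cl <- x$classes[i, ]
      cat(sprintf("  %-8s %-12s Class %d/%d  %s  coseg: %s\n", cl$gene,
                  cl$mode, cl$class_m, cl$class_f,
                  if (cl$eligible) "eligible for PND/PGD"
                  else if (cl$reportable) "reportable (VUS)"
                  else "not reportable",
                  cl$coseg_status))
    }
  }
  if (nrow(x$xl_maternal) > 0)
    cat("  maternal X-linked carrier findings: ",
        paste(unique(x$xl_maternal$gene), collapse = ", "), "\n", sep = "")
  cat("  tier: ", x$summary_tier, "\n", sep = "")
  invisible(x)
}

#' @export
summary.couple_report <- function(object, ...) {
  cat(object$couple_id, ": ", object$summary_tier, ", ",
      nrow(object$classes), " candidate gene(s), ",
      sum(object$classes$eligible), " eligible\n", sep = "")
  invisible(object$classes)
}

#' Summarize a cohort of couple reports
#'
#' Tiers every couple by its best candidate (eligible Class-4/5 pair >
#' reportable Class-3 candidate > no finding) and counts couples with at
#' least one cosegregation-confirmed candidate. Invariant:
#' `n_class45_match + n_class3_candidate + n_no_finding = n_couples`.
#'
#' @param reports list of `couple_report` objects.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(reports) {
  ids <- vapply(reports, function(r) r$couple_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate couple_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tiers <- vapply(reports, function(r) r$summary_tier, character(1))
  confirmed <- vapply(reports, function(r)
    any(vapply(r$cosegregation, function(c) c$status == "confirmed",
               logical(1))), logical(1))
  structure(list(
    n_couples = length(reports),
    n_class45_match = sum(tiers == "class45_match"),
    n_class3_candidate = sum(tiers == "class3_candidate"),
    n_no_finding = sum(tiers == "no_finding"),
    n_confirmed_in_child = sum(confirmed),
    tiers = stats::setNames(tiers, ids),
    confirmed = stats::setNames(confirmed, ids)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  pct <- function(n) sprintf("%d/%d (%.0f%%)", n, x$n_couples,
                             100 * n / max(x$n_couples, 1))
  cat("Cohort of ", x$n_couples, " couples\n", sep = "")
  cat("  likely causative (Class 4/5, eligible):  ",
      pct(x$n_class45_match), "\n", sep = "")
  cat("  novel candidate (Class 3, reportable):   ",
      pct(x$n_class3_candidate), "\n", sep = "")
  cat("  no finding:                              ",
      pct(x$n_no_finding), "\n", sep = "")
  cat("  confirmed in an affected child:          ",
      x$n_confirmed_in_child, "\n", sep = "")
  invisible(x)
}

#' Run the screen over a fixture cohort directory
#'
#' Expects the layout written by [build_table1_fixture()] (or
#' [write_simulated_couple()] outputs arranged the same way): one directory
#' per couple with `mother.vcf`, `father.vcf` and optional `children.vcf`,
#' `pedigree.tsv`, `evidence.tsv`.
#'
#' @param dir cohort directory.
#' @param params a [filter_params()] object (currently applied through the
#'   per-couple defaults; pass a config file via `config_path`).
#' @param panel_path optional panel file applied to every couple (`NULL` =
#'   WES mode, as used for the demonstration cohort, whose exome-tier
#'   findings lie outside any panel).
#' @param config_path optional filter-parameter YAML applied to every
#'   couple.
#' @return list with `reports` (list of `couple_report`) and `summary`
#'   (a `cohort_summary`).
#' @export
run_cohort <- function(dir, panel_path = NULL, config_path = NULL) {
  fam_dirs <- sort(list.dirs(dir, recursive = FALSE))
  fam_dirs <- fam_dirs[file.exists(file.path(fam_dirs, "mother.vcf"))]
  if (length(fam_dirs) == 0) stop("no couple directories under ", dir)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  reports <- lapply(fam_dirs, function(fdir) {
    id <- basename(fdir)
    ped_path <- file.path(fdir, "pedigree.tsv")
    kids_path <- file.path(fdir, "children.vcf")
    ev_path <- file.path(fdir, "evidence.tsv")
    consang <- if (!is.null(manifest$families[[id]]$consanguinity))
      manifest$families[[id]]$consanguinity else "unknown"
    screen_couple_files(
      file.path(fdir, "mother.vcf"), file.path(fdir, "father.vcf"),
      couple_id = id, panel_path = panel_path, config_path = config_path,
      pedigree_path = if (file.exists(ped_path)) ped_path else NULL,
      children_vcf = if (file.exists(kids_path)) kids_path else NULL,
      evidence_path = if (file.exists(ev_path)) ev_path else NULL,
      consanguinity = consang)
  })
  list(reports = reports, summary = summarize_cohort(reports))
}
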