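#' Kinship coefficient from a pedigree relationship
#'
#' Standard path-counting kinship: every loop through a common ancestor of
#' total length \eqn{L} (meioses up one side, down the other, plus one)
#' contributes \eqn{(1/2)^L}, assuming non-inbred common ancestors. First
#' cousins have two such loops of length 5, giving \eqn{\phi = 2 (1/2)^5 =
#' 1/16}; double first cousins have four, giving 1/8. The inbreeding
#' coefficient of the couple's offspring equals the partners' kinship
#' \eqn{F = \phi}.
#'
#' @param relation one of `"unrelated"`, `"first_cousins"`,
#'   `"double_first_cousins"`, `"custom"`.
#' @param paths for `relation = "custom"`: integer vector of loop lengths
#'   (each >= 2), one per connecting loop.
#' @return the kinship coefficient \eqn{\phi} as a fraction.
#' @export
#' @examples
#' kinship_coefficient("first_cousins")         # 1/16
#' kinship_coefficient("custom", paths = c(5, 5, 5, 5))  # double first cousins
kinship_coefficient <- function(relation = c("unrelated", "first_cousins",
                                             "double_first_cousins",
                                             "custom"),
                                paths = NULL) {
  relation <- match.arg(relation)
  paths <- switch(relation,
    unrelated = integer(0),
    first_cousins = c(5L, 5L),
    double_first_cousins = c(5L, 5L, 5L, 5L),
    custom = {
      if (is.null(paths) || length(paths) == 0 ||
          any(is.na(paths)) || any(paths < 2) || any(paths != round(paths)))
        stop("custom relation needs integer loop path lengths >= 2")
      as.integer(paths)
    })
  sum(0.5 ^ paths)
}

#' Configuration for the couple-genotype simulator
#'
#' @param n_background_variants number of rare background heterozygous
#'   variants given to each parent.
#' @param maf_spectrum two-column matrix or data.frame (`frequency`,
#'   `weight`): the population allele-frequency spectrum background
#'   variants are drawn from; weights must sum to 1.
#' @param kinship kinship coefficient \eqn{\phi} between the partners, in
#'   \[0, 0.25\].
#' @param planted_candidates data.frame with columns `gene` and `mode`
#'   (`"shared_hom"`/`"compound_het"`): engineered candidates spiked into
#'   both partners, guaranteed to pass the filter cascade.
#' @param seed integer seed; identical configurations produce byte-identical
#'   output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_background_variants = 64L,
                              maf_spectrum = data.frame(frequency = 0.001,
                                                        weight = 1),
                              kinship = 1 / 16,
                              planted_candidates = NULL,
                              seed = 1L) {
  maf_spectrum <- as.data.frame(maf_spectrum)
  stopifnot(n_background_variants >= 0,
            all(c("frequency", "weight") %in% names(maf_spectrum)),
            all(maf_spectrum$frequency >= 0 & maf_spectrum$frequency <= 1),
            abs(sum(maf_spectrum$weight) - 1) < 1e-8,
            kinship >= 0, kinship <= 0.25)
  if (is.null(planted_candidates))
    planted_candidates <- data.frame(gene = character(),
                                     mode = character(),
                                     stringsAsFactors = FALSE)
  stopifnot(all(planted_candidates$mode %in%
                  c("shared_hom", "compound_het")))
  structure(list(n_background_variants = as.integer(n_background_variants),
                 maf_spectrum = maf_spectrum,
                 kinship = kinship,
                 planted_candidates = planted_candidates,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulator configuration from YAML
#'
#' Keys: `n_background_variants`, `kinship`, `seed`, `maf_spectrum` (list of
#' `{frequency, weight}` maps), `planted_candidates` (list of
#' `{gene, mode}` maps).
#'
#' @param path YAML file path.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_background_variants", "maf_spectrum", "kinship",
             "planted_candidates", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown simulator configuration key(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(cfg$maf_spectrum))
    cfg$maf_spectrum <- do.call(rbind, lapply(cfg$maf_spectrum,
                                              as.data.frame))
  if (!is.null(cfg$planted_candidates))
    cfg$planted_candidates <- do.call(rbind, lapply(cfg$planted_candidates,
                                                    as.data.frame))
  do.call(simulation_config, cfg)
}

sim_gene <- function(i) sprintf("GENE%04d", i)

# A background variant passing every filter predicate: rare missense with a
# high CADD score. `freq` goes into the ExAC field (clamped under 1).
sim_background_records <- function(sample_id, idx, freq, zygosity = "het") {
  n <- length(idx)
  if (n == 0) return(record_columns())
  validate_records(data.frame(
    chrom = rep("1", n), pos = as.integer(idx * 1000L),
    ref = rep("A", n), alt = rep("G", n),
    gene = sim_gene(idx), transcript = rep("", n),
    hgvs_c = sprintf("c.%d00A>G", idx), hgvs_p = rep("", n),
    consequence = rep("missense", n), kind = rep("snv", n),
    exon = rep(NA_character_, n), sample_id = rep(sample_id, n),
    zygosity = rep(zygosity, n),
    maf_dbsnp = rep(NA_real_, n), maf_esp = rep(NA_real_, n),
    maf_exac = pmin(freq, 0.0099),
    hgmd_dm = rep(FALSE, n), clinvar_patho = rep(FALSE, n),
    cadd = rep(25, n), sift_del = rep(TRUE, n), pph2_dam = rep(TRUE, n),
    splice_dam = rep(NA, n), acmg = rep(NA_character_, n),
    stringsAsFactors = FALSE))
}

plant_records <- function(sample_id, planted, offset) {
  recs <- record_columns()
  if (nrow(planted) == 0) return(recs)
  for (i in seq_len(nrow(planted))) {
    pos <- as.integer(offset + i * 1000L)
    # compound_het: the two partners get different alleles at neighbouring
    # positions of the same gene; shared_hom: the identical variant.
    second_allele <- planted$mode[i] == "compound_het" &&
      sample_id == "father"
    recs <- rbind(recs, variant_record(
      chrom = "2", pos = pos + if (second_allele) 10L else 0L,
      ref = "C", alt = if (second_allele) "G" else "T",
      gene = planted$gene[i],
      hgvs_c = sprintf("c.%dC>%s", pos, if (second_allele) "G" else "T"),
      consequence = "missense", kind = "snv",
      sample_id = sample_id, zygosity = "het", cadd = 28))
  }
  recs
}

#' Simulate a carrier couple with known ground truth
#'
#' The mother receives `n_background_variants` rare heterozygous variants,
#' one per synthetic gene, with population frequencies drawn from the
#' configured spectrum. For each of them the father carries the *identical*
#' variant with probability \eqn{\phi + (1-\phi)\,2p(1-p)}: with
#' probability \eqn{\phi} the partners' alleles are identical by descent,
#' otherwise the father happens to carry the same allele by chance at
#' population frequency \eqn{p} (heterozygote frequency \eqn{2p(1-p)}).
#' The father additionally receives his own independent background variants
#' in separate genes, and any planted candidates are inserted in both
#' partners. Every simulated variant passes the filter cascade, so the
#' screen's behaviour on the output is governed purely by the sharing
#' structure.
#'
#' The returned truth table lists every gene engineered to be shared
#' (background IBD/chance sharing plus planted candidates); the recovery
#' property is that [match_couple()] on the filtered output finds exactly
#' the planted candidates plus background-shared genes.
#'
#' @param cfg a [simulation_config()].
#' @return list with `mother`, `father` (record tables) and `truth`
#'   (data.frame: `gene`, `mode`, `origin` in
#'   `background_shared`/`planted`).
#' @export
simulate_couple <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_background_variants
  draw_freqs <- function(n) {
    if (n == 0) return(numeric(0))
    idx <- sample.int(nrow(cfg$maf_spectrum), n, replace = TRUE,
                      prob = cfg$maf_spectrum$weight)
    cfg$maf_spectrum$frequency[idx]
  }
  freqs <- draw_freqs(n)
  mother <- sim_background_records("mother", seq_len(n), freqs)
  p_share <- cfg$kinship + (1 - cfg$kinship) * 2 * freqs * (1 - freqs)
  shared <- if (n > 0) stats::runif(n) < p_share else logical(0)
  father_shared <- mother[shared, , drop = FALSE]
  if (nrow(father_shared) > 0) father_shared$sample_id <- "father"
  father_freqs <- draw_freqs(n)
  father_own <- sim_background_records("father", n + seq_len(n),
                                       father_freqs)
  planted_m <- plant_records("mother", cfg$planted_candidates, 10000L)
  planted_f <- plant_records("father", cfg$planted_candidates, 10000L)
  mother <- rbind(mother, planted_m)
  father <- rbind(father_shared, father_own, planted_f)
  truth <- rbind(
    if (any(shared)) data.frame(gene = sim_gene(which(shared)),
                                mode = "shared_hom",
                                origin = "background_shared",
                                stringsAsFactors = FALSE),
    if (nrow(cfg$planted_candidates))
      data.frame(gene = cfg$planted_candidates$gene,
                 mode = cfg$planted_candidates$mode,
                 origin = "planted", stringsAsFactors = FALSE))
  if (is.null(truth))
    truth <- data.frame(gene = character(), mode = character(),
                        origin = character(), stringsAsFactors = FALSE)
  list(mother = mother, father = father, truth = truth)
}

#' Expected number of shared candidate genes under the sharing model
#'
#' Closed form for the mean size of [simulate_couple()]'s truth table:
#' \deqn{n\,[\phi + (1-\phi) \sum_j w_j\, 2 p_j (1-p_j)] + n_{planted}.}
#' With first-cousin kinship \eqn{\phi = 1/16}, 64 effectively private
#' background variants (\eqn{p \to 0}) and nothing planted this is
#' \eqn{64/16 = 4} shared genes — the order of magnitude seen when exome
#' screening consanguineous couples.
#'
#' @param cfg a [simulation_config()].
#' @return expected shared-gene count (numeric).
#' @export
expected_shared_genes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- cfg$maf_spectrum$frequency
  w <- cfg$maf_spectrum$weight
  chance <- sum(w * 2 * p * (1 - p))
  cfg$n_background_variants * (cfg$kinship + (1 - cfg$kinship) * chance) +
    nrow(cfg$planted_candidates)
}

#' Write a simulated couple to a directory
#'
#' Emits `mother.vcf`, `father.vcf` and `truth.tsv`; identical seeds give
#' byte-identical trees.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return the simulation list from [simulate_couple()], invisibly.
#' @export
write_simulated_couple <- function(cfg, dir) {
  sim <- simulate_couple(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotated_vcf(sim$mother, file.path(dir, "mother.vcf"))
  write_annotated_vcf(sim$father, file.path(dir, "father.vcf"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}
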