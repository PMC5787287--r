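shared_candidate <- function(gene = "ACADVL", pos = 1274L) {
  candidate_gene(
    gene, "shared_hom",
    mk_rec(gene = gene, pos = pos, ref = "T", alt = "C",
           sample_id = "mother"),
    mk_rec(gene = gene, pos = pos, ref = "T", alt = "C",
           sample_id = "father"))
}

comphet_candidate <- function(gene = "APAF1") {
  candidate_gene(
    gene, "compound_het",
    mk_rec(gene = gene, pos = 1350L, ref = "C", alt = "G",
           sample_id = "mother"),
    mk_rec(gene = gene, pos = 3127L, ref = "C", alt = "G",
           sample_id = "father"))
}

child_at <- function(id, affected, gene, pos, zygosity, ref = "T",
                     alt = "C") {
  child_observation(id, affected,
                    mk_rec(gene = gene, pos = pos, ref = ref, alt = alt,
                           sample_id = id, zygosity = zygosity))
}

test_that("an affected homozygous child confirms a shared candidate", {
  res <- check_cosegregation(
    shared_candidate(),
    list(child_at("child1", TRUE, "ACADVL", 1274L, "hom")))
  expect_equal(res$status, "confirmed")
  expect_equal(unname(res$per_child["child1"]), "affected_genotype")
})

test_that("an affected child heterozygous at a shared candidate marks the
           gene carrier-only", {
  res <- check_cosegregation(
    shared_candidate("FTCD", 530L),
    list(child_at("child3", TRUE, "FTCD", 530L, "het")))
  expect_equal(res$status, "carrier_only")
})

test_that("affected children carrying both alleles confirm a compound
           candidate", {
  fetus <- function(id) {
    child_observation(id, TRUE, rbind(
      mk_rec(gene = "APAF1", pos = 1350L, ref = "C", alt = "G",
             sample_id = id, zygosity = "het"),
      mk_rec(gene = "APAF1", pos = 3127L, ref = "C", alt = "G",
             sample_id = id, zygosity = "het")))
  }
  res <- check_cosegregation(comphet_candidate(),
                             list(fetus("fetus1"), fetus("fetus2")))
  expect_equal(res$status, "confirmed")
  expect_true(all(res$per_child == "affected_genotype"))
  # one allele only -> carrier
  one <- child_observation("fetus3", TRUE,
    mk_rec(gene = "APAF1", pos = 1350L, ref = "C", alt = "G",
           sample_id = "fetus3", zygosity = "het"))
  expect_equal(check_cosegregation(comphet_candidate(),
                                   list(one))$status, "carrier_only")
})

test_that("status falls back to unavailable / inconsistent correctly", {
  no_material <- child_observation("child1", TRUE,
                                   material_available = FALSE)
  expect_equal(check_cosegregation(shared_candidate(),
                                   list(no_material))$status, "unavailable")
  expect_equal(check_cosegregation(shared_candidate(), list())$status,
               "unavailable")
  # an unaffected child with the risk genotype contradicts causality
  healthy_hom <- child_at("child2", FALSE, "ACADVL", 1274L, "hom")
  expect_equal(check_cosegregation(shared_candidate(),
                                   list(healthy_hom))$status,
               "inconsistent")
  # an unaffected wildtype child changes nothing
  healthy_wt <- child_at("child2", FALSE, "ACADVL", 1274L, "absent")
  expect_equal(check_cosegregation(
    shared_candidate(),
    list(healthy_wt, child_at("child1", TRUE, "ACADVL", 1274L, "hom")))$status,
    "confirmed")
})

test_that("a genotype at a variant unknown to the candidate is an error", {
  stray <- child_at("child1", TRUE, "ACADVL", 9999L, "het")
  expect_error(check_cosegregation(shared_candidate(), list(stray)),
               "absent from")
})

test_that("fetal genotypes are interpreted against the risk genotype", {
  expect_equal(fetal_genotype_interpretation(
    shared_candidate("CTSD", 268L),
    child_at("fetus", FALSE, "CTSD", 268L, "het")), "carrier")
  expect_equal(fetal_genotype_interpretation(
    shared_candidate("FTCD", 530L),
    child_at("fetus", FALSE, "FTCD", 530L, "absent")),
    "unaffected_noncarrier")
  both <- child_observation("fetus", FALSE, rbind(
    mk_rec(gene = "APAF1", pos = 1350L, ref = "C", alt = "G",
           sample_id = "fetus", zygosity = "het"),
    mk_rec(gene = "APAF1", pos = 3127L, ref = "C", alt = "G",
           sample_id = "fetus", zygosity = "het")))
  expect_equal(fetal_genotype_interpretation(comphet_candidate(), both),
               "affected_genotype")
})

test_that("recurrence risks are the exact Mendelian values", {
  expect_equal(recurrence_risk("AR", both_parents_carriers = TRUE), 0.25)
  expect_equal(recurrence_risk("AR", fetus_sex = "male",
                               both_parents_carriers = TRUE), 0.25)
  expect_equal(recurrence_risk("AR", fetus_sex = "female",
                               both_parents_carriers = TRUE), 0.25)
  expect_equal(recurrence_risk("AR", both_parents_carriers = FALSE), 0)
  expect_equal(recurrence_risk("XL_maternal", fetus_sex = "male",
                               mother_carrier = TRUE), 0.5)
  expect_equal(recurrence_risk("XL_maternal", fetus_sex = "female",
                               mother_carrier = TRUE), 0)
  expect_equal(recurrence_risk("XL_maternal", fetus_sex = "unknown",
                               mother_carrier = TRUE), 0.25)
  expect_equal(recurrence_risk("XL_maternal", fetus_sex = "male",
                               mother_carrier = FALSE), 0)
  # closed set of attainable values
  grid <- expand.grid(inh = c("AR", "XL_maternal"),
                      sex = c("male", "female", "unknown"),
                      bc = c(TRUE, FALSE), mc = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  vals <- mapply(function(i, s, b, m)
    recurrence_risk(i, s, both_parents_carriers = b, mother_carrier = m),
    grid$inh, grid$sex, grid$bc, grid$mc)
  expect_true(all(vals %in% c(0, 0.25, 0.5)))
})

test_that("Mendelian transmission from carrier parents reproduces the
           25% recurrence risk", {
  set.seed(202)
  cand <- shared_candidate()
  n <- 1000
  hits <- 0
  for (i in seq_len(n)) {
    m_allele <- stats::runif(1) < 0.5
    f_allele <- stats::runif(1) < 0.5
    zyg <- if (m_allele && f_allele) "hom"
           else if (m_allele || f_allele) "het" else "absent"
    g <- fetal_genotype_interpretation(
      cand, child_at("sim", TRUE, "ACADVL", 1274L, zyg))
    if (g == "affected_genotype") hits <- hits + 1
  }
  p_hat <- hits / n
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(p_hat - recurrence_risk("AR", both_parents_carriers = TRUE)),
            3 * se)
})
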