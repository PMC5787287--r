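test_that("kinship coefficients follow path counting", {
  expect_equal(kinship_coefficient("unrelated"), 0)
  expect_equal(kinship_coefficient("first_cousins"), 1 / 16)
  # path-counting oracle for double first cousins: four loops, each a
  # grandparent path of 5 meiotic links
  expect_equal(kinship_coefficient("double_first_cousins"),
               sum(rep(0.5 ^ 5, 4)))
  expect_equal(kinship_coefficient("custom", paths = c(5, 5)), 1 / 16)
  # full sibs: two loops through the two parents, length 3 each
  expect_equal(kinship_coefficient("custom", paths = c(3, 3)), 1 / 4)
  expect_error(kinship_coefficient("custom", paths = c(1, 5)), ">= 2")
  expect_error(kinship_coefficient("custom"), ">= 2")
})

test_that("expected shared-gene count matches its closed form", {
  # single variant at p = 0.5, unrelated couple: chance sharing 2p(1-p)
  cfg <- simulation_config(n_background_variants = 1, kinship = 0,
                           maf_spectrum = data.frame(frequency = 0.5,
                                                     weight = 1))
  expect_equal(expected_shared_genes(cfg), 0.5)
  # first cousins, 64 effectively private variants: n * phi = 4
  cfg2 <- simulation_config(n_background_variants = 64, kinship = 1 / 16,
                            maf_spectrum = data.frame(frequency = 0,
                                                      weight = 1))
  expect_equal(expected_shared_genes(cfg2), 4)
  # planted candidates add one expected shared gene each
  cfg3 <- simulation_config(n_background_variants = 0, kinship = 0,
                            planted_candidates = data.frame(
                              gene = c("A", "B"),
                              mode = c("shared_hom", "compound_het")))
  expect_equal(expected_shared_genes(cfg3), 2)
})

test_that("no sharing mechanism means no shared genes", {
  cfg <- simulation_config(n_background_variants = 40, kinship = 0,
                           maf_spectrum = data.frame(frequency = 0,
                                                     weight = 1),
                           seed = 9)
  sim <- simulate_couple(cfg)
  expect_equal(nrow(sim$truth), 0L)
  cands <- match_couple(filter_parent_variants(sim$mother),
                        filter_parent_variants(sim$father))
  expect_length(cands, 0L)
})

test_that("planted candidates are recovered by the full pipeline", {
  for (seed in 1:20) {
    cfg <- simulation_config(
      n_background_variants = 30, kinship = 1 / 16,
      maf_spectrum = data.frame(frequency = 0.001, weight = 1),
      planted_candidates = data.frame(
        gene = c("PLANTA", "PLANTB"),
        mode = c("shared_hom", "compound_het")),
      seed = seed)
    sim <- simulate_couple(cfg)
    cands <- match_couple(filter_parent_variants(sim$mother),
                          filter_parent_variants(sim$father))
    found <- vapply(cands, function(c) paste(c$gene, c$mode), character(1))
    expect_true(all(c("PLANTA shared_hom", "PLANTB compound_het") %in%
                      found))
    # every truth gene is found, and every found gene is in the truth
    expect_setequal(unique(vapply(cands, function(c) c$gene,
                                  character(1))),
                    unique(sim$truth$gene))
  }
})

test_that("identical seeds give byte-identical simulator output", {
  cfg <- simulation_config(n_background_variants = 25, kinship = 1 / 16,
                           seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_couple(cfg, d1)
  write_simulated_couple(cfg, d2)
  for (f in c("mother.vcf", "father.vcf", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the realization
  write_simulated_couple(simulation_config(n_background_variants = 25,
                                           kinship = 1 / 16, seed = 43),
                         d2)
  expect_false(identical(readLines(file.path(d1, "father.vcf")),
                         readLines(file.path(d2, "father.vcf"))))
})

test_that("empirical shared-gene counts agree with the closed form", {
  cfg_of <- function(seed)
    simulation_config(n_background_variants = 48, kinship = 1 / 16,
                      maf_spectrum = data.frame(
                        frequency = c(0.0005, 0.005),
                        weight = c(0.5, 0.5)),
                      seed = seed)
  n_rep <- 400
  sizes <- vapply(seq_len(n_rep),
                  function(s) nrow(simulate_couple(cfg_of(s))$truth),
                  numeric(1))
  expected <- expected_shared_genes(cfg_of(1))
  se <- stats::sd(sizes) / sqrt(n_rep)
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("simulator configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_background_variants: 12",
    "kinship: 0.0625",
    "seed: 5",
    "maf_spectrum:",
    "  - frequency: 0.001",
    "    weight: 0.8",
    "  - frequency: 0.01",
    "    weight: 0.2",
    "planted_candidates:",
    "  - gene: COQ2",
    "    mode: compound_het"), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_background_variants, 12L)
  expect_equal(cfg$kinship, 1 / 16)
  expect_equal(cfg$planted_candidates$gene, "COQ2")
  expect_equal(nrow(cfg$maf_spectrum), 2L)
  writeLines("kinship_phi: 0.1", path)
  expect_error(read_simulation_config(path), "unknown simulator")
  expect_error(simulation_config(kinship = 0.3), "kinship")
})
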