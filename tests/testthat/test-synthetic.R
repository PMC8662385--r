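test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_single_copy = 80, n_multi_copy = 10,
                          planted_enriched_size = 15,
                          planted_target_size = 15, planted_overlap = 5,
                          seed = 23)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_synthetic_inputs(simulate_two_species(cfg), d1)
  f2 <- write_synthetic_inputs(simulate_two_species(cfg), d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]), info = nm)
  }
})

test_that("planted composition and overlap are realised exactly", {
  cfg <- synthetic_config(n_single_copy = 1000, n_multi_copy = 50,
                          planted_enriched_size = 60,
                          planted_target_size = 50, planted_overlap = 20,
                          seed = 2)
  sim <- simulate_two_species(cfg)
  tr <- sim$truth
  expect_length(tr$enriched_ids, 60)
  expect_length(tr$target_ids, 50)
  expect_length(tr$overlap_orthogroups, 20)
  expect_true(all(tr$overlap_orthogroups %in%
                    tr$enriched_single_copy_orthogroups))
  expect_true(all(tr$overlap_orthogroups %in%
                    tr$target_single_copy_orthogroups))
  # the planted overlap is exactly the intersection of the projections
  scm <- single_copy_map(sim$orthogroups)
  pe <- project_gene_set(gene_set(tr$enriched_ids), scm, "speciesA")
  pt <- project_gene_set(gene_set(tr$target_ids), scm, "speciesB")
  expect_setequal(intersect(pe, pt), tr$overlap_orthogroups)

  # multi-copy orthogroups carry 2-4 genes on one side, 1 on the other
  sizes <- vapply(sim$orthogroups$membership,
                  function(m) max(length(m[[1]]), length(m[[2]])),
                  numeric(1))
  mins <- vapply(sim$orthogroups$membership,
                 function(m) min(length(m[[1]]), length(m[[2]])),
                 numeric(1))
  expect_equal(sum(sizes >= 2), 50)
  expect_true(all(sizes <= 4))
  expect_true(all(mins[sizes >= 2] == 1))
})

test_that("counts follow the configured negative-binomial moments", {
  # constant baseline mean makes the pooled moments checkable
  cfg <- synthetic_config(n_single_copy = 2500, n_multi_copy = 0,
                          n_species_specific_A = 0, n_species_specific_B = 0,
                          nb_mean_range = c(100, 100), nb_dispersion = 0.1,
                          planted_fold = 1, planted_enriched_size = 0,
                          planted_overlap = 0, planted_target_size = 10,
                          replicates = 3, seed = 19)
  counts <- simulate_two_species(cfg)$study$values
  mu <- 100; v_expected <- mu + 0.1 * mu^2
  x <- as.vector(counts)
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v_expected / length(x)))
  # mean per-gene sample variance estimates the NB variance; its standard
  # error is taken from the spread of the per-gene variances themselves
  gv <- apply(counts, 1, var)
  expect_lt(abs(mean(gv) - v_expected), 3 * sd(gv) / sqrt(length(gv)))
})

test_that("infeasible configurations fail before generation", {
  expect_error(synthetic_config(n_single_copy = 10,
                                planted_enriched_size = 20,
                                planted_target_size = 5,
                                planted_overlap = 2),
               "infeasible")
  expect_error(synthetic_config(planted_overlap = 55,
                                planted_target_size = 50),
               "planted_overlap")
  expect_error(synthetic_config(replicates = 0), "replicates")
  expect_error(synthetic_config(planted_enriched_nonortho = 80,
                                planted_enriched_size = 60),
               "planted_enriched_nonortho")
  expect_error(synthetic_config(n_single_copy = 60,
                                planted_enriched_size = 55,
                                planted_target_size = 20,
                                planted_overlap = 2),
               "not enough non-enriched")
})

test_that("emitted files parse back through the pipeline readers", {
  cfg <- synthetic_config(n_single_copy = 60, n_multi_copy = 8,
                          n_species_specific_A = 6, n_species_specific_B = 6,
                          planted_enriched_size = 12,
                          planted_target_size = 10, planted_overlap = 4,
                          seed = 31)
  sim <- simulate_two_species(cfg)
  d <- withr::local_tempdir()
  paths <- write_synthetic_inputs(sim, d)

  st <- read_expression_tsv(paths[["counts"]],
                            sample_groups = sim$study$sample_groups)
  expect_equal(unname(st$values), unname(sim$study$values))
  og <- read_orthogroups(paths[["orthogroups"]])
  expect_equal(og$membership, sim$orthogroups$membership)
  expect_setequal(read_gene_set(paths[["target"]])$ids, sim$target$ids)
  hits <- label_blast_hits(read_blast_outfmt6(paths[["blast"]]),
                           read.delim(paths[["subject_groups"]],
                                      header = FALSE))
  expect_equal(sort(unique(hits$qseqid)), sort(unique(sim$blast$qseqid)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$overlap_orthogroups, sim$truth$overlap_orthogroups)
})
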