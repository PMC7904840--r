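test_that("rank-sum test reproduces exact small-sample p-values", {
  res <- rank_sum_test(c(1, 2), c(3, 4), min_group_size = 2)
  expect_true(res$testable)
  expect_equal(res$p_value, 1 / 6)
  # wrong direction: mutants far above wild-type is non-significant
  res <- rank_sum_test(c(11, 12, 13), c(1, 2, 3))
  expect_gt(res$p_value, 0.9)
  # groups below the minimum size are untestable, not a p-value
  res <- rank_sum_test(numeric(0), c(1, 2, 3))
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
  expect_false(rank_sum_test(c(1, 2), c(3, 4, 5))$testable)
})

test_that("exact p-values agree with enumeration on random no-tie splits", {
  withr::local_seed(31)
  for (i in 1:40) {
    N <- sample(4:10, 1)
    k <- sample(2:(N - 2), 1)
    v <- sample(100, N)  # distinct values, no ties
    mut <- v[seq_len(k)]
    wt <- v[-seq_len(k)]
    expect_equal(rank_sum_test(mut, wt, min_group_size = 1)$p_value,
                 rank_sum_oracle(mut, wt), tolerance = 1e-12)
  }
})

test_that("p-values are invariant to positive rescaling", {
  withr::local_seed(17)
  mut <- rlnorm(8); wt <- rlnorm(9)
  p1 <- rank_sum_test(mut, wt)$p_value
  p2 <- rank_sum_test(3.7 * mut, 3.7 * wt)$p_value
  expect_equal(p1, p2)
})

test_that("mutation-status assignment partitions by cancer type and gene", {
  mut <- tibble(
    cell_line = sprintf("L%d", 1:8),
    gene = "BRCA1",
    status = c("mutant", "mutant", rep("wild_type", 4), "mutant", "wild_type"),
    cancer_type = c(rep("OV", 6), "LUAD", "LUAD")
  )
  cmap <- tibble(cancer_name = "Ovarian Carcinoma", tcga_code = "OV")
  cand <- tibble(cancer = "Ovarian Carcinoma", mutant_gene = "BRCA1")
  part <- assign_mutation_status(mut, cand, cmap)
  expect_true(part$testable)
  expect_equal(part$mutant, c("L1", "L2"))
  expect_length(part$wildtype, 4)
  # unmapped cancer -> untestable
  part <- assign_mutation_status(
    mut, tibble(cancer = "No Such Cancer", mutant_gene = "BRCA1"), cmap)
  expect_false(part$testable)
  # gene absent from the table -> every line wild-type
  part <- assign_mutation_status(
    mut, tibble(cancer = "Ovarian Carcinoma", mutant_gene = "XYZ"), cmap)
  expect_length(part$mutant, 0)
  expect_length(part$wildtype, 6)
})

test_that("candidate validation summarizes testable and validated counts", {
  p <- synth_params(n_cell_lines_per_group = 10, sensitivity_effect = 2,
                    seed = 9)
  sim <- generate_kg(p)
  truth <- sim$truth |> filter(failure_mode == "none")
  sens <- generate_sensitivity(p, truth)
  v <- validate_candidates(truth, sens$sensitivity, sens$mutations,
                           sens$cancer_map)
  expect_equal(v$summary$n_testable, nrow(truth))
  expect_equal(v$summary$n_validated, nrow(truth))
  expect_equal(v$summary$proportion_validated, 1)
  expect_true(all(v$results$p_value < 0.05))
  # with no pharmacology rows nothing is testable; proportion is NA
  v0 <- validate_candidates(truth, sens$sensitivity[0, ],
                            sens$mutations[0, ], sens$cancer_map[0, ])
  expect_equal(v0$summary$n_testable, 0)
  expect_true(is.na(v0$summary$proportion_validated))
  vempty <- validate_candidates(truth[0, ], sens$sensitivity,
                                sens$mutations, sens$cancer_map)
  expect_equal(vempty$summary$n_candidates, 0)
})

test_that("pharm tables load with schema checks and canonical drug names", {
  dir <- withr::local_tempdir()
  readr::write_tsv(tibble(cell_line = c("L1", "L2"), drug = c("OSI-906", "x"),
                          measure = "AUC", value = c(0.5, 0.7)),
                   file.path(dir, "sensitivity.tsv"))
  readr::write_tsv(tibble(cell_line = c("L1", "L2"), gene = "tp53",
                          status = "mutant", cancer_type = "OV"),
                   file.path(dir, "cell_mutations.tsv"))
  readr::write_tsv(tibble(cancer_name = "Ovarian Carcinoma",
                          tcga_code = "OV"),
                   file.path(dir, "cancer_map.tsv"))
  g <- make_kg(tiny_tables())
  tabs <- load_pharm_tables(file.path(dir, "sensitivity.tsv"),
                            file.path(dir, "cell_mutations.tsv"),
                            file.path(dir, "cancer_map.tsv"), graph = g)
  expect_equal(tabs$sensitivity$drug, c("linsitinib", "x"))
  expect_equal(tabs$mutations$gene, c("TP53", "TP53"))
  # bad measure enum is reported with its line
  readr::write_tsv(tibble(cell_line = "L1", drug = "x", measure = "EC50",
                          value = 1), file.path(dir, "sensitivity.tsv"))
  expect_error(load_pharm_tables(file.path(dir, "sensitivity.tsv"),
                                 file.path(dir, "cell_mutations.tsv"),
                                 file.path(dir, "cancer_map.tsv")),
               "line 2")
})
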