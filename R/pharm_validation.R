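# Cell-line pharmacologic validation: for each selected candidate, cell
# lines of the candidate's cancer type are split into mutant and
# wild-type for the mutant gene, and a one-sided Wilcoxon rank-sum test
# asks whether mutant lines are more sensitive (smaller AUC or IC50) to
# the candidate drug.

#' Read cell-line pharmacology tables
#'
#' `sensitivity.tsv` (cell_line, drug, measure AUC|IC50, value),
#' `cell_mutations.tsv` (cell_line, gene, status mutant|wild_type,
#' cancer_type) and `cancer_map.tsv` (cancer_name, tcga_code). Drug
#' names are canonicalized with the graph's synonym table when a graph
#' is supplied. AUC is dimensionless; IC50 values are in micromolar.
#'
#' @param sensitivity_path,mutations_path,cancer_map_path File paths.
#' @param graph Optional `slkg` whose synonym table canonicalizes drug
#'   names.
#' @return List of tibbles `sensitivity`, `mutations`, `cancer_map`.
#' @export
load_pharm_tables <- function(sensitivity_path, mutations_path,
                              cancer_map_path, graph = NULL) {
  sens <- read_kg_tsv(sensitivity_path,
                      c("cell_line", "drug", "measure", "value"),
                      enums = list(measure = c("AUC", "IC50")),
                      numeric_cols = "value")
  mut <- read_kg_tsv(mutations_path,
                     c("cell_line", "gene", "status", "cancer_type"),
                     enums = list(status = c("mutant", "wild_type")))
  cmap <- read_kg_tsv(cancer_map_path, c("cancer_name", "tcga_code"))
  if (!is.null(graph)) {
    sens$drug <- canonicalize_drug_name(sens$drug, graph$synonyms)$canonical
  } else {
    sens$drug <- tolower(trimws(sens$drug))
  }
  mut$gene <- toupper(trimws(mut$gene))
  mut$status <- toupper(mut$status)
  if (anyDuplicated(sens[c("cell_line", "drug", "measure")])) {
    abort(paste0(sensitivity_path,
                 ": duplicate (cell_line, drug, measure) record"))
  }
  if (anyDuplicated(mut[c("cell_line", "gene")])) {
    abort(paste0(mutations_path, ": conflicting status for a (cell_line, gene)"))
  }
  list(sensitivity = sens, mutations = mut, cancer_map = cmap)
}

#' Partition cell lines into mutant and wild-type for one candidate
#'
#' Restricts the mutation table to cell lines whose annotated cancer
#' type maps (via the cancer-name-to-code table) to the candidate's
#' cancer, then splits them by the mutant gene's status. Lines with no
#' record for the gene are wild-type. A candidate whose cancer has no
#' code mapping is untestable.
#'
#' @param mutations Tibble `cell_line`, `gene`, `status`, `cancer_type`.
#' @param candidate One-row candidate (fields `cancer`, `mutant_gene`).
#' @param cancer_map Tibble `cancer_name`, `tcga_code`.
#' @return List: `testable` (here, whether the cancer mapped), `mutant`
#'   and `wildtype` character vectors of cell-line identifiers.
#' @export
assign_mutation_status <- function(mutations, candidate, cancer_map) {
  codes <- cancer_map$tcga_code[cancer_map$cancer_name == candidate$cancer]
  if (length(codes) == 0) {
    return(list(testable = FALSE, mutant = character(),
                wildtype = character()))
  }
  lines <- mutations |> filter(cancer_type %in% codes)
  all_lines <- unique(lines$cell_line)
  mutant <- lines |>
    filter(gene == candidate$mutant_gene, toupper(status) == "MUTANT") |>
    pull(cell_line) |>
    unique()
  list(testable = TRUE, mutant = sort(mutant),
       wildtype = sort(setdiff(all_lines, mutant)))
}

#' One-sided Wilcoxon rank-sum test for drug sensitivity
#'
#' Tests whether mutant-line sensitivity values (AUC or IC50; smaller =
#' more sensitive) are stochastically smaller than wild-type values.
#' Uses the exact null distribution when the combined sample size is at
#' most 20 and there are no ties, and the normal approximation with
#' continuity and tie correction otherwise. Groups below the minimum
#' size yield an untestable result rather than a p-value.
#'
#' @param mutant_values,wildtype_values Numeric sensitivity values.
#' @param min_group_size Minimum per-group size to attempt the test
#'   (default 3).
#' @return List: `testable`, `p_value` (NA when untestable),
#'   `n_mutant`, `n_wildtype`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4), min_group_size = 2)$p_value  # 1/6
rank_sum_test <- function(mutant_values, wildtype_values,
                          min_group_size = 3) {
  n_m <- length(mutant_values)
  n_w <- length(wildtype_values)
  if (n_m < min_group_size || n_w < min_group_size) {
    return(list(testable = FALSE, p_value = NA_real_,
                n_mutant = n_m, n_wildtype = n_w))
  }
  no_ties <- !anyDuplicated(c(mutant_values, wildtype_values))
  use_exact <- (n_m + n_w) <= 20 && no_ties
  p <- suppressWarnings(
    wilcox.test(mutant_values, wildtype_values, alternative = "less",
                exact = use_exact, correct = TRUE)$p.value
  )
  list(testable = TRUE, p_value = p, n_mutant = n_m, n_wildtype = n_w)
}

#' Validate candidates against cell-line sensitivity data
#'
#' For each candidate: map its cancer to cell-line cancer-type codes,
#' partition the lines by mutant-gene status, pull the candidate drug's
#' sensitivity values under the kind's measure (AUC for SL, IC50 for SDL
#' by default) and run the one-sided rank-sum test. A candidate is
#' validated when it is testable and its p-value is below `alpha`
#' (per-candidate, no multiple-testing correction). Untestable
#' candidates are excluded from the summary denominator.
#'
#' @param candidates Selected candidates (`drug`, `cancer`,
#'   `mutant_gene`, `kind`).
#' @param sensitivity Tibble `cell_line`, `drug`, `measure`, `value`.
#' @param mutations Tibble `cell_line`, `gene`, `status`, `cancer_type`.
#' @param cancer_map Tibble `cancer_name`, `tcga_code`.
#' @param config Configuration (`alpha`, `min_group_size`,
#'   `measure_by_kind`).
#' @return List with `results` (one row per candidate: `measure`,
#'   `n_mutant`, `n_wildtype`, `p_value`, `testable`, `validated`) and
#'   `summary` (`n_candidates`, `n_testable`, `n_validated`,
#'   `proportion_validated`, NA when nothing is testable).
#' @export
validate_candidates <- function(candidates, sensitivity, mutations,
                                cancer_map, config = default_config()) {
  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    meas <- unname(config$measure_by_kind[[cand$kind]])
    part <- assign_mutation_status(mutations, cand, cancer_map)
    vals <- sensitivity |> filter(drug == cand$drug, measure == meas)
    mv <- vals$value[vals$cell_line %in% part$mutant]
    wv <- vals$value[vals$cell_line %in% part$wildtype]
    if (!part$testable) {
      t <- list(testable = FALSE, p_value = NA_real_,
                n_mutant = length(mv), n_wildtype = length(wv))
    } else {
      t <- rank_sum_test(mv, wv, config$min_group_size)
    }
    tibble(drug = cand$drug, cancer = cand$cancer,
           mutant_gene = cand$mutant_gene,
           target_gene = cand$target_gene %||% NA_character_,
           kind = cand$kind, measure = meas,
           n_mutant = t$n_mutant, n_wildtype = t$n_wildtype,
           p_value = t$p_value, testable = t$testable,
           validated = isTRUE(t$testable) && !is.na(t$p_value) &&
             t$p_value < config$alpha)
  })
  if (nrow(candidates) == 0) {
    res <- tibble(drug = character(), cancer = character(),
                  mutant_gene = character(), target_gene = character(),
                  kind = character(), measure = character(),
                  n_mutant = integer(), n_wildtype = integer(),
                  p_value = double(), testable = logical(),
                  validated = logical())
  }
  n_testable <- sum(res$testable)
  n_validated <- sum(res$validated)
  list(results = res,
       summary = list(n_candidates = nrow(res),
                      n_testable = n_testable,
                      n_validated = n_validated,
                      proportion_validated =
                        if (n_testable > 0) n_validated / n_testable
                        else NA_real_))
}
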