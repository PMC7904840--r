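# End-to-end orchestration: map -> score -> normalize -> select -> rank
# -> validate -> combinations, with TSV outputs and a run log.

write_stage_tsv <- function(df, path) {
  df <- df |> mutate(across(where(is.list),
                            ~ purrr::map_chr(.x, paste, collapse = ";")))
  readr::write_tsv(df, path, progress = FALSE)
  path
}

#' Run the full repurposing pipeline
#'
#' Loads (or accepts) a knowledge graph, maps and scores candidates for
#' the requested kinds, selects the best candidates by the per-kind
#' thresholds, orders them by robust rank aggregation, validates them
#' against cell-line sensitivity data when provided, and mines two-drug
#' combinations (SL only). Writes `candidates.tsv`,
#' `ranked_candidates.tsv`, `validation.tsv`, `combos.tsv` and
#' `run_log.tsv` to `out_dir`. Deterministic: identical inputs and
#' configuration give identical outputs.
#'
#' @param input Either an `slkg` object or a directory / named path set
#'   accepted by [load_kg_tables()].
#' @param out_dir Output directory (created if needed).
#' @param kind `"SL"`, `"SDL"` or `"both"`.
#' @param pharm Optional list with tibbles `sensitivity`, `mutations`,
#'   `cancer_map` (see [load_pharm_tables()]); `NULL` skips validation.
#' @param synergy Optional synergy tibble (`drug_a`, `drug_b`,
#'   `s_score`).
#' @param config Configuration.
#' @return Invisibly, a list with the four result tibbles
#'   (`candidates`, `ranked`, `validation`, `combos`) and the summary
#'   from the validation stage.
#' @export
run_pipeline <- function(input, out_dir, kind = c("both", "SL", "SDL"),
                         pharm = NULL, synergy = NULL,
                         config = default_config()) {
  kind <- match.arg(kind)
  kinds <- if (kind == "both") c("SL", "SDL") else kind
  graph <- if (inherits(input, "slkg")) input else
    load_kg_tables(input, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  candidates <- stage("map/score", {
    purrr::map_dfr(kinds, function(k) {
      mapped <- map_candidates(graph, k, config)
      if (nrow(mapped) == 0) return(NULL)
      score_candidates(mapped, graph, config) |>
        annotate_indications(graph)
    })
  })
  if (nrow(candidates)) {
    candidates <- candidates |>
      mutate(selected = FALSE)
    for (k in kinds) {
      sel <- candidates$kind == k
      if (any(sel)) {
        candidates$selected[sel] <-
          passes_thresholds(candidates[sel, ], config$thresholds[[k]])
      }
    }
  } else {
    candidates <- candidates |> mutate(selected = logical())
  }

  ranked <- stage("rank", {
    purrr::map_dfr(kinds, function(k) {
      best <- candidates |> filter(kind == k, selected)
      if (nrow(best) == 0) return(NULL)
      aggregate_ranks(best, config)
    })
  })

  validation <- NULL
  if (!is.null(pharm) && nrow(ranked)) {
    validation <- stage("validate", {
      validate_candidates(ranked, pharm$sensitivity, pharm$mutations,
                          pharm$cancer_map, config)
    })
  }

  combos <- stage("combos", {
    if ("SL" %in% kinds) mine_combinations(graph, synergy, config = config)
    else tibble(drug_a = character(), drug_b = character(),
                mutant_gene = character(), objective = double(),
                n_covered_pairs = integer(), covered_pairs = character(),
                antagonism_status = character(), atc_a = character(),
                atc_b = character())
  })

  val_results <- if (!is.null(validation)) validation$results else
    tibble(drug = character(), cancer = character(),
           mutant_gene = character(), target_gene = character(),
           kind = character(), measure = character(), n_mutant = integer(),
           n_wildtype = integer(), p_value = double(), testable = logical(),
           validated = logical())

  write_stage_tsv(candidates |> mutate(selected = as.integer(selected)),
                  file.path(out_dir, "candidates.tsv"))
  write_stage_tsv(ranked, file.path(out_dir, "ranked_candidates.tsv"))
  write_stage_tsv(val_results, file.path(out_dir, "validation.tsv"))
  write_stage_tsv(combos, file.path(out_dir, "combos.tsv"))

  log <- tibble(
    stage = c("candidates", "selected", "ranked", "validation", "combos"),
    rows = c(nrow(candidates), sum(candidates$selected), nrow(ranked),
             nrow(val_results), nrow(combos))
  )
  readr::write_tsv(log, file.path(out_dir, "run_log.tsv"), progress = FALSE)

  invisible(list(candidates = candidates, ranked = ranked,
                 validation = val_results,
                 summary = if (!is.null(validation)) validation$summary else NULL,
                 combos = combos))
}
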