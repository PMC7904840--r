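# The three-part repurposing scoring schema: noisy-OR evidence
# aggregation for SL/SDL pairs, a development-status drug score with
# specificity and database-support terms, the gene-disease cancer score,
# min-max normalization and threshold selection.

#' Aggregate per-source evidence scores for an SL/SDL pair
#'
#' A pair reported by several independent collection methods is more
#' reliable than one reported by a single method. Each method carries a
#' quantitative score \eqn{p_i \in (0,1)} and the aggregated pair score is
#' the noisy-OR combination
#' \deqn{s = 1 - \prod_{i=1}^{n} (1 - p_i),}
#' which is order-invariant, strictly below 1, and strictly increases as
#' evidence is added. A pair supported by a CRISPR screen (0.98) and
#' GenomeRNAi (0.75) scores \eqn{1 - 0.02 \times 0.25 = 0.995}.
#'
#' @param evidence_scores Non-empty numeric vector of scores in (0, 1).
#' @return The aggregated score in (0, 1).
#' @export
#' @examples
#' aggregate_evidence_score(c(0.98, 0.75))  # 0.995
aggregate_evidence_score <- function(evidence_scores) {
  if (length(evidence_scores) == 0) {
    abort("an interaction without evidence is malformed (empty score list)")
  }
  if (any(!is.finite(evidence_scores)) ||
      any(evidence_scores <= 0 | evidence_scores >= 1)) {
    abort("evidence scores must lie strictly in (0, 1)")
  }
  1 - prod(1 - evidence_scores)
}

#' Pre-computed DScore by development status and target type
#'
#' Lookup of the base drug score from development status (approved,
#' clinical trials, experimental) and whether the scored gene is a direct
#' target of the drug: approved 1 / 0.8, clinical trials 0.6 / 0.4,
#' experimental 0.2 / 0.1 (direct / other).
#'
#' @param status Character vector: `"APPROVED"`, `"CLINICAL_TRIALS"` or
#'   `"EXPERIMENTAL"` (case-insensitive).
#' @param is_direct Logical vector: direct target (default `TRUE`).
#' @param config Configuration holding the lookup table.
#' @return Numeric vector of pre-computed DScore values.
#' @export
#' @examples
#' precomputed_dscore("APPROVED", TRUE)        # 1
#' precomputed_dscore("CLINICAL_TRIALS", TRUE) # 0.6
precomputed_dscore <- function(status, is_direct = TRUE,
                               config = default_config()) {
  status <- toupper(status)
  tbl <- config$dscore_table
  bad <- setdiff(unique(status), names(tbl))
  if (length(bad)) {
    abort(paste0("unknown drug development status: ",
                 paste(bad, collapse = ", ")))
  }
  n <- max(length(status), length(is_direct))
  status <- rep_len(status, n)
  is_direct <- rep_len(is_direct, n)
  vapply(seq_len(n), function(i) {
    unname(tbl[[status[i]]][if (is_direct[i]) "direct" else "other"])
  }, numeric(1))
}

#' Drug score from status, specificity and database support
#'
#' \deqn{DrugScore = \max\{\text{pre-computed DScore}\}
#'   - 0.01 \times \text{collective gene impact}
#'   + 0.001 \times \text{database factor}}
#' where the collective gene impact is the number of distinct target
#' genes of the drug (a specificity penalty: promiscuous drugs score
#' lower) and the database factor is the number of distinct source
#' databases supporting the drug-target link.
#'
#' @param precomputed Numeric: the (maximum) pre-computed DScore over the
#'   drug's links relevant to the candidate.
#' @param collective_gene_impact Non-negative integer count of distinct
#'   target genes of the drug.
#' @param database_factor Non-negative integer count of distinct source
#'   databases supporting the link.
#' @return The raw DrugScore.
#' @export
#' @examples
#' drug_score(1, 3, 2)  # 0.972
drug_score <- function(precomputed, collective_gene_impact = 0,
                       database_factor = 0) {
  stopifnot(is.numeric(precomputed),
            all(collective_gene_impact >= 0),
            all(database_factor >= 0))
  precomputed - 0.01 * collective_gene_impact + 0.001 * database_factor
}

#' Min-max normalization to [0, 1]
#'
#' \deqn{x' = (x - \min x) / (\max x - \min x)} applied to one scoring
#' function's values across all candidates of one interaction kind. A
#' constant vector makes the transform undefined; it is mapped to all
#' zeros with a warning so degenerate single-candidate inputs remain
#' runnable.
#'
#' @param x Non-empty numeric vector of finite values.
#' @return Numeric vector in [0, 1].
#' @export
#' @examples
#' minmax_normalize(c(0, 5, 10))  # 0, 0.5, 1
minmax_normalize <- function(x) {
  if (length(x) == 0) abort("cannot normalize an empty score vector")
  if (any(!is.finite(x))) abort("score vector must be finite")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn("constant score vector: min-max normalization undefined, returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Score mapped repurposing candidates
#'
#' Attaches the three raw scores to mapped candidates — the pair score
#' (noisy-OR aggregated evidence of the SL/SDL interaction), the drug
#' score (max pre-computed DScore of the (drug, target gene) link, minus
#' the specificity penalty, plus the database-support term) and the
#' cancer score (gene-disease association of the mutant gene in the
#' candidate's cancer) — then min-max-normalizes each score across all
#' candidates of the same kind (SL and SDL are normalized separately).
#'
#' @param candidates Tibble from [map_candidates()].
#' @param graph The `slkg` the candidates were mapped from.
#' @param config Configuration.
#' @return The candidates with columns `pair_score`, `drug_score`,
#'   `cancer_score` and `*_norm` counterparts.
#' @export
score_candidates <- function(candidates, graph,
                             config = graph$config %||% default_config()) {
  if (nrow(candidates) == 0) {
    return(candidates |>
             mutate(pair_score = double(), drug_score = double(),
                    cancer_score = double(), pair_score_norm = double(),
                    drug_score_norm = double(), cancer_score_norm = double()))
  }
  links <- target_links(graph, config)
  impact <- links |> group_by(drug) |> summarise(n_targets = n())
  inter <- graph$interactions |>
    mutate(pair_key = paste(gene_a, gene_b, kind, sep = "|")) |>
    select(pair_key, pair_score)
  scored <- candidates |>
    mutate(pair_key = paste(pmin(mutant_gene, target_gene),
                            pmax(mutant_gene, target_gene), kind,
                            sep = "|")) |>
    left_join(inter, by = "pair_key") |>
    select(-pair_key) |>
    left_join(links |> select(drug, gene, n_sources, dscore_max),
              by = c("drug", target_gene = "gene")) |>
    left_join(impact, by = "drug") |>
    left_join(graph$cancer_genes,
              by = c("cancer", mutant_gene = "gene")) |>
    mutate(drug_score = drug_score(dscore_max, n_targets, n_sources)) |>
    select(-n_sources, -dscore_max, -n_targets)
  if (anyNA(scored$pair_score) || anyNA(scored$drug_score) ||
      anyNA(scored$cancer_score)) {
    abort("candidate refers to an interaction, link or cancer-gene score absent from the graph")
  }
  scored |>
    group_by(kind) |>
    mutate(pair_score_norm = minmax_normalize(pair_score),
           drug_score_norm = minmax_normalize(drug_score),
           cancer_score_norm = minmax_normalize(cancer_score)) |>
    ungroup()
}

passes_thresholds <- function(candidates, thresholds) {
  candidates$pair_score_norm > thresholds$pair_score_min &
    candidates$drug_score_norm > thresholds$drug_score_min &
    candidates$cancer_score_norm > thresholds$cancer_score_min
}

#' Select the best repurposable candidates by score thresholds
#'
#' Retains candidates whose three normalized scores are all strictly
#' greater than the per-kind thresholds (SL: pair > 0.7, drug > 0.8,
#' cancer > 0.7; SDL: pair > 0.8, drug > 0.5, cancer > 0.3 by default).
#' Input order is preserved.
#'
#' @param candidates Scored candidates (normalized columns present).
#' @param thresholds One entry of `config$thresholds` (a list with
#'   `kind`, `pair_score_min`, `drug_score_min`, `cancer_score_min`).
#' @return The retained sublist of `candidates`.
#' @export
select_best_candidates <- function(candidates, thresholds) {
  req <- c("pair_score_norm", "drug_score_norm", "cancer_score_norm", "kind")
  missing <- setdiff(req, names(candidates))
  if (length(missing)) {
    abort(paste0("candidates lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(candidates) == 0) return(candidates)
  if (!is.null(thresholds$kind) && any(candidates$kind != thresholds$kind)) {
    abort(paste0("threshold set is for kind ", thresholds$kind,
                 " but candidates include other kinds"))
  }
  candidates[passes_thresholds(candidates, thresholds), , drop = FALSE]
}
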