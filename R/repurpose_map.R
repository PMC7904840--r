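# Mapping mutant genes and druggable targets onto SL/SDL pairs.
#
# A drug becomes a repurposing candidate for a cancer when the cancer
# carries a mutation in one gene of an SL/SDL pair and the drug inhibits
# the partner gene. Gene A and gene B of a pair are interchangeable, so
# both orientations are tried.

#' Map repurposing candidates from the knowledge graph
#'
#' For every interaction of the requested kind and both orientations of
#' its (unordered) gene pair, emits one candidate per combination of
#' (cancer linked to the mutant gene) x (drug with an inhibitory link to
#' the partner gene), subject to the role filter: the mutant gene must be
#' a tumor suppressor gene for SL and an oncogene for SDL. Duplicate
#' (drug, cancer, mutant gene, target gene) tuples are collapsed; output
#' order is deterministic (lexicographic by drug, cancer, mutant gene,
#' target gene).
#'
#' @param graph An `slkg` object.
#' @param kind `"SL"` or `"SDL"`.
#' @param config Configuration (inhibitory mode-of-action labels).
#' @return Tibble of unscored candidates: `drug`, `cancer`,
#'   `mutant_gene`, `target_gene`, `kind`.
#' @export
map_candidates <- function(graph, kind = c("SL", "SDL"),
                           config = graph$config %||% default_config()) {
  kind <- match.arg(kind)
  required_role <- if (kind == "SL") "TSG" else "ONCOGENE"
  empty <- tibble(drug = character(), cancer = character(),
                  mutant_gene = character(), target_gene = character(),
                  kind = character())
  inter <- graph$interactions |> filter(kind == !!kind)
  if (nrow(inter) == 0) return(empty)

  # both reciprocal orientations of each unordered pair
  oriented <- bind_rows(
    inter |> transmute(mutant_gene = gene_a, target_gene = gene_b),
    inter |> transmute(mutant_gene = gene_b, target_gene = gene_a)
  )
  eligible <- graph$genes |>
    filter(role == required_role) |>
    pull(symbol)
  oriented <- oriented |> filter(mutant_gene %in% eligible)
  if (nrow(oriented) == 0) return(empty)

  inhib <- target_links(graph, config) |>
    filter(inhibitory) |>
    select(drug, gene)

  oriented |>
    inner_join(graph$cancer_genes |> select(cancer, gene),
               by = c(mutant_gene = "gene"), relationship = "many-to-many") |>
    inner_join(inhib, by = c(target_gene = "gene"),
               relationship = "many-to-many") |>
    transmute(drug, cancer, mutant_gene, target_gene, kind = !!kind) |>
    distinct() |>
    arrange(drug, cancer, mutant_gene, target_gene)
}

#' Flag candidates whose drug is already indicated for their cancer
#'
#' Repositioning proposes a *new* indication; candidates whose
#' (drug, cancer) pair already exists as a known indication are flagged
#' so downstream interpretation can separate confirmation from novelty.
#'
#' @param candidates Candidate tibble (any scoring stage).
#' @param graph The `slkg` object.
#' @return `candidates` with a logical `known_indication` column.
#' @export
annotate_indications <- function(candidates, graph) {
  if (nrow(candidates) == 0) {
    return(candidates |> mutate(known_indication = logical()))
  }
  known <- graph$indications |> mutate(known_indication = TRUE)
  candidates |>
    left_join(known, by = c("drug", "cancer")) |>
    mutate(known_indication = !is.na(known_indication))
}
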