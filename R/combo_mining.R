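# Two-drug combination mining. For each mutant gene, a weighted
# bipartite graph is built with the gene's SL pairs on one side and the
# drugs inhibiting their partner genes on the other; the weight s_ij is
# drug i's DrugScore when it covers pair j and 0 otherwise. The integer
# program
#   max Z = sum_i sum_j d_i * s_ij,  subject to sum_i d_i = 2
# is solved exactly. Because the objective is separable given the
# cardinality constraint, the optimum is the top-2 drugs by weight
# row-sum; exhaustive pair enumeration is used so the tie-break
# (coverage, then drug name) is explicit.

#' Per-drug DrugScore table for combination mining
#'
#' One DrugScore per drug: the maximum pre-computed DScore over the
#' drug's target links, minus 0.01 per distinct target gene, plus 0.001
#' times the best per-link database support.
#'
#' @param graph An `slkg` object.
#' @param config Configuration.
#' @return Named numeric vector, drug -> DrugScore.
#' @export
drug_score_table <- function(graph,
                             config = graph$config %||% default_config()) {
  links <- target_links(graph, config)
  if (nrow(links) == 0) return(setNames(numeric(0), character(0)))
  tab <- links |>
    group_by(drug) |>
    summarise(score = drug_score(max(dscore_max), n(), max(n_sources)))
  setNames(tab$score, tab$drug)
}

#' Construct a weighted bipartite drug-vs-SL-pair problem
#'
#' SL nodes are all SL pairs containing `mutant_gene`; drug nodes are
#' the drugs with an inhibitory link to at least one partner gene (a
#' drug targeting only the mutant gene itself is excluded). The weight
#' matrix holds `drug_scores[drug]` where the drug inhibits the partner
#' gene of the pair, 0 elsewhere. Problems with fewer than one SL pair
#' or fewer than `k` drugs are flagged infeasible.
#'
#' @param graph An `slkg` object.
#' @param mutant_gene Gene symbol shared by the SL pairs.
#' @param drug_scores Named drug -> DrugScore vector (default
#'   [drug_score_table()]).
#' @param config Configuration (`combo_k`, inhibitory modes).
#' @return A `combo_problem` object (see [combo_problem()]).
#' @export
build_combo_problem <- function(graph, mutant_gene,
                                drug_scores = drug_score_table(graph, config),
                                config = graph$config %||% default_config()) {
  g <- toupper(trimws(mutant_gene))
  pairs <- query_partners(graph, g, "SL")
  sl_nodes <- if (nrow(pairs)) paste(pmin(g, pairs$partner),
                                     pmax(g, pairs$partner), sep = "+")
              else character()
  inhib <- target_links(graph, config) |>
    filter(inhibitory, gene %in% pairs$partner)
  drug_nodes <- sort(unique(inhib$drug))
  weights <- matrix(0, nrow = length(drug_nodes), ncol = length(sl_nodes),
                    dimnames = list(drug_nodes, sl_nodes))
  if (length(drug_nodes) && length(sl_nodes)) {
    for (i in seq_len(nrow(inhib))) {
      j <- which(pairs$partner == inhib$gene[i])
      weights[inhib$drug[i], j] <- unname(drug_scores[inhib$drug[i]])
    }
  }
  combo_problem(g, sl_nodes, drug_nodes, weights, k = config$combo_k %||% 2)
}

#' Construct a combination problem directly
#'
#' @param mutant_gene The shared mutant gene symbol.
#' @param sl_nodes Character labels of the SL pairs (columns).
#' @param drug_nodes Character drug names (rows).
#' @param weights Numeric matrix, drugs x SL pairs, non-negative;
#'   `weights[i, j]` is drug i's DrugScore when it covers pair j, 0
#'   otherwise.
#' @param k Combination size (default 2).
#' @return A `combo_problem`: list with the fields above plus
#'   `feasible` (at least one SL pair and at least `k` drugs).
#' @export
combo_problem <- function(mutant_gene, sl_nodes, drug_nodes, weights, k = 2) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == length(drug_nodes),
            ncol(weights) == length(sl_nodes))
  if (any(weights < 0)) abort("combination weights must be non-negative")
  structure(
    list(mutant_gene = mutant_gene, sl_nodes = sl_nodes,
         drug_nodes = drug_nodes, weights = weights, k = k,
         feasible = length(sl_nodes) >= 1 && length(drug_nodes) >= k),
    class = "combo_problem"
  )
}

#' Solve a combination problem exactly
#'
#' Enumerates all \eqn{\binom{n}{k}} drug subsets (k defaults to 2) and
#' returns the one maximizing \eqn{Z = \sum_i \sum_j d_i s_{ij}}. Ties
#' are broken first by the number of distinct SL pairs covered (more is
#' better), then lexicographically by the sorted drug names.
#'
#' @param problem A `combo_problem`.
#' @return List of class `combo_result`: `drugs` (sorted character
#'   vector), `mutant_gene`, `objective`, `covered_pairs`, `n_covered`.
#' @export
select_combination <- function(problem) {
  stopifnot(inherits(problem, "combo_problem"))
  if (!problem$feasible) {
    abort(paste0("infeasible combination problem for ", problem$mutant_gene,
                 ": needs at least ", problem$k, " candidate drugs and 1 SL pair"))
  }
  k <- problem$k
  if (k > 3) {
    abort("exact enumeration supported for combination sizes up to 3")
  }
  n <- length(problem$drug_nodes)
  idx <- combn(n, k)
  best <- NULL
  for (c_i in seq_len(ncol(idx))) {
    sel <- idx[, c_i]
    z <- sum(problem$weights[sel, , drop = FALSE])
    covered <- problem$sl_nodes[
      colSums(problem$weights[sel, , drop = FALSE] > 0) > 0]
    cand <- list(drugs = sort(problem$drug_nodes[sel]),
                 mutant_gene = problem$mutant_gene,
                 objective = z, covered_pairs = covered,
                 n_covered = length(covered))
    if (is.null(best) ||
        z > best$objective + 1e-12 ||
        (abs(z - best$objective) <= 1e-12 &&
           (cand$n_covered > best$n_covered ||
              (cand$n_covered == best$n_covered &&
                 paste(cand$drugs, collapse = "|") <
                   paste(best$drugs, collapse = "|"))))) {
      best <- cand
    }
  }
  structure(best, class = "combo_result")
}

#' Mine drug combinations across mutant genes
#'
#' Builds one combination problem per mutant gene (by default every
#' tumor-suppressor gene that appears in an SL pair), solves the
#' feasible ones, de-duplicates identical drug pairs across genes
#' keeping the maximum-objective instance, filters antagonistic pairs by
#' synergy score, and annotates first-level ATC categories.
#' Combinations are mined for SL only; SDL pairs are too sparse for
#' combination coverage and are not considered.
#'
#' @param graph An `slkg` object.
#' @param synergy Optional tibble `drug_a`, `drug_b`, `s_score`
#'   (unordered pairs).
#' @param mutant_genes Genes to mine (default: TSGs occurring in SL
#'   pairs and linked to at least one cancer).
#' @param config Configuration.
#' @return Tibble: `drug_a`, `drug_b`, `mutant_gene`, `objective`,
#'   `n_covered_pairs`, `covered_pairs` (semicolon list),
#'   `antagonism_status`, `atc_a`, `atc_b`.
#' @export
mine_combinations <- function(graph, synergy = NULL, mutant_genes = NULL,
                              config = graph$config %||% default_config()) {
  if (is.null(mutant_genes)) {
    tsg <- graph$genes$symbol[graph$genes$role == "TSG"]
    in_sl <- unique(c(graph$interactions$gene_a[graph$interactions$kind == "SL"],
                      graph$interactions$gene_b[graph$interactions$kind == "SL"]))
    mutant_genes <- sort(intersect(intersect(tsg, in_sl),
                                   unique(graph$cancer_genes$gene)))
  }
  scores <- drug_score_table(graph, config)
  rows <- purrr::map_dfr(mutant_genes, function(g) {
    prob <- build_combo_problem(graph, g, scores, config)
    if (!prob$feasible) return(NULL)
    res <- select_combination(prob)
    tibble(drug_a = res$drugs[1], drug_b = res$drugs[2],
           mutant_gene = g, objective = res$objective,
           n_covered_pairs = res$n_covered,
           covered_pairs = paste(res$covered_pairs, collapse = ";"))
  })
  if (nrow(rows) == 0) {
    rows <- tibble(drug_a = character(), drug_b = character(),
                   mutant_gene = character(), objective = double(),
                   n_covered_pairs = integer(), covered_pairs = character())
  }
  # identical drug pair found for several genes: keep the best instance
  rows <- rows |>
    group_by(drug_a, drug_b) |>
    arrange(desc(objective), mutant_gene, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(drug_a, drug_b)
  rows <- filter_antagonistic(rows, synergy, config$s_min %||% 5)
  annotate_atc(rows, graph$drugs)
}

#' Filter antagonistic drug pairs by synergy score
#'
#' Removes combinations whose recorded synergy S score is strictly
#' below `s_min` (antagonism at IC50); pairs absent from the synergy
#' table are retained with status `UNKNOWN`, pairs at or above the
#' cutoff with status `SYNERGISTIC_OR_ADDITIVE`.
#'
#' @param results Combination tibble (`drug_a`, `drug_b`, ...).
#' @param synergy Tibble `drug_a`, `drug_b`, `s_score`, pairs unordered;
#'   `NULL` means no synergy data (everything `UNKNOWN`).
#' @param s_min Antagonism cutoff (default 5).
#' @return `results` without antagonistic pairs, with an
#'   `antagonism_status` column.
#' @export
filter_antagonistic <- function(results, synergy = NULL, s_min = 5) {
  if (nrow(results) == 0) {
    return(results |> mutate(antagonism_status = character()))
  }
  key <- function(a, b) paste(pmin(tolower(a), tolower(b)),
                              pmax(tolower(a), tolower(b)), sep = "|")
  if (is.null(synergy) || nrow(synergy) == 0) {
    return(results |> mutate(antagonism_status = "UNKNOWN"))
  }
  lut <- setNames(synergy$s_score, key(synergy$drug_a, synergy$drug_b))
  s <- unname(lut[key(results$drug_a, results$drug_b)])
  results |>
    mutate(antagonism_status = dplyr::case_when(
      is.na(s) ~ "UNKNOWN",
      s < s_min ~ "ANTAGONISTIC",
      TRUE ~ "SYNERGISTIC_OR_ADDITIVE"
    )) |>
    filter(antagonism_status != "ANTAGONISTIC")
}

#' Annotate first-level ATC categories
#'
#' Attaches the first letter of each drug's 7-character ATC code (one of
#' the 14 anatomical main groups). Missing or malformed codes leave the
#' drug unannotated (with a warning for malformed ones).
#'
#' @param results Combination tibble (`drug_a`, `drug_b`).
#' @param atc_table Tibble with columns `drug` and `atc_code` (the
#'   graph's `drugs` table works directly).
#' @return `results` with `atc_a`, `atc_b` columns (NA when
#'   unannotated).
#' @export
annotate_atc <- function(results, atc_table) {
  lvl1 <- function(code) {
    out <- rep(NA_character_, length(code))
    ok <- !is.na(code) & nchar(code) == 7 &
      substr(code, 1, 1) %in% ATC_LETTERS
    bad <- !is.na(code) & !ok
    if (any(bad)) {
      warn(paste0("malformed ATC code(s), left unannotated: ",
                  paste(unique(code[bad]), collapse = ", ")))
    }
    out[ok] <- substr(code[ok], 1, 1)
    out
  }
  if (nrow(results) == 0) {
    return(results |> mutate(atc_a = character(), atc_b = character()))
  }
  lut <- setNames(atc_table$atc_code, tolower(atc_table$drug))
  results |>
    mutate(atc_a = lvl1(unname(lut[tolower(drug_a)])),
           atc_b = lvl1(unname(lut[tolower(drug_b)])))
}
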