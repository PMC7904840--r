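# In-memory knowledge graph: three entity types (gene, drug, cancer type)
# and four relationship types (SL/SDL gene pairs, cancer-mutant gene links,
# drug-target links, drug-indication links), loaded from TSV exports.

KG_FILES <- c(
  interactions = "interactions.tsv",
  gene_roles = "gene_roles.tsv",
  drug_targets = "drug_targets.tsv",
  cancer_genes = "cancer_genes.tsv",
  indications = "indications.tsv",
  synonyms = "synonyms.tsv",
  drug_atc = "drug_atc.tsv"
)

GENE_ROLES <- c("TSG", "ONCOGENE", "OTHER")
PAIR_KINDS <- c("SL", "SDL")
DRUG_STATUSES <- c("approved", "clinical_trials", "experimental")
TARGET_SOURCES <- c("TTD", "DRUGBANK", "DGIDB")
ATC_LETTERS <- c("A", "B", "C", "D", "G", "H", "J", "L",
                 "M", "N", "P", "R", "S", "V")

#' Canonicalize drug names against a synonym table
#'
#' Drug names differ between source databases (a trade name in one, the
#' common name in another, e.g. OSI-906 vs linsitinib). This resolves each
#' name through an alias-to-canonical mapping, case-insensitively and
#' after trimming whitespace. Unknown names pass through unchanged with
#' `resolved = FALSE` (or error, under `policy = "error"`). Canonical
#' names are returned lower-cased; the operation is idempotent for alias
#' tables whose canonical names map to themselves (alias chains are not
#' followed).
#'
#' @param name Character vector of drug names.
#' @param synonym_table Named character vector or two-column data frame
#'   (`alias`, `canonical`) mapping aliases to canonical names.
#' @param policy `"passthrough"` (default) or `"error"` for unknown names.
#' @return A tibble with columns `input`, `canonical`, `resolved`.
#' @export
#' @examples
#' canonicalize_drug_name("OSI-906", c("OSI-906" = "linsitinib"))
canonicalize_drug_name <- function(name, synonym_table = character(),
                                   policy = "passthrough") {
  if (length(name) == 0) return(tibble(input = character(),
                                       canonical = character(),
                                       resolved = logical()))
  if (any(is.na(name)) || any(!nzchar(trimws(name)))) {
    abort("malformed input: empty or missing drug name")
  }
  if (is.data.frame(synonym_table)) {
    synonym_table <- setNames(synonym_table$canonical, synonym_table$alias)
  }
  key <- tolower(trimws(name))
  lut <- setNames(tolower(trimws(unname(synonym_table))),
                  tolower(trimws(names(synonym_table))))
  hit <- key %in% names(lut)
  out <- key
  out[hit] <- unname(lut[key[hit]])
  if (policy == "error" && any(!hit)) {
    abort(paste0("unresolved drug aliases: ",
                 paste(unique(name[!hit]), collapse = ", ")))
  }
  tibble(input = name, canonical = out, resolved = hit)
}

# Read one TSV with schema validation; errors name the file and line.
read_kg_tsv <- function(path, cols, enums = list(), numeric_cols = character()) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(path, ": missing column(s) ", paste(missing, collapse = ", ")))
  }
  df <- df[cols]
  for (cl in cols) {
    bad <- which(is.na(df[[cl]]) | !nzchar(trimws(df[[cl]])))
    if (length(bad)) {
      abort(paste0(path, ": line ", bad[1] + 1L, ": empty value in '", cl, "'"))
    }
  }
  for (cl in names(enums)) {
    bad <- which(!df[[cl]] %in% enums[[cl]])
    if (length(bad)) {
      abort(paste0(path, ": line ", bad[1] + 1L, ": invalid value '",
                   df[[cl]][bad[1]], "' in column '", cl, "' (expected one of ",
                   paste(enums[[cl]], collapse = ", "), ")"))
    }
  }
  for (cl in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      abort(paste0(path, ": line ", bad[1] + 1L, ": non-numeric value '",
                   df[[cl]][bad[1]], "' in column '", cl, "'"))
    }
    df[[cl]] <- vals
  }
  as_tibble(df)
}

# Upper-case gene symbols; error if two distinct spellings collide.
fold_gene_symbols <- function(x, context) {
  up <- toupper(trimws(x))
  tab <- unique(tibble(raw = trimws(x), up = up))
  dup <- tab |> count(up) |> filter(n > 1)
  if (nrow(dup)) {
    abort(paste0(context, ": gene symbol case-fold collision for ",
                 paste(dup$up, collapse = ", ")))
  }
  up
}

evidence_score_for <- function(labels, config) {
  scores <- config$evidence_scores
  out <- unname(scores[labels])
  if (anyNA(out)) {
    unk <- unique(labels[is.na(out)])
    if (is.null(config$unknown_evidence_score)) {
      abort(paste0("unknown evidence source label(s) with no configured score: ",
                   paste(unk, collapse = ", ")))
    }
    out[is.na(out)] <- config$unknown_evidence_score
  }
  out
}

#' Load knowledge-graph tables from TSV files
#'
#' Reads the seven input tables (SL/SDL interactions, gene roles,
#' drug-target links, cancer-gene scores, drug indications, drug
#' synonyms, ATC codes), validates their schemas, canonicalizes drug
#' names through the synonym table, and assembles a referentially intact
#' knowledge graph.
#'
#' Gene symbols are upper-cased on ingest. SL/SDL pairs are unordered:
#' a pair listed as (A,B) and (B,A) is stored once with the union of its
#' evidence labels, and its aggregated score is computed with
#' [aggregate_evidence_score()] from the configured per-source scores.
#' Duplicate cancer-gene rows keep the maximum score. Drug-target rows
#' are stored as read (exact duplicates dropped); the merged
#' one-link-per-(drug, gene) view is available via [target_links()].
#'
#' @param paths Directory containing the standard file names
#'   (`interactions.tsv`, `gene_roles.tsv`, `drug_targets.tsv`,
#'   `cancer_genes.tsv`, `indications.tsv`, `synonyms.tsv`,
#'   `drug_atc.tsv`), or a named character vector of file paths. Only
#'   `interactions.tsv` is required; missing optional tables are treated
#'   as empty.
#' @param config A [default_config()] list (evidence scores, alias policy).
#' @return An object of class `slkg`: a list of tibbles `genes`, `drugs`,
#'   `cancers`, `interactions`, `drug_targets`, `cancer_genes`,
#'   `indications`, plus the `synonyms` lookup used.
#' @export
load_kg_tables <- function(paths, config = default_config()) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    paths <- setNames(file.path(paths, KG_FILES), names(KG_FILES))
  }
  get_tbl <- function(key, cols, enums = list(), numeric_cols = character(),
                      required = FALSE) {
    p <- paths[[key]]
    if (is.null(p) || !file.exists(p)) {
      if (required) abort(paste0("required table '", key, "' not found"))
      return(as_tibble(setNames(rep(list(character()), length(cols)), cols)))
    }
    read_kg_tsv(p, cols, enums, numeric_cols)
  }

  inter_raw <- get_tbl("interactions",
                       c("gene_a", "gene_b", "kind", "evidence_sources"),
                       enums = list(kind = PAIR_KINDS), required = TRUE)
  roles_raw <- get_tbl("gene_roles", c("gene", "role"),
                       enums = list(role = GENE_ROLES))
  targets_raw <- get_tbl("drug_targets",
                         c("drug", "gene", "mode_of_action", "is_direct",
                           "status", "source"),
                         enums = list(is_direct = c("0", "1"),
                                      status = DRUG_STATUSES,
                                      source = TARGET_SOURCES))
  cgenes_raw <- get_tbl("cancer_genes", c("cancer", "gene", "cancer_score"),
                        numeric_cols = "cancer_score")
  indic_raw <- get_tbl("indications", c("drug", "cancer"))
  syn_raw <- get_tbl("synonyms", c("alias", "canonical"))
  atc_raw <- get_tbl("drug_atc", c("drug", "atc_code"))

  if (any(cgenes_raw$cancer_score < 0 | cgenes_raw$cancer_score > 1)) {
    abort("cancer_genes.tsv: cancer_score outside [0, 1]")
  }

  synonyms <- setNames(tolower(trimws(syn_raw$canonical)),
                       tolower(trimws(syn_raw$alias)))

  canon <- function(x) {
    res <- canonicalize_drug_name(x, synonyms, policy = config$alias_policy)
    unres <- unique(res$canonical[!res$resolved &
                                    !res$canonical %in% unname(synonyms)])
    if (length(unres) && length(synonyms)) {
      warn(paste0("drug name(s) not in synonym table, kept as-is: ",
                  paste(unres, collapse = ", ")))
    }
    res$canonical
  }

  roles_raw$gene <- fold_gene_symbols(roles_raw$gene, "gene_roles.tsv")
  if (anyDuplicated(roles_raw$gene)) {
    dup <- roles_raw$gene[duplicated(roles_raw$gene)]
    abort(paste0("gene_roles.tsv: duplicate role rows for ",
                 paste(unique(dup), collapse = ", ")))
  }

  # unordered SL/SDL pairs: orient lexicographically, merge evidence
  inter <- inter_raw |>
    mutate(gene_a = toupper(trimws(gene_a)), gene_b = toupper(trimws(gene_b)))
  if (any(inter$gene_a == inter$gene_b)) {
    abort("interactions.tsv: self-pair (gene_a == gene_b)")
  }
  interactions <- inter |>
    mutate(a = pmin(gene_a, gene_b), b = pmax(gene_a, gene_b)) |>
    mutate(evidence_sources = strsplit(evidence_sources, ";", fixed = TRUE)) |>
    group_by(gene_a = a, gene_b = b, kind) |>
    summarise(
      evidence_sources = list(sort(unique(trimws(unlist(evidence_sources))))),
      .groups = "drop"
    ) |>
    mutate(pair_score = purrr::map_dbl(
      evidence_sources,
      ~ aggregate_evidence_score(evidence_score_for(.x, config))
    )) |>
    arrange(gene_a, gene_b, kind)

  drug_targets <- targets_raw |>
    mutate(drug = canon(drug),
           gene = toupper(trimws(gene)),
           mode_of_action = tolower(trimws(mode_of_action)),
           is_direct = is_direct == "1",
           status = toupper(status)) |>
    distinct() |>
    arrange(drug, gene, source)

  cancer_genes <- cgenes_raw |>
    mutate(cancer = trimws(cancer), gene = toupper(trimws(gene))) |>
    group_by(cancer, gene) |>
    summarise(cancer_score = max(cancer_score), .groups = "drop") |>
    arrange(cancer, gene)

  indications <- indic_raw |>
    mutate(drug = canon(drug), cancer = trimws(cancer)) |>
    distinct() |>
    arrange(drug, cancer)

  atc <- atc_raw |> mutate(drug = canon(drug), atc_code = trimws(atc_code))
  bad_atc <- !grepl("^[ABCDGHJLMNPRSV]", atc$atc_code) | nchar(atc$atc_code) != 7
  if (any(bad_atc)) {
    warn(paste0("drug_atc.tsv: dropping malformed ATC code(s): ",
                paste(atc$atc_code[bad_atc], collapse = ", ")))
    atc <- atc[!bad_atc, ]
  }

  gene_symbols <- sort(unique(c(interactions$gene_a, interactions$gene_b,
                                roles_raw$gene, drug_targets$gene,
                                cancer_genes$gene)))
  genes <- tibble(symbol = gene_symbols) |>
    left_join(roles_raw, by = c(symbol = "gene")) |>
    mutate(role = ifelse(is.na(role), "OTHER", role))

  drug_names <- sort(unique(c(drug_targets$drug, indications$drug, atc$drug)))
  drugs <- tibble(drug = drug_names) |>
    left_join(atc |> distinct(drug, .keep_all = TRUE), by = "drug")

  cancers <- tibble(cancer = sort(unique(c(cancer_genes$cancer,
                                           indications$cancer))))

  graph <- structure(
    list(genes = genes, drugs = drugs, cancers = cancers,
         interactions = interactions, drug_targets = drug_targets,
         cancer_genes = cancer_genes, indications = indications,
         synonyms = synonyms, config = config),
    class = "slkg"
  )
  validate_kg(graph)
  graph
}

#' Check referential integrity of a knowledge graph
#'
#' One full pass over every relationship table, verifying that each
#' endpoint resolves to a registered entity.
#'
#' @param graph An `slkg` object.
#' @return The graph, invisibly; aborts with the dangling endpoints
#'   otherwise.
#' @export
validate_kg <- function(graph) {
  stopifnot(inherits(graph, "slkg"))
  gsym <- graph$genes$symbol
  dn <- graph$drugs$drug
  cn <- graph$cancers$cancer
  dangling <- c(
    setdiff(c(graph$interactions$gene_a, graph$interactions$gene_b), gsym),
    setdiff(graph$drug_targets$gene, gsym),
    setdiff(graph$cancer_genes$gene, gsym),
    setdiff(graph$drug_targets$drug, dn),
    setdiff(graph$indications$drug, dn),
    setdiff(graph$cancer_genes$cancer, cn),
    setdiff(graph$indications$cancer, cn)
  )
  if (length(dangling)) {
    abort(paste0("dangling relationship endpoint(s): ",
                 paste(unique(dangling), collapse = ", ")))
  }
  if (anyDuplicated(tolower(dn))) {
    abort("duplicate canonical drug names after case-folding")
  }
  invisible(graph)
}

#' Merged drug-target link view
#'
#' Collapses the stored drug-target evidence rows into one link per
#' (drug, gene) with the union of source databases, an any-row direct
#' flag, the set of modes of action, a per-link inhibitory flag (mode
#' matched against `config$inhibitory_modes`), and the maximum
#' pre-computed DScore over the link's (status, target-type) rows.
#'
#' @param graph An `slkg` object.
#' @param config Configuration (for mode labels and the DScore table).
#' @return Tibble: `drug`, `gene`, `sources` (list), `n_sources`,
#'   `is_direct`, `modes` (list), `inhibitory`, `dscore_max`.
#' @export
target_links <- function(graph, config = graph$config %||% default_config()) {
  if (nrow(graph$drug_targets) == 0) {
    return(tibble(drug = character(), gene = character(),
                  sources = list(), n_sources = integer(),
                  is_direct = logical(), modes = list(),
                  inhibitory = logical(), dscore_max = double()))
  }
  graph$drug_targets |>
    mutate(dscore = precomputed_dscore(status, is_direct, config)) |>
    group_by(drug, gene) |>
    summarise(
      sources = list(sort(unique(source))),
      n_sources = length(unique(source)),
      is_direct = any(is_direct),
      modes = list(sort(unique(mode_of_action))),
      inhibitory = any(mode_of_action %in% tolower(config$inhibitory_modes)),
      dscore_max = max(dscore),
      .groups = "drop"
    )
}

#' Query SL/SDL partners of a gene
#'
#' @param graph An `slkg` object.
#' @param gene Gene symbol (case-insensitive).
#' @param kind `"SL"` or `"SDL"`.
#' @return Tibble of the gene's interactions of that kind with columns
#'   `gene`, `partner`, `kind`, `evidence_sources`, `pair_score`,
#'   ordered lexicographically by partner. Unknown genes yield an empty
#'   tibble.
#' @export
query_partners <- function(graph, gene, kind = c("SL", "SDL")) {
  kind <- match.arg(kind)
  g <- toupper(trimws(gene))
  graph$interactions |>
    filter(kind == !!kind, gene_a == g | gene_b == g) |>
    mutate(partner = ifelse(gene_a == g, gene_b, gene_a), gene = g) |>
    select(gene, partner, kind, evidence_sources, pair_score) |>
    arrange(partner)
}

#' Write a knowledge graph back to TSV tables
#'
#' Inverse of [load_kg_tables()]: re-loading the written directory yields
#' an identical graph (entity and edge multisets equal).
#'
#' @param graph An `slkg` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kg_tables <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_tsv(df, file.path(dir, name), progress = FALSE)
  }
  wr(graph$interactions |>
       mutate(evidence_sources = purrr::map_chr(evidence_sources,
                                                paste, collapse = ";")) |>
       select(gene_a, gene_b, kind, evidence_sources),
     "interactions.tsv")
  wr(graph$genes |> rename(gene = symbol), "gene_roles.tsv")
  wr(graph$drug_targets |>
       mutate(is_direct = as.integer(is_direct), status = tolower(status)),
     "drug_targets.tsv")
  wr(graph$cancer_genes, "cancer_genes.tsv")
  wr(graph$indications, "indications.tsv")
  wr(tibble(alias = names(graph$synonyms),
            canonical = unname(graph$synonyms)), "synonyms.tsv")
  wr(graph$drugs |> filter(!is.na(atc_code)), "drug_atc.tsv")
  invisible(dir)
}

#' @export
print.slkg <- function(x, ...) {
  cat("Synthetic-lethality knowledge graph\n")
  cat(sprintf("  entities: %d genes, %d drugs, %d cancer types\n",
              nrow(x$genes), nrow(x$drugs), nrow(x$cancers)))
  cat(sprintf(
    "  relationships: %d SL/SDL pairs, %d drug-target rows, %d cancer-gene links, %d indications\n",
    nrow(x$interactions), nrow(x$drug_targets), nrow(x$cancer_genes),
    nrow(x$indications)))
  invisible(x)
}
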