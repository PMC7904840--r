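# Synthetic knowledge-graph generator with planted ground truth.
#
# Emits the full set of input tables at toy scale so every pipeline
# stage can be exercised without external downloads. A configurable
# number of candidates is planted so that their normalized scores exceed
# the SL thresholds, while decoy candidates fail exactly one threshold
# each (low pair evidence, low drug score, low cancer score) and random
# background structure fills out the score distributions below every
# threshold. A separate block plants a mutant gene with four SL pairs
# covered by two drugs, exercising the combination miner.

#' Parameters for the synthetic knowledge-graph generator
#'
#' Sizes refer to the random background on top of which planted
#' candidates, decoys, the combination block and a small SDL block are
#' added with dedicated entities.
#'
#' @param n_genes Background genes (default 24).
#' @param n_drugs Background drugs (default 8).
#' @param n_cancers Background cancer types (default 4).
#' @param n_sl_pairs,n_sdl_pairs Background SL / SDL pairs (16 / 6).
#' @param n_planted_candidates Candidates planted to pass the SL
#'   thresholds (default 3).
#' @param sensitivity_effect Downward shift, in units of the log-scale
#'   SD, of mutant-line sensitivity values relative to wild-type
#'   (default 2).
#' @param n_cell_lines_per_group Cell lines per mutant / wild-type group
#'   (default 10).
#' @param seed Random seed (default 42).
#' @param preset `"tiny"` (defaults above) or `"paper-shaped"` (a larger
#'   background: 120 genes, 30 drugs, 10 cancers, 80 SL / 20 SDL pairs).
#' @return A named list of class `synth_params`.
#' @export
synth_params <- function(n_genes = NULL, n_drugs = NULL, n_cancers = NULL,
                         n_sl_pairs = NULL, n_sdl_pairs = NULL,
                         n_planted_candidates = 3, sensitivity_effect = 2,
                         n_cell_lines_per_group = 10, seed = 42,
                         preset = c("tiny", "paper-shaped")) {
  preset <- match.arg(preset)
  base <- if (preset == "tiny") {
    list(n_genes = 24, n_drugs = 8, n_cancers = 4,
         n_sl_pairs = 16, n_sdl_pairs = 6)
  } else {
    list(n_genes = 120, n_drugs = 30, n_cancers = 10,
         n_sl_pairs = 80, n_sdl_pairs = 20)
  }
  p <- list(
    n_genes = n_genes %||% base$n_genes,
    n_drugs = n_drugs %||% base$n_drugs,
    n_cancers = n_cancers %||% base$n_cancers,
    n_sl_pairs = n_sl_pairs %||% base$n_sl_pairs,
    n_sdl_pairs = n_sdl_pairs %||% base$n_sdl_pairs,
    n_planted_candidates = n_planted_candidates,
    sensitivity_effect = sensitivity_effect,
    n_cell_lines_per_group = n_cell_lines_per_group,
    seed = seed, preset = preset
  )
  sizes <- unlist(p[c("n_genes", "n_drugs", "n_cancers")])
  if (any(sizes < 2) || p$n_planted_candidates < 0 ||
      p$sensitivity_effect < 0 || p$n_cell_lines_per_group < 1) {
    abort("invalid generator parameters: sizes must be >= 2, counts non-negative")
  }
  if (p$n_sl_pairs + p$n_sdl_pairs > choose(p$n_genes, 2)) {
    abort("infeasible parameters: more background pairs requested than distinct gene pairs")
  }
  structure(p, class = "synth_params")
}

sample_pairs <- function(genes, n) {
  all_pairs <- t(combn(genes, 2))
  all_pairs[sample.int(nrow(all_pairs), n), , drop = FALSE]
}

#' Generate synthetic knowledge-graph tables with planted truth
#'
#' Deterministic under a fixed seed: the same parameters always produce
#' identical tables. Planted candidates carry the strongest evidence
#' (CRISPR + synthetic-lethality screen), an approved direct-target
#' inhibitor supported by all three drug databases, and a high
#' gene-disease score, so their normalized scores reach 1. Three decoys
#' each fail exactly one threshold; background candidates fail at least
#' the drug and cancer thresholds. All drug names appearing in the
#' tables are registered in the synonym table (plus one trade-name alias
#' per planted drug, used in the indications table to exercise
#' canonicalization).
#'
#' @param params A [synth_params()] list.
#' @param dir Optional directory; when given, the tables are written as
#'   TSV files (the [load_kg_tables()] schemas plus `synergy.tsv`).
#' @return List with `tables` (named tibbles: interactions, gene_roles,
#'   drug_targets, cancer_genes, indications, synonyms, drug_atc,
#'   synergy) and `truth` (planted + decoy candidates with a
#'   `failure_mode` column, `"none"` for true positives).
#' @export
generate_kg <- function(params = synth_params(), dir = NULL) {
  withr::with_seed(params$seed, generate_kg_impl(params, dir))
}

generate_kg_impl <- function(params, dir) {
  np <- params$n_planted_candidates
  ip <- seq_len(np)

  # --- planted SL candidates -------------------------------------------
  planted <- tibble(
    mutant_gene = sprintf("MUTG%d", ip),
    target_gene = sprintf("TARG%d", ip),
    cancer = sprintf("Planted Cancer %d", ip),
    drug = sprintf("pdrug%d", ip),
    kind = "SL", failure_mode = "none"
  )

  # --- decoys: one per threshold-failure mode --------------------------
  decoys <- tibble(
    mutant_gene = sprintf("DMUT%d", 1:3),
    target_gene = sprintf("DTAR%d", 1:3),
    cancer = sprintf("Decoy Cancer %d", 1:3),
    drug = sprintf("ddrug%d", 1:3),
    kind = "SL",
    failure_mode = c("low_pair_score", "low_drug_score", "low_cancer_score")
  )

  # --- combination block: one TSG with 4 SL pairs, 2 covering drugs ----
  combo_mut <- "CMBG1"
  combo_partners <- sprintf("CPAR%d", 1:4)
  combo_drugs <- c("cdrug1", "cdrug2")

  # --- small SDL block -------------------------------------------------
  sdl_onco <- c("OMG1", "OMG2")
  sdl_targets <- c("OTG1", "OTG2")
  sdl_drugs <- c("sdrug1", "sdrug2")

  # --- background ------------------------------------------------------
  bg_genes <- sprintf("BG%03d", seq_len(params$n_genes))
  bg_drugs <- sprintf("bdrug%d", seq_len(params$n_drugs))
  bg_cancers <- sprintf("Background Cancer %d", seq_len(params$n_cancers))
  bg_tsg <- bg_genes[seq_len(max(2, params$n_genes %/% 4))]

  bg_pairs <- sample_pairs(bg_genes, params$n_sl_pairs + params$n_sdl_pairs)
  bg_sl <- bg_pairs[seq_len(params$n_sl_pairs), , drop = FALSE]
  bg_sdl <- bg_pairs[params$n_sl_pairs + seq_len(params$n_sdl_pairs), ,
                     drop = FALSE]
  bg_labels <- c("GENOMERNAI", "DAISY", "TEXT_MINING", "DECIPHER")
  bg_evidence <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(bg_labels, sample(1:2, 1)), collapse = ";")
    }, character(1))
  }

  interactions <- bind_rows(
    tibble(gene_a = planted$mutant_gene, gene_b = planted$target_gene,
           kind = "SL", evidence_sources = "CRISPR;SYNLETHALITY"),
    tibble(gene_a = decoys$mutant_gene, gene_b = decoys$target_gene,
           kind = "SL",
           evidence_sources = c("DAISY", "CRISPR;SYNLETHALITY",
                                "CRISPR;SYNLETHALITY")),
    tibble(gene_a = combo_mut, gene_b = combo_partners, kind = "SL",
           evidence_sources = "TEXT_MINING;GENOMERNAI"),
    tibble(gene_a = sdl_onco, gene_b = sdl_targets, kind = "SDL",
           evidence_sources = c("CRISPR", "TEXT_MINING")),
    tibble(gene_a = bg_sl[, 1], gene_b = bg_sl[, 2], kind = "SL",
           evidence_sources = bg_evidence(nrow(bg_sl))),
    tibble(gene_a = bg_sdl[, 1], gene_b = bg_sdl[, 2], kind = "SDL",
           evidence_sources = bg_evidence(nrow(bg_sdl)))
  )

  gene_roles <- bind_rows(
    tibble(gene = c(planted$mutant_gene, decoys$mutant_gene, combo_mut,
                    bg_tsg), role = "TSG"),
    tibble(gene = sdl_onco, role = "ONCOGENE"),
    tibble(gene = c(planted$target_gene, decoys$target_gene, combo_partners,
                    sdl_targets, setdiff(bg_genes, bg_tsg)), role = "OTHER")
  )

  approved_row <- function(drug, gene, sources = c("TTD", "DRUGBANK", "DGIDB")) {
    tibble(drug = drug, gene = gene, mode_of_action = "inhibition",
           is_direct = "1", status = "approved", source = sources)
  }
  bg_target_rows <- purrr::map_dfr(seq_along(bg_drugs), function(j) {
    genes <- sample(bg_genes, sample(1:3, 1))
    tibble(drug = bg_drugs[j], gene = genes,
           mode_of_action = sample(c("inhibition", "activation"),
                                   length(genes), replace = TRUE,
                                   prob = c(0.7, 0.3)),
           is_direct = "1", status = "experimental", source = "DGIDB")
  })
  drug_targets <- bind_rows(
    purrr::map_dfr(ip, ~ approved_row(planted$drug[.x],
                                      planted$target_gene[.x])),
    approved_row("ddrug1", "DTAR1"),
    tibble(drug = "ddrug2", gene = "DTAR2", mode_of_action = "inhibition",
           is_direct = "0", status = "experimental", source = "DGIDB"),
    approved_row("ddrug3", "DTAR3"),
    tibble(drug = "cdrug1", gene = combo_partners[1:2],
           mode_of_action = "inhibition", is_direct = "1",
           status = "approved", source = "TTD"),
    tibble(drug = "cdrug2", gene = combo_partners[3:4],
           mode_of_action = "inhibition", is_direct = "1",
           status = "approved", source = "TTD"),
    tibble(drug = sdl_drugs, gene = sdl_targets,
           mode_of_action = "inhibition", is_direct = "1",
           status = c("approved", "clinical_trials"), source = "DRUGBANK"),
    bg_target_rows
  )

  cancer_genes <- bind_rows(
    tibble(cancer = planted$cancer, gene = planted$mutant_gene,
           cancer_score = 0.95),
    tibble(cancer = decoys$cancer, gene = decoys$mutant_gene,
           cancer_score = c(0.95, 0.95, 0.02)),
    tibble(cancer = "Combo Cancer 1", gene = combo_mut, cancer_score = 0.1),
    tibble(cancer = sprintf("SDL Cancer %d", 1:2), gene = sdl_onco,
           cancer_score = c(0.6, 0.35)),
    purrr::map_dfr(seq_along(bg_cancers), function(j) {
      genes <- sample(bg_tsg, min(length(bg_tsg), sample(2:4, 1)))
      tibble(cancer = bg_cancers[j], gene = genes,
             cancer_score = round(runif(length(genes), 0.05, 0.4), 3))
    })
  )

  all_drugs <- unique(drug_targets$drug)
  synonyms <- bind_rows(
    tibble(alias = all_drugs, canonical = all_drugs),
    tibble(alias = sprintf("%s-trade", planted$drug), canonical = planted$drug)
  )

  # planted drug 1's indication is recorded under its trade name
  indications <- tibble(
    drug = c(if (np >= 1) sprintf("%s-trade", planted$drug[1]), "cdrug1"),
    cancer = c(if (np >= 1) "Background Cancer 1", "Combo Cancer 1")
  )

  drug_atc <- tibble(
    drug = c(planted$drug, combo_drugs, sdl_drugs),
    atc_code = sprintf("L01XE%02d", seq_len(np + 4))
  )

  synergy <- tibble(
    drug_a = c("cdrug1", "bdrug1"),
    drug_b = c("cdrug2", "bdrug2"),
    s_score = c(12, 3)
  )

  tables <- list(
    interactions = interactions, gene_roles = gene_roles,
    drug_targets = drug_targets, cancer_genes = cancer_genes,
    indications = indications, synonyms = synonyms, drug_atc = drug_atc,
    synergy = synergy
  )
  truth <- bind_rows(planted, decoys) |>
    select(drug, cancer, mutant_gene, target_gene, kind, failure_mode)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  list(tables = tables, truth = truth)
}

#' Generate synthetic cell-line sensitivity and mutation tables
#'
#' For each candidate, `n_cell_lines_per_group` mutant and wild-type
#' cell lines of the candidate's cancer type are created. Sensitivity
#' values (AUC for SL candidates, IC50 for SDL) are log-normal —
#' positive support and a heavy right tail, as observed for IC50
#' screens — with the mutant group's log-mean shifted downward by
#' `sensitivity_effect` log-scale standard deviations (more sensitive).
#' An effect of 0 makes the groups exchangeable (null data).
#'
#' @param params A [synth_params()] list.
#' @param candidates Candidates to back with cell-line data (`drug`,
#'   `cancer`, `mutant_gene`, `kind`), e.g. the planted truth.
#' @param dir Optional directory for `sensitivity.tsv`,
#'   `cell_mutations.tsv`, `cancer_map.tsv`.
#' @return List of tibbles `sensitivity`, `mutations`, `cancer_map`.
#' @export
generate_sensitivity <- function(params, candidates, dir = NULL) {
  if (params$n_cell_lines_per_group < 1) abort("group size must be >= 1")
  withr::with_seed(params$seed + 1L, {
    sdlog <- 0.5
    n <- params$n_cell_lines_per_group
    out <- purrr::map(seq_len(nrow(candidates)), function(i) {
      cand <- candidates[i, ]
      code <- sprintf("SC%02d", i)
      lines <- sprintf("%s_L%02d", code, seq_len(2 * n))
      mut_lines <- lines[seq_len(n)]
      meas <- if (cand$kind == "SL") "AUC" else "IC50"
      vals <- c(rlnorm(n, meanlog = -params$sensitivity_effect * sdlog,
                       sdlog = sdlog),
                rlnorm(n, meanlog = 0, sdlog = sdlog))
      list(
        sensitivity = tibble(cell_line = lines, drug = cand$drug,
                             measure = meas, value = signif(vals, 6)),
        mutations = tibble(cell_line = lines, gene = cand$mutant_gene,
                           status = ifelse(lines %in% mut_lines,
                                           "mutant", "wild_type"),
                           cancer_type = code),
        cancer_map = tibble(cancer_name = cand$cancer, tcga_code = code)
      )
    })
    tabs <- list(
      sensitivity = purrr::map_dfr(out, "sensitivity"),
      mutations = purrr::map_dfr(out, "mutations"),
      cancer_map = purrr::map_dfr(out, "cancer_map") |> distinct()
    )
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_tsv(tabs$sensitivity, file.path(dir, "sensitivity.tsv"),
                       progress = FALSE)
      readr::write_tsv(tabs$mutations, file.path(dir, "cell_mutations.tsv"),
                       progress = FALSE)
      readr::write_tsv(tabs$cancer_map, file.path(dir, "cancer_map.tsv"),
                       progress = FALSE)
    }
    tabs
  })
}
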