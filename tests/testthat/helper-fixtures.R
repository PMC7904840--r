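# Fixtures are built in code: tables are written to a temp directory and
# loaded through the package's own TSV ingestion.

library(dplyr)

# Write a named list of tibbles as <name>.tsv and load the graph.
make_kg <- function(tables, config = default_config()) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  for (nm in names(tables)) {
    readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  load_kg_tables(dir, config)
}

# Four genes, three drugs, two cancers; one SL pair with two evidence
# sources, one weak SL pair, one SDL pair.
tiny_tables <- function() {
  list(
    interactions = tibble(
      gene_a = c("TP53", "TP53", "KRAS"),
      gene_b = c("PARP1", "EGFR", "EGFR"),
      kind = c("SL", "SL", "SDL"),
      evidence_sources = c("CRISPR;GENOMERNAI", "DAISY", "TEXT_MINING")
    ),
    gene_roles = tibble(
      gene = c("TP53", "KRAS", "PARP1", "EGFR"),
      role = c("TSG", "ONCOGENE", "OTHER", "OTHER")
    ),
    drug_targets = tibble(
      drug = c("olaparib", "olaparib", "erlotinib", "actidrug"),
      gene = c("PARP1", "PARP1", "EGFR", "PARP1"),
      mode_of_action = c("inhibition", "inhibition", "inhibition",
                         "activation"),
      is_direct = c("1", "1", "1", "1"),
      status = c("approved", "approved", "approved", "approved"),
      source = c("TTD", "DRUGBANK", "DGIDB", "TTD")
    ),
    cancer_genes = tibble(
      cancer = c("Breast Cancer", "Lung Cancer"),
      gene = c("TP53", "KRAS"),
      cancer_score = c(0.9, 0.8)
    ),
    indications = tibble(drug = "olaparib", cancer = "Breast Cancer"),
    synonyms = tibble(
      alias = c("olaparib", "erlotinib", "actidrug", "OSI-906"),
      canonical = c("olaparib", "erlotinib", "actidrug", "linsitinib")
    )
  )
}

# The four-SL-pair combination example: two drugs each covering two of
# the mutant gene's pairs.
combo_tables <- function() {
  list(
    interactions = tibble(
      gene_a = c("ABCG2", "BRCA1", "BRCA1", "BRCA1"),
      gene_b = c("BRCA1", "EGFR", "PARP1", "PARP2"),
      kind = "SL",
      evidence_sources = "CRISPR"
    ),
    gene_roles = tibble(
      gene = c("BRCA1", "ABCG2", "EGFR", "PARP1", "PARP2"),
      role = c("TSG", "OTHER", "OTHER", "OTHER", "OTHER")
    ),
    drug_targets = tibble(
      drug = rep(c("erlotinib", "olaparib"), each = 2),
      gene = c("ABCG2", "EGFR", "PARP1", "PARP2"),
      mode_of_action = "inhibition",
      is_direct = "1", status = "approved",
      source = "TTD"
    ),
    cancer_genes = tibble(cancer = "Ovarian Carcinoma", gene = "BRCA1",
                          cancer_score = 0.9)
  )
}

# Independent oracle: exact one-sided rank-sum p-value by enumeration
# over all equally likely rank subsets for the first group.
rank_sum_oracle <- function(mutant, wildtype) {
  v <- c(mutant, wildtype)
  r <- rank(v)
  k <- length(mutant)
  obs <- sum(r[seq_len(k)])
  sets <- combn(length(v), k)
  sums <- colSums(matrix(r[sets], nrow = k))
  mean(sums <= obs)
}

# Independent oracle: best drug pair by exhaustive enumeration.
combo_oracle <- function(weights) {
  n <- nrow(weights)
  best_z <- -Inf
  best <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    z <- sum(weights[i, ]) + sum(weights[j, ])
    if (z > best_z + 1e-12) {
      best_z <- z
      best <- c(i, j)
    }
  }
  list(idx = best, objective = best_z)
}

# Monte-Carlo oracle for the beta order-statistic probabilities:
# Pr(U_(k) <= r_k) = Pr(at least k of n uniforms <= r_k).
rho_mc_oracle <- function(r, n_draws = 1e6) {
  n <- length(r)
  u <- matrix(runif(n_draws * n), ncol = n)
  probs <- vapply(seq_len(n), function(k) {
    mean(rowSums(u <= r[k]) >= k)
  }, numeric(1))
  min(probs)
}
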