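test_that("drug-name canonicalization resolves aliases case-insensitively", {
  res <- canonicalize_drug_name("OSI-906", c("OSI-906" = "linsitinib"))
  expect_equal(res$canonical, "linsitinib")
  expect_true(res$resolved)

  res <- canonicalize_drug_name(
    "linsitinib", c("OSI-906" = "linsitinib", "linsitinib" = "linsitinib"))
  expect_equal(res$canonical, "linsitinib")
  expect_true(res$resolved)

  res <- canonicalize_drug_name("unknowndrug", character())
  expect_equal(res$canonical, "unknowndrug")
  expect_false(res$resolved)

  expect_error(canonicalize_drug_name("", c(a = "b")), "malformed")
  expect_error(canonicalize_drug_name("x", c(a = "b"), policy = "error"),
               "unresolved")
})

test_that("canonicalization is idempotent on well-formed alias tables", {
  tab <- c("OSI-906" = "linsitinib", "linsitinib" = "linsitinib",
           "Iressa" = "gefitinib", "gefitinib" = "gefitinib")
  names <- c("osi-906", "IRESSA", "gefitinib", "novel-compound")
  once <- canonicalize_drug_name(names, tab)$canonical
  twice <- canonicalize_drug_name(once, tab)$canonical
  expect_identical(once, twice)
})

test_that("the tiny fixture loads with the expected entities and edges", {
  g <- make_kg(tiny_tables())
  expect_s3_class(g, "slkg")
  expect_equal(nrow(g$genes), 4)
  # synonyms are a lookup, not an entity roster: only drugs occurring in
  # relationship tables are registered
  expect_equal(sort(g$drugs$drug), c("actidrug", "erlotinib", "olaparib"))
  expect_equal(nrow(g$cancers), 2)
  expect_equal(nrow(g$interactions), 3)
  expect_silent(validate_kg(g))
  # merged target-link view: olaparib-PARP1 has two source databases
  links <- target_links(g)
  ol <- links[links$drug == "olaparib" & links$gene == "PARP1", ]
  expect_equal(ol$n_sources, 2)
  expect_equal(ol$sources[[1]], c("DRUGBANK", "TTD"))
  expect_equal(ol$dscore_max, 1)
  # single-source link keeps its one source
  er <- links[links$drug == "erlotinib", ]
  expect_equal(er$sources[[1]], "DGIDB")
})

test_that("unordered duplicate pairs merge with unioned evidence", {
  tabs <- tiny_tables()
  tabs$interactions <- bind_rows(
    tabs$interactions,
    tibble(gene_a = "PARP1", gene_b = "TP53", kind = "SL",
           evidence_sources = "TEXT_MINING")
  )
  g <- make_kg(tabs)
  pair <- g$interactions |> filter(gene_a == "PARP1", gene_b == "TP53")
  expect_equal(nrow(pair), 1)
  expect_equal(pair$evidence_sources[[1]],
               c("CRISPR", "GENOMERNAI", "TEXT_MINING"))
  # noisy-OR over the union
  expect_equal(pair$pair_score, 1 - 0.02 * 0.25 * 0.2)
})

test_that("writing and re-loading a graph round-trips", {
  g <- make_kg(tiny_tables())
  dir <- withr::local_tempdir()
  write_kg_tables(g, dir)
  g2 <- load_kg_tables(dir)
  for (tb in c("genes", "drugs", "cancers", "interactions",
               "drug_targets", "cancer_genes", "indications")) {
    expect_equal(as.data.frame(g[[tb]]), as.data.frame(g2[[tb]]),
                 info = tb)
  }
})

test_that("query_partners returns lexicographically ordered partners", {
  g <- make_kg(tiny_tables())
  res <- query_partners(g, "tp53", "SL")
  expect_equal(res$partner, c("EGFR", "PARP1"))
  expect_equal(nrow(query_partners(g, "ABSENT", "SL")), 0)
  expect_equal(nrow(query_partners(g, "PARP1", "SDL")), 0)
})

test_that("schema violations are reported with file and line", {
  tabs <- tiny_tables()
  tabs$drug_targets$status[2] <- "banana"
  expect_error(make_kg(tabs), "drug_targets.tsv: line 3")
  tabs <- tiny_tables()
  tabs$interactions$kind[1] <- "XX"
  expect_error(make_kg(tabs), "interactions.tsv: line 2")
  tabs <- tiny_tables()
  tabs$interactions$evidence_sources <- NULL
  expect_error(make_kg(tabs), "missing column")
})

test_that("unknown evidence labels without a configured score error", {
  tabs <- tiny_tables()
  tabs$interactions$evidence_sources[1] <- "CRISPR;MYSTERY_SOURCE"
  expect_error(make_kg(tabs), "MYSTERY_SOURCE")
  # but a configured fallback score accepts them
  g <- make_kg(tabs, default_config(unknown_evidence_score = 0.3))
  pair <- g$interactions |> filter(gene_b == "TP53" | gene_a == "TP53") |>
    filter(gene_a == "PARP1" | gene_b == "PARP1")
  expect_equal(pair$pair_score, 1 - 0.02 * 0.7)
})

test_that("gene symbols are case-folded and collisions rejected", {
  tabs <- tiny_tables()
  tabs$interactions$gene_a[1] <- "tp53"
  g <- make_kg(tabs)
  expect_true("TP53" %in% g$genes$symbol)
  tabs <- tiny_tables()
  tabs$gene_roles <- bind_rows(tabs$gene_roles,
                               tibble(gene = "tp53", role = "TSG"))
  expect_error(make_kg(tabs), "collision")
})

test_that("self-pairs are rejected", {
  tabs <- tiny_tables()
  tabs$interactions$gene_b[1] <- "TP53"
  expect_error(make_kg(tabs), "self-pair")
})
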