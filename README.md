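# slrepurpose

Drug repurposing from synthetic lethality. When a tumor carries a
loss-of-function mutation in a tumor suppressor gene (TSG), inhibiting a
synthetic-lethal (SL) partner of that gene kills the tumor cell
selectively — the PARP-inhibitor-in-*BRCA*-mutant-cancer paradigm.
Synthetic dosage lethality (SDL) is the oncogene analogue: inhibiting
the partner of an overexpressed oncogene. `slrepurpose` integrates SL
and SDL gene pairs with drug–target, gene–disease and drug–indication
tables into an in-memory knowledge graph, prioritizes repurposable
(drug, cancer, mutant gene) candidates, validates them against
cell-line pharmacology, and mines two-drug combinations.

It is aimed at computational biologists who have tabular exports of
SL/SDL pair collections (SynLethDB-style), drug–target databases
(TTD/DrugBank/DGIdb-style), gene–disease scores (DisGeNET-style) and
cell-line sensitivity screens (GDSC/CTRP-style), and want a
reproducible prioritization pipeline over them.

## The scoring schema

A candidate is a drug inhibiting gene B of an SL (SDL) pair whose
partner gene A is a mutated TSG (oncogene) in a given cancer. Both
orientations of each unordered pair are mapped. Three scores are
attached:

* **Pair score** (SLScore / SDLScore). Each evidence source *i*
  supporting the pair carries a reliability score *p<sub>i</sub>*
  (CRISPR screen 0.98, synthetic-lethality screen 0.95, text mining
  0.8, GenomeRNAi / Decipher 0.75, computational predictions 0.5 or
  0.25). Multiple sources combine by noisy-OR:

  *s* = 1 − ∏ (1 − *p<sub>i</sub>*)

  so a CRISPR + GenomeRNAi pair scores 1 − 0.02 × 0.25 = **0.995**.

* **DrugScore** = max{pre-computed DScore} − 0.01 × (collective gene
  impact) + 0.001 × (database factor), where the pre-computed DScore is
  a status lookup (approved 1 / 0.8, clinical trials 0.6 / 0.4,
  experimental 0.2 / 0.1 for direct / other targets), the collective
  gene impact is the drug's number of distinct targets (specificity
  penalty) and the database factor counts the source databases
  supporting the link.

* **CancerScore**: the gene–disease association score of the mutant
  gene in that cancer, in [0, 1].

Each score is min-max normalized per kind, and the best candidates are
those strictly above the per-kind thresholds (SL: 0.7 / 0.8 / 0.7;
SDL: 0.8 / 0.5 / 0.3 for pair / drug / cancer). Robust rank aggregation
orders them: each candidate's three normalized ranks
*r*<sub>(1)</sub> ≤ *r*<sub>(2)</sub> ≤ *r*<sub>(3)</sub> give

ρ = min<sub>k</sub> B(*r*<sub>(k)</sub>; *k*, *n* − *k* + 1),

the minimum beta order-statistic probability; small ρ means the
candidate sits near the top of all three lists.

Validation labels cell lines of the candidate's cancer type as mutant
or wild-type for the mutant gene and applies a one-sided Wilcoxon
rank-sum test to AUC (SL) or IC50 (SDL) values — smaller values mean
more sensitive. Combination mining builds, per mutant gene, a weighted
bipartite graph of drugs versus the gene's SL pairs and solves

max Z = Σ<sub>i</sub> Σ<sub>j</sub> d<sub>i</sub> s<sub>ij</sub>  subject to  Σ d<sub>i</sub> = 2

exactly, then drops pairs whose recorded synergy S score is below 5
(antagonism).

## Worked example

```r
library(slrepurpose)

aggregate_evidence_score(c(0.98, 0.75))
#> [1] 0.995

## synthetic tables with 3 planted candidates and per-threshold decoys
p   <- synth_params(seed = 1)
dir <- file.path(tempdir(), "slkg-demo")
sim <- generate_kg(p, dir = dir)
g   <- load_kg_tables(dir)
g
#> Synthetic-lethality knowledge graph
#>   entities: 45 genes, 18 drugs, 13 cancer types
#>   relationships: 34 SL/SDL pairs, 39 drug-target rows, 20 cancer-gene links, 2 indications

pharm <- generate_sensitivity(p, subset(sim$truth, failure_mode == "none"))
res <- run_pipeline(g, file.path(tempdir(), "slkg-out"),
                    pharm = pharm, synergy = sim$tables$synergy)
res$ranked[res$ranked$kind == "SL",
           c("drug", "cancer", "mutant_gene", "rho", "aggregate_rank")]
#>   drug   cancer           mutant_gene   rho aggregate_rank
#> 1 pdrug1 Planted Cancer 1 MUTG1       0.296              1
#> 2 pdrug2 Planted Cancer 2 MUTG2       0.296              2
#> 3 pdrug3 Planted Cancer 3 MUTG3       0.296              3
res$summary
#> $n_candidates  [1] 4
#> $n_testable    [1] 3
#> $n_validated   [1] 3
#> $proportion_validated [1] 1
```

The three planted candidates — and only they — pass the SL thresholds,
tie on ρ (each tops one list by construction), and all three validate
(mutant lines were simulated 2 SD more sensitive). The combination
miner recovers the planted mutant gene whose four SL pairs are covered
by two drugs:

```r
res$combos[res$combos$mutant_gene == "CMBG1", ]
#>   drug_a drug_b mutant_gene objective n_covered_pairs antagonism_status
#> 1 cdrug1 cdrug2 CMBG1            3.92               4 SYNERGISTIC_OR_ADDITIVE
```

A thin command-line wrapper covers the same flow:

```sh
Rscript inst/cli/slkg.R simulate --out sim --seed 42
Rscript inst/cli/slkg.R run --in sim --out results
```

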