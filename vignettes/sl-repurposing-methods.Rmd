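---
title: "Methods: synthetic-lethality-based drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-lethality-based drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrepurpose)
library(dplyr)
```

## The model

Synthetic lethality (SL) pairs a tumor suppressor gene (TSG) with a
partner whose inhibition is lethal only when the TSG is lost; synthetic
dosage lethality (SDL) pairs an overexpressed oncogene with a partner
whose inhibition is lethal only in that context. Both turn an
undruggable mutation into a druggable vulnerability: inhibit the
partner, spare normal cells. `slrepurpose` operationalizes this as a
knowledge-graph traversal. Entities are genes, drugs and cancer types;
relationships are (1) SL/SDL gene pairs with per-source evidence, (2)
cancer–mutant-gene links with an association score, (3) drug–target
links with mode of action, development status and source databases, and
(4) known drug indications.

A repurposing candidate is a tuple (drug, cancer, mutant gene, target
gene) such that {mutant gene, target gene} is an SL (SDL) pair, the
mutant gene is a TSG (oncogene) mutated in the cancer, and the drug
holds an *inhibitory* link to the target gene. Gene A and gene B of a
pair carry no intrinsic orientation, so both assignments are tried; a
gene that is both TSG and oncogene across role sources is eligible for
both kinds, because the role filter is applied per kind. The inhibitory
filter matches the mode-of-action label against a configurable set
(`inhibition`, `inhibitor`, `antagonist` by default): source databases
are inconsistent in their vocabulary, and a single hard-coded label
would silently drop valid links.

## Scores, normalization, thresholds

**Pair score.** Each evidence source has a reliability score
$p_i \in (0,1)$: CRISPR screens 0.98, dedicated synthetic-lethality
screens 0.95, text mining 0.8, GenomeRNAi and Decipher 0.75,
computational predictions 0.5 (Daisy-style) or 0.25 (other methods).
Sources combine by noisy-OR, $s = 1 - \prod_i (1 - p_i)$, which is
permutation-invariant, strictly increasing in added evidence and
bounded below 1 — independent unreliable witnesses, any one of which
could be wrong. Unknown evidence labels are an error by default rather
than a silent default score; a fallback score is configurable.

**Drug score.**
$\mathrm{DrugScore} = \max\{\text{pre-computed DScore}\} -
0.01\,I + 0.001\,F$, with the pre-computed DScore a lookup in
(approved 1/0.8, clinical trials 0.6/0.4, experimental 0.2/0.1 for
direct/other target). The penalty term $I$ ("collective gene impact")
and bonus term $F$ ("database factor") are not fully pinned down by the
PanDrugs-style convention the schema follows; this package defines $I$
as the drug's number of distinct target genes (promiscuity penalty) and
$F$ as the number of distinct source databases supporting the
drug–target link, both computed from the graph and both documented as
deliberate choices. When a merged (drug, gene) link carries several
status rows, the maximum pre-computed value is used. A link with no
explicit direct/other flag is treated as direct — the conservative
reading, since the primary row of the status table is the direct one.

**Cancer score.** Taken directly from the gene–disease table; when
several rows give different scores for one (cancer, gene), the maximum
is kept — trusting the strongest reported association rather than
averaging away a well-supported link.

**Normalization and selection.** Each score vector is min-max
normalized, separately per kind and per scoring function, because SL
and SDL score distributions differ systematically (SDL evidence is
sparser, so SDL pair scores are less spread). A constant vector makes
the transform undefined; it is mapped to zeros with a warning, which
keeps one-candidate toy inputs runnable while making the degeneracy
visible. Candidates are retained when all three normalized scores are
*strictly* greater than the kind's thresholds — SL: pair 0.7, drug
0.8, cancer 0.7; SDL: pair 0.8, drug 0.5, cancer 0.3 — matching the
"greater than" reading of the published cutoffs.

## Robust rank aggregation

Selected candidates are ordered by integrating their ranks on the
three score lists. For one candidate, the three normalized ranks
(rank/length, mean rank for ties) are sorted and
$\rho = \min_k B(r_{(k)}; k, n-k+1)$ is taken, $B$ the beta
distribution function — the probability that the $k$-th smallest of
$n$ uniform ranks would be at most $r_{(k)}$ under the null of random
list positions. Because ranks are invariant to monotone transforms,
aggregating raw or normalized scores is equivalent. The classical
$n$-fold (Bonferroni-style) correction of $\rho$ is exposed as a
config flag but off by default: it is monotone, so it cannot change an
ordering, and the package uses $\rho$ only for ordering. Ties in
$\rho$ break lexicographically by (drug, cancer) so runs are
reproducible.

## Cell-line validation

For each candidate, cell lines of the candidate's cancer (mapped
through a cancer-name → standardized-code table, e.g. Ovarian
Carcinoma → OV) are partitioned by the mutant gene's status; lines with
no record for that gene count as wild-type. The one-sided Wilcoxon
rank-sum test asks whether mutant lines have *smaller* AUC (SL) or
IC50 (SDL) — smaller means more sensitive in both measures, so the
direction is the same. The implementation delegates to
`stats::wilcox.test`, exact when the combined sample is at most 20 with
no ties and the tie-corrected normal approximation otherwise; an
independent enumeration oracle in the test suite verifies the exact
branch over every split up to combined $n = 10$. Candidates need at
least 3 lines per group to be testable; with fewer than 3 in either
group the smallest attainable exact p-value of a balanced split
(1/C(4,2) = 1/6) cannot approach $\alpha$, so smaller groups can never
inform the decision. Significance is $\alpha = 0.05$ per candidate with no
multiple-testing correction, matching how per-candidate validation
p-values are conventionally reported in this setting; both knobs are
configurable. Untestable candidates are excluded from the summary
denominator.

## Combination mining

Resistance via alternative pathways motivates pairing drugs that
jointly cover many SL pairs of one mutant gene. Per mutant gene, a
bipartite graph holds the gene's SL pairs on one side and on the other
every drug inhibiting at least one *partner* gene; $s_{ij}$ is drug
$i$'s DrugScore where it covers pair $j$ and 0 otherwise. A drug
targeting only the shared mutant gene is excluded: every pair contains
the mutant gene, so counting it as coverage would make such a drug
trivially cover everything. The selection program
$\max Z = \sum_i \sum_j d_i s_{ij}$, $\sum_i d_i = 2$, contains no
per-pair coverage variables, so $Z$ is separable and the optimum is
the top two drugs by weight row-sum; the solver nevertheless
enumerates all pairs exactly (sizes up to 3 are supported) so the
tie-break — more distinct covered pairs, then drug-name order — is
explicit, and a property test asserts the row-sum identity on random
instances. Per-gene problems are solved independently (the
published four-pairs-two-drugs example is consistent with per-gene
subproblems) and identical drug pairs found for several genes keep the
maximum-objective instance. Pairs with a recorded synergy S score
strictly below 5 are antagonistic at IC50 and removed; unrecorded
pairs are kept as `UNKNOWN` rather than silently assumed synergistic.
Combinations are mined for SL only — SDL collections are too sparse to
support multi-pair coverage. First-level ATC letters annotate the
surviving pairs.

## The synthetic-data generator

`generate_kg()` emulates the *shape* of the real inputs — per-source
evidence labels, development statuses, gene–disease scores, trade-name
aliases — at toy scale with planted ground truth, so the whole
pipeline is testable offline. Its defaults are fixed study conditions,
not tuning knobs: 3 planted candidates; a background of 24 genes, 8
drugs, 4 cancers, 16 SL and 6 SDL pairs (the `paper-shaped` preset
scales the background to 120/30/10/80/20); sensitivity effect 2
log-scale SD; 10 cell lines per group; seed 42.

Planted candidates get CRISPR + screen evidence (pair score 0.999), an
approved single-target inhibitor backed by all three drug databases
(DrugScore 0.993) and a cancer score of 0.95 — the maximum of each
score distribution, hence normalized to 1. Three decoys each fail
exactly one threshold (computational-only evidence; an experimental
indirect drug; a 0.02 cancer score) so each cutoff is exercised
independently, and background candidates fall below the drug and
cancer thresholds by construction. A dedicated block plants one TSG
with four SL pairs covered two-by-two by two drugs for the combination
miner, plus one antagonistic background pair (S = 3) for the synergy
filter. Sensitivity values are log-normal (positive support, heavy
right tail, as IC50 measurements are) with the mutant group's log-mean
shifted down by the effect size; effect 0 gives exchangeable null
groups. With 10 lines per group and a 2 SD shift, the one-sided test
detects the shift in essentially every replicate, which is what makes
planted-recovery tests sharp.

What passing on synthetic data does *not* show: real SL collections
have correlated evidence sources, hub genes, and score distributions
whose thresholds were calibrated on database-scale cumulative curves;
the generator plants clean separations instead. Results at database
scale (thousands of pairs, hundreds of candidates) depend on the
snapshots of the source databases and are outside what this package
can reproduce.

## Numerical and interface choices

* Pairs are stored unordered (lexicographically oriented) and merged
  with unioned evidence; gene symbols are upper-cased on ingest, with
  case-fold collisions rejected rather than silently merged.
* Canonical drug names are lower-cased; unknown aliases pass through
  unchanged with a warning (drug-name standardization in the source
  databases is partly manual, so a hard error would be unusable),
  while a strict `error` policy is available.
* Synonym tables are lookups, not entity rosters: only drugs occurring
  in relationship tables become graph entities.
* Test problem sizes (e.g. exhaustive rank-sum enumeration to combined
  $n = 10$, 100 random combination instances up to 12 drugs, $10^6$
  Monte-Carlo draws for the beta order-statistic check, 1000 null and
  200 power replicates) were chosen so each suite of checks runs in
  seconds to a couple of minutes while leaving the estimates' Monte
  Carlo error well inside the asserted tolerances.

## Limitations

Druggability is represented purely by the presence of drug–target
links; genes without links are invisible to the mapper. The DrugScore
penalty/bonus definitions are package choices where the upstream
convention is underspecified. The validation stage assumes the
sensitivity and mutation tables share cell-line identifiers and that
cancer-type codes are consistent; no fuzzy matching is attempted.
Combination mining fixes the pair size at 2 (3 with exact enumeration)
and does not model dose or scheduling; synergy filtering depends
entirely on the supplied S-score table.
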