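#' Default pipeline configuration
#'
#' Returns the configuration used throughout the pipeline: the per-source
#' quantitative evidence scores for SL/SDL pairs, the pre-computed DScore
#' lookup by drug development status and target type, the per-kind
#' normalized-score thresholds that define the best repurposable
#' candidates, and the statistical / combination-mining parameters.
#'
#' The defaults are:
#' \itemize{
#'   \item evidence scores: CRISPR 0.98, SYNLETHALITY 0.95, GENOMERNAI 0.75,
#'     DECIPHER 0.75, TEXT_MINING 0.8, DAISY 0.5, COMPUTATIONAL_OTHER 0.25;
#'   \item pre-computed DScore: approved 1 (direct) / 0.8 (other),
#'     clinical trials 0.6 / 0.4, experimental 0.2 / 0.1;
#'   \item thresholds: SL pair > 0.7, drug > 0.8, cancer > 0.7;
#'     SDL pair > 0.8, drug > 0.5, cancer > 0.3 (on normalized scores,
#'     strict inequality);
#'   \item inhibitory mode-of-action labels: inhibition, inhibitor,
#'     antagonist (case-insensitive);
#'   \item Wilcoxon validation: alpha = 0.05, minimum 3 cell lines per
#'     group, AUC for SL and IC50 for SDL;
#'   \item combinations: pair size k = 2, synergy S-score cutoff 5.
#' }
#'
#' @param ... Named overrides for any top-level configuration entry.
#' @return A named list of class `slkg_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$evidence_scores[["CRISPR"]]
default_config <- function(...) {
  cfg <- list(
    evidence_scores = c(
      CRISPR = 0.98,
      SYNLETHALITY = 0.95,
      GENOMERNAI = 0.75,
      DECIPHER = 0.75,
      TEXT_MINING = 0.8,
      DAISY = 0.5,
      COMPUTATIONAL_OTHER = 0.25
    ),
    # unknown evidence labels error unless given a score here
    unknown_evidence_score = NULL,
    dscore_table = list(
      APPROVED = c(direct = 1, other = 0.8),
      CLINICAL_TRIALS = c(direct = 0.6, other = 0.4),
      EXPERIMENTAL = c(direct = 0.2, other = 0.1)
    ),
    thresholds = list(
      SL = list(kind = "SL", pair_score_min = 0.7, drug_score_min = 0.8,
                cancer_score_min = 0.7),
      SDL = list(kind = "SDL", pair_score_min = 0.8, drug_score_min = 0.5,
                 cancer_score_min = 0.3)
    ),
    inhibitory_modes = c("inhibition", "inhibitor", "antagonist"),
    alias_policy = "passthrough",   # or "error"
    alpha = 0.05,
    min_group_size = 3,
    measure_by_kind = c(SL = "AUC", SDL = "IC50"),
    combo_k = 2,
    s_min = 5,
    rra_bonferroni = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      abort(paste0("unknown config entries: ", paste(bad, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "slkg_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Entries present in the file override the defaults of
#' [default_config()]; everything else keeps its default. Nested tables
#' (`evidence_scores`, `dscore_table`, `thresholds`) replace the default
#' table wholesale when given.
#'
#' @param path Path to a YAML file.
#' @return A `slkg_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) {
      abort(paste0("unknown config entry '", nm, "' in ", path))
    }
    val <- raw[[nm]]
    if (nm == "evidence_scores") val <- unlist(val)
    if (nm == "measure_by_kind") val <- unlist(val)
    if (nm == "dscore_table") val <- lapply(val, unlist)
    cfg[[nm]] <- val
  }
  cfg
}
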