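# Robust rank aggregation: each candidate holds one rank per scoring
# function; the rho score is the minimum over k of the Beta(k, n-k+1)
# distribution function evaluated at the k-th smallest normalized rank —
# the probability that the k-th order statistic of uniform ranks would be
# at least that small by chance. Smaller rho = stronger joint support.

#' Normalized ranks of a score vector
#'
#' Rank 1 is best (the highest score when `descending = TRUE`); tied
#' values receive the mean of their positions; ranks are divided by the
#' vector length so every value lies in (0, 1].
#'
#' @param scores Non-empty numeric vector.
#' @param descending If `TRUE` (default), larger scores rank better.
#' @return Numeric vector of normalized ranks in (0, 1].
#' @export
#' @examples
#' normalized_ranks(c(10, 30, 20))  # 1, 1/3, 2/3
normalized_ranks <- function(scores, descending = TRUE) {
  if (length(scores) == 0) abort("cannot rank an empty score vector")
  r <- rank(if (descending) -scores else scores, ties.method = "average")
  r / length(scores)
}

#' Rho score of a sorted vector of normalized ranks
#'
#' For normalized ranks \eqn{r_{(1)} \le \dots \le r_{(n)}},
#' \deqn{\rho = \min_k P\left(U_{(k)} \le r_{(k)}\right)
#'            = \min_k \; B(r_{(k)}; k, n - k + 1),}
#' the minimum over k of the beta order-statistic distribution function.
#' An optional Bonferroni-style correction multiplies rho by n (capped at
#' 1); it is monotone, so it never changes an ordering.
#'
#' @param r Numeric vector of normalized ranks, sorted ascending, in
#'   (0, 1].
#' @param bonferroni Apply the n-fold correction (default `FALSE`).
#' @return Rho in (0, 1].
#' @export
#' @examples
#' rho_score(c(0.1, 0.2))  # 0.04
rho_score <- function(r, bonferroni = FALSE) {
  if (length(r) == 0) abort("empty rank vector")
  if (any(!is.finite(r)) || any(r <= 0 | r > 1)) {
    abort("normalized ranks must lie in (0, 1]")
  }
  if (is.unsorted(r)) abort("normalized ranks must be sorted ascending")
  n <- length(r)
  k <- seq_len(n)
  rho <- min(pbeta(r, k, n - k + 1))
  if (bonferroni) rho <- min(1, rho * n)
  rho
}

#' Order candidates by robust rank aggregation
#'
#' Builds one normalized-rank list per scoring function (pair, drug,
#' cancer; larger scores rank better), computes each candidate's rho
#' score from its three ranks, and assigns `aggregate_rank` 1..n in
#' increasing rho; ties in rho are broken lexicographically by
#' (drug, cancer) for reproducibility. Ranks are invariant under
#' monotone transforms of the scores, so raw and min-max-normalized
#' scores give the same ordering.
#'
#' @param candidates Scored candidates (columns `pair_score`,
#'   `drug_score`, `cancer_score`).
#' @param config Configuration (Bonferroni flag).
#' @return `candidates` with columns `rho` and `aggregate_rank`, ordered
#'   by rank.
#' @export
aggregate_ranks <- function(candidates, config = default_config()) {
  if (nrow(candidates) == 0) {
    return(candidates |> mutate(rho = double(), aggregate_rank = integer()))
  }
  req <- c("pair_score", "drug_score", "cancer_score")
  if (!all(req %in% names(candidates)) || anyNA(candidates[req])) {
    abort("candidates must carry complete pair/drug/cancer scores")
  }
  rmat <- cbind(normalized_ranks(candidates$pair_score),
                normalized_ranks(candidates$drug_score),
                normalized_ranks(candidates$cancer_score))
  rho <- apply(rmat, 1, function(r) {
    rho_score(sort(r), bonferroni = isTRUE(config$rra_bonferroni))
  })
  candidates |>
    mutate(rho = rho) |>
    arrange(rho, drug, cancer) |>
    mutate(aggregate_rank = row_number())
}
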