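# Pairwise combination scoring: combined OMU vectors (component-wise max,
# proportion-normalized), growth impact scores from the balance model, the
# three-case differential growth impact score (DGIS), and the candidate
# ranking.

#' Proportion-normalize an OMU vector
#' @param v Named numeric vector or long tibble (`omu`, `value`).
#' @return Named numeric vector summing to 1.
#' @export
normalize_vector <- function(v) {
  if (is.data.frame(v)) v <- setNames(v$value, v$omu)
  s <- sum(v)
  if (s <= 0) stop_omu("cannot normalize an all-zero vector")
  v / s
}

#' Combine two single-drug OMU vectors
#'
#' Shared OMU components take the larger of the two values (each drug is
#' assumed to drive the OMU at least as strongly as it does alone); the
#' result is renormalized to proportions summing to 1. `combine = "sum"`
#' adds components instead, for sensitivity analysis. Combining a vector
#' with itself returns its own proportions.
#'
#' @param v1,v2 Named numeric vectors over the same OMU system (or long
#'   tibbles `omu`, `value`).
#' @param combine `"max"` (default) or `"sum"`.
#' @return Named numeric proportion vector over the same OMUs.
#' @export
combine_omu_vectors <- function(v1, v2, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (is.data.frame(v1)) v1 <- setNames(v1$value, v1$omu)
  if (is.data.frame(v2)) v2 <- setNames(v2$value, v2$omu)
  if (!identical(names(v1), names(v2)))
    stop_omu("vectors must share one OMU system (same components, same order)")
  cv <- if (combine == "max") pmax(v1, v2) else v1 + v2
  normalize_vector(cv)
}

#' Growth impact score of a (combined) OMU vector
#'
#' GIS = intercept + slope * balance at the model's node. Unlike GRmax the
#' prediction is unbounded. Undefined balances yield `NA` (the candidate is
#' flagged unscorable by the ranking step).
#'
#' @param cv Proportion vector from [combine_omu_vectors()] (or any OMU
#'   vector).
#' @param model An `omu_balance_fit`.
#' @param node The balance-tree row the model was fitted at (e.g.
#'   `attr(model, "node_row")`).
#' @param pseudocount See [ilr_balance()].
#' @return The GIS, or `NA_real_` when the balance is undefined.
#' @export
growth_impact_score <- function(cv, model, node, pseudocount = NULL) {
  b <- ilr_balance(cv, node, pseudocount)
  if (is.na(b)) return(NA_real_)
  model$intercept + model$slope * b
}

#' Differential growth impact score
#'
#' Compares a pair's GIS with its two self-pair GIS values: below both the
#' DGIS is the (negative) gap to the lower one, predicting super-additive
#' growth inhibition; between them (inclusive) it is 0, the independent
#' case; above both it is the (positive) gap to the higher one.
#'
#' @param gis12 GIS of the combined pair.
#' @param gis11,gis22 GIS of each drug combined with itself.
#' @return The DGIS. Exactly 0 for a self-pair.
#' @export
dgis <- function(gis12, gis11, gis22) {
  stopifnot(is.finite(gis12), is.finite(gis11), is.finite(gis22))
  lo <- min(gis11, gis22); hi <- max(gis11, gis22)
  if (gis12 < lo) gis12 - lo
  else if (gis12 > hi) gis12 - hi
  else 0
}

#' Score all pairwise drug combinations
#'
#' Builds every unordered pair's combined vector, computes GIS for the pair
#' and both self-pairs, and the DGIS. Pairs with an undefined balance are
#' flagged unscorable (`NA` scores) and reported.
#'
#' @param vectors Long OMU-vector tibble for all drugs (`sample`, `omu`,
#'   `value`).
#' @param model An `omu_balance_fit`.
#' @param node The model's balance-tree row.
#' @param combine `"max"` (default) or `"sum"`.
#' @param pseudocount See [ilr_balance()].
#' @return Tibble (`drug_1`, `drug_2`, `gis`, `dgis`, `scorable`), one row
#'   per unordered pair with `drug_1 < drug_2`.
#' @export
score_combinations <- function(vectors, model, node,
                               combine = c("max", "sum"),
                               pseudocount = NULL) {
  combine <- match.arg(combine)
  drugs <- sort(unique(vectors$sample))
  omus <- unique(vectors$omu)
  vlist <- map(drugs, function(d) {
    v <- vectors[vectors$sample == d, ]
    setNames(v$value, v$omu)[omus]
  })
  names(vlist) <- drugs
  self_gis <- map_dbl(vlist, function(v)
    growth_impact_score(combine_omu_vectors(v, v, combine), model, node,
                        pseudocount))
  idx <- utils::combn(length(drugs), 2)
  rows <- map(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    g12 <- growth_impact_score(
      combine_omu_vectors(vlist[[i]], vlist[[j]], combine), model, node,
      pseudocount)
    scorable <- !is.na(g12) && !is.na(self_gis[i]) && !is.na(self_gis[j])
    tibble(drug_1 = drugs[i], drug_2 = drugs[j],
           gis = g12,
           dgis = if (scorable) dgis(g12, self_gis[i], self_gis[j]) else NA_real_,
           scorable = scorable)
  })
  out <- list_rbind(rows)
  n_bad <- sum(!out$scorable)
  if (n_bad > 0)
    message(sprintf("%d pair(s) unscorable (undefined balance); excluded from ranking",
                    n_bad))
  out
}

#' Rank candidate combinations by DGIS
#'
#' Ascending DGIS (most negative = strongest predicted synergy first); ties
#' broken by GIS ascending then lexicographic pair order. Unscorable pairs
#' are dropped.
#'
#' @param scores Tibble from [score_combinations()].
#' @param top_k Number of top candidates to flag (default 30). When larger
#'   than the number of scorable pairs, all are returned with a warning.
#' @return Object of class `omu_ranking`: the full sorted tibble with
#'   columns `rank` and `top` (logical, the top-k flag).
#' @export
rank_pairs <- function(scores, top_k = 30) {
  sc <- filter(scores, .data$scorable)
  if (nrow(sc) == 0) stop_omu("no scorable pair to rank")
  if (top_k > nrow(sc)) {
    warning(sprintf("top_k = %d exceeds %d scorable pairs; returning all",
                    top_k, nrow(sc)))
    top_k <- nrow(sc)
  }
  out <- sc |>
    arrange(.data$dgis, .data$gis, .data$drug_1, .data$drug_2) |>
    mutate(rank = row_number(), top = row_number() <= top_k)
  class(out) <- c("omu_ranking", class(out))
  out
}

#' Histogram of the DGIS distribution
#' @param object An `omu_ranking`.
#' @param binwidth Histogram bin width (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.omu_ranking <- function(object, binwidth = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dgis)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(x = "DGIS", y = "pairs",
                  title = "Differential growth impact scores of all pairs") +
    ggplot2::theme_minimal()
}
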