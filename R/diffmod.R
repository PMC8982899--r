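# Differential network comparison: baseline community structure on the
# untreated network, per-edge differential modularity of a treated network
# against it, and Louvain aggregation of the positive part into differential
# gene modules.

# Modularity machinery assumes non-negative weights; z-scored networks are
# shifted by a common constant before comparison (ordering-preserving).
shift_nonneg <- function(w, shift = NULL) {
  if (is.null(shift)) shift <- min(w)
  w - shift
}

grn_to_graph <- function(w) {
  # bipartite graph with prefixed node names so a TF that is also a target
  # gene cannot alias
  el <- which(w > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("tf:", rownames(w)[el[, 1]]),
               to = paste0("gene:", colnames(w)[el[, 2]]),
               weight = w[el]),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("tf:", rownames(w)),
                                   paste0("gene:", colnames(w))))
  )
  g
}

#' Community structure of the untreated (baseline) network
#'
#' Weighted Louvain modularity maximization on the bipartite TF-gene graph.
#' Negative z-score weights are shifted by subtracting the matrix minimum
#' (or a supplied `shift`, so that treated/control comparisons use one common
#' shift) before community detection.
#'
#' @param grn An `omu_grn` object (the untreated condition).
#' @param seed Integer RNG seed making Louvain aggregation reproducible
#'   (default 1).
#' @param shift Optional pre-computed shift constant (a minimum weight); by
#'   default the network's own minimum.
#' @return Tibble with columns `node` (prefixed `tf:`/`gene:`), `type`,
#'   `community` (contiguous integers from 0, largest community first) and a
#'   `modularity` attribute.
#' @export
baseline_partition <- function(grn, seed = 1, shift = NULL) {
  w <- shift_nonneg(grn$weights, shift)
  if (length(w) == 0 || all(w == 0)) stop_omu("empty network")
  g <- grn_to_graph(w)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  part <- tibble(node = names(memb), community = as.integer(memb))
  # canonicalize community ids: size descending, ties by smallest node id
  ord <- part |>
    group_by(.data$community) |>
    summarise(sz = n(), first = min(.data$node), .groups = "drop") |>
    arrange(desc(.data$sz), .data$first)
  remap <- setNames(seq_len(nrow(ord)) - 1L, ord$community)
  part$community <- unname(remap[as.character(part$community)])
  part$type <- ifelse(startsWith(part$node, "tf:"), "tf", "gene")
  part <- arrange(part[, c("node", "type", "community")], .data$community, .data$node)
  attr(part, "modularity") <- igraph::modularity(g, memb + 1,
                                                 weights = igraph::E(g)$weight)
  part
}

# save/restore global RNG state so seeded internals do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Differential modularity matrix of a treated vs control network
#'
#' The baseline partition is treated as a stochastic-block null for change:
#' for the TF-gene pairs in each community-pair block (TFs of baseline
#' community Ci against genes of community Cj), the expected treated weight
#' is the control weight pattern rescaled to the treated block total:
#' `e(tf, g) = w_c(tf, g) + e_conf(tf, g) * (rho - 1)`, where
#' `e_conf = s_c(tf | Ci x Cj) d_c(g | Ci x Cj) / W_c(Ci x Cj)` is the
#' control's block-restricted bipartite configuration expectation and
#' `rho = W_t(Ci x Cj) / W_c(Ci x Cj)` the block's overall weight change.
#' The differential modularity is the observed excess over that
#' expectation, floored at zero:
#' `D = max(0, w_t - w_c - e_conf * (rho - 1))`, i.e. the edge-level change
#' beyond a uniform rescaling of its baseline community-pair block — both
#' redistribution inside a baseline community and coherent rewiring between
#' communities score. An identical treated and control network gives D = 0
#' everywhere, and scaling both networks by a constant scales D by that
#' constant.
#'
#' @param treated,control `omu_grn` objects over identical node sets.
#' @param base Baseline partition of the control network
#'   ([baseline_partition()]), computed with the joint shift.
#' @return Non-negative TF x gene matrix `D`.
#' @export
differential_modularity_matrix <- function(treated, control, base,
                                           shift = NULL) {
  if (!identical(treated$tf_ids, control$tf_ids) ||
      !identical(treated$gene_ids, control$gene_ids)) {
    dtf <- c(setdiff(treated$tf_ids, control$tf_ids),
             setdiff(control$tf_ids, treated$tf_ids))
    dg <- c(setdiff(treated$gene_ids, control$gene_ids),
            setdiff(control$gene_ids, treated$gene_ids))
    stop_omu(paste0("node sets differ between treated and control: ",
                    paste(unique(c(dtf, dg)), collapse = ", ")))
  }
  if (is.null(shift)) shift <- min(min(treated$weights), min(control$weights))
  wt <- shift_nonneg(treated$weights, shift)
  wc <- shift_nonneg(control$weights, shift)

  comm <- setNames(base$community, base$node)
  ctf <- comm[paste0("tf:", treated$tf_ids)]
  cg <- comm[paste0("gene:", treated$gene_ids)]
  if (anyNA(ctf) || anyNA(cg))
    stop_omu("baseline partition does not cover all treated/control nodes")

  D <- matrix(0, nrow(wt), ncol(wt), dimnames = dimnames(wt))
  for (Ci in unique(ctf)) {
    ti <- which(ctf == Ci)
    for (Cj in unique(cg)) {
      gi <- which(cg == Cj)
      if (length(ti) == 0 || length(gi) == 0) next
      wtb <- wt[ti, gi, drop = FALSE]
      wcb <- wc[ti, gi, drop = FALSE]
      Wc <- sum(wcb)
      if (Wc == 0) {
        e_scale <- wcb * 0
      } else {
        rho <- sum(wtb) / Wc
        e_scale <- outer(rowSums(wcb), colSums(wcb)) / Wc * (rho - 1)
      }
      D[ti, gi] <- pmax(0, wtb - wcb - e_scale)
    }
  }
  D
}

#' Extract differential gene modules from a differential modularity matrix
#'
#' Louvain aggregation on the graph whose edge weights are the positive
#' entries of `D`; a module keeps the edges whose two endpoints share a
#' community (so modules of one sample are edge-disjoint) and is retained
#' when it has at least `min_edges` edges. Per-edge scores are the `D`
#' entries; the module weight is their sum.
#'
#' @param D Non-negative TF x gene matrix from
#'   [differential_modularity_matrix()].
#' @param sample_id Drug/sample label attached to every module.
#' @param seed Integer Louvain seed (default 1).
#' @param min_edges Minimum edges for a module to be kept (default 2).
#' @return Tibble of module edges: columns `sample`, `module` (integers from
#'   1 by descending module weight), `tf`, `gene`, `score`. Zero rows when
#'   `D` is all zero (treated identical to control).
#' @export
extract_differential_modules <- function(D, sample_id, seed = 1,
                                         min_edges = 2) {
  stopifnot(all(D >= 0))
  empty <- tibble(sample = character(), module = integer(),
                  tf = character(), gene = character(), score = double())
  if (all(D == 0)) return(empty)
  g <- grn_to_graph(D)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  el <- which(D > 0, arr.ind = TRUE)
  edges <- tibble(tf = rownames(D)[el[, 1]], gene = colnames(D)[el[, 2]],
                  score = D[el])
  ctf <- memb[paste0("tf:", edges$tf)]
  cg <- memb[paste0("gene:", edges$gene)]
  edges <- edges[!is.na(ctf) & !is.na(cg) & ctf == cg, , drop = FALSE]
  edges$comm <- ctf[!is.na(ctf) & !is.na(cg) & ctf == cg]
  if (nrow(edges) == 0) return(empty)
  keep <- edges |>
    group_by(.data$comm) |>
    summarise(n_edges = n(), weight = sum(.data$score), .groups = "drop") |>
    filter(.data$n_edges >= min_edges) |>
    arrange(desc(.data$weight), .data$comm)
  if (nrow(keep) == 0) return(empty)
  keep$module <- seq_len(nrow(keep))
  edges |>
    semi_join(keep, by = "comm") |>
    left_join(keep[, c("comm", "module")], by = "comm") |>
    mutate(sample = sample_id) |>
    arrange(.data$module, .data$tf, .data$gene) |>
    select("sample", "module", "tf", "gene", "score")
}

#' Compare a treated network with the control and extract modules
#'
#' Convenience wrapper: computes the joint weight shift, the baseline
#' partition of the control, the differential modularity matrix and the
#' differential modules in one call.
#'
#' @inheritParams differential_modularity_matrix
#' @inheritParams extract_differential_modules
#' @param sample_id Label for the treated sample (defaults to the treated
#'   network's condition).
#' @param base Optional pre-computed baseline partition (reused across many
#'   treated-vs-control comparisons that share a control and shift).
#' @param shift Optional common weight shift (e.g. the global minimum across
#'   a whole study's networks).
#' @return Module edge tibble as from [extract_differential_modules()].
#' @export
differential_modules <- function(treated, control, sample_id = treated$condition,
                                 seed = 1, min_edges = 2, base = NULL,
                                 shift = NULL) {
  if (is.null(shift)) shift <- min(min(treated$weights), min(control$weights))
  if (is.null(base)) base <- baseline_partition(control, seed = seed, shift = shift)
  D <- differential_modularity_matrix(treated, control, base, shift = shift)
  extract_differential_modules(D, sample_id, seed = seed, min_edges = min_edges)
}

#' Summarize module weights
#'
#' @param modules Module edge tibble.
#' @return Tibble with one row per (sample, module): `n_edges`, `weight`
#'   (sum of per-edge differential-modularity scores).
#' @export
module_weights <- function(modules) {
  modules |>
    group_by(.data$sample, .data$module) |>
    summarise(n_edges = n(), weight = sum(.data$score), .groups = "drop")
}
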