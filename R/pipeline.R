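# End-to-end orchestration: networks -> differential modules -> OMU system
# -> balance model -> combination ranking (-> optional ZIP validation and
# enrichment), with a manifest recording every stage.

checksum_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full prioritization pipeline on a study
#'
#' Stages: (a) per-condition network inference, (b) differential modules per
#' drug against the control, (c) OMU system construction with mean GRmax,
#' (d) drug OMU vectors, (e) balance tree and ILR-GRmax linear model,
#' (f)-(h) combined vectors, GIS and DGIS for all pairs, (i) ranking.
#' When the study carries planted synergy pairs (or `zip_pairs` is given),
#' dose-response matrices are generated and ZIP-scored, and the enrichment
#' statistic of the top-k list versus a random sample is reported.
#'
#' @param study An `omu_study` from [simulate_study()], or a list with the
#'   same fields read from files (`expression`, `prior`, `ppi`, `gr`, and a
#'   `config` holding at least `seed`).
#' @param min_similarity OMU Jaccard threshold (default 0.25).
#' @param min_edges Minimum module size in edges (default 2).
#' @param top_k Size of the candidate list (default 30, capped at the number
#'   of pairs).
#' @param bounds Balance-point centroid window (default c(-0.5, 0.5)).
#' @param min_fraction Minimum fraction of drugs with defined balance at a
#'   candidate node (default 0.9).
#' @param combine Combination rule, `"max"` (default) or `"sum"`.
#' @param vector_weights OMU vector weighting, `"module"` (default) or
#'   `"structure"`; see [omu_vector()].
#' @param pseudocount Zero-replacement value on the proportion scale used
#'   for every balance in the pipeline (default 1e-4); `NULL` switches to
#'   positive-part balances, where a drug without weight on both sides of a
#'   node is undefined there. See [ilr_balance()].
#' @param use_root Use the root balance point instead of searching.
#' @param zip_threshold ZIP synergy call threshold (default 5).
#' @param run_zip Whether to generate and score dose-response matrices for
#'   the top-k and a random 10 percent sample (default: TRUE when the study
#'   has planted synergy pairs).
#' @param seed Seed for the seeded stages (baseline partition, Louvain,
#'   random validation draw); defaults to the study seed.
#' @return Object of class `omu_run`: list with `grns`, `modules`, `system`,
#'   `vectors`, `tree`, `model`, `scores`, `ranking`, optional `zip`,
#'   `enrichment`, and `manifest` (stage, n_out, seconds, checksum).
#' @export
run_pipeline <- function(study, min_similarity = 0.25, min_edges = 2,
                         top_k = 30, bounds = c(-0.5, 0.5),
                         min_fraction = 0.9, combine = "max",
                         vector_weights = "module",
                         pseudocount = 1e-4, use_root = FALSE,
                         zip_threshold = 5, run_zip = NULL,
                         seed = study$config$seed) {
  t0 <- Sys.time()
  manifest <- list()
  log_stage <- function(stage, obj, t_start) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage,
      n_out = if (is.data.frame(obj)) nrow(obj) else length(obj),
      seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
      checksum = checksum_obj(obj))
  }

  expr <- study$expression
  drugs <- setdiff(colnames(expr), "control")
  if (!"control" %in% colnames(expr))
    stop_omu("stage (a) networks: expression matrix must contain a 'control' column")
  if (is.null(study$gr))
    stop_omu("stage (c) OMU system: GR table is missing")

  # (a) per-condition networks; pooled co-expression shared across
  # conditions, condition-specific deviation term per drug
  ts <- Sys.time()
  coexpr <- compute_coexpression(expr)
  grns <- list(control = infer_grn(study$prior, study$ppi, coexpr,
                                   condition = "control"))
  for (d in drugs) {
    grns[[d]] <- infer_grn(study$prior, study$ppi, coexpr, condition = d,
                           condition_profile = expr[, d] - expr[, "control"])
  }
  log_stage("a_networks", grns, ts)

  # (b) differential modules per drug, one baseline partition and one
  # common weight shift across the whole study
  ts <- Sys.time()
  shift <- min(map_dbl(grns, function(g) min(g$weights)))
  base <- baseline_partition(grns$control, seed = seed, shift = shift)
  modules <- map(drugs, function(d)
    differential_modules(grns[[d]], grns$control, sample_id = d, seed = seed,
                         min_edges = min_edges, base = base, shift = shift)) |>
    list_rbind()
  if (nrow(modules) == 0)
    stop_omu("stage (b) differential modules: no drug produced any module")
  log_stage("b_differential_modules", modules, ts)

  # (c) OMU system with mean GRmax
  ts <- Sys.time()
  system <- build_omu_system(modules, min_similarity = min_similarity)
  system <- assign_mean_grmax(system, study$gr, modules)
  log_stage("c_omu_system", system, ts)

  # (d) drug OMU vectors
  ts <- Sys.time()
  vectors <- omu_vectors(modules, system, weights = vector_weights)
  log_stage("d_omu_vectors", vectors, ts)

  # (e) balance tree and linear model
  ts <- Sys.time()
  tree <- cluster_omus(system)
  model <- fit_balance_model(tree, vectors, study$gr, bounds = bounds,
                             min_fraction = min_fraction,
                             pseudocount = pseudocount, use_root = use_root)
  log_stage("e_balance_model", glance(model), ts)

  # (f)-(h) combined vectors, GIS, DGIS
  ts <- Sys.time()
  scores <- score_combinations(vectors, model, attr(model, "node_row"),
                               combine = combine, pseudocount = pseudocount)
  log_stage("f_h_combination_scores", scores, ts)

  # (i) ranking
  ts <- Sys.time()
  top_k_eff <- min(top_k, sum(scores$scorable))
  ranking <- rank_pairs(scores, top_k = top_k_eff)
  log_stage("i_ranking", ranking, ts)

  out <- list(grns = grns, modules = modules, system = system,
              vectors = vectors, tree = tree, model = model,
              scores = scores, ranking = ranking)

  if (is.null(run_zip))
    run_zip <- !is.null(study$config$synergy_pairs) &&
      nrow(study$config$synergy_pairs) > 0
  if (run_zip) {
    ts <- Sys.time()
    top_pairs <- ranking |> filter(.data$top) |>
      select("drug_1", "drug_2")
    n_rand <- validation_sample_size(nrow(scores))
    old <- .Random.seed_save(); set.seed(seed + 7L)
    rand_pairs <- scores[sample(nrow(scores), min(n_rand, nrow(scores))), ] |>
      select("drug_1", "drug_2")
    .Random.seed_restore(old)
    all_pairs <- distinct(bind_rows(top_pairs, rand_pairs))
    dr <- generate_dose_response(study$config, study$gr, pairs = all_pairs)
    zips <- map(dr$matrices, function(mm)
      tidy(zip_synergy(mm, threshold = zip_threshold))) |> list_rbind()
    top_z <- semi_join(zips, top_pairs, by = c("drug_1", "drug_2"))
    rand_z <- semi_join(zips, rand_pairs, by = c("drug_1", "drug_2"))
    enrichment <- joint_binomial_mle(
      k1 = sum(top_z$synergy), s1 = nrow(top_z),
      k2 = sum(rand_z$synergy), s2 = nrow(rand_z),
      finite_population = nrow(scores))
    out$zip <- zips
    out$enrichment <- enrichment
    r <- left_join(as_tibble(out$ranking), zips,
                   by = c("drug_1", "drug_2")) |>
      select(-"synergy")
    class(r) <- c("omu_ranking", class(r))
    out$ranking <- r
    log_stage("zip_validation", zips, ts)
  }

  out$manifest <- list_rbind(manifest) |>
    mutate(total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(out) <- "omu_run"
  out
}

#' @export
print.omu_run <- function(x, ...) {
  cat(sprintf("<omu_run> %d drugs, %d OMUs, model %s (r = %.3f); %d ranked pairs\n",
              length(x$grns) - 1, nrow(x$system$omus), x$model$node,
              x$model$pearson_r, nrow(x$ranking)))
  print(x$manifest[, c("stage", "n_out", "seconds")])
  invisible(x)
}
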