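# Operational Module Unit (OMU) system: similar differential modules from
# different drug samples are pooled into OMUs carrying a shared edge
# structure, a member list and a mean GRmax; each drug is then summarized as
# a sparse activity vector over the OMU compendium.

edge_key <- function(tf, gene) paste(tf, gene, sep = "\r")

module_edge_sets <- function(modules) {
  modules |>
    mutate(key = edge_key(.data$tf, .data$gene)) |>
    group_by(.data$sample, .data$module) |>
    summarise(edges = list(.data$key), weight = sum(.data$score),
              .groups = "drop")
}

#' Jaccard similarity between two differential modules
#'
#' Edge-set Jaccard index: `|A ∩ B| / (|A| + |B| - |A ∩ B|)`. An edge
#' matches only when both its TF and its gene are identical.
#'
#' @param a,b Module edge tibbles (columns `tf`, `gene`), e.g. one
#'   sample-module slice of the module table.
#' @return A number in \[0, 1\]; symmetric in its arguments.
#' @export
module_jaccard <- function(a, b) {
  ka <- unique(edge_key(a$tf, a$gene))
  kb <- unique(edge_key(b$tf, b$gene))
  if (length(ka) == 0 || length(kb) == 0)
    stop_omu("modules must be non-empty")
  inter <- length(intersect(ka, kb))
  inter / (length(ka) + length(kb) - inter)
}

jaccard_keys <- function(ka, kb) {
  inter <- length(intersect(ka, kb))
  inter / (length(ka) + length(kb) - inter)
}

#' Build the OMU system from all samples' differential modules
#'
#' Cross-sample module pairs are visited in descending Jaccard order (ties
#' by lexicographic pair id). For a pair with similarity at or above
#' `min_similarity`, the pair's shared edge set either extends an existing
#' OMU it overlaps (the OMU whose structure has the highest Jaccard with the
#' shared set, provided that Jaccard is itself at or above
#' `min_similarity`; the structure narrows to the intersection) or founds a
#' new OMU. Modules that never pair above the threshold become singleton
#' OMUs from their full edge set. A module may be a member of several OMUs.
#' The greedy order is total, so rebuilding from the same module inventory
#' is bit-identical.
#'
#' @param modules Module edge tibble for all samples (columns `sample`,
#'   `module`, `tf`, `gene`, `score`).
#' @param min_similarity Jaccard threshold (default 0.25).
#' @return An object of class `omu_system`: list with
#'   * `omus`: tibble (`omu`, `n_members`, `n_edges`, `mean_grmax` = NA until
#'     [assign_mean_grmax()]),
#'   * `structure`: tibble (`omu`, `tf`, `gene`),
#'   * `members`: tibble (`omu`, `sample`, `module`),
#'   * `params`: the similarity threshold.
#' @export
build_omu_system <- function(modules, min_similarity = 0.25) {
  ms <- module_edge_sets(modules) |>
    arrange(.data$sample, .data$module)
  if (nrow(ms) == 0) stop_omu("no modules supplied")
  # zero-padded module index so lexicographic pair-id tie-breaks follow
  # numeric module order
  mid <- sprintf("%s\r%06d", ms$sample, ms$module)
  sets <- setNames(ms$edges, mid)

  # cross-sample pairs with J >= threshold, descending J, ties by pair id
  pairs <- NULL
  n <- nrow(ms)
  if (n > 1) {
    idx <- utils::combn(n, 2)
    keep <- ms$sample[idx[1, ]] != ms$sample[idx[2, ]]
    idx <- idx[, keep, drop = FALSE]
    if (ncol(idx) > 0) {
      js <- vapply(seq_len(ncol(idx)), function(k)
        jaccard_keys(sets[[idx[1, k]]], sets[[idx[2, k]]]), numeric(1))
      pairs <- tibble(i = idx[1, ], j = idx[2, ], jac = js,
                      id1 = mid[idx[1, ]], id2 = mid[idx[2, ]]) |>
        filter(.data$jac >= min_similarity) |>
        arrange(desc(.data$jac), .data$id1, .data$id2)
    }
  }

  omu_structures <- list()
  omu_members <- list()
  paired <- character(0)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      shared <- intersect(sets[[pairs$i[r]]], sets[[pairs$j[r]]])
      mem <- c(pairs$id1[r], pairs$id2[r])
      paired <- union(paired, mem)
      best <- 0; best_k <- NA_integer_
      for (k in seq_along(omu_structures)) {
        jk <- jaccard_keys(omu_structures[[k]], shared)
        if (jk > best) { best <- jk; best_k <- k }
      }
      if (!is.na(best_k) && best >= min_similarity &&
          length(intersect(omu_structures[[best_k]], shared)) > 0) {
        omu_structures[[best_k]] <- intersect(omu_structures[[best_k]], shared)
        omu_members[[best_k]] <- union(omu_members[[best_k]], mem)
      } else {
        omu_structures[[length(omu_structures) + 1]] <- shared
        omu_members[[length(omu_members) + 1]] <- mem
      }
    }
  }
  # singleton OMUs for modules never paired
  for (m in setdiff(mid, paired)) {
    omu_structures[[length(omu_structures) + 1]] <- sets[[m]]
    omu_members[[length(omu_members) + 1]] <- m
  }

  omu_ids <- paste0("OMU", seq_along(omu_structures))
  split_mid <- function(x) {
    parts <- strsplit(x, "\r", fixed = TRUE)
    tibble(sample = vapply(parts, `[`, "", 1),
           module = as.integer(vapply(parts, `[`, "", 2)))
  }
  structure_tbl <- imap(omu_structures, function(keys, k) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    tibble(omu = omu_ids[k],
           tf = vapply(parts, `[`, "", 1),
           gene = vapply(parts, `[`, "", 2))
  }) |> list_rbind() |> arrange(.data$omu, .data$tf, .data$gene)
  members_tbl <- imap(omu_members, function(m, k)
    mutate(split_mid(sort(m)), omu = omu_ids[k])) |>
    list_rbind() |> select("omu", "sample", "module")

  omus <- members_tbl |>
    group_by(.data$omu) |>
    summarise(n_members = n(), .groups = "drop") |>
    left_join(structure_tbl |> group_by(.data$omu) |>
                summarise(n_edges = n(), .groups = "drop"), by = "omu") |>
    mutate(mean_grmax = NA_real_) |>
    arrange(match(.data$omu, omu_ids))

  structure(list(omus = omus, structure = structure_tbl,
                 members = members_tbl,
                 params = list(min_similarity = min_similarity)),
            class = "omu_system")
}

#' @export
print.omu_system <- function(x, ...) {
  cat(sprintf("<omu_system> %d OMUs from %d member modules (min similarity %.2f)\n",
              nrow(x$omus), nrow(x$members), x$params$min_similarity))
  invisible(x)
}

#' Assign each OMU its mean GRmax
#'
#' For an OMU with member modules i, the mean GRmax is
#' `sum_i GR_i * X_i / sum_i Y_i`, where `GR_i` is the GRmax of module i's
#' sample, `X_i` the module's weight (sum of its differential-modularity
#' edge scores) and `Y_i` the total module weight of that sample. Each
#' member thus contributes its sample's GRmax in proportion to the module's
#' share of the sample's differential signal, which keeps the result in
#' \[-1, 1\].
#'
#' @param system An `omu_system`.
#' @param gr GR table (columns `drug`, `grmax`) covering every member
#'   sample.
#' @param modules The module edge tibble the system was built from.
#' @return The system with `omus$mean_grmax` filled in.
#' @export
assign_mean_grmax <- function(system, gr, modules) {
  gr <- validate_gr_table(gr)
  mw <- module_weights(modules)
  totals <- mw |>
    group_by(.data$sample) |>
    summarise(y_tot = sum(.data$weight), .groups = "drop")
  missing <- setdiff(unique(system$members$sample), gr$drug)
  if (length(missing) > 0)
    stop_omu(paste0("no GRmax for sample(s): ", paste(missing, collapse = ", ")))
  contrib <- system$members |>
    left_join(mw, by = c("sample", "module")) |>
    left_join(totals, by = "sample") |>
    left_join(gr, by = c(sample = "drug")) |>
    group_by(.data$omu) |>
    summarise(mean_grmax = sum(.data$grmax * .data$weight) / sum(.data$y_tot),
              .groups = "drop")
  system$omus <- system$omus |>
    select(-"mean_grmax") |>
    left_join(contrib, by = "omu")
  system
}

#' Convert one sample's modules to its sparse OMU vector
#'
#' With `weights = "module"` (default) the component for OMU k is the full
#' weight (sum of differential-modularity scores over every edge) of this
#' sample's member modules there: one module contributes its whole weight
#' to every OMU it belongs to. With `weights = "structure"` the component
#' instead sums only the scores of the module edges lying inside OMU k's
#' structure, so a module contributes in proportion to the structure it
#' actually shares.
#'
#' @param sample_modules Module edge tibble of a single sample.
#' @param system An `omu_system` that was built including this sample.
#' @param weights `"module"` (default) or `"structure"`; see Details.
#' @return Tibble (`sample`, `omu`, `value`) with one row per OMU in system
#'   order; values are non-negative and at least one is positive.
#' @export
omu_vector <- function(sample_modules, system,
                       weights = c("module", "structure")) {
  weights <- match.arg(weights)
  if (nrow(sample_modules) == 0)
    stop_omu("sample has no differential modules; no OMU vector representable")
  sid <- unique(sample_modules$sample)
  stopifnot(length(sid) == 1)
  mem <- filter(system$members, .data$sample == sid)
  if (weights == "module") {
    mw <- module_weights(sample_modules)
    vals <- mem |>
      left_join(mw, by = c("sample", "module")) |>
      group_by(.data$omu) |>
      summarise(value = sum(.data$weight), .groups = "drop")
  } else {
    # scores of the module's edges restricted to each OMU's structure
    vals <- mem |>
      left_join(sample_modules, by = c("sample", "module"),
                relationship = "many-to-many") |>
      semi_join(system$structure, by = c("omu", "tf", "gene")) |>
      group_by(.data$omu) |>
      summarise(value = sum(.data$score), .groups = "drop")
  }
  out <- tibble(sample = sid, omu = system$omus$omu) |>
    left_join(vals, by = "omu") |>
    mutate(value = ifelse(is.na(.data$value), 0, .data$value))
  if (all(out$value == 0))
    stop_omu(sprintf("sample '%s' has no weight in any OMU", sid))
  out
}

#' OMU vectors for every sample in a module table
#' @param modules Module edge tibble for all samples.
#' @param system An `omu_system` built from those modules.
#' @inheritParams omu_vector
#' @return Long tibble (`sample`, `omu`, `value`).
#' @export
omu_vectors <- function(modules, system,
                        weights = c("module", "structure")) {
  weights <- match.arg(weights)
  modules |>
    group_by(.data$sample) |>
    dplyr::group_split() |>
    map(omu_vector, system = system, weights = weights) |>
    list_rbind()
}

#' Write OMU vectors as sparse TSV
#' @param vectors Long vector tibble from [omu_vectors()].
#' @param path Output TSV path; only non-zero components are written.
#' @return `path`, invisibly.
#' @export
write_omu_vectors <- function(vectors, path) {
  readr::write_tsv(filter(vectors, .data$value > 0), path, progress = FALSE)
  invisible(path)
}

#' Plot the OMU compendium by mean GRmax
#' @param object An `omu_system` with mean GRmax assigned.
#' @param ... Unused.
#' @return A ggplot: OMUs ordered by mean GRmax, point size = member count.
#' @export
autoplot.omu_system <- function(object, ...) {
  om <- arrange(object$omus, .data$mean_grmax)
  om$omu <- factor(om$omu, levels = om$omu)
  ggplot2::ggplot(om, ggplot2::aes(x = .data$omu, y = .data$mean_grmax,
                                   size = .data$n_members)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean GRmax", size = "members") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Heat map of all drug OMU vectors
#'
#' Drugs ordered by GRmax against OMUs ordered by mean GRmax, tile
#' brightness showing each drug's (log1p) OMU activity.
#'
#' @param vectors Long OMU-vector tibble.
#' @param system An `omu_system` with mean GRmax assigned.
#' @param gr GR table (`drug`, `grmax`).
#' @return A ggplot.
#' @export
plot_omu_vectors <- function(vectors, system, gr) {
  om <- arrange(system$omus, .data$mean_grmax)
  gr <- arrange(validate_gr_table(gr), .data$grmax)
  df <- vectors |>
    mutate(omu = factor(.data$omu, levels = om$omu),
           sample = factor(.data$sample, levels = gr$drug))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omu, y = .data$sample,
                                   fill = log1p(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "OMU (by mean GRmax)", y = "drug (by GRmax)",
                  fill = "log activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
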