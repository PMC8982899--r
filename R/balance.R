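# Compositional analysis of OMU vectors: hierarchical clustering of OMUs by
# mean GRmax defines a balance tree; the isometric log-ratio (ILR) at an
# internal node contrasts the geometric means of the left (lower mean
# GRmax) and right (higher mean GRmax) subtree components; the node whose
# balances correlate best with GRmax anchors the linear model.

#' Hierarchical clustering of OMUs by mean GRmax
#'
#' Average-linkage clustering on the absolute difference of mean GRmax.
#' OMUs are pre-sorted by (mean GRmax, id) so the tree is invariant to the
#' input order; at every internal node the left subtree is the one with the
#' lower centroid mean GRmax.
#'
#' @param system An `omu_system` with mean GRmax assigned.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default "average").
#' @return An object of class `balance_tree`: tibble of internal nodes with
#'   columns `node` (id, root = "N1"), `depth` (root = 0), `centroid`
#'   (mean of member OMU mean GRmax), `left`/`right` (list-columns of OMU
#'   ids), `centroid_left`, `centroid_right`.
#' @export
cluster_omus <- function(system, linkage = "average") {
  om <- system$omus
  if (nrow(om) < 2) stop_omu("need >= 2 OMUs to build a balance tree")
  if (anyNA(om$mean_grmax)) stop_omu("assign mean GRmax before clustering")
  om <- arrange(om, .data$mean_grmax, .data$omu)
  hc <- hclust(dist(om$mean_grmax), method = linkage)

  n <- nrow(om)
  leaf_sets <- vector("list", nrow(hc$merge))
  get_set <- function(k) {
    if (k < 0) om$omu[-k] else leaf_sets[[k]]
  }
  nodes <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- get_set(hc$merge[i, 1]); b <- get_set(hc$merge[i, 2])
    leaf_sets[[i]] <- c(a, b)
    ca <- mean(om$mean_grmax[match(a, om$omu)])
    cb <- mean(om$mean_grmax[match(b, om$omu)])
    if (ca <= cb) {
      nodes[[i]] <- list(left = sort(a), right = sort(b),
                         centroid_left = ca, centroid_right = cb)
    } else {
      nodes[[i]] <- list(left = sort(b), right = sort(a),
                         centroid_left = cb, centroid_right = ca)
    }
  }
  # depth: root is the last merge; the immediate parent of node i is its
  # smallest strict superset among later merges
  m <- nrow(hc$merge)
  depth <- rep(NA_integer_, m)
  depth[m] <- 0L
  if (m >= 2) {
    for (i in (m - 1):1) {
      js <- seq(i + 1, m)
      containing <- js[vapply(js, function(j)
        all(leaf_sets[[i]] %in% leaf_sets[[j]]), logical(1))]
      parent <- containing[which.min(lengths(leaf_sets[containing]))]
      depth[i] <- depth[parent] + 1L
    }
  }
  out <- tibble(
    node = paste0("N", rev(seq_len(m))),  # N1 = root
    depth = rev(depth),
    centroid = rev(vapply(leaf_sets, function(s)
      mean(om$mean_grmax[match(s, om$omu)]), numeric(1))),
    left = rev(map(nodes, "left")),
    right = rev(map(nodes, "right")),
    centroid_left = rev(map_dbl(nodes, "centroid_left")),
    centroid_right = rev(map_dbl(nodes, "centroid_right"))
  )
  class(out) <- c("balance_tree", class(out))
  out
}

#' Isometric log-ratio balance of an OMU vector at a tree node
#'
#' `b = sqrt(nL * nR / (nL + nR)) * ln(g(iL) / g(iR))` where the geometric
#' means g are taken over the positive components of the vector on each
#' side and nL, nR count those positive components. If either side has no
#' positive component the balance is undefined and `NA` is returned
#' (callers treat it as an explicit sentinel, never silent). Alternatively a
#' positive `pseudocount` is added to every component, in which case all
#' components count and absent OMUs contribute through the zero-replacement
#' value. The vector is converted to proportions (sum 1) first: for
#' positive-part balances this is cosmetic (the log-ratio is scale free);
#' for pseudocount balances it fixes the scale on which epsilon is meant.
#'
#' @param v One sample's OMU vector as a named numeric vector (names = OMU
#'   ids) or a long tibble (`omu`, `value`).
#' @param node One row of a `balance_tree` (or a list with `left`/`right`
#'   OMU id character vectors).
#' @param pseudocount Optional epsilon added to every component (default
#'   `NULL`, i.e. positive-part geometric means).
#' @return The balance, or `NA_real_` when undefined.
#' @export
ilr_balance <- function(v, node, pseudocount = NULL) {
  if (is.data.frame(v)) v <- setNames(v$value, v$omu)
  if (sum(v) > 0) v <- v / sum(v)
  left <- unlist(node$left); right <- unlist(node$right)
  vl <- v[left][!is.na(v[left])]
  vr <- v[right][!is.na(v[right])]
  if (!is.null(pseudocount)) {
    vl <- vl + pseudocount
    vr <- vr + pseudocount
  }
  vl <- vl[vl > 0]; vr <- vr[vr > 0]
  nl <- length(vl); nr <- length(vr)
  if (nl == 0 || nr == 0) return(NA_real_)
  gl <- exp(mean(log(vl))); gr <- exp(mean(log(vr)))
  sqrt(nl * nr / (nl + nr)) * log(gl / gr)
}

#' Balances of many samples at one node
#' @param vectors Long OMU-vector tibble (`sample`, `omu`, `value`).
#' @param node A `balance_tree` row.
#' @param pseudocount See [ilr_balance()].
#' @return Tibble (`sample`, `ilr`), `NA` where undefined.
#' @export
ilr_balances <- function(vectors, node, pseudocount = NULL) {
  vectors |>
    group_by(.data$sample) |>
    summarise(ilr = ilr_balance(setNames(.data$value, .data$omu), node,
                                pseudocount),
              .groups = "drop")
}

#' Select the balance point best correlated with GRmax
#'
#' Candidate nodes are internal nodes whose centroid mean GRmax lies within
#' `bounds` (default \[-0.5, 0.5\]) and where at least `min_fraction`
#' (default 0.9) of samples have a defined balance. Among candidates the
#' node maximizing |Pearson r| between per-sample balances and GRmax wins;
#' ties go to the deeper node, then the smaller node id. Samples with an
#' undefined balance at the chosen node are excluded (reported in the
#' result). With `use_root = TRUE` the search is skipped and the root node
#' (all OMUs) is used.
#'
#' @param tree A `balance_tree`.
#' @param vectors Long OMU-vector tibble for all samples.
#' @param gr GR table (`drug`, `grmax`).
#' @param bounds Centroid window for candidate nodes (default c(-0.5, 0.5)).
#' @param min_fraction Minimum fraction of samples with defined balance
#'   (default 0.9).
#' @param pseudocount See [ilr_balance()].
#' @param use_root Use the root node instead of searching (default FALSE).
#' @return List with `node` (the chosen tree row), `ilrs` (tibble `sample`,
#'   `ilr`, `grmax`, defined samples only), `pearson_r`, `excluded`
#'   (sample ids with undefined balance).
#' @export
select_balance_point <- function(tree, vectors, gr, bounds = c(-0.5, 0.5),
                                 min_fraction = 0.9, pseudocount = NULL,
                                 use_root = FALSE) {
  gr <- validate_gr_table(gr)
  samples <- unique(vectors$sample)
  if (length(samples) < 3) stop_omu("need >= 3 samples to select a balance point")
  cand <- if (use_root) {
    tree[tree$depth == 0, , drop = FALSE]
  } else {
    tree[tree$centroid >= bounds[1] & tree$centroid <= bounds[2], , drop = FALSE]
  }
  if (nrow(cand) == 0)
    stop_omu("no candidate balance node within the centroid bounds; widen `bounds` or lower `min_similarity`")
  evals <- map(seq_len(nrow(cand)), function(i) {
    node <- cand[i, ]
    b <- ilr_balances(vectors, node, pseudocount)
    b <- left_join(b, gr, by = c(sample = "drug"))
    def <- !is.na(b$ilr)
    frac <- mean(def)
    r <- if (sum(def) >= 3 && sd(b$ilr[def]) > 0 && sd(b$grmax[def]) > 0)
      cor(b$ilr[def], b$grmax[def]) else NA_real_
    list(node = node, balances = b, frac = frac, r = r)
  })
  ok <- map_lgl(evals, function(e) e$frac >= min_fraction && !is.na(e$r))
  if (!any(ok))
    stop_omu("no candidate node with enough defined balances; try a pseudocount or lower min_fraction")
  evals <- evals[ok]
  score <- map_dbl(evals, function(e) abs(e$r))
  depth <- map_dbl(evals, function(e) e$node$depth)
  ids <- map_dbl(evals, function(e) as.numeric(sub("^N", "", e$node$node)))
  best <- order(-score, -depth, ids)[1]
  e <- evals[[best]]
  def <- !is.na(e$balances$ilr)
  list(node = e$node,
       ilrs = e$balances[def, , drop = FALSE],
       pearson_r = e$r,
       excluded = e$balances$sample[!def])
}

#' Fit the ILR-to-GRmax linear model
#'
#' Ordinary least squares of GRmax on the per-sample balance at the chosen
#' node (the same regression `lm(grmax ~ ilr)` would produce).
#'
#' @param ilrs Tibble with columns `sample`, `ilr`, `grmax` (e.g. from
#'   [select_balance_point()]).
#' @param node Optional chosen balance node (stored on the fit).
#' @return Object of class `omu_balance_fit`: `slope`, `intercept`,
#'   `pearson_r`, `r_squared`, `node`, `data`.
#' @export
fit_linear_model <- function(ilrs, node = NULL) {
  stopifnot(all(c("ilr", "grmax") %in% colnames(ilrs)))
  if (nrow(ilrs) < 3) stop_omu("need >= 3 paired observations")
  if (sd(ilrs$ilr) == 0) stop_omu("zero variance in ILR; cannot fit")
  fit <- lm(grmax ~ ilr, data = ilrs)
  r <- cor(ilrs$ilr, ilrs$grmax)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = r,
                 r_squared = r^2,
                 node = if (is.null(node)) NA_character_ else node$node,
                 data = as_tibble(ilrs)),
            class = "omu_balance_fit")
}

#' Select the balance point and fit the model in one step
#' @inheritParams select_balance_point
#' @return An `omu_balance_fit` with the selection's exclusions attached as
#'   attribute `excluded`.
#' @export
fit_balance_model <- function(tree, vectors, gr, bounds = c(-0.5, 0.5),
                              min_fraction = 0.9, pseudocount = NULL,
                              use_root = FALSE) {
  sel <- select_balance_point(tree, vectors, gr, bounds, min_fraction,
                              pseudocount, use_root)
  fit <- fit_linear_model(sel$ilrs, sel$node)
  attr(fit, "excluded") <- sel$excluded
  attr(fit, "node_row") <- sel$node
  fit
}

#' @export
print.omu_balance_fit <- function(x, ...) {
  cat(sprintf("<omu_balance_fit> node %s: GRmax = %.4f %+.4f * ILR (r = %.3f, R^2 = %.3f, n = %d)\n",
              x$node, x$intercept, x$slope, x$pearson_r, x$r_squared,
              nrow(x$data)))
  invisible(x)
}

#' Tidy the balance-model coefficients
#' @param x An `omu_balance_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.omu_balance_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "ilr"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of the balance model
#' @param x An `omu_balance_fit`.
#' @param ... Unused.
#' @return Tibble with `node`, `pearson_r`, `r.squared`, `nobs`.
#' @export
glance.omu_balance_fit <- function(x, ...) {
  tibble(node = x$node, pearson_r = x$pearson_r, r.squared = x$r_squared,
         nobs = nrow(x$data))
}

#' Plot the ILR-GRmax regression
#' @param object An `omu_balance_fit`.
#' @param ... Unused.
#' @return A ggplot: per-drug balance vs GRmax with the fitted line.
#' @export
autoplot.omu_balance_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ilr, y = .data$grmax)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = sprintf("ILR balance at %s", object$node),
                  y = "GRmax",
                  title = sprintf("r = %.3f, R² = %.3f",
                                  object$pearson_r, object$r_squared)) +
    ggplot2::theme_minimal()
}
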