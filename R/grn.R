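#' Gene-gene co-expression similarity
#'
#' Pearson correlation across samples; the expression component of network
#' inference. Zero-variance genes get correlation 0 against everything (with
#' a warning) and 1 on the diagonal.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @return Symmetric genes x genes matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @export
compute_coexpression <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2)
    stop_omu("co-expression needs >= 2 samples")
  v <- apply(expr, 1, sd)
  cc <- suppressWarnings(cor(t(expr)))
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance gene(s); their correlations set to 0",
                    sum(v == 0)))
    cc[v == 0, ] <- 0
    cc[, v == 0] <- 0
  }
  diag(cc) <- 1
  cc[is.na(cc)] <- 0
  cc
}

# Row+column z-score normalization used on each input network before message
# passing; keeps the three data types on a comparable scale.
normalize_network <- function(x) {
  mu_r <- rowMeans(x); sd_r <- apply(x, 1, sd)
  mu_c <- colMeans(x); sd_c <- apply(x, 2, sd)
  sd_r[sd_r == 0] <- 1; sd_c[sd_c == 0] <- 1
  zr <- sweep(sweep(x, 1, mu_r, "-"), 1, sd_r, "/")
  zc <- sweep(sweep(x, 2, mu_c, "-"), 2, sd_c, "/")
  (zr + zc) / sqrt(2)
}

# Continuous Tanimoto similarity between the rows of A and columns of B:
# T_ij = (AB)_ij / sqrt(|A_i.|^2 + |B_.j|^2 - |(AB)_ij|)
tanimoto <- function(A, B) {
  ab <- A %*% B
  den <- sqrt(outer(rowSums(A^2), colSums(B^2), "+") - abs(ab))
  den[den == 0] <- 1
  ab / den
}

# Annealing stabilizer for the square similarity updates: the diagonal is
# re-inflated to (off-diagonal row sd) * n * exp(2 * alpha * iter). The
# growing self-similarity progressively damps the Tanimoto messages, so the
# iteration settles on a graded fixed point instead of a saturated one.
inflate_diagonal <- function(m, alpha, iter) {
  n <- nrow(m)
  d <- diag(m)
  # row sd excluding the diagonal, vectorized
  rs <- rowSums(m) - d
  rs2 <- rowSums(m^2) - d^2
  mu <- rs / (n - 1)
  s <- sqrt(pmax(0, (rs2 - (n - 1) * mu^2) / (n - 2)))
  s[!is.finite(s) | s == 0] <- 1
  diag(m) <- s * n * exp(2 * alpha * iter)
  m
}

#' Infer a weighted bipartite TF-to-gene regulatory network
#'
#' Message passing integrates three data sources: a (0/1 or confidence)
#' regulatory prior, TF-TF protein interactions, and gene-gene co-expression.
#' At each iteration a responsibility term (do interacting TFs agree on the
#' target?) and an availability term (do co-expressed genes share the
#' regulator?) are blended into the current network with update step
#' `alpha = 0.1`; the PPI and co-expression matrices are nudged toward the
#' network's implied TF-TF and gene-gene similarity at the same rate.
#' Convergence is declared when the mean absolute change of the weight
#' matrix drops below `tol` (default 1e-3), within `max_iter` (default 200)
#' iterations; otherwise the last iterate is returned with a warning flag.
#' Only TFs and genes present in all three sources are retained (intersection
#' behavior). The final matrix is z-scaled over all entries. Deterministic:
#' no randomness is involved.
#'
#' @param prior Edge-list tibble (`source` TF, `target` gene, `weight`).
#' @param ppi Symmetric TF-TF edge-list tibble.
#' @param coexpr Gene-gene similarity matrix from [compute_coexpression()].
#' @param condition Label stored on the result (e.g. drug id or "control").
#' @param condition_profile Optional named numeric vector of per-gene
#'   deviations for this condition (treated minus control expression). When
#'   supplied, its normalized outer product is added to the shared
#'   co-expression so single-profile conditions still yield
#'   condition-specific networks; weight set by `condition_weight`.
#' @param condition_weight Scale of the condition-specific co-expression
#'   term (default 1).
#' @param alpha Update step (default 0.1).
#' @param tol Convergence tolerance on mean absolute change (default 1e-3).
#' @param max_iter Iteration cap (default 200).
#' @return An object of class `omu_grn`: list with `weights` (TF x gene
#'   z-scored matrix), `tf_ids`, `gene_ids`, `condition`, `converged`,
#'   `iterations`.
#' @export
infer_grn <- function(prior, ppi, coexpr, condition = "condition",
                      condition_profile = NULL, condition_weight = 1,
                      alpha = 0.1, tol = 1e-3, max_iter = 200) {
  tfs <- sort(intersect(unique(prior$source), unique(c(ppi$source, ppi$target))))
  genes <- sort(intersect(unique(prior$target), rownames(coexpr)))
  if (length(tfs) == 0 || length(genes) == 0)
    stop_omu("no overlap between prior, PPI and expression ids after intersection")

  W0 <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  keep <- prior$source %in% tfs & prior$target %in% genes
  W0[cbind(prior$source[keep], prior$target[keep])] <- prior$weight[keep]

  P <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  kp <- ppi$source %in% tfs & ppi$target %in% tfs
  P[cbind(ppi$source[kp], ppi$target[kp])] <- ppi$weight[kp]
  P <- (P + t(P)) / 2
  diag(P) <- 1

  C <- coexpr[genes, genes, drop = FALSE]
  if (!is.null(condition_profile)) {
    u <- condition_profile[genes]
    u[is.na(u)] <- 0
    nu <- sqrt(sum(u^2))
    if (nu > 0) {
      u <- u / nu
      C <- C + condition_weight * tcrossprod(u) * length(u)
      C <- (C + t(C)) / 2
    }
  }

  W <- normalize_network(W0)
  P <- normalize_network(P); P <- (P + t(P)) / 2
  C <- normalize_network(C); C <- (C + t(C)) / 2

  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    resp <- tanimoto(P, W)
    avail <- tanimoto(W, C)
    W_new <- (resp + avail) / 2
    # mean absolute change between the weight matrix and its proposal
    delta <- mean(abs(W - W_new))
    W <- (1 - alpha) * W + alpha * W_new
    P_new <- tanimoto(W, t(W))
    P_new <- inflate_diagonal((P_new + t(P_new)) / 2, alpha, it)
    P <- (1 - alpha) * P + alpha * P_new
    C_new <- tanimoto(t(W), W)
    C_new <- inflate_diagonal((C_new + t(C_new)) / 2, alpha, it)
    C <- (1 - alpha) * C + alpha * C_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("network inference for '%s' did not converge in %d iterations",
                    condition, max_iter))
  # z-scale over all entries
  W <- (W - mean(W)) / sd(W)
  structure(list(weights = W, tf_ids = tfs, gene_ids = genes,
                 condition = condition, converged = converged,
                 iterations = it),
            class = "omu_grn")
}

#' @export
print.omu_grn <- function(x, ...) {
  cat(sprintf("<omu_grn> condition '%s': %d TFs x %d genes (%d edges), %s after %d iterations\n",
              x$condition, length(x$tf_ids), length(x$gene_ids),
              length(x$weights), if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Tidy a weighted regulatory network into an edge tibble
#' @param x An `omu_grn` object.
#' @param ... Unused.
#' @return Tibble with columns `tf`, `gene`, `weight`, `condition`.
#' @export
tidy.omu_grn <- function(x, ...) {
  tibble(
    tf = rep(x$tf_ids, times = length(x$gene_ids)),
    gene = rep(x$gene_ids, each = length(x$tf_ids)),
    weight = as.vector(x$weights),
    condition = x$condition
  )
}

#' Write a weighted network as a TF x gene TSV matrix
#' @param grn An `omu_grn` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path) {
  df <- tibble::as_tibble(grn$weights, rownames = "tf")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
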