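# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive transcriptions, kept independent of the package's
# implementation paths.

# exhaustive maximum-modularity partition of a small weighted graph
# (igraph::modularity scores each candidate; search is exhaustive)
oracle_best_partition <- function(g, weights) {
  n <- igraph::vcount(g)
  stopifnot(n <= 10)
  best_q <- -Inf
  best <- NULL
  # enumerate set partitions via restricted growth strings
  grow <- function(prefix, maxval) {
    if (length(prefix) == n) {
      q <- igraph::modularity(g, prefix + 1, weights = weights)
      if (q > best_q) {
        best_q <<- q
        best <<- prefix
      }
      return(invisible())
    }
    for (v in 0:(maxval + 1)) grow(c(prefix, v), max(maxval, v))
  }
  grow(integer(0), -1L)
  list(membership = best, modularity = best_q)
}

# ordinary least squares via the closed-form normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = sxy / sqrt(sxx * sum((y - mean(y))^2)))
}

# ILR balance by direct transcription of the formula
oracle_ilr <- function(v, left, right) {
  vl <- v[left]; vl <- vl[vl > 0]
  vr <- v[right]; vr <- vr[vr > 0]
  if (length(vl) == 0 || length(vr) == 0) return(NA_real_)
  gl <- prod(vl)^(1 / length(vl))
  gr <- prod(vr)^(1 / length(vr))
  sqrt(length(vl) * length(vr) / (length(vl) + length(vr))) * log(gl / gr)
}

# DGIS three-case rule, written out independently
oracle_dgis <- function(g12, g11, g22) {
  lo <- min(g11, g22); hi <- max(g11, g22)
  if (g12 < lo) return(g12 - lo)
  if (g12 > hi) return(g12 - hi)
  0
}

# independent transcription of the greedy OMU merge on a list of edge-key
# sets named "sample\rmodule" (zero-padded), for tiny inventories
oracle_omu_merge <- function(sets, samples, min_sim = 0.25) {
  jac <- function(a, b) {
    i <- length(intersect(a, b))
    i / (length(a) + length(b) - i)
  }
  n <- length(sets)
  pairs <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (samples[i] == samples[j]) next
      J <- jac(sets[[i]], sets[[j]])
      if (J >= min_sim)
        pairs <- rbind(pairs, data.frame(i = i, j = j, J = J,
                                         id1 = names(sets)[i],
                                         id2 = names(sets)[j]))
    }
  }
  if (!is.null(pairs))
    pairs <- pairs[order(-pairs$J, pairs$id1, pairs$id2), , drop = FALSE]
  structures <- list(); members <- list()
  paired <- character(0)
  if (!is.null(pairs)) for (r in seq_len(nrow(pairs))) {
    shared <- intersect(sets[[pairs$i[r]]], sets[[pairs$j[r]]])
    mem <- c(pairs$id1[r], pairs$id2[r])
    paired <- union(paired, mem)
    best <- 0; bk <- NA
    for (k in seq_along(structures)) {
      jk <- jac(structures[[k]], shared)
      if (jk > best) { best <- jk; bk <- k }
    }
    if (!is.na(bk) && best >= min_sim &&
        length(intersect(structures[[bk]], shared)) > 0) {
      structures[[bk]] <- intersect(structures[[bk]], shared)
      members[[bk]] <- union(members[[bk]], mem)
    } else {
      structures[[length(structures) + 1]] <- shared
      members[[length(members) + 1]] <- mem
    }
  }
  for (m in setdiff(names(sets), paired)) {
    structures[[length(structures) + 1]] <- sets[[m]]
    members[[length(members) + 1]] <- m
  }
  list(structures = structures, members = lapply(members, sort))
}

# small helpers to build module tibbles / grn objects in tests
make_modules <- function(...) {
  # ... = named lists: list(sample=, module=, edges=data.frame(tf, gene), score=)
  dplyr::bind_rows(lapply(list(...), function(m) {
    tibble::tibble(sample = m$sample, module = m$module,
                   tf = m$edges$tf, gene = m$edges$gene,
                   score = if (length(m$score) == 1)
                     rep(m$score, nrow(m$edges)) else m$score)
  }))
}

make_grn <- function(w, condition = "x") {
  structure(list(weights = w, tf_ids = rownames(w), gene_ids = colnames(w),
                 condition = condition, converged = TRUE, iterations = 1L),
            class = "omu_grn")
}

make_node <- function(left, right) list(left = list(left), right = list(right))
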