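make_system <- function(mean_grmax, ids = paste0("OMU", seq_along(mean_grmax))) {
  structure(list(
    omus = tibble::tibble(omu = ids, n_members = 1, n_edges = 2,
                          mean_grmax = mean_grmax),
    structure = tibble::tibble(), members = tibble::tibble(),
    params = list(min_similarity = 0.25)), class = "omu_system")
}

test_that("OMU clustering merges nearest mean-GRmax values first", {
  tree <- cluster_omus(make_system(c(-0.5, -0.4, 0.6)))
  # deepest node joins -0.5 and -0.4
  deepest <- tree[which.max(tree$depth), ]
  expect_setequal(c(unlist(deepest$left), unlist(deepest$right)),
                  c("OMU1", "OMU2"))
  # root orientation: left centroid below right centroid
  root <- tree[tree$depth == 0, ]
  expect_lte(root$centroid_left, root$centroid_right)
  expect_setequal(unlist(root$right), "OMU3")

  # two OMUs: root only
  t2 <- cluster_omus(make_system(c(-0.2, 0.4)))
  expect_equal(nrow(t2), 1)

  # permuting input order leaves the tree unchanged
  s1 <- make_system(c(0.6, -0.4, -0.5, 0.1), ids = paste0("OMU", c(3, 2, 1, 4)))
  s2 <- make_system(c(-0.5, -0.4, 0.1, 0.6), ids = paste0("OMU", c(1, 2, 4, 3)))
  expect_equal(cluster_omus(s1), cluster_omus(s2))

  expect_error(cluster_omus(make_system(0.1)), ">= 2")
})

test_that("ILR balances match hand evaluation and direct transcription", {
  node <- make_node("OMU1", "OMU2")
  expect_equal(ilr_balance(c(OMU1 = 0.4, OMU2 = 0.1), node),
               sqrt(1 / 2) * log(4), tolerance = 1e-12)
  expect_equal(ilr_balance(c(OMU1 = 0.4, OMU2 = 0.1), node), 0.9803,
               tolerance = 1e-4)
  node2 <- make_node(c("OMU1", "OMU2"), "OMU3")
  expect_equal(ilr_balance(c(OMU1 = 0.2, OMU2 = 0.2, OMU3 = 0.1), node2),
               sqrt(2 / 3) * log(2), tolerance = 1e-12)
  expect_equal(ilr_balance(c(OMU1 = 0.2, OMU2 = 0.2, OMU3 = 0.1), node2),
               0.5659, tolerance = 1e-4)
  # equal geometric means -> 0
  expect_equal(ilr_balance(c(OMU1 = 0.3, OMU2 = 0.3), node), 0)
  # undefined: a side with no positive component is an explicit NA sentinel
  expect_true(is.na(ilr_balance(c(OMU1 = 0, OMU2 = 0.5), node)))
  # pseudocount mode makes it defined
  expect_false(is.na(ilr_balance(c(OMU1 = 0, OMU2 = 0.5), node,
                                 pseudocount = 1e-6)))
})

test_that("balances are scale invariant and antisymmetric under side swap", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    ids <- paste0("OMU", 1:n)
    v <- setNames(rbinom(n, 1, 0.7) * runif(n), ids)
    k <- sample(2:(n - 2), 1)
    node <- make_node(ids[1:k], ids[(k + 1):n])
    b <- ilr_balance(v, node)
    expect_equal(b, oracle_ilr(v, ids[1:k], ids[(k + 1):n]), tolerance = 1e-10)
    if (!is.na(b)) {
      expect_equal(ilr_balance(v * runif(1, 0.1, 10), node), b,
                   tolerance = 1e-9)
      flipped <- make_node(ids[(k + 1):n], ids[1:k])
      expect_equal(ilr_balance(v, flipped), -b, tolerance = 1e-12)
    }
  }
})

test_that("the selected balance point is the exhaustive-scan argmax", {
  set.seed(22)
  n_omu <- 8
  mg <- sort(runif(n_omu, -0.45, 0.45))
  sys <- make_system(mg)
  tree <- cluster_omus(sys)
  # planted monotone relation: low-GRmax OMU activity scales with -grmax
  drugs <- sprintf("d%02d", 1:12)
  gr <- tibble::tibble(drug = drugs,
                       grmax = seq(-0.9, 0.9, length.out = 12))
  vecs <- purrr::map2(drugs, gr$grmax, function(d, g) {
    w <- exp(-2 * g * (mg < 0)) * runif(n_omu, 0.8, 1.2)
    tibble::tibble(sample = d, omu = paste0("OMU", 1:n_omu), value = w)
  }) |> purrr::list_rbind()
  sel <- select_balance_point(tree, vecs, gr)
  # exhaustive scan over every internal node (no centroid filter)
  rs <- purrr::map_dbl(seq_len(nrow(tree)), function(i) {
    b <- ilr_balances(vecs, tree[i, ])
    b <- dplyr::left_join(b, gr, by = c(sample = "drug"))
    if (mean(!is.na(b$ilr)) < 0.9) return(NA_real_)
    abs(cor(b$ilr, b$grmax, use = "complete.obs"))
  })
  cand <- which(tree$centroid >= -0.5 & tree$centroid <= 0.5 & !is.na(rs))
  expect_equal(sel$node$node, tree$node[cand[which.max(rs[cand])]])
  expect_equal(abs(sel$pearson_r), max(rs[cand]), tolerance = 1e-12)
})

test_that("root mode and degenerate selections behave as documented", {
  sys <- make_system(c(-0.3, -0.1, 0.2, 0.4))
  tree <- cluster_omus(sys)
  drugs <- sprintf("d%d", 1:5)
  vecs <- purrr::map(drugs, function(d)
    tibble::tibble(sample = d, omu = paste0("OMU", 1:4),
                   value = runif(4, 0.1, 1))) |> purrr::list_rbind()
  gr <- tibble::tibble(drug = drugs, grmax = runif(5, -1, 1))
  sel <- select_balance_point(tree, vecs, gr, use_root = TRUE)
  expect_equal(sel$node$depth, 0)
  # impossible centroid window -> actionable error
  expect_error(select_balance_point(tree, vecs, gr, bounds = c(0.9, 1)),
               "no candidate")
})

test_that("OLS fit matches the normal equations and records r^2 = r squared", {
  d <- tibble::tibble(ilr = c(-1, 0, 1, 2), grmax = 2 * c(-1, 0, 1, 2) + 1)
  fit <- fit_linear_model(d)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:20) {
    d <- tibble::tibble(ilr = rnorm(10), grmax = rnorm(10))
    fit <- fit_linear_model(d)
    o <- oracle_ols(d$ilr, d$grmax)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$pearson_r, o$r, tolerance = 1e-10)
    expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
  }

  anti <- tibble::tibble(ilr = 1:5, grmax = c(0.9, 0.3, 0.1, -0.4, -0.8))
  expect_lt(fit_linear_model(anti)$pearson_r, 0)

  expect_error(fit_linear_model(tibble::tibble(ilr = c(1, 1, 1),
                                               grmax = c(0, 1, 2))),
               "variance")
  expect_error(fit_linear_model(tibble::tibble(ilr = 1:2, grmax = 1:2)),
               ">= 3")
})

test_that("tidy and glance summarize the fitted model", {
  d <- tibble::tibble(sample = letters[1:4], ilr = c(-1, 0, 1, 2),
                      grmax = c(0.9, 0.5, -0.1, -0.6))
  fit <- fit_linear_model(d)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "ilr"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$nobs, 4)
  expect_s3_class(autoplot(fit), "ggplot")
})
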