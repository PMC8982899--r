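test_that("combined vectors take the larger component and renormalize", {
  v1 <- c(OMU1 = 0.6, OMU2 = 0, OMU3 = 0.4)
  v2 <- c(OMU1 = 0, OMU2 = 0.5, OMU3 = 0.5)
  cv <- combine_omu_vectors(v1, v2)
  expect_equal(unname(cv), c(0.6, 0.5, 0.5) / 1.6, tolerance = 1e-12)
  expect_equal(unname(cv), c(0.375, 0.3125, 0.3125))
  # sum mode for sensitivity analysis
  expect_equal(unname(combine_omu_vectors(v1, v2, combine = "sum")),
               c(0.6, 0.5, 0.9) / 2)
})

test_that("combination is idempotent and commutative", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    v1 <- setNames(rbinom(n, 1, 0.6) * runif(n), paste0("OMU", 1:n))
    v2 <- setNames(rbinom(n, 1, 0.6) * runif(n), paste0("OMU", 1:n))
    if (sum(v1) == 0) v1[1] <- 0.5
    if (sum(v2) == 0) v2[2] <- 0.5
    expect_equal(combine_omu_vectors(v1, v1), normalize_vector(v1),
                 tolerance = 1e-12)
    expect_equal(combine_omu_vectors(v1, v2), combine_omu_vectors(v2, v1),
                 tolerance = 1e-12)
    expect_equal(sum(combine_omu_vectors(v1, v2)), 1, tolerance = 1e-12)
  }
})

test_that("the three-case DGIS rule matches its independent transcription", {
  expect_equal(dgis(-0.8, -0.5, 0.2), -0.3)
  expect_equal(dgis(0.5, -0.5, 0.2), 0.3)
  expect_equal(dgis(-0.5, -0.5, 0.2), 0)   # boundary inclusive
  expect_equal(dgis(0.2, -0.5, 0.2), 0)
  expect_equal(dgis(0, -0.5, 0.2), 0)
  set.seed(12)
  for (i in 1:200) {
    g <- rnorm(3)
    expect_equal(dgis(g[1], g[2], g[3]), oracle_dgis(g[1], g[2], g[3]))
    expect_equal(dgis(g[1], g[2], g[3]), dgis(g[1], g[3], g[2]))
  }
  # self-pair identity
  expect_identical(dgis(-0.4, -0.4, -0.4), 0)
})

toy_model <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept, pearson_r = -1,
                 r_squared = 1, node = "N1",
                 data = tibble::tibble()), class = "omu_balance_fit")
}

test_that("GIS is the linear prediction at the model's balance point", {
  node <- make_node("OMU1", "OMU2")
  model <- toy_model(slope = -1, intercept = 0)
  # one positive component per side, 0.4 vs 0.1: b = sqrt(1/2) ln 4
  cv <- c(OMU1 = 0.4, OMU2 = 0.1)
  b <- sqrt(1 / 2) * log(4)
  expect_equal(growth_impact_score(cv, model, node), -b, tolerance = 1e-10)
  expect_equal(growth_impact_score(cv, model, node), -0.9803,
               tolerance = 1e-4)
  # balance 0 -> GIS = intercept
  model2 <- toy_model(slope = 2, intercept = 0.3)
  expect_equal(growth_impact_score(c(OMU1 = 0.25, OMU2 = 0.25), model2, node),
               0.3)
  # undefined balance -> NA
  expect_true(is.na(growth_impact_score(c(OMU1 = 0, OMU2 = 1), model, node)))
})

test_that("pairwise scoring yields symmetric DGIS and exact self-pair zeros", {
  set.seed(13)
  n_omu <- 6
  omus <- paste0("OMU", 1:n_omu)
  drugs <- sprintf("d%02d", 1:8)
  vecs <- purrr::map(drugs, function(d) {
    v <- rbinom(n_omu, 1, 0.7) * runif(n_omu)
    v[sample(1:3, 1)] <- runif(1, 0.3, 1)       # something on the left side
    v[sample(4:n_omu, 1)] <- runif(1, 0.3, 1)   # and on the right
    tibble::tibble(sample = d, omu = omus, value = v)
  }) |> purrr::list_rbind()
  node <- make_node(omus[1:3], omus[4:6])
  model <- toy_model(slope = -0.8, intercept = 0.1)
  scores <- score_combinations(vecs, model, node)
  expect_equal(nrow(scores), n_pairs(8))
  # DGIS of a self-pair is exactly zero: check via the identity chain
  for (d in drugs) {
    v <- dplyr::filter(vecs, sample == d)
    g_self <- growth_impact_score(combine_omu_vectors(v, v), model, node)
    expect_identical(dgis(g_self, g_self, g_self), 0)
  }
  # symmetry of the pair: recompute with swapped vector arguments
  v1 <- dplyr::filter(vecs, sample == "d01")
  v2 <- dplyr::filter(vecs, sample == "d02")
  g12 <- growth_impact_score(combine_omu_vectors(v1, v2), model, node)
  g21 <- growth_impact_score(combine_omu_vectors(v2, v1), model, node)
  expect_equal(g12, g21, tolerance = 1e-12)
})

test_that("ranking sorts ascending by DGIS with deterministic ties", {
  scores <- tibble::tibble(
    drug_1 = c("a", "a", "b", "c"), drug_2 = c("b", "c", "c", "d"),
    gis = c(0.2, -0.3, 0.2, 0.1),
    dgis = c(0, -1.0, -0.5, 0),
    scorable = TRUE)
  rk <- rank_pairs(scores, top_k = 2)
  expect_equal(rk$dgis, c(-1.0, -0.5, 0, 0))
  expect_equal(rk$top, c(TRUE, TRUE, FALSE, FALSE))
  # the two DGIS = 0 rows: gis tie-break then pair order
  expect_equal(rk$drug_1[3:4], c("c", "a"))
  expect_warning(rank_pairs(scores, top_k = 10), "exceeds")
  expect_error(rank_pairs(dplyr::mutate(scores, scorable = FALSE)),
               "no scorable")
})

test_that("a pair whose combined vector pushes the balance to the killing side tops the ranking", {
  # vector-level study: 12 drugs over 10 OMUs split 5 (low mean GRmax) / 5;
  # the designated pair carries strong complementary low-side components, so
  # its combined (max) vector accumulates more killing-side mass than either
  # self-pair
  omus <- paste0("OMU", 1:10)
  node <- make_node(omus[1:5], omus[6:10])
  model <- toy_model(slope = -1, intercept = 0)
  hits <- logical(50)
  for (rep in 1:50) {
    set.seed(rep)
    vecs <- purrr::map(sprintf("d%02d", 1:12), function(d) {
      v <- rbinom(10, 1, 0.5) * runif(10, 0.1, 1)
      v[sample(1:5, 1)] <- runif(1, 0.2, 0.8)
      v[sample(6:10, 1)] <- runif(1, 0.2, 0.8)
      tibble::tibble(sample = d, omu = omus, value = v)
    }) |> purrr::list_rbind()
    # complementary low-side activity: the max-combined vector activates the
    # union {OMU1..OMU4}, which neither self-pair reaches
    engineer <- function(v, left_on) {
      v$value <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
      v$value[left_on] <- 2
      v$value[sample(6:10, 1)] <- 0.5
      v
    }
    vecs[vecs$sample == "d01", ] <- engineer(vecs[vecs$sample == "d01", ], 1:2)
    vecs[vecs$sample == "d02", ] <- engineer(vecs[vecs$sample == "d02", ], 3:4)
    rk <- rank_pairs(score_combinations(vecs, model, node,
                                        pseudocount = 1e-4), top_k = 7)
    r <- rk$rank[rk$drug_1 == "d01" & rk$drug_2 == "d02"]
    hits[rep] <- length(r) == 1 && r <= ceiling(nrow(rk) / 10)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("without planted interactions the DGIS mode sits at zero", {
  set.seed(99)
  omus <- paste0("OMU", 1:8)
  node <- make_node(omus[1:4], omus[5:8])
  model <- toy_model(slope = -0.5, intercept = 0)
  vecs <- purrr::map(sprintf("d%02d", 1:15), function(d)
    tibble::tibble(sample = d, omu = omus,
                   value = rbinom(8, 1, 0.7) * runif(8, 0.2, 1))) |>
    purrr::list_rbind()
  scores <- score_combinations(vecs, model, node, pseudocount = 1e-4)
  bins <- cut(scores$dgis, breaks = seq(-2, 2, by = 0.1))
  zero_bin <- cut(0, breaks = seq(-2, 2, by = 0.1))
  expect_equal(names(which.max(table(bins))), as.character(zero_bin))
})
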