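edges_df <- function(tf, gene) data.frame(tf = tf, gene = gene)

test_that("module Jaccard follows the edge-set definition", {
  a <- edges_df(c("t1", "t1", "t2"), c("g1", "g2", "g1"))
  b <- edges_df(c("t1", "t1", "t2"), c("g1", "g2", "g9"))
  expect_equal(module_jaccard(a, a), 1)
  expect_equal(module_jaccard(a, b), 0.5)  # |A|=|B|=3, overlap 2
  expect_equal(module_jaccard(a, b), module_jaccard(b, a))
  disj <- edges_df("t9", "g9")
  expect_equal(module_jaccard(a, disj), 0)
  expect_error(module_jaccard(a, edges_df(character(0), character(0))),
               "non-empty")
})

test_that("identical and disjoint modules build the expected OMUs", {
  ed <- edges_df(c("t1", "t1", "t2"), c("g1", "g2", "g1"))
  mods <- make_modules(
    list(sample = "d1", module = 1, edges = ed, score = 1),
    list(sample = "d2", module = 1, edges = ed, score = 2))
  sys <- build_omu_system(mods)
  expect_equal(nrow(sys$omus), 1)
  expect_equal(sys$omus$n_members, 2)
  expect_setequal(paste(sys$structure$tf, sys$structure$gene),
                  paste(ed$tf, ed$gene))

  # three mutually disjoint modules -> three singleton OMUs
  mods3 <- make_modules(
    list(sample = "d1", module = 1, edges = edges_df("t1", "g1"), score = 1),
    list(sample = "d2", module = 1, edges = edges_df("t2", "g2"), score = 1),
    list(sample = "d3", module = 1, edges = edges_df("t3", "g3"), score = 1))
  sys3 <- build_omu_system(mods3)
  expect_equal(nrow(sys3$omus), 3)
  expect_true(all(sys3$omus$n_members == 1))
})

test_that("greedy merging matches an independent transcription of the rule", {
  set.seed(41)
  all_edges <- expand.grid(tf = paste0("t", 1:4), gene = paste0("g", 1:5),
                           stringsAsFactors = FALSE)
  for (rep in 1:25) {
    n_samp <- sample(2:4, 1)
    mods <- list()
    for (s in 1:n_samp) {
      for (m in 1:sample(1:3, 1)) {
        e <- all_edges[sample(nrow(all_edges), sample(2:8, 1)), ]
        mods[[length(mods) + 1]] <- list(sample = paste0("d", s), module = m,
                                         edges = e, score = runif(1, 0.5, 2))
      }
    }
    mt <- do.call(make_modules, mods)
    sys <- build_omu_system(mt, min_similarity = 0.25)
    ms <- mt |>
      dplyr::mutate(key = paste(tf, gene, sep = "\r")) |>
      dplyr::group_by(sample, module) |>
      dplyr::summarise(edges = list(unique(key)), .groups = "drop") |>
      dplyr::arrange(sample, module)
    sets <- setNames(ms$edges, sprintf("%s\r%06d", ms$sample, ms$module))
    o <- oracle_omu_merge(sets, ms$sample, 0.25)
    expect_equal(nrow(sys$omus), length(o$structures))
    got_structs <- split(paste(sys$structure$tf, sys$structure$gene, sep = "\r"),
                         sys$structure$omu)
    ord <- unique(sys$structure$omu)
    for (k in seq_along(o$structures)) {
      expect_setequal(got_structs[[paste0("OMU", k)]], o$structures[[k]])
    }
    got_members <- sys$members |>
      dplyr::mutate(id = sprintf("%s\r%06d", sample, module))
    for (k in seq_along(o$members)) {
      expect_setequal(got_members$id[got_members$omu == paste0("OMU", k)],
                      o$members[[k]])
    }
  }
})

test_that("rebuilding from the same inventory is bit-identical and covering", {
  set.seed(42)
  all_edges <- expand.grid(tf = paste0("t", 1:5), gene = paste0("g", 1:6),
                           stringsAsFactors = FALSE)
  mods <- list()
  for (s in 1:4) for (m in 1:3) {
    e <- all_edges[sample(nrow(all_edges), sample(3:10, 1)), ]
    mods[[length(mods) + 1]] <- list(sample = paste0("d", s), module = m,
                                     edges = e, score = runif(1))
  }
  mt <- do.call(make_modules, mods)
  expect_identical(build_omu_system(mt), build_omu_system(mt))
  sys <- build_omu_system(mt)
  # coverage: every module appears as a member at least once
  expect_equal(nrow(dplyr::distinct(sys$members, sample, module)), 12)
  expect_gte(nrow(sys$members), 12)
})

test_that("mean GRmax follows the proportional-weight formula", {
  # one member: GR -0.4, module weight 2, sample total 8 -> -0.1
  ed <- edges_df(c("t1", "t2"), c("g1", "g2"))
  mods <- make_modules(
    list(sample = "d1", module = 1, edges = ed, score = 1),          # X = 2
    list(sample = "d1", module = 2,
         edges = edges_df(paste0("t", 3:5), paste0("g", 3:5)), score = 2), # 6
    list(sample = "d2", module = 1, edges = ed, score = 0.5))
  sys <- build_omu_system(mods, min_similarity = 0.9)
  gr <- tibble::tibble(drug = c("d1", "d2"), grmax = c(-0.4, 0.6))
  sys <- assign_mean_grmax(sys, gr, mods)
  omu_of <- function(s, m) {
    sys$members$omu[sys$members$sample == s & sys$members$module == m][1]
  }
  # d1 module 2 is a singleton OMU: mean = GR * X / Y = -0.4 * 6 / 8
  expect_equal(sys$omus$mean_grmax[sys$omus$omu == omu_of("d1", 2)],
               -0.4 * 6 / 8)
  # the shared OMU (d1 m1 with d2 m1): (-0.4*2 + 0.6*1) / (8 + 1)
  shared <- omu_of("d1", 1)
  expect_equal(shared, omu_of("d2", 1))
  expect_equal(sys$omus$mean_grmax[sys$omus$omu == shared],
               (-0.4 * 2 + 0.6 * 1) / (8 + 1))

  # an OMU whose single member is its sample's only module: mean = GRmax
  solo <- make_modules(list(sample = "d9", module = 1, edges = ed, score = 3))
  sys9 <- assign_mean_grmax(build_omu_system(solo),
                            tibble::tibble(drug = "d9", grmax = -0.7), solo)
  expect_equal(sys9$omus$mean_grmax, -0.7)

  # two members with equal GR g: |mean| <= |g| with the sign of g
  two <- make_modules(
    list(sample = "a", module = 1, edges = ed, score = 1),
    list(sample = "a", module = 2, edges = edges_df("t8", "g8"), score = 2),
    list(sample = "b", module = 1, edges = ed, score = 3))
  sysg <- assign_mean_grmax(build_omu_system(two),
                            tibble::tibble(drug = c("a", "b"),
                                           grmax = c(-0.5, -0.5)), two)
  shared_g <- sysg$omus$mean_grmax[sysg$omus$n_members == 2]
  expect_lt(shared_g, 0)
  expect_lte(abs(shared_g), 0.5)
  # all mean GRmax within the member range
  expect_true(all(sysg$omus$mean_grmax >= -0.5 & sysg$omus$mean_grmax <= 0))

  expect_error(assign_mean_grmax(sys, tibble::tibble(drug = "d1", grmax = 0),
                                 mods), "d2")
})

test_that("OMU vectors sum module weights into system components", {
  ed1 <- edges_df(c("t1", "t2"), c("g1", "g2"))
  ed2 <- edges_df(c("t3", "t4"), c("g3", "g4"))
  mods <- make_modules(
    list(sample = "d1", module = 1, edges = ed1, score = 1),    # weight 2
    list(sample = "d1", module = 2, edges = ed1, score = 1.5),  # weight 3
    list(sample = "d2", module = 1, edges = ed1, score = 1),
    list(sample = "d2", module = 2, edges = ed2, score = 2))
  sys <- build_omu_system(mods, min_similarity = 0.5)
  v1 <- omu_vector(dplyr::filter(mods, sample == "d1"), sys)
  # both d1 modules share the ed1 OMU: component = 2 + 3
  shared <- sys$members |>
    dplyr::filter(sample == "d1") |> dplyr::pull(omu) |> unique()
  expect_equal(v1$value[v1$omu %in% shared], 5)
  expect_true(all(v1$value[!v1$omu %in% shared] == 0))
  expect_equal(nrow(v1), nrow(sys$omus))
  # structure-restricted variant only counts edges inside the OMU structure
  v1s <- omu_vector(dplyr::filter(mods, sample == "d1"), sys,
                    weights = "structure")
  expect_equal(v1s$value[v1s$omu %in% shared], 5)  # ed1 is the full structure

  vv <- omu_vectors(mods, sys)
  expect_equal(nrow(vv), 2 * nrow(sys$omus))
  # sparsity: d1 has no weight in d2's private OMU
  expect_true(any(vv$value == 0))
  expect_error(omu_vector(mods[0, ], sys), "no differential modules")
})
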