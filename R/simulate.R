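# Seeded synthetic studies: a block-structured regulatory prior and PPI,
# per-condition expression in which each drug perturbs a small set of
# regulatory blocks with a magnitude that tracks its assigned GRmax, and
# Hill-curve dose-response matrices with planted synergy. Every input format
# of the pipeline can be produced without any download.

#' Configuration for a synthetic drug-combination study
#'
#' @param n_drugs Number of drugs (default 20).
#' @param n_tfs Number of transcription factors (default 30).
#' @param n_genes Number of target genes (default 200).
#' @param n_blocks Number of planted regulatory blocks (default 7). The
#'   first `n_death_blocks` blocks are death-associated (perturbing them
#'   lowers GRmax); the last two blocks are perturbed by every drug: a
#'   stress block whose perturbation scales with the drug's kill signal and
#'   a housekeeping block perturbed independently of phenotype. The blocks
#'   in between are phenotype-neutral; every drug additionally perturbs one
#'   random neutral block, so every drug's activity spans both
#'   death-associated and neutral regulatory programs.
#' @param n_death_blocks Number of death-associated blocks (default 2).
#' @param grmax_range Clipping range for assigned GRmax (default c(-1, 1)).
#' @param synergy_pairs Optional tibble (`drug_1`, `drug_2`, `strength`) of
#'   planted synergistic pairs. Members of a planted pair perturb
#'   complementary death blocks, so their combined OMU vector pushes the
#'   balance further toward the negative-GRmax side than either drug alone,
#'   and their dose-response matrices get `strength` extra inhibition over
#'   the Bliss expectation.
#' @param noise_sd Gaussian noise sd on assigned GRmax (default 0.1).
#' @param expr_noise_sd Gaussian noise sd on log-scale expression
#'   (default 0.3).
#' @param response_jitter Relative sd of the per-gene, per-drug response
#'   heterogeneity around the planted block magnitude (default 0.3).
#' @param dose_noise_sd Gaussian noise sd on dose-response cells
#'   (default 0).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_drugs = 20, n_tfs = 30, n_genes = 200,
                         n_blocks = 7, n_death_blocks = 2,
                         grmax_range = c(-1, 1), synergy_pairs = NULL,
                         noise_sd = 0.1, expr_noise_sd = 0.3,
                         response_jitter = 0.3, dose_noise_sd = 0, seed = 1) {
  stopifnot(n_drugs >= 2, n_tfs >= n_blocks, n_genes >= n_blocks,
            n_blocks >= n_death_blocks + 3)
  if (!is.null(synergy_pairs)) {
    stopifnot(all(c("drug_1", "drug_2", "strength") %in% colnames(synergy_pairs)))
    ids <- drug_ids(n_drugs)
    if (!all(c(synergy_pairs$drug_1, synergy_pairs$drug_2) %in% ids))
      stop_omu("synergy pairs must name configured drugs (drug01, drug02, ...)")
  }
  structure(list(n_drugs = n_drugs, n_tfs = n_tfs, n_genes = n_genes,
                 n_blocks = n_blocks, n_death_blocks = n_death_blocks,
                 grmax_range = grmax_range, synergy_pairs = synergy_pairs,
                 noise_sd = noise_sd, expr_noise_sd = expr_noise_sd,
                 response_jitter = response_jitter,
                 dose_noise_sd = dose_noise_sd, seed = as.integer(seed)),
            class = "study_config")
}

drug_ids <- function(n) sprintf("drug%02d", seq_len(n))

# run expr with a derived sub-seed, restoring the caller's RNG state
with_subseed <- function(seed, offset, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  expr
}

#' Generate the regulatory prior and PPI of a synthetic study
#'
#' TFs and genes are split into `n_blocks` blocks; prior TF-to-gene edges
#' are dense within a block and sparse across; TF-TF interactions are denser
#' and stronger within blocks.
#'
#' @param cfg A `study_config`.
#' @return List with `prior` and `ppi` edge-list tibbles, plus `tf_block`
#'   and `gene_block` assignments.
#' @export
generate_network_priors <- function(cfg) {
  with_subseed(cfg$seed, 101L, {
    tfs <- sprintf("TF%03d", seq_len(cfg$n_tfs))
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    tf_block <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_tfs)
    gene_block <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_genes)
    same <- outer(tf_block, gene_block, "==")
    p <- ifelse(same, 0.7, 0.03)
    a <- matrix(rbinom(length(p), 1, p), nrow = cfg$n_tfs)
    el <- which(a == 1, arr.ind = TRUE)
    prior <- tibble(source = tfs[el[, 1]], target = genes[el[, 2]],
                    weight = 1.0) |>
      arrange(.data$source, .data$target)
    same_tt <- outer(tf_block, tf_block, "==")
    pp <- ifelse(same_tt, 0.6, 0.05)
    upper <- upper.tri(pp)
    keep <- upper & matrix(rbinom(length(pp), 1, pp) == 1, nrow = cfg$n_tfs)
    ee <- which(keep, arr.ind = TRUE)
    w <- ifelse(same_tt[keep], runif(nrow(ee), 0.5, 1), runif(nrow(ee), 0.1, 0.4))
    ppi <- tibble(source = tfs[ee[, 1]], target = tfs[ee[, 2]], weight = w)
    ppi <- bind_rows(ppi, tibble(source = ppi$target, target = ppi$source,
                                 weight = ppi$weight)) |>
      arrange(.data$source, .data$target)
    list(prior = prior, ppi = ppi,
         tf_block = setNames(tf_block, tfs),
         gene_block = setNames(gene_block, genes))
  })
}

# block perturbation magnitudes per drug; encodes the study design:
# - planted synergy-pair members hit complementary death blocks
# - other drugs hit one primary block: a death block (prob 0.4) or a
#   neutral block
# - every drug additionally perturbs one random neutral secondary block,
#   the stress block (scaling with its kill signal) and the housekeeping
#   block (independently of phenotype)
drug_block_design <- function(cfg) {
  drugs <- drug_ids(cfg$n_drugs)
  death_blocks <- seq_len(cfg$n_death_blocks)
  neutral_blocks <- setdiff(seq_len(cfg$n_blocks - 2), death_blocks)
  stress_block <- cfg$n_blocks - 1L
  hk_block <- cfg$n_blocks
  M <- matrix(0, cfg$n_drugs, cfg$n_blocks,
              dimnames = list(drugs, NULL))
  planted <- character(0)
  if (!is.null(cfg$synergy_pairs)) {
    for (r in seq_len(nrow(cfg$synergy_pairs))) {
      d1 <- cfg$synergy_pairs$drug_1[r]; d2 <- cfg$synergy_pairs$drug_2[r]
      b1 <- death_blocks[1 + (r - 1) %% length(death_blocks)]
      b2 <- death_blocks[1 + r %% length(death_blocks)]
      M[d1, b1] <- runif(1, 0.9, 1.2)
      M[d2, b2] <- runif(1, 0.9, 1.2)
      planted <- c(planted, d1, d2)
    }
  }
  for (d in setdiff(drugs, planted)) {
    if (runif(1) < 0.4) {
      M[d, sample(death_blocks, 1)] <- runif(1, 0.8, 1.6)
    } else {
      M[d, sample(neutral_blocks, 1)] <- runif(1, 0.8, 1.6)
    }
  }
  for (d in drugs) {
    free <- neutral_blocks[M[d, neutral_blocks] == 0]
    M[d, if (length(free) > 1) sample(free, 1) else free] <- runif(1, 0.5, 0.9)
  }
  kill <- rowSums(M[, death_blocks, drop = FALSE])
  M[, stress_block] <- 0.3 + 0.5 * kill + runif(cfg$n_drugs, 0, 0.1)
  M[, hk_block] <- runif(cfg$n_drugs, 0.4, 0.8)
  M
}

#' Generate expression profiles and the GRmax table
#'
#' One control profile plus one profile per drug. Each drug adds its block
#' perturbation magnitudes to the baseline expression of the genes in the
#' perturbed blocks (times a per-gene loading), plus i.i.d. Gaussian noise
#' on the log scale. GRmax decreases linearly in the drug's summed
#' death-block perturbation, plus Gaussian noise, clipped to `grmax_range`.
#'
#' @param cfg A `study_config`.
#' @param priors Output of [generate_network_priors()].
#' @return List with `expression` (matrix, columns `control` then drugs),
#'   `gr` (tibble `drug`, `grmax`), `design` (drug-by-block magnitude
#'   matrix).
#' @export
generate_expression_and_gr <- function(cfg, priors) {
  with_subseed(cfg$seed, 202L, {
    drugs <- drug_ids(cfg$n_drugs)
    genes <- names(priors$gene_block)
    M <- drug_block_design(cfg)
    mu <- rnorm(cfg$n_genes, 8, 1)
    loading <- rnorm(cfg$n_genes, 1, 0.2)
    expr <- matrix(0, cfg$n_genes, cfg$n_drugs + 1,
                   dimnames = list(genes, c("control", drugs)))
    expr[, "control"] <- mu + rnorm(cfg$n_genes, 0, cfg$expr_noise_sd)
    for (d in drugs) {
      bump <- M[d, priors$gene_block] * loading *
        (1 + rnorm(cfg$n_genes, 0, cfg$response_jitter))
      expr[, d] <- mu + bump + rnorm(cfg$n_genes, 0, cfg$expr_noise_sd)
    }
    kill <- rowSums(M[, seq_len(cfg$n_death_blocks), drop = FALSE])
    grmax <- 0.9 - 1.1 * kill + rnorm(cfg$n_drugs, 0, cfg$noise_sd)
    grmax <- pmin(cfg$grmax_range[2], pmax(cfg$grmax_range[1], grmax))
    list(expression = expr,
         gr = tibble(drug = drugs, grmax = grmax),
         design = M)
  })
}

#' Generate 6x6 combination dose-response matrices
#'
#' Each drug gets a four-parameter logistic inhibition curve whose plateau
#' matches its GRmax (`(1 - GRmax) / 2`). A pair's matrix is the Bliss
#' expectation of the two curves; planted synergy pairs additionally gain
#' their configured `strength` of inhibition on every interior cell
#' (both concentrations positive), plus optional Gaussian noise; responses
#' are clipped to \[0, 1\].
#'
#' @param cfg A `study_config`.
#' @param gr GR table from [generate_expression_and_gr()].
#' @param pairs Tibble (`drug_1`, `drug_2`) of pairs to generate (default:
#'   the configured synergy pairs, if any).
#' @param doses Concentration grid (default 0 plus five 4-fold dilutions).
#' @return List with `matrices` (named list of `dose_response_matrix`
#'   objects, names "drug_1|drug_2") and `curves` (tibble of per-drug 4PL
#'   parameters).
#' @export
generate_dose_response <- function(cfg, gr, pairs = cfg$synergy_pairs,
                                   doses = c(0, 0.0625, 0.25, 1, 4, 16)) {
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_omu("no pairs requested for dose-response generation")
  with_subseed(cfg$seed, 303L, {
    gr <- validate_gr_table(gr)
    curves <- gr |>
      mutate(emax = (1 - .data$grmax) / 2,
             ec50 = exp(rnorm(n(), 0, 0.5)),
             h = runif(n(), 1, 2))
    strength <- if ("strength" %in% colnames(pairs)) pairs$strength else
      rep(0, nrow(pairs))
    mats <- map(seq_len(nrow(pairs)), function(r) {
      p1 <- curves[curves$drug == pairs$drug_1[r], ]
      p2 <- curves[curves$drug == pairs$drug_2[r], ]
      if (nrow(p1) == 0 || nrow(p2) == 0)
        stop_omu("dose-response pair names a drug without GRmax")
      y1 <- hill4(doses, 0, p1$emax, p1$ec50, p1$h)
      y2 <- hill4(doses, 0, p2$emax, p2$ec50, p2$h)
      resp <- outer(y1, y2, function(a, b) a + b - a * b)
      interior <- outer(doses > 0, doses > 0, "&")
      resp[interior] <- resp[interior] + strength[r]
      if (cfg$dose_noise_sd > 0)
        resp <- resp + rnorm(length(resp), 0, cfg$dose_noise_sd)
      resp <- pmin(1, pmax(0, resp))
      long <- tibble(drug1 = pairs$drug_1[r],
                     conc1 = rep(doses, times = length(doses)),
                     drug2 = pairs$drug_2[r],
                     conc2 = rep(doses, each = length(doses)),
                     response = as.vector(resp))
      dose_response_matrix(long)
    })
    names(mats) <- paste(pairs$drug_1, pairs$drug_2, sep = "|")
    list(matrices = mats, curves = curves)
  })
}

#' Generate a complete synthetic study
#'
#' @param cfg A `study_config` (or arguments forwarded to [study_config()]).
#' @param ... Arguments forwarded to [study_config()] when `cfg` is missing.
#' @return Object of class `omu_study`: list with `config`, `prior`, `ppi`,
#'   `tf_block`, `gene_block`, `expression`, `gr`, `design`.
#' @export
simulate_study <- function(cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- study_config(...)
  stopifnot(inherits(cfg, "study_config"))
  priors <- generate_network_priors(cfg)
  eg <- generate_expression_and_gr(cfg, priors)
  structure(list(config = cfg, prior = priors$prior, ppi = priors$ppi,
                 tf_block = priors$tf_block, gene_block = priors$gene_block,
                 expression = eg$expression, gr = eg$gr, design = eg$design),
            class = "omu_study")
}

#' @export
print.omu_study <- function(x, ...) {
  cat(sprintf("<omu_study> seed %d: %d drugs, %d TFs x %d genes, %d blocks\n",
              x$config$seed, x$config$n_drugs, x$config$n_tfs,
              x$config$n_genes, x$config$n_blocks))
  invisible(x)
}

#' Write every input file of a study to a directory
#' @param study An `omu_study`.
#' @param dir Output directory (created if missing).
#' @return Tibble of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = write_expression(study$expression, file.path(dir, "expression.tsv")),
    prior = write_edge_list(study$prior, file.path(dir, "prior.tsv")),
    ppi = write_edge_list(study$ppi, file.path(dir, "ppi.tsv")),
    gr = write_gr_table(study$gr, file.path(dir, "gr.csv"))
  )
  invisible(tibble(input = names(paths), path = unname(paths)))
}
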