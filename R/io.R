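#' Read a genes-by-samples expression matrix
#'
#' Expression matrices are TSV files with a header row of sample identifiers
#' and a first column of gene identifiers. One column per condition (the
#' untreated control or a single drug treatment), values on log scale.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes in rows, samples in columns) with gene and
#'   sample ids as dimnames.
#' @details Duplicate gene or sample ids and non-numeric cells are hard
#'   errors that name the offending entry; rows with missing values are
#'   rejected with a report rather than silently dropped.
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) stop_omu("expression file needs a gene column plus >= 1 sample column")
  gene_ids <- as.character(raw[[1]])
  sample_ids <- colnames(raw)[-1]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0)
    stop_omu(paste0("duplicate gene ids: ", paste(dup_g, collapse = ", ")))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0)
    stop_omu(paste0("duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  num <- matrix(num, nrow = length(gene_ids),
                dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_omu(sprintf("non-numeric cell at gene '%s', sample '%s'",
                     gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  incomplete <- !complete.cases(num)
  if (any(incomplete))
    stop_omu(paste0("rows with missing values: ",
                    paste(gene_ids[incomplete], collapse = ", ")))
  message(sprintf("read expression matrix: %d genes x %d samples",
                  nrow(num), ncol(num)))
  num
}

#' Write an expression matrix
#'
#' @param x Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- tibble::as_tibble(x, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a directed edge list (regulatory prior or TF-TF interactions)
#'
#' @param path TSV with columns `source`, `target` and an optional numeric
#'   `weight` (default 1.0 when absent).
#' @param symmetric If `TRUE` (protein-interaction mode) every edge (a, b)
#'   implies (b, a) with the same weight, and self-loops are dropped with a
#'   warning that counts them.
#' @return A tibble with columns `source`, `target`, `weight`.
#' @export
read_edge_list <- function(path, symmetric = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("source", "target")
  if (!all(need %in% colnames(raw)))
    stop_omu("edge list must have columns 'source' and 'target'")
  el <- tibble(
    source = as.character(raw$source),
    target = as.character(raw$target),
    weight = if ("weight" %in% colnames(raw)) {
      w <- suppressWarnings(as.numeric(raw$weight))
      if (anyNA(w) | any(!is.finite(w)))
        stop_omu("malformed weight in edge list (non-numeric or non-finite)")
      w
    } else 1.0
  )
  if (anyNA(el$source) || anyNA(el$target))
    stop_omu("malformed line in edge list (missing source/target)")
  if (symmetric) {
    loops <- el$source == el$target
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop(s) from symmetric edge list",
                      sum(loops)))
      el <- el[!loops, , drop = FALSE]
    }
    el <- bind_rows(el, tibble(source = el$target, target = el$source,
                               weight = el$weight)) |>
      distinct(.data$source, .data$target, .keep_all = TRUE)
  }
  arrange(el, .data$source, .data$target)
}

#' Write an edge list
#' @param el Tibble with columns `source`, `target`, `weight`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(el, path) {
  readr::write_tsv(el[, c("source", "target", "weight")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a per-drug GRmax table
#'
#' GRmax is the maximal growth-rate-inhibition effect of a drug, bounded in
#' \[-1, 1\]: negative values are cytotoxic, 0 cytostatic, 1 no effect.
#'
#' @param path CSV with columns `drug`, `grmax`.
#' @return Tibble with one validated record per drug.
#' @export
read_gr_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    drug = readr::col_character(), grmax = readr::col_double()
  ), progress = FALSE)
  validate_gr_table(raw)
}

validate_gr_table <- function(gr) {
  if (!all(c("drug", "grmax") %in% colnames(gr)))
    stop_omu("GR table must have columns 'drug' and 'grmax'")
  gr <- tibble(drug = as.character(gr$drug), grmax = as.numeric(gr$grmax))
  dup <- unique(gr$drug[duplicated(gr$drug)])
  if (length(dup) > 0)
    stop_omu(paste0("duplicate drug ids in GR table: ", paste(dup, collapse = ", ")))
  bad <- !is.finite(gr$grmax) | gr$grmax < -1 | gr$grmax > 1
  if (any(bad))
    stop_omu(paste0("GRmax outside [-1, 1] for: ",
                    paste(gr$drug[bad], collapse = ", ")))
  gr
}

#' Write a GRmax table
#' @param gr Tibble with columns `drug`, `grmax`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gr_table <- function(gr, path) {
  readr::write_csv(validate_gr_table(gr), path, progress = FALSE)
  invisible(path)
}

#' Read a long-format dose-response combination table
#'
#' @param path CSV with columns `drug1`, `conc1`, `drug2`, `conc2`,
#'   `response` (fractional inhibition in \[0, 1\]).
#' @return Tibble of the records.
#' @export
read_dose_response <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    drug1 = readr::col_character(), conc1 = readr::col_double(),
    drug2 = readr::col_character(), conc2 = readr::col_double(),
    response = readr::col_double()
  ), progress = FALSE)
}

#' Write a long-format dose-response combination table
#' @param dr Tibble with columns `drug1`, `conc1`, `drug2`, `conc2`,
#'   `response`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(dr, path) {
  readr::write_csv(dr[, c("drug1", "conc1", "drug2", "conc2", "response")],
                   path, progress = FALSE)
  invisible(path)
}

#' Write a ranked combination table
#'
#' Rows are sorted ascending by DGIS (most promising candidates first), ties
#' broken lexicographically by (`drug_1`, `drug_2`).
#'
#' @param ranking Tibble with columns `drug_1`, `drug_2`, `gis`, `dgis` and
#'   optionally `zip`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  need <- c("drug_1", "drug_2", "gis", "dgis")
  if (!all(need %in% colnames(ranking)))
    stop_omu("ranking needs columns drug_1, drug_2, gis, dgis")
  keep <- intersect(c(need, "zip"), colnames(ranking))
  out <- arrange(ranking[, keep], .data$dgis, .data$drug_1, .data$drug_2)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a ranked combination table written by [write_ranking()]
#' @param path TSV path.
#' @return Tibble.
#' @export
read_ranking <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    drug_1 = readr::col_character(), drug_2 = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
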