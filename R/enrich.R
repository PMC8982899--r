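# Enrichment of true synergistic pairs in the top-k candidate list versus a
# random sample, via a joint two-trial maximum-likelihood argument over the
# unknown population proportion of synergistic pairs.

#' Number of unordered drug pairs
#' @param n_drugs Number of drugs (>= 2).
#' @return `n * (n - 1) / 2`.
#' @export
n_pairs <- function(n_drugs) {
  if (any(n_drugs < 2)) stop_omu("need at least 2 drugs")
  n_drugs * (n_drugs - 1) / 2
}

#' Size of a fractional random validation sample
#' @param n Population size (e.g. number of pairs).
#' @param fraction Sampled fraction (default 0.1).
#' @return `round(n * fraction)`.
#' @export
validation_sample_size <- function(n, fraction = 0.1) {
  round(n * fraction)
}

#' Joint maximum-likelihood proportion from two sampling trials
#'
#' Finds the population proportion M of synergistic pairs maximizing the
#' joint probability of drawing `k1` hits in `s1` samples (the ranked top
#' list) and `k2` hits in `s2` samples (a random draw), under a binomial
#' (with-replacement) model: the numeric argmax is checked against the
#' pooled closed form `(k1 + k2) / (s1 + s2)`. When `finite_population`
#' is supplied, a hypergeometric variant maximizes over the integer number
#' of true synergistic pairs K in the population and reports `K / N`
#' alongside.
#'
#' @param k1,s1 Hits and draws in the first trial.
#' @param k2,s2 Hits and draws in the second trial.
#' @param finite_population Optional population size N for the
#'   hypergeometric variant.
#' @return Tibble with one row per model (`model`, `m_hat`,
#'   `joint_prob_at_mhat`, plus `k_hat` for the hypergeometric row).
#' @export
joint_binomial_mle <- function(k1, s1, k2, s2, finite_population = NULL) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= s1, k2 <= s2)
  if (s1 + s2 == 0) stop_omu("at least one trial must have draws")
  loglik <- function(m) dbinom(k1, s1, m, log = TRUE) +
    dbinom(k2, s2, m, log = TRUE)
  closed <- (k1 + k2) / (s1 + s2)
  if (closed == 0) {
    m_hat <- 0
  } else if (closed == 1) {
    m_hat <- 1
  } else {
    m_hat <- optimize(loglik, c(1e-12, 1 - 1e-12), maximum = TRUE,
                      tol = 1e-12)$maximum
  }
  out <- tibble(model = "binomial", m_hat = m_hat,
                joint_prob_at_mhat = exp(loglik(m_hat)), k_hat = NA_real_)
  if (!is.null(finite_population)) {
    N <- as.integer(finite_population)
    stopifnot(N >= max(s1, s2))
    ks <- 0:N
    jp <- dhyper(k1, ks, N - ks, s1) * dhyper(k2, ks, N - ks, s2)
    k_hat <- ks[which.max(jp)]
    out <- bind_rows(out, tibble(model = "hypergeometric",
                                 m_hat = k_hat / N,
                                 joint_prob_at_mhat = max(jp),
                                 k_hat = as.numeric(k_hat)))
  }
  out
}
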