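# Growth-rate inhibition (GR) metrics and zero-interaction-potency (ZIP)
# synergy scoring for 6x6 combination dose-response matrices.

#' Growth-rate inhibition value
#'
#' `GR = 2^(k_ct / k0) - 1`, the treated-over-control growth-rate ratio
#' normalized to one cell division: 1 means no effect, 0 full cytostasis,
#' negative values cell killing (bounded below by -1).
#'
#' @param k_ct Growth rate under treatment (per hour).
#' @param k0 Growth rate of the untreated control (per hour, must be > 0).
#' @return The GR value.
#' @export
gr_value <- function(k_ct, k0) {
  if (any(k0 <= 0)) stop_omu("control growth rate must be positive")
  2^(k_ct / k0) - 1
}

#' GR dose-response curve and GRmax from cell counts or growth rates
#'
#' Growth rates from counts are `k = ln(x_t / x_0) / t`; the control rate
#' comes from the untreated wells, and each concentration's GR value is
#' [gr_value()]. GRmax is the minimum GR over tested concentrations (the
#' maximal drug effect).
#'
#' @param drug Drug id.
#' @param concentrations Numeric vector of tested concentrations.
#' @param x0,xt Cell counts (or viability readouts) at time 0 and `t` per
#'   concentration; alternatively pass `rates` directly.
#' @param control_x0,control_xt Untreated counts (scalars); alternatively
#'   `control_rate`.
#' @param t Incubation time in hours (default 72).
#' @param rates Optional per-concentration growth rates (overrides counts).
#' @param control_rate Optional control growth rate.
#' @return Object of class `gr_curve`: tibble (`drug`, `concentration`,
#'   `gr`) with attribute `gr_max`.
#' @export
gr_curve <- function(drug, concentrations, x0 = NULL, xt = NULL,
                     control_x0 = NULL, control_xt = NULL, t = 72,
                     rates = NULL, control_rate = NULL) {
  if (is.null(rates)) {
    if (any(x0 <= 0) || any(xt <= 0)) stop_omu("cell counts must be positive")
    rates <- log(xt / x0) / t
  }
  if (is.null(control_rate)) {
    if (any(control_x0 <= 0) || any(control_xt <= 0))
      stop_omu("control counts must be positive")
    control_rate <- log(control_xt / control_x0) / t
  }
  gr <- gr_value(rates, control_rate)
  out <- tibble(drug = drug, concentration = concentrations, gr = gr)
  class(out) <- c("gr_curve", class(out))
  attr(out, "gr_max") <- min(gr)
  out
}

#' Maximal drug effect of a GR curve
#' @param curve A `gr_curve`.
#' @return GRmax, the minimum GR over tested concentrations.
#' @export
gr_max <- function(curve) attr(curve, "gr_max")

# 4PL: y(d) = ymin + (ymax - ymin) / (1 + (ec50/d)^h); y(0) = ymin
hill4 <- function(d, ymin, ymax, ec50, h) {
  y <- ymin + (ymax - ymin) / (1 + (ec50 / d)^h)
  y[d == 0] <- ymin
  y
}

#' Fit a four-parameter logistic (Hill) curve
#'
#' Bounded least squares (Levenberg-Marquardt): `ymin`, `ymax` in \[0, 1\],
#' `ec50` within the positive dose range times \[0.01, 100\], slope `h` in
#' (0, 10\]. On non-convergence the fit falls back to monotone linear
#' interpolation of the observed responses (flagged by `converged = FALSE`);
#' a constant response is flagged `degenerate`.
#'
#' @param doses Numeric doses (>= 4 points; zero dose allowed and anchors
#'   `ymin`).
#' @param responses Fractional inhibition in \[0, 1\].
#' @return Object of class `hill_fit`: list with `ymin`, `ymax`, `ec50`,
#'   `h`, `converged`, `degenerate`, and `predict(fit, d)` support.
#' @export
fit_hill <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  if (length(doses) < 4) stop_omu("need >= 4 dose points for a 4PL fit")
  pos <- doses > 0
  if (sd(responses) == 0) {
    fit <- list(ymin = responses[1], ymax = responses[1],
                ec50 = exp(mean(log(doses[pos]))), h = 1,
                converged = TRUE, degenerate = TRUE,
                doses = doses, responses = responses)
    class(fit) <- "hill_fit"
    return(fit)
  }
  lo_d <- min(doses[pos]); hi_d <- max(doses[pos])
  # multi-start over slope and midpoint; keep the best converged fit
  starts <- expand.grid(h = c(0.5, 1, 2, 4),
                        ec50 = c(exp(mean(log(range(doses[pos])))),
                                 stats::median(doses[pos])))
  fit <- NULL; best_ssr <- Inf
  for (k in seq_len(nrow(starts))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ hill4(doses, ymin, ymax, ec50, h),
        start = list(ymin = max(0, min(responses)),
                     ymax = min(1, max(responses)),
                     ec50 = starts$ec50[k], h = starts$h[k]),
        lower = c(ymin = 0, ymax = 0, ec50 = lo_d * 0.01, h = 1e-3),
        upper = c(ymin = 1, ymax = 1, ec50 = hi_d * 100, h = 10),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) NULL)
    if (!is.null(cand)) {
      ssr <- sum(stats::residuals(cand)^2)
      if (ssr < best_ssr) { best_ssr <- ssr; fit <- cand }
    }
  }
  if (is.null(fit)) {
    warning("4PL fit did not converge; falling back to monotone interpolation")
    out <- list(ymin = responses[which.min(doses)],
                ymax = responses[which.max(doses)],
                ec50 = exp(mean(log(range(doses[pos])))), h = NA_real_,
                converged = FALSE, degenerate = FALSE,
                doses = doses, responses = responses)
    class(out) <- "hill_fit"
    return(out)
  }
  p <- as.list(coef(fit))
  out <- c(p, list(converged = TRUE, degenerate = FALSE,
                   doses = doses, responses = responses))
  class(out) <- "hill_fit"
  out
}

#' Predict from a Hill fit
#' @param object A `hill_fit`.
#' @param newdata Numeric doses.
#' @param ... Unused.
#' @return Predicted fractional inhibition.
#' @export
predict.hill_fit <- function(object, newdata, ...) {
  if (!object$converged) {
    # monotone interpolation fallback on the observed points
    o <- order(object$doses)
    return(stats::approx(object$doses[o], object$responses[o], xout = newdata,
                         rule = 2)$y)
  }
  hill4(newdata, object$ymin, object$ymax, object$ec50, object$h)
}

#' Build a dose-response matrix object from a long table
#'
#' @param dr Long tibble (`drug1`, `conc1`, `drug2`, `conc2`, `response`)
#'   for one drug pair, covering a full grid including the zero-concentration
#'   margins (monotherapies). Responses are clipped to \[0, 1\] with the
#'   clip count logged.
#' @return Object of class `dose_response_matrix`: list with `drug1`,
#'   `drug2`, `conc1`, `conc2` (sorted, including 0) and `response` matrix
#'   (rows = conc1, cols = conc2).
#' @export
dose_response_matrix <- function(dr) {
  stopifnot(all(c("drug1", "conc1", "drug2", "conc2", "response") %in% colnames(dr)))
  d1 <- unique(dr$drug1); d2 <- unique(dr$drug2)
  stopifnot(length(d1) == 1, length(d2) == 1)
  c1 <- sort(unique(dr$conc1)); c2 <- sort(unique(dr$conc2))
  if (!(0 %in% c1) || !(0 %in% c2))
    stop_omu("dose-response matrix must include zero-concentration margins")
  resp <- dr$response
  n_clip <- sum(resp < 0 | resp > 1)
  if (n_clip > 0) {
    message(sprintf("clipped %d response(s) to [0, 1]", n_clip))
    resp <- pmin(1, pmax(0, resp))
  }
  m <- matrix(NA_real_, length(c1), length(c2),
              dimnames = list(c1, c2))
  m[cbind(match(dr$conc1, c1), match(dr$conc2, c2))] <- resp
  if (anyNA(m)) stop_omu("incomplete dose-response grid")
  structure(list(drug1 = d1, drug2 = d2, conc1 = c1, conc2 = c2,
                 response = m, n_clipped = n_clip),
            class = "dose_response_matrix")
}

#' ZIP synergy score of a combination dose-response matrix
#'
#' Four-parameter logistic curves are fitted to the two monotherapy margins;
#' each interior cell's expected inhibition under zero interaction is the
#' Bliss independence surface of the fitted margins,
#' `y1 + y2 - y1 * y2`. The per-cell delta is observed minus expected, and
#' the ZIP score is the mean interior delta in percentage points
#' (multiplied by 100). The synergy call applies the `> 5` threshold.
#'
#' @param m A `dose_response_matrix` (or a long tibble accepted by
#'   [dose_response_matrix()]).
#' @param threshold Synergy call threshold in percentage points (default 5).
#' @return Object of class `zip_result`: list with `drug1`, `drug2`,
#'   `zip_score`, `synergy_call`, `delta` (interior delta matrix), and the
#'   margin fits.
#' @export
zip_synergy <- function(m, threshold = 5) {
  if (!inherits(m, "dose_response_matrix")) m <- dose_response_matrix(m)
  c1 <- m$conc1; c2 <- m$conc2
  y1_obs <- m$response[, which(c2 == 0)]   # drug1 alone over c1
  y2_obs <- m$response[which(c1 == 0), ]   # drug2 alone over c2
  f1 <- fit_hill(c1, y1_obs)
  f2 <- fit_hill(c2, y2_obs)
  i1 <- which(c1 > 0); i2 <- which(c2 > 0)
  y1 <- predict(f1, c1[i1])
  y2 <- predict(f2, c2[i2])
  expected <- outer(y1, y2, function(a, b) a + b - a * b)
  delta <- m$response[i1, i2, drop = FALSE] - expected
  score <- mean(delta) * 100
  structure(list(drug1 = m$drug1, drug2 = m$drug2,
                 zip_score = score, synergy_call = score > threshold,
                 delta = delta, fit1 = f1, fit2 = f2,
                 threshold = threshold),
            class = "zip_result")
}

#' @export
print.zip_result <- function(x, ...) {
  cat(sprintf("<zip_result> %s + %s: ZIP = %.3f (%s)\n", x$drug1, x$drug2,
              x$zip_score,
              if (x$synergy_call) "synergistic" else "not synergistic"))
  invisible(x)
}

#' Tidy a ZIP result
#' @param x A `zip_result`.
#' @param ... Unused.
#' @return One-row tibble (`drug_1`, `drug_2`, `zip`, `synergy`).
#' @export
tidy.zip_result <- function(x, ...) {
  tibble(drug_1 = x$drug1, drug_2 = x$drug2, zip = x$zip_score,
         synergy = x$synergy_call)
}

#' Heatmap of the ZIP delta surface
#' @param object A `zip_result`.
#' @param ... Unused.
#' @return A ggplot tile map of per-cell deviation from the
#'   zero-interaction expectation.
#' @export
autoplot.zip_result <- function(object, ...) {
  df <- as_tibble(object$delta, rownames = "conc1") |>
    tidyr::pivot_longer(-"conc1", names_to = "conc2", values_to = "delta")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc1, y = .data$conc2,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "seagreen", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = paste(object$drug1, "concentration"),
                  y = paste(object$drug2, "concentration"),
                  fill = "delta",
                  title = sprintf("ZIP = %.2f", object$zip_score)) +
    ggplot2::theme_minimal()
}
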