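#' Dichotomize CY-BOCS totals into severity classes
#'
#' Totals at or above 24 are severe; below 24 mild-to-moderate; missing
#' stays missing (such probands drop out of the severity model). Scores
#' outside [0, 40] are an error.
#'
#' @param cybocs_total numeric vector of CY-BOCS totals (0-40 or NA)
#' @return character vector: "severe", "mild_moderate", NA
#' @export
severity_class <- function(cybocs_total) {
  ok <- is.na(cybocs_total) | (cybocs_total >= 0 & cybocs_total <= 40)
  assert_that(all(ok), "CY-BOCS total outside [0, 40]")
  ifelse(is.na(cybocs_total), NA_character_,
         ifelse(cybocs_total >= 24, "severe", "mild_moderate"))
}

vif_or_na <- function(fit) {
  # VIF needs >= 2 non-intercept model terms
  nt <- length(attr(terms(fit), "term.labels"))
  if (nt < 2) return(setNames(rep(NA_real_, nt),
                              attr(terms(fit), "term.labels")))
  car::vif(fit)
}

coef_table <- function(fit, conf = 0.95) {
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  est <- sm[keep, 1]; se <- sm[keep, 2]; p <- sm[keep, 4]
  z <- qnorm(1 - (1 - conf) / 2)
  data.frame(predictor = rownames(sm)[keep], estimate = est, se = se,
             ci_lower = est - z * se, ci_upper = est + z * se,
             p = p, p_adj = bh_fdr(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Ordinary least squares with diagnostics and BH-FDR over predictors
#'
#' Fits the model by OLS on complete cases (listwise deletion), reporting
#' per-predictor estimate, Wald 95% CI, SE, p, and Benjamini-Hochberg
#' adjusted p across the model's non-intercept predictors. Diagnostics:
#' Shapiro-Wilk residual-normality p, variance inflation factors (flagged
#' at >= 5), and a residual-vs-fitted table for visual homoscedasticity
#' assessment (no automated decision is made).
#'
#' @param formula model formula
#' @param data data.frame (one row per proband)
#' @param vif_flag VIF flag threshold (default 5)
#' @return list of class `triodnv_fit`: `coefficients` (per-predictor
#'   table), `diagnostics` (shapiro_p, vif, vif_flagged, n_used,
#'   excluded_ids), `residual_table`, `fit`
#' @export
fit_linear <- function(formula, data, vif_flag = 5) {
  vars <- all.vars(formula)
  assert_that(all(vars %in% names(data)), "formula variable missing: %s",
              paste(setdiff(vars, names(data)), collapse = ","))
  cc <- complete.cases(data[vars])
  used <- data[cc, , drop = FALSE]
  fit <- lm(formula, data = used)
  if (fit$rank < length(coef(fit))) {
    collinear <- names(coef(fit))[is.na(coef(fit))]
    stop_msg("rank-deficient design; collinear columns: %s",
             paste(collinear, collapse = ","))
  }
  res <- resid(fit)
  structure(list(
    coefficients = coef_table(fit),
    diagnostics = list(
      shapiro_p = if (length(res) >= 3) shapiro.test(res)$p.value else NA,
      vif = vif_or_na(fit),
      vif_flagged = any(vif_or_na(fit) >= vif_flag, na.rm = TRUE),
      n_used = nrow(used),
      excluded_ids = if ("id" %in% names(data)) data$id[!cc] else which(!cc)),
    residual_table = data.frame(fitted = fitted(fit), residual = res),
    fit = fit), class = "triodnv_fit")
}

#' Logistic regression with McFadden R2, diagnostics and BH-FDR
#'
#' Maximum-likelihood logistic fit on complete cases with Wald CIs and
#' BH-FDR across predictors. Reports McFadden's pseudo-R2
#' (`1 - logLik(model) / logLik(null)`) with the > 0.4 good-fit flag, VIFs
#' flagged at >= 10, and an events-per-variable flag when the rarer outcome
#' supplies fewer than 10 events per predictor (small cohorts with many
#' covariates). Complete separation is an error naming the predictor with
#' the largest diverging coefficient.
#'
#' @param formula model formula; outcome must be binary (0/1, logical, or
#'   two-level factor)
#' @param data data.frame
#' @param vif_flag VIF flag threshold (default 10)
#' @return list of class `triodnv_fit` with `coefficients`, `diagnostics`
#'   (mcfadden_r2, good_fit, vif, vif_flagged, low_epv, n_used,
#'   excluded_ids), `fit`
#' @export
fit_logistic <- function(formula, data, vif_flag = 10) {
  vars <- all.vars(formula)
  assert_that(all(vars %in% names(data)), "formula variable missing: %s",
              paste(setdiff(vars, names(data)), collapse = ","))
  cc <- complete.cases(data[vars])
  used <- data[cc, , drop = FALSE]
  fit <- suppressWarnings(glm(formula, data = used, family = binomial()))
  probs <- fitted(fit)
  if (any(abs(coef(fit)[-1]) > 15) && (max(probs) > 1 - 1e-8 || min(probs) < 1e-8)) {
    worst <- names(which.max(abs(coef(fit)[-1])))
    stop_msg("complete separation detected; separating predictor: %s", worst)
  }
  null_fit <- glm(stats::update(formula, . ~ 1), data = used, family = binomial())
  mcf <- 1 - as.numeric(logLik(fit)) / as.numeric(logLik(null_fit))
  y <- fit$y
  n_events <- min(sum(y == 1), sum(y == 0))
  n_pred <- length(coef(fit)) - 1
  structure(list(
    coefficients = coef_table(fit),
    diagnostics = list(
      mcfadden_r2 = mcf,
      good_fit = mcf > 0.4,
      vif = vif_or_na(fit),
      vif_flagged = any(vif_or_na(fit) >= vif_flag, na.rm = TRUE),
      low_epv = n_events / max(1, n_pred) < 10,
      n_used = nrow(used),
      excluded_ids = if ("id" %in% names(data)) data$id[!cc] else which(!cc)),
    fit = fit), class = "triodnv_fit")
}

#' @exportS3Method base::print
print.triodnv_fit <- function(x, ...) {
  print(x$coefficients, digits = 3)
  cat(sprintf("n used: %d\n", x$diagnostics$n_used))
  invisible(x)
}

#' Minimal detectable Cohen's f2 for a fixed-df regression F test
#'
#' Solves for the effect size f2 at which the noncentral-F test with
#' numerator df `u`, denominator df `v = n - u - 1` and noncentrality
#' `lambda = f2 * (u + v + 1)` reaches the requested power at level
#' `alpha` (monotone bisection to |delta power| < 1e-6). Conventional
#' benchmarks: 0.02 small, 0.15 medium, 0.35 large.
#'
#' @param u numerator degrees of freedom (number of tested predictors)
#' @param n sample size (supply `n` or `v`)
#' @param v denominator degrees of freedom (`n - u - 1`)
#' @param alpha significance level (default 0.05)
#' @param power target power (default 0.8)
#' @return the minimal detectable f2
#' @export
minimal_detectable_f2 <- function(u, n = NULL, v = NULL, alpha = 0.05,
                                  power = 0.8) {
  assert_that(xor(is.null(n), is.null(v)), "supply exactly one of n, v")
  if (is.null(v)) v <- n - u - 1
  assert_that(v > 0, "denominator df must be positive (n > u + 1)")
  assert_that(alpha > 0 && alpha < 1 && power > alpha && power < 1,
              "need 0 < alpha < power < 1")
  crit <- qf(1 - alpha, u, v)
  pw <- function(f2) 1 - pf(crit, u, v, ncp = f2 * (u + v + 1))
  hi <- 1
  while (pw(hi) < power) hi <- hi * 2
  # pw is strictly increasing in f2 (pw(0) = alpha < power), so bisection
  # converges; tolerance well below the 1e-6 power tolerance
  lo <- 0
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (pw(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
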