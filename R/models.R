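#' Z-score standardization
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation.
#'
#' @param x numeric vector with at least two distinct values.
#' @return standardized vector (mean 0, sd 1).
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zscore undefined: zero variance",
                                    call. = FALSE)
  (x - mean(x)) / s
}

#' Significance stars
#'
#' @param p p-value(s) in \[0, 1\].
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `""`.
#' @export
stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Fit a random-intercept linear mixed model with standardized effects
#'
#' Fits `response ~ fixed effects + (1 | g)` for each grouping factor `g`
#' (independent, crossed random intercepts) by REML via lme4. Numeric fixed
#' effects are z-scored before fitting; the response is z-scored when
#' `zscore_response` is TRUE. Reports Wald-normal 95% confidence intervals
#' (`beta +/- 1.96 se`) and two-sided normal-approximation p-values with
#' significance stars. Grouping factors observed at a single level cannot
#' carry a random intercept and are dropped; if none remain the model
#' degenerates to ordinary least squares (same reporting conventions).
#'
#' @param data data.frame holding response, fixed effects and grouping
#'   factors.
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names.
#' @param random_intercepts character vector of grouping-factor column
#'   names.
#' @param zscore_response z-score the response first? (default TRUE)
#' @param zscore_fixed z-score the numeric fixed effects? (default TRUE;
#'   logical columns are converted to 0/1 and left unscaled)
#' @return list of class `lmm_result`: `terms` (data.frame with `term`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`, `stars`), `n`, `varcomp`
#'   (named group + residual variances), `converged`, `fit`.
#' @export
fit_lmm <- function(data, response, fixed, random_intercepts = character(),
                    zscore_response = TRUE, zscore_fixed = TRUE) {
  stopifnot(response %in% names(data), all(fixed %in% names(data)),
            all(random_intercepts %in% names(data)))
  d <- data
  d$.y <- if (zscore_response) zscore(d[[response]]) else d[[response]]
  for (f in fixed) {
    v <- d[[f]]
    if (is.logical(v)) v <- as.numeric(v)
    if (zscore_fixed && length(unique(v)) > 2L) v <- zscore(v)
    d[[f]] <- v
  }
  usable <- random_intercepts[vapply(random_intercepts, function(g) {
    length(unique(d[[g]])) > 1L
  }, logical(1))]

  rhs <- paste(fixed, collapse = " + ")
  if (length(usable)) {
    form <- stats::as.formula(paste(
      ".y ~", rhs, "+",
      paste(sprintf("(1 | %s)", usable), collapse = " + ")))
    fit <- lme4::lmer(form, data = d, REML = TRUE)
    cf <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, sub("^Residual$", "residual",
                                            vc$grp))
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    # a boundary (singular) fit is a valid zero variance estimate, not a
    # convergence failure
    msgs <- msgs[!grepl("singular", msgs)]
    converged <- length(msgs) == 0L
    n <- stats::nobs(fit)
  } else {
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
    cf <- summary(fit)$coefficients
    varcomp <- c(residual = summary(fit)$sigma^2)
    converged <- TRUE
    n <- stats::nobs(fit)
  }
  keep <- rownames(cf) != "(Intercept)"
  beta <- cf[keep, 1]; se <- cf[keep, 2]
  p <- 2 * stats::pnorm(-abs(beta / se))
  terms <- data.frame(
    term = rownames(cf)[keep], beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    p = p, stars = stars(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!converged) {
    warning("mixed model did not converge cleanly: ",
            paste(unlist(msgs), collapse = "; "))
  }
  structure(list(terms = terms, n = n, varcomp = varcomp,
                 converged = converged, fit = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model (n =", x$n, ")\n")
  print(x$terms, digits = 3)
  cat("Variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' OLS of network IBI on topology metrics
#'
#' Ordinary least squares of the per-network IBI on the four topology
#' metrics (size, connectance, modularity, mean co-occurrence strength),
#' reporting the coefficient vector and the coefficient of determination.
#'
#' @param ensemble ensemble metric table with columns `ibi`, `size`,
#'   `connectance`, `modularity`, `mean_strength`.
#' @param predictors predictor column names.
#' @return list: `r_squared`, `coefficients`, `n`, `fit`.
#' @export
fit_ols_r2 <- function(ensemble,
                       predictors = c("size", "connectance", "modularity",
                                      "mean_strength")) {
  stopifnot(all(c("ibi", predictors) %in% names(ensemble)))
  form <- stats::as.formula(paste("ibi ~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(form, data = ensemble)
  if (anyNA(stats::coef(fit))) {
    stop("collinear predictors: OLS design matrix is rank deficient",
         call. = FALSE)
  }
  list(r_squared = summary(fit)$r.squared,
       coefficients = stats::coef(fit),
       n = stats::nobs(fit), fit = fit)
}
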