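#' Two-sided p-value from the Student t distribution
#'
#' @param t t-statistic (finite).
#' @param df Residual degrees of freedom (>= 1).
#' @return `P(|T| >= |t|)` under Student t with `df` degrees of freedom.
#' @examples
#' t_pvalue(2.5791, 10) # 0.0275
#' @export
t_pvalue <- function(t, df) {
  if (any(!is.finite(t))) {
    abort_tmr("`t` must be finite.", class = "parameter")
  }
  if (!is.numeric(df) || any(df < 1)) {
    abort_tmr("`df` must be >= 1.", class = "parameter")
  }
  2 * stats::pt(-abs(t), df)
}

#' Ordinary least-squares fit with Wald inference
#'
#' Fits `response ~ predictors` with an intercept by ordinary least squares
#' and reports per-term coefficients, standard errors, t-statistics and
#' two-sided p-values from the Student t distribution with the residual
#' degrees of freedom, plus the model R-squared. This is the single fitting
#' routine behind every TMR model category and the joint taxa-on-lung-function
#' models.
#'
#' @param data A data frame containing the response and predictor columns.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names; default all
#'   other numeric columns (the sample column, if present, is excluded).
#' @return A `tmr_fit`: list with `coefficients` (tibble: `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`), `r_squared`,
#'   `df_resid`, `nobs`, `response`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 6), x = c(1, 2, 3, 4, 5))
#' tidy(fit_ols(d, "y", "x"))
#' @export
fit_ols <- function(data, response, predictors = NULL) {
  if (!is.data.frame(data)) {
    abort_tmr("`data` must be a data frame.", class = "validation")
  }
  predictors <- predictors %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c(response, "sample"))
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort_tmr(sprintf("Column(s) not found: %s.",
                      paste(missing_cols, collapse = ", ")),
              class = "parameter")
  }
  y <- as.numeric(data[[response]])
  x <- as.matrix(data[predictors])
  storage.mode(x) <- "double"
  n <- length(y)
  p <- ncol(x)
  if (!all(is.finite(y)) || !all(is.finite(x))) {
    abort_tmr("Non-finite values in response or predictors.",
              class = "validation")
  }
  if (n < p + 2) {
    abort_tmr(
      sprintf("Need at least %d samples for %d predictors; got %d.",
              p + 2, p, n),
      class = "insufficient_data"
    )
  }
  xi <- cbind(`(Intercept)` = 1, x)
  qrx <- qr(xi)
  if (qrx$rank < ncol(xi)) {
    dep <- colnames(xi)[qrx$pivot[(qrx$rank + 1):ncol(xi)]]
    abort_tmr(
      sprintf("Collinear predictor(s): %s.", paste(dep, collapse = ", ")),
      class = "collinearity"
    )
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- c("(Intercept)", predictors)
  coefficients <- tibble::tibble(
    term = terms,
    estimate = unname(co[, 1]),
    std.error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    p.value = unname(co[, 4])
  )
  structure(
    list(
      coefficients = coefficients,
      r_squared = sm$r.squared,
      df_resid = fit$df.residual,
      nobs = n,
      response = response
    ),
    class = "tmr_fit"
  )
}

#' @export
print.tmr_fit <- function(x, ...) {
  cat(sprintf("<tmr_fit> %s ~ %d predictor(s), n = %d, R^2 = %.4f\n",
              x$response, nrow(x$coefficients) - 1, x$nobs, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy tmr_fit
#' @export
tidy.tmr_fit <- function(x, ...) x$coefficients

#' @method glance tmr_fit
#' @export
glance.tmr_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    df.residual = x$df_resid,
    nobs = x$nobs
  )
}

#' Joint group regression (all predictors of one group at once)
#'
#' Fits one response variable on all variables of a predictor group
#' simultaneously, in the style of a multivariate-Y / multiple-X regression
#' run one response at a time (e.g. all ALR-transformed taxa as joint
#' predictors of a lung-function parameter).
#'
#' @param dataset An aligned `tmr_dataset`.
#' @param predictor_group Name of the group supplying the predictors.
#' @param response_group,response_var Group and variable of the response.
#' @return A `tmr_fit`.
#' @export
fit_group_regression <- function(dataset, predictor_group,
                                 response_group, response_var) {
  pg <- dataset$groups[[predictor_group]]
  rg <- dataset$groups[[response_group]]
  if (is.null(pg) || is.null(rg)) {
    abort_tmr("Unknown group name.", class = "parameter")
  }
  d <- dplyr::bind_cols(
    pg$data[vg_vars(pg)],
    rg$data[response_var]
  )
  fit_ols(d, response_var, vg_vars(pg))
}
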