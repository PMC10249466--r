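#' Baseline and slope features from a dose-response series
#'
#' Forced-oscillation lung-function parameters (Newtonian resistance Rn,
#' tissue damping G, tissue elastance H, total resistance Rrs, total
#' elastance Ers) are recorded at baseline and across increasing nebulized
#' methacholine doses (typically 0, 3.125, 12.5, 25 and 50 mg/mL). The TMR
#' framework summarizes each such series by two response features: the
#' baseline (the value at the lowest dose, dose 0 when present) and the
#' ordinary least-squares slope of response versus dose.
#'
#' The slope is fit on the raw dose scale by default, with the dose-0 point
#' included; `dose_scale = "log"` fits against `log(dose + 1)` instead for
#' users who prefer a log-dose response model.
#'
#' @param doses Strictly increasing non-negative numeric vector.
#' @param responses Numeric vector, same length as `doses`.
#' @param dose_scale `"linear"` (default) or `"log"` (`log(dose + 1)`).
#'
#' @return A one-row tibble with columns `baseline` and `slope`.
#' @examples
#' derive_response_features(c(0, 10, 20), c(3, 5, 7)) # baseline 3, slope 0.2
#' @export
derive_response_features <- function(doses, responses,
                                     dose_scale = c("linear", "log")) {
  dose_scale <- match.arg(dose_scale)
  if (length(doses) != length(responses)) {
    abort_tmr("`doses` and `responses` must have equal length.",
              class = "validation")
  }
  if (length(doses) < 2) {
    abort_tmr("At least 2 dose points are required for a slope.",
              class = "insufficient_data")
  }
  if (!all(is.finite(doses)) || any(doses < 0)) {
    abort_tmr("Doses must be finite and non-negative.", class = "validation")
  }
  if (!all(is.finite(responses))) {
    abort_tmr("Non-finite response value in dose-response series.",
              class = "validation")
  }
  ord <- order(doses)
  doses <- doses[ord]
  responses <- responses[ord]
  if (any(diff(doses) <= 0)) {
    abort_tmr("Doses must be strictly increasing (no duplicates).",
              class = "validation")
  }
  x <- if (dose_scale == "log") log(doses + 1) else doses
  xc <- x - mean(x)
  slope <- sum(xc * responses) / sum(xc^2)
  tibble::tibble(baseline = responses[1], slope = slope)
}

#' Reduce a wide dose-response table to baseline/slope response features
#'
#' Expects columns following the `<param>@<dose>` convention, e.g.
#' `G@0`, `G@3.125`, ..., `H@50`. Each parameter's series is summarized by
#' [derive_response_features()] into `<param>_baseline` and `<param>_slope`
#' columns. Plain (non-`@`) columns are carried through unchanged.
#'
#' @param data A data frame (sample column plus `<param>@<dose>` columns) or
#'   a [var_group].
#' @param sample_col Sample-identifier column name for data-frame input.
#' @inheritParams derive_response_features
#' @return Same container as the input, with per-parameter baseline and
#'   slope columns.
#' @export
derive_response_group <- function(data, sample_col = "sample",
                                  dose_scale = c("linear", "log")) {
  dose_scale <- match.arg(dose_scale)
  df <- as_group_data(data, sample_col)
  vars <- value_cols(df, "sample")
  dr_vars <- vars[grepl("@", vars, fixed = TRUE)]
  plain <- setdiff(vars, dr_vars)
  if (length(dr_vars) == 0) {
    abort_tmr("No `<param>@<dose>` columns found.", class = "validation")
  }
  param <- sub("@.*$", "", dr_vars)
  dose <- suppressWarnings(as.numeric(sub("^.*@", "", dr_vars)))
  if (anyNA(dose)) {
    abort_tmr("Could not parse dose from column name(s).", class = "validation")
  }
  out <- tibble::tibble(sample = df$sample)
  for (p in unique(param)) {
    cols <- dr_vars[param == p]
    d <- dose[param == p]
    feats <- purrr::map(seq_len(nrow(df)), function(i) {
      derive_response_features(d, as.numeric(df[i, cols]),
                               dose_scale = dose_scale)
    })
    feats <- dplyr::bind_rows(feats)
    out[[paste0(p, "_baseline")]] <- feats$baseline
    out[[paste0(p, "_slope")]] <- feats$slope
  }
  out[plain] <- df[plain]
  restore_container(out, data)
}
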