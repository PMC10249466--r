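#' Choose a normalizing transform for one variable
#'
#' Tests the raw values with the Shapiro-Wilk test. If normality is rejected
#' (p below `normality_alpha`), square-root and logarithm transforms are
#' applied separately and the candidate with the largest Shapiro-Wilk W
#' statistic (i.e. best normality) is chosen; otherwise the identity is
#' kept. The square root requires a non-negative minimum; the logarithm
#' requires a positive minimum, except that zeros are accommodated as
#' `ln(x + eps)` with `eps` equal to half the smallest positive value of the
#' variable (an order-preserving offset). Variables containing negative
#' values skip both transforms.
#'
#' @param x Numeric vector (at least 3 finite values, nonzero variance).
#' @param normality_alpha Normality threshold for the raw-scale gate
#'   (default 0.05).
#' @param always_compare If `TRUE`, skip the gate and always pick the
#'   candidate with the largest W.
#' @return A one-row tibble: `chosen` (`"identity"`, `"sqrt"` or `"log"`),
#'   `W_raw`, `p_raw`, `W_sqrt`, `W_log` (`NA` when a transform is
#'   inapplicable), and `log_offset` (the eps used for zeros, 0 otherwise).
#' @export
choose_transform <- function(x, normality_alpha = 0.05, always_compare = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 3) {
    abort_tmr("At least 3 finite values are required.",
              class = "insufficient_data")
  }
  if (stats::var(x) == 0) {
    abort_tmr("Constant variable: cannot assess normality.",
              class = "degenerate")
  }
  # shapiro.test caps n at 5000; subsetting is not needed at study scale
  sw <- stats::shapiro.test(x)
  rec <- tibble::tibble(
    chosen = "identity", W_raw = unname(sw$statistic), p_raw = sw$p.value,
    W_sqrt = NA_real_, W_log = NA_real_, log_offset = 0
  )
  if (!always_compare && sw$p.value >= normality_alpha) {
    return(rec)
  }
  if (min(x) >= 0) {
    sx <- sqrt(x)
    if (stats::var(sx) > 0) rec$W_sqrt <- unname(stats::shapiro.test(sx)$statistic)
    eps <- 0
    if (min(x) == 0) {
      pos <- x[x > 0]
      if (length(pos) == 0) {
        abort_tmr("Constant variable: cannot assess normality.",
                  class = "degenerate")
      }
      eps <- min(pos) / 2
    }
    lx <- log(x + eps)
    if (stats::var(lx) > 0) {
      rec$W_log <- unname(stats::shapiro.test(lx)$statistic)
      rec$log_offset <- eps
    }
  }
  w <- c(identity = rec$W_raw, sqrt = rec$W_sqrt, log = rec$W_log)
  rec$chosen <- names(which.max(w))
  rec
}

# apply a chosen transform record to a vector
apply_transform <- function(x, chosen, log_offset = 0) {
  switch(chosen,
    identity = x,
    sqrt = sqrt(x),
    log = log(x + log_offset),
    abort_tmr(sprintf("Unknown transform '%s'.", chosen), class = "parameter")
  )
}

#' PCA-based proxy-variable selection for one variable group
#'
#' Reduces a high-dimensional omics group to a small set of representative
#' observed variables in two steps. First, each variable is (optionally)
#' transformed toward normality via [choose_transform()]. Second, PCA is
#' performed on the correlation matrix of the (transformed) variables;
#' principal components contributing more than `variance_threshold` of the
#' total variance (strictly) are retained, and for each retained PC, in
#' order, the not-yet-selected variable with the largest absolute Pearson
#' correlation to the PC scores is chosen as its proxy. Proxies are kept
#' distinct across PCs so the selected set is non-redundant; ties are broken
#' by variable name. Using observed proxies instead of PC scores keeps the
#' downstream association models interpretable in the original variables.
#'
#' @param data A data frame (sample column plus numeric variables) or a
#'   [var_group] with at least 2 variables and 3 samples.
#' @param variance_threshold Retain PCs with variance fraction strictly
#'   greater than this (default 0.01).
#' @param normality_alpha,always_compare Passed to [choose_transform()];
#'   set `transform = FALSE` to skip the transform step entirely.
#' @param transform Apply the normality-guided transform step? Default `TRUE`.
#' @param sample_col Sample-identifier column name for data-frame input.
#' @return An object of class `pca_selection`: list with
#'   `selections` (tibble: `pc`, `variance_fraction`, `proxy`,
#'   `proxy_correlation`, `unconstrained_proxy`), `transforms` (one row per
#'   variable from [choose_transform()]), `reduced` (tibble of the selected
#'   proxy variables on their transformed scale), `scores` (PC score
#'   matrix), and `variance_fractions` (all PCs). Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
pca_select <- function(data, variance_threshold = 0.01,
                       normality_alpha = 0.05, always_compare = FALSE,
                       transform = TRUE, sample_col = "sample") {
  if (!is_scalar_number(variance_threshold) ||
      variance_threshold < 0 || variance_threshold >= 1) {
    abort_tmr("`variance_threshold` must be in [0, 1).", class = "parameter")
  }
  df <- as_group_data(data, sample_col)
  vars <- value_cols(df, "sample")
  if (length(vars) < 2) {
    abort_tmr("At least 2 variables are required for PCA.",
              class = "insufficient_data")
  }
  if (nrow(df) < 3) {
    abort_tmr("At least 3 samples are required.", class = "insufficient_data")
  }
  m <- as.matrix(df[vars])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    abort_tmr(
      sprintf("Constant variable(s): %s. Filter before selection.",
              paste(vars[sds == 0], collapse = ", ")),
      class = "degenerate"
    )
  }

  if (transform) {
    transforms <- purrr::map(vars, function(v) {
      rec <- choose_transform(m[, v], normality_alpha = normality_alpha,
                              always_compare = always_compare)
      dplyr::mutate(rec, variable = v, .before = 1)
    })
    transforms <- dplyr::bind_rows(transforms)
    for (i in seq_along(vars)) {
      m[, vars[i]] <- apply_transform(m[, vars[i]], transforms$chosen[i],
                                      transforms$log_offset[i])
    }
  } else {
    transforms <- tibble::tibble(
      variable = vars, chosen = "identity",
      W_raw = NA_real_, p_raw = NA_real_,
      W_sqrt = NA_real_, W_log = NA_real_, log_offset = 0
    )
  }

  # PCA on the correlation matrix == PCA of z-scored variables
  pca <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pca$sdev^2
  vf <- ev / sum(ev)
  retained <- which(vf > variance_threshold)
  z <- scale(m)

  chosen_proxies <- character(0)
  sel <- purrr::map(retained, function(k) {
    r <- as.numeric(stats::cor(z, pca$x[, k]))
    names(r) <- vars
    ord <- order(-abs(r), vars)
    unconstrained <- vars[ord][1]
    avail <- vars[ord][!vars[ord] %in% chosen_proxies]
    proxy <- avail[1]
    chosen_proxies <<- c(chosen_proxies, proxy)
    tibble::tibble(
      pc = k, variance_fraction = vf[k], proxy = proxy,
      proxy_correlation = r[[proxy]],
      unconstrained_proxy = unconstrained
    )
  })
  selections <- dplyr::bind_rows(sel)

  reduced <- tibble::tibble(sample = df$sample)
  reduced[selections$proxy] <- as.data.frame(m[, selections$proxy, drop = FALSE])

  structure(
    list(
      selections = selections,
      transforms = transforms,
      reduced = reduced,
      scores = pca$x,
      variance_fractions = vf,
      variance_threshold = variance_threshold
    ),
    class = "pca_selection"
  )
}

#' @export
print.pca_selection <- function(x, ...) {
  cat(sprintf(
    "<pca_selection> %d of %d PCs retained (> %.3g variance fraction), %.1f%% variance\n",
    nrow(x$selections), length(x$variance_fractions), x$variance_threshold,
    100 * sum(x$selections$variance_fraction)
  ))
  print(x$selections)
  invisible(x)
}

#' @method tidy pca_selection
#' @export
tidy.pca_selection <- function(x, ...) x$selections

#' @method glance pca_selection
#' @export
glance.pca_selection <- function(x, ...) {
  tibble::tibble(
    n_pcs_retained = nrow(x$selections),
    n_variables = length(x$variance_fractions),
    cumulative_variance = sum(x$selections$variance_fraction),
    n_transformed = sum(x$transforms$chosen != "identity")
  )
}

#' Apply proxy selection to every measured group of a dataset
#'
#' Runs [pca_select()] on each measured group and replaces it by its reduced
#' proxy table; treatment and response groups pass through unchanged. Groups
#' whose variable count is already at or below `min_variables` are kept
#' whole.
#'
#' @param dataset An aligned `tmr_dataset` (measured groups already on their
#'   modeling scale, e.g. after [transform_measured()]).
#' @param min_variables Skip selection for groups with this many variables
#'   or fewer (default 3).
#' @inheritParams pca_select
#' @return A list with `dataset` (reduced, re-aligned) and `selection`
#'   (named list of `pca_selection` objects per reduced group).
#' @export
select_dataset <- function(dataset, variance_threshold = 0.01,
                           normality_alpha = 0.05, always_compare = FALSE,
                           transform = TRUE, min_variables = 3) {
  selections <- list()
  groups <- lapply(dataset$groups, function(g) {
    if (g$role != "measured" || length(vg_vars(g)) <= min_variables) {
      return(g)
    }
    sel <- pca_select(g$data, variance_threshold = variance_threshold,
                      normality_alpha = normality_alpha,
                      always_compare = always_compare, transform = transform)
    selections[[g$name]] <<- sel
    g$data <- sel$reduced
    g$meta$proxy_selected <- TRUE
    g
  })
  list(dataset = align_dataset(unname(groups)), selection = selections)
}
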