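#' Convert a taxa count table to relative abundances
#'
#' Divides each sample row by its row sum so rows sum to one. Counts must be
#' non-negative with at least one positive entry per sample.
#'
#' @param data A data frame (sample column plus taxa columns) or a
#'   [var_group] with compositional values.
#' @param sample_col Sample-identifier column name for data-frame input.
#' @return Same container as the input, with rows normalized to sum to 1.
#' @examples
#' to_relative_abundance(
#'   data.frame(sample = "s1", a = 5, b = 5, c = 10)
#' )
#' @export
to_relative_abundance <- function(data, sample_col = "sample") {
  df <- as_group_data(data, sample_col)
  vars <- value_cols(df, "sample")
  m <- as.matrix(df[vars])
  if (any(!is.finite(m)) || any(m < 0)) {
    abort_tmr("Counts must be finite and non-negative.", class = "validation")
  }
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort_tmr(
      sprintf("All-zero sample row(s): %s.",
              paste(df$sample[rs == 0], collapse = ", ")),
      class = "degenerate"
    )
  }
  df[vars] <- m / rs
  restore_container(df, data)
}

#' Keep the most abundant taxa, pooling the rest into a remainder bucket
#'
#' Ranks taxa by mean relative abundance across samples and keeps the top
#' `n`; all remaining taxa are summed into a single `Remainder` column so
#' per-sample totals are preserved exactly. Low-abundance taxa are pooled
#' rather than dropped because they can carry large coefficients of
#' variation while contributing little abundance. Ties in mean abundance at
#' the boundary are broken by taxon name (lexicographic) for determinism.
#'
#' @param data A relative-abundance data frame or [var_group].
#' @param n Number of taxa to keep (default 10).
#' @param remainder Name for the pooled column.
#' @param sample_col Sample-identifier column name for data-frame input.
#' @return Same container, with `n` taxa columns plus the remainder column.
#' @export
select_top_taxa <- function(data, n = 10, remainder = "Remainder",
                            sample_col = "sample") {
  if (!is_scalar_number(n) || n < 1) {
    abort_tmr("`n` must be a positive integer.", class = "parameter")
  }
  df <- as_group_data(data, sample_col)
  vars <- value_cols(df, "sample")
  m <- as.matrix(df[vars])
  means <- colMeans(m)
  ord <- order(-means, colnames(m)) # descending mean, name breaks ties
  keep <- colnames(m)[ord][seq_len(min(n, ncol(m)))]
  rest <- setdiff(colnames(m), keep)
  out <- tibble::tibble(sample = df$sample)
  out[keep] <- df[keep]
  out[[remainder]] <- if (length(rest) > 0) rowSums(m[, rest, drop = FALSE]) else 0
  restore_container(out, data)
}

#' Additive log-ratio (ALR) transform of a compositional table
#'
#' Maps a D-part composition to D-1 unconstrained coordinates:
#' for sample i and non-reference taxon j,
#' `alr_ij = ln((x_ij + pseudocount) / (x_i,ref + pseudocount))`.
#' The transformed values can then be treated as ordinary real-valued
#' predictors in linear models and Euclidean distance computations.
#'
#' The reference component defaults to the `Remainder` pooling bucket when
#' present (it is stable and always positive after pooling); otherwise the
#' taxon with minimal variance of log abundance is used. Both choices are
#' reported in the result's attributes so the coordinate system is always
#' explicit. A small additive pseudocount (default `1e-6` on the
#' relative-abundance scale) guards against zeros; it may be set to 0 only
#' when all entries are positive.
#'
#' @param data A relative-abundance data frame or [var_group].
#' @param reference Reference taxon name; default as described above.
#' @param pseudocount Non-negative additive pseudocount (default `1e-6`).
#' @param sample_col Sample-identifier column name for data-frame input.
#' @return Same container with one fewer column (the reference is consumed),
#'   carrying attributes `alr_reference` and `alr_pseudocount` (on the
#'   tibble, or in `meta` for a `var_group`).
#' @examples
#' alr_transform(
#'   data.frame(sample = "s1", a = 0.5, b = 0.25, c = 0.25),
#'   reference = "c", pseudocount = 0
#' )
#' @export
alr_transform <- function(data, reference = NULL, pseudocount = 1e-6,
                          sample_col = "sample") {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      !is.finite(pseudocount) || pseudocount < 0) {
    abort_tmr("`pseudocount` must be a single non-negative number.",
              class = "parameter")
  }
  df <- as_group_data(data, sample_col)
  vars <- value_cols(df, "sample")
  m <- as.matrix(df[vars])
  if (any(!is.finite(m)) || any(m < 0)) {
    abort_tmr("Compositional values must be finite and non-negative.",
              class = "validation")
  }
  if (is.null(reference)) {
    reference <- if ("Remainder" %in% vars) {
      "Remainder"
    } else {
      lv <- apply(log(m + max(pseudocount, 1e-12)), 2, stats::var)
      vars[which.min(lv)]
    }
  }
  if (!reference %in% vars) {
    abort_tmr(sprintf("Reference taxon '%s' not found.", reference),
              class = "parameter")
  }
  if (pseudocount == 0 && any(m == 0)) {
    abort_tmr("pseudocount = 0 requires strictly positive values.",
              class = "parameter")
  }
  ref_vals <- m[, reference] + pseudocount
  keep <- setdiff(vars, reference)
  out <- tibble::tibble(sample = df$sample)
  out[keep] <- as.data.frame(log((m[, keep, drop = FALSE] + pseudocount) / ref_vals))
  if (is_var_group(data)) {
    data$data <- out
    data$meta$alr_reference <- reference
    data$meta$alr_pseudocount <- pseudocount
    data$meta$compositional <- FALSE # now unconstrained coordinates
    data
  } else {
    attr(out, "alr_reference") <- reference
    attr(out, "alr_pseudocount") <- pseudocount
    out
  }
}
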