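# Internal helpers shared across modules.

abort_tmr <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("tmrnet_error_", class), "tmrnet_error"), ...)
}

# numeric columns of a data frame, excluding the sample-id column
value_cols <- function(data, sample_col) {
  setdiff(names(data), sample_col)
}

check_sample_col <- function(data, sample_col) {
  if (!sample_col %in% names(data)) {
    abort_tmr(
      sprintf("Sample column '%s' not found in data.", sample_col),
      class = "validation"
    )
  }
  vars <- value_cols(data, sample_col)
  bad <- vars[!vapply(data[vars], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort_tmr(
      sprintf("Non-numeric variable column(s): %s.", paste(bad, collapse = ", ")),
      class = "validation"
    )
  }
  invisible(data)
}

# strictly upper triangle of a square matrix, flattened column-major
upper_tri_vec <- function(m) {
  m[upper.tri(m, diag = FALSE)]
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
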