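#' Create a variable group
#'
#' A variable group is one named block of numeric variables measured over a
#' common set of samples, together with its role in the
#' treatment--measured--response (TMR) framework. Treatment groups hold
#' experimenter-controlled covariates (binary treatment indicators, weight),
#' measured groups hold omics layers (taxa abundances, metabolites, gene
#' expression), and response groups hold clinical outcome features
#' (lung-function baselines and dose-response slopes).
#'
#' Samples with any missing value are dropped from the group (with a message),
#' since the downstream regression machinery requires complete cases; the
#' number dropped is recorded in `meta$n_dropped`.
#'
#' @param data A data frame with one row per sample: a sample-identifier
#'   column plus numeric variable columns.
#' @param name Short unique label for the group (e.g. `"16S_DNA"`).
#' @param role One of `"treatment"`, `"measured"`, `"response"`.
#' @param sample_col Name of the sample-identifier column. Default `"sample"`.
#' @param compositional Logical; `TRUE` for taxa tables that are parts of a
#'   whole and need log-ratio treatment before modeling.
#' @param meta Named list of free-form annotations.
#'
#' @return An object of class `var_group`.
#' @examples
#' g <- var_group(
#'   data.frame(sample = c("m1", "m2"), taxon_a = c(1, 2), taxon_b = c(3, 4)),
#'   name = "16S_DNA", role = "measured", compositional = TRUE
#' )
#' g
#' @export
var_group <- function(data, name, role = c("measured", "treatment", "response"),
                      sample_col = "sample", compositional = FALSE,
                      meta = list()) {
  role <- match.arg(role)
  if (!is.data.frame(data)) {
    abort_tmr("`data` must be a data frame.", class = "validation")
  }
  check_sample_col(data, sample_col)
  data <- tibble::as_tibble(data)
  samples <- as.character(data[[sample_col]])
  if (anyDuplicated(samples) > 0) {
    abort_tmr(
      sprintf("Duplicate sample identifiers in group '%s'.", name),
      class = "validation"
    )
  }
  vars <- value_cols(data, sample_col)
  if (length(vars) == 0) {
    abort_tmr(sprintf("Group '%s' has no variable columns.", name),
              class = "validation")
  }
  if (anyDuplicated(vars) > 0) {
    abort_tmr(sprintf("Duplicate variable names in group '%s'.", name),
              class = "validation")
  }
  values <- as.matrix(data[vars])
  complete <- stats::complete.cases(values)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("Group '%s': dropped %d sample(s) with missing values.",
                    name, n_dropped))
    data <- data[complete, , drop = FALSE]
    samples <- samples[complete]
  }
  if (nrow(data) == 0) {
    abort_tmr(sprintf("Group '%s' has no complete samples.", name),
              class = "validation")
  }
  out <- tibble::tibble(sample = samples)
  out[vars] <- data[vars]
  meta$compositional <- isTRUE(compositional) || isTRUE(meta$compositional)
  meta$n_dropped <- n_dropped
  structure(
    list(name = as.character(name), role = role, data = out, meta = meta),
    class = "var_group"
  )
}

#' @export
print.var_group <- function(x, ...) {
  cat(sprintf("<var_group> %s [%s]%s: %d samples x %d variables\n",
              x$name, x$role,
              if (isTRUE(x$meta$compositional)) " (compositional)" else "",
              nrow(x$data), length(vg_vars(x))))
  invisible(x)
}

#' @method as_tibble var_group
#' @export
as_tibble.var_group <- function(x, ...) x$data

# sample ids, variable names and the numeric matrix of a group
vg_samples <- function(g) g$data$sample
vg_vars <- function(g) setdiff(names(g$data), "sample")
vg_matrix <- function(g) {
  m <- as.matrix(g$data[vg_vars(g)])
  rownames(m) <- vg_samples(g)
  m
}

# replace the value block of a group, keeping samples/role/meta
vg_replace_values <- function(g, values, vars = colnames(values)) {
  out <- tibble::tibble(sample = vg_samples(g))
  out[vars] <- as.data.frame(values)
  g$data <- out
  g
}

is_var_group <- function(x) inherits(x, "var_group")

# Coerce a data frame (or pass through a var_group) for compositional ops.
as_group_data <- function(data, sample_col = "sample") {
  if (is_var_group(data)) return(data$data)
  check_sample_col(data, sample_col)
  out <- tibble::as_tibble(data)
  if (sample_col != "sample") {
    names(out)[names(out) == sample_col] <- "sample"
  }
  out$sample <- as.character(out$sample)
  out
}

# Return result in the same container the caller supplied.
restore_container <- function(result, original) {
  if (is_var_group(original)) {
    original$data <- result
    original
  } else {
    result
  }
}
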