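#' Align variable groups on their shared samples
#'
#' All TMR regressions, distances and ordinations operate on the samples
#' common to every variable group. `align_dataset()` takes the intersection
#' of sample identifiers across groups (in the order they appear in the first
#' group), row-subsets and row-orders every group to that index, and returns
#' the aligned collection. Identifiers are matched by strict string equality.
#'
#' @param groups A list of [var_group] objects.
#'
#' @return A `tmr_dataset`: a list with `groups` (named list of aligned
#'   `var_group`s) and `sample_index` (the canonical shared sample order).
#'   Per-group dropped-sample counts from alignment are recorded in each
#'   group's `meta$n_dropped_alignment`.
#' @examples
#' a <- var_group(data.frame(sample = c("m1", "m2", "m3"), x = 1:3),
#'                name = "A", role = "treatment")
#' b <- var_group(data.frame(sample = c("m2", "m3", "m4"), y = 4:6),
#'                name = "B", role = "measured")
#' align_dataset(list(a, b))$sample_index
#' @export
align_dataset <- function(groups) {
  if (is_var_group(groups)) groups <- list(groups)
  if (!is.list(groups) || length(groups) == 0 ||
      !all(vapply(groups, is_var_group, logical(1)))) {
    abort_tmr("`groups` must be a non-empty list of var_group objects.",
              class = "validation")
  }
  nms <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(nms) > 0) {
    abort_tmr(
      sprintf("Duplicate group names: %s.",
              paste(unique(nms[duplicated(nms)]), collapse = ", ")),
      class = "validation"
    )
  }
  sample_sets <- lapply(groups, vg_samples)
  idx <- Reduce(intersect, sample_sets)
  if (length(idx) == 0) {
    # name a disjoint pair to make the failure actionable
    pair <- NULL
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i < j && length(intersect(sample_sets[[i]], sample_sets[[j]])) == 0) {
          pair <- c(nms[i], nms[j])
          break
        }
      }
      if (!is.null(pair)) break
    }
    abort_tmr(
      if (is.null(pair)) "Empty sample intersection across groups."
      else sprintf("Empty sample intersection: groups '%s' and '%s' share no samples.",
                   pair[1], pair[2]),
      class = "alignment"
    )
  }
  groups <- lapply(groups, function(g) {
    dropped <- sum(!vg_samples(g) %in% idx)
    g$data <- g$data[match(idx, vg_samples(g)), , drop = FALSE]
    g$meta$n_dropped_alignment <- dropped
    g
  })
  names(groups) <- nms
  structure(list(groups = groups, sample_index = idx), class = "tmr_dataset")
}

#' @export
print.tmr_dataset <- function(x, ...) {
  cat(sprintf("<tmr_dataset> %d samples, %d groups\n",
              length(x$sample_index), length(x$groups)))
  for (g in x$groups) {
    cat(sprintf("  %-20s %-10s %d variables\n", g$name, g$role,
                length(vg_vars(g))))
  }
  invisible(x)
}

# groups of a given role, as a named list
dataset_groups <- function(dataset, role) {
  Filter(function(g) g$role == role, dataset$groups)
}

#' Read a variable group from a delimited file
#'
#' Expects one row per sample: the first column holds sample identifiers and
#' the header row holds variable names. Tab- and comma-separated files are
#' both accepted (inferred from the extension unless `sep` is given).
#'
#' @param path File path.
#' @param name,role,compositional,meta Passed to [var_group()].
#' @param sep Field separator; default inferred (`","` for `.csv`, else tab).
#' @return A [var_group].
#' @export
read_variable_group <- function(path, name, role, compositional = FALSE,
                                meta = list(), sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  names(raw)[1] <- "sample"
  var_group(raw, name = name, role = role, sample_col = "sample",
            compositional = compositional, meta = meta)
}

#' Write a variable group to a TSV file
#'
#' @param group A [var_group].
#' @param path Output path.
#' @param comment Optional comment line(s) written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_variable_group <- function(group, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con)
  }
  utils::write.table(group$data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dataset from a YAML manifest
#'
#' The manifest maps files to groups:
#' ```yaml
#' groups:
#'   - file: dna_counts.tsv
#'     name: 16S_DNA
#'     role: measured
#'     compositional: true
#'   - file: responses.tsv
#'     name: flexiVent
#'     role: response
#'     dose_response: true   # columns follow the <param>@<dose> convention
#' ```
#' Paths are resolved relative to the manifest's directory. Groups flagged
#' `dose_response` are reduced to `<param>_baseline` / `<param>_slope`
#' features via [derive_response_group()] before alignment.
#'
#' @param path Path to the manifest YAML.
#' @param dose_scale Dose scale for slope features; see
#'   [derive_response_features()].
#' @return An aligned `tmr_dataset`.
#' @export
read_dataset <- function(path, dose_scale = c("linear", "log")) {
  dose_scale <- match.arg(dose_scale)
  manifest <- yaml::read_yaml(path)
  if (is.null(manifest$groups)) {
    abort_tmr("Manifest has no `groups` entry.", class = "config")
  }
  base <- dirname(path)
  groups <- lapply(manifest$groups, function(entry) {
    g <- read_variable_group(
      file.path(base, entry$file),
      name = entry$name,
      role = entry$role,
      compositional = isTRUE(entry$compositional)
    )
    if (isTRUE(entry$dose_response)) {
      g <- derive_response_group(g, dose_scale = dose_scale)
    }
    g
  })
  align_dataset(groups)
}

#' Write a dataset as per-group TSVs plus a manifest
#'
#' @param dataset A `tmr_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dataset$groups, function(g) {
    fname <- paste0(gsub("[^A-Za-z0-9_.-]", "_", g$name), ".tsv")
    comment <- if (!is.null(g$meta$alr_reference)) {
      sprintf("ALR-transformed; reference = %s, pseudocount = %g",
              g$meta$alr_reference, g$meta$alr_pseudocount)
    }
    write_variable_group(g, file.path(dir, fname), comment = comment)
    list(file = fname, name = g$name, role = g$role,
         compositional = isTRUE(g$meta$compositional))
  })
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(groups = unname(entries)), manifest_path)
  invisible(manifest_path)
}
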