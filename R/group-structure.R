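#' Euclidean inter-sample distance matrix for one variable group
#'
#' Computes pairwise Euclidean distances between samples using only the
#' group's variables. Because variable groups mix units (log-ratio
#' coordinates, relative amounts, expression levels), variables are z-scored
#' before the distance computation by default; pass `standardize = FALSE`
#' for raw-scale distances.
#'
#' @param data A data frame (sample column plus numeric variables) or a
#'   [var_group]; at least 2 samples, all values finite.
#' @param standardize Z-score each variable first? Default `TRUE`.
#' @param sample_col Sample-identifier column name for data-frame input.
#' @return A [stats::dist] object labeled by sample identifiers.
#' @export
euclidean_distances <- function(data, standardize = TRUE,
                                sample_col = "sample") {
  df <- as_group_data(data, sample_col)
  m <- as.matrix(df[value_cols(df, "sample")])
  rownames(m) <- df$sample
  if (nrow(m) < 2) {
    abort_tmr("At least 2 samples are required.", class = "insufficient_data")
  }
  if (any(!is.finite(m))) {
    abort_tmr("Non-finite values in group.", class = "validation")
  }
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    keep <- sds > 0
    if (!any(keep)) {
      abort_tmr("All variables are constant; distances are degenerate.",
                class = "degenerate")
    }
    m <- scale(m[, keep, drop = FALSE])
  }
  stats::dist(m, method = "euclidean")
}

#' Mantel correlation between two distance matrices
#'
#' The Pearson correlation between the corresponding strictly-upper-triangle
#' entries of two inter-sample distance matrices over the same samples —
#' the Mantel test statistic, used here as a similarity between variable
#' groups (no permutation test is attached).
#'
#' @param a,b [stats::dist] objects or square symmetric matrices over
#'   identical samples in identical order (at least 3 samples).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
mantel_correlation <- function(a, b) {
  am <- as.matrix(a)
  bm <- as.matrix(b)
  if (!identical(dim(am), dim(bm))) {
    abort_tmr("Distance matrices differ in size.", class = "alignment")
  }
  if (!is.null(rownames(am)) && !is.null(rownames(bm)) &&
      !identical(rownames(am), rownames(bm))) {
    abort_tmr("Distance matrices are labeled with different samples/orders.",
              class = "alignment")
  }
  if (nrow(am) < 3) {
    abort_tmr("At least 3 samples are required.", class = "insufficient_data")
  }
  x <- upper_tri_vec(am)
  y <- upper_tri_vec(bm)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_tmr("Zero variance in a distance matrix upper triangle.",
              class = "degenerate")
  }
  stats::cor(x, y)
}

#' Inter-group dendrogram from Mantel correlations
#'
#' Summarizes how variable groups (omics layers, treatments, responses)
#' relate to one another as whole blocks: each group is reduced to its
#' Euclidean inter-sample distance matrix, every pair of groups is compared
#' with the Mantel correlation, the dissimilarity between groups is defined
#' as `1 - |cor|`, and the groups are hierarchically clustered with Ward's
#' minimum variance criterion. Groups whose samples co-vary — however
#' different their units — end up adjacent in the dendrogram.
#'
#' @param dataset An aligned `tmr_dataset`, or a list of sample-aligned
#'   [var_group]s (at least 2).
#' @param standardize Z-score variables before distances (see
#'   [euclidean_distances()]).
#' @param method Agglomeration criterion passed to [stats::hclust()]:
#'   `"ward.D"` (default; Lance-Williams Ward update applied directly to the
#'   `1 - |cor|` dissimilarities) or `"ward.D2"` (the squared-update
#'   variant).
#' @return A `group_dendrogram`: list with `hclust` (the merge tree),
#'   `dissimilarity` (matrix of `1 - |cor|`), `mantel` (matrix of Mantel
#'   correlations) and `method`.
#' @export
group_dendrogram <- function(dataset, standardize = TRUE,
                             method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  groups <- if (inherits(dataset, "tmr_dataset")) dataset$groups else dataset
  if (length(groups) < 2) {
    abort_tmr("At least 2 groups are required.", class = "insufficient_data")
  }
  nms <- vapply(groups, function(g) g$name, character(1))
  dists <- lapply(groups, euclidean_distances, standardize = standardize)
  k <- length(groups)
  cors <- diag(1, k)
  dimnames(cors) <- list(nms, nms)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cors[i, j] <- cors[j, i] <- mantel_correlation(dists[[i]], dists[[j]])
    }
  }
  dis <- 1 - abs(cors)
  diag(dis) <- 0
  hc <- stats::hclust(stats::as.dist(dis), method = method)
  structure(
    list(hclust = hc, dissimilarity = dis, mantel = cors, method = method),
    class = "group_dendrogram"
  )
}

#' @export
print.group_dendrogram <- function(x, ...) {
  cat(sprintf("<group_dendrogram> %d groups, %s linkage on 1-|Mantel cor|\n",
              nrow(x$dissimilarity), x$method))
  print(round(x$dissimilarity, 4))
  invisible(x)
}

#' @method tidy group_dendrogram
#' @export
tidy.group_dendrogram <- function(x, ...) {
  k <- nrow(x$dissimilarity)
  nms <- rownames(x$dissimilarity)
  pairs <- which(upper.tri(x$dissimilarity), arr.ind = TRUE)
  tibble::tibble(
    group_a = nms[pairs[, 1]],
    group_b = nms[pairs[, 2]],
    mantel_correlation = x$mantel[pairs],
    dissimilarity = x$dissimilarity[pairs]
  )
}

#' Write a group dendrogram as Newick
#'
#' Branch lengths carry the Ward merge heights.
#'
#' @param dendrogram A `group_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

# names of the two groups joined at the dendrogram's first (lowest) merge
first_merge_pair <- function(dendrogram) {
  hc <- dendrogram$hclust
  m <- hc$merge[1, ]
  sort(unname(hc$labels[-m]))
}
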