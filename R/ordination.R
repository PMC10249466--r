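#' Classical multidimensional scaling (principal coordinates)
#'
#' Embeds samples in `k` dimensions from their inter-sample distances by
#' double-centering `-0.5 * D^2` and eigen-decomposing, the standard view of
#' community similarity/dissimilarity as 2-D spatial distance. Axes are
#' scaled by the square roots of their (non-negative) eigenvalues; negative
#' eigenvalues, which arise for non-Euclidean dissimilarities, are reported
#' but contribute no axis.
#'
#' @param d A [stats::dist] object or square distance matrix.
#' @param k Number of axes (default 2; must be < number of samples).
#' @return A `tmr_mds`: list with `coordinates` (tibble: `sample`,
#'   `MDS1`..`MDSk`), `eigenvalues` (all of them, decreasing) and
#'   `variance_explained` (per returned axis, relative to the sum of
#'   positive eigenvalues).
#' @export
classical_mds <- function(d, k = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (!is_scalar_number(k) || k < 1 || k >= n) {
    abort_tmr("`k` must be a positive integer below the number of samples.",
              class = "parameter")
  }
  fit <- suppressWarnings(stats::cmdscale(dm, k = k, eig = TRUE))
  pts <- fit$points
  labels <- rownames(dm) %||% as.character(seq_len(n))
  coords <- tibble::tibble(sample = labels)
  if (ncol(pts) > 0) {
    colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
    coords <- dplyr::bind_cols(coords, tibble::as_tibble(pts))
  }
  pos_sum <- sum(pmax(fit$eig, 0))
  structure(
    list(
      coordinates = coords,
      eigenvalues = fit$eig,
      variance_explained = if (ncol(pts) > 0) fit$eig[seq_len(ncol(pts))] / pos_sum
                           else numeric(0)
    ),
    class = "tmr_mds"
  )
}

#' @export
print.tmr_mds <- function(x, ...) {
  cat(sprintf("<tmr_mds> %d samples, %d axes (%.1f%% variance)\n",
              nrow(x$coordinates), length(x$variance_explained),
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' @method tidy tmr_mds
#' @export
tidy.tmr_mds <- function(x, ...) x$coordinates

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sum of squares of an inter-sample distance matrix by
#' covariates and tests each term with a pseudo-F statistic whose null
#' distribution is obtained by randomly permuting sample labels. The
#' partition works on the Gower-centered inner-product matrix
#' `G = -0.5 * C D^2 C`; terms are added sequentially (type-I) in the order
#' given, so earlier covariates absorb shared variance, matching the common
#' sequential-SS convention. P-values use the add-one estimator
#' `(1 + #{F* >= F}) / (1 + n_perm)`, so the smallest attainable p-value is
#' `1 / (n_perm + 1)`.
#'
#' @param d A [stats::dist] or square distance matrix over the samples.
#' @param covariates A data frame of covariates (numeric or factor), one row
#'   per sample in the order of `d`'s labels; a `sample` column, when
#'   present, is checked against `d`'s labels and dropped.
#' @param n_perm Number of permutations (default 999, minimum 99).
#' @param seed Integer seed for the permutation stream.
#' @param by `"terms"` (sequential, default) or `"margin"` (each term
#'   adjusted for all others).
#' @return A `tmr_permanova`: tibble of class with one row per term plus
#'   `Residual` and `Total` rows, columns `term`, `df`, `sum_of_squares`,
#'   `r_squared`, `pseudo_F`, `p_value`; attributes `n_perm` and `seed`.
#' @export
permanova <- function(d, covariates, n_perm = 999, seed = 1,
                      by = c("terms", "margin")) {
  by <- match.arg(by)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (!is.data.frame(covariates)) {
    abort_tmr("`covariates` must be a data frame.", class = "validation")
  }
  covariates <- as.data.frame(covariates)
  if ("sample" %in% names(covariates)) {
    labs <- rownames(dm)
    if (!is.null(labs) && !identical(as.character(covariates$sample), labs)) {
      abort_tmr("Covariate samples do not match distance-matrix labels/order.",
                class = "alignment")
    }
    covariates$sample <- NULL
  }
  if (nrow(covariates) != n) {
    abort_tmr("Covariate rows must match the number of samples.",
              class = "alignment")
  }
  if (!is_scalar_number(n_perm) || n_perm < 99) {
    abort_tmr("`n_perm` must be at least 99.", class = "parameter")
  }

  # Gower-centered inner-product matrix
  a <- -0.5 * dm^2
  cmat <- diag(n) - matrix(1 / n, n, n)
  g <- cmat %*% a %*% cmat
  ss_total <- sum(diag(g))

  # per-term design blocks (factors expanded to indicator contrasts)
  terms <- names(covariates)
  blocks <- lapply(terms, function(tm) {
    v <- covariates[[tm]]
    if (is.numeric(v)) {
      matrix(v, ncol = 1, dimnames = list(NULL, tm))
    } else {
      stats::model.matrix(~v)[, -1, drop = FALSE]
    }
  })
  x_full <- cbind(1, do.call(cbind, blocks))
  if (qr(x_full)$rank < ncol(x_full)) {
    abort_tmr("Covariates are rank-deficient.", class = "collinearity")
  }

  hat_of <- function(x) {
    q <- qr.Q(qr(x))
    tcrossprod(q)
  }

  # projection-difference matrix for each term, per the chosen SS type
  h_full <- hat_of(x_full)
  projs <- vector("list", length(terms))
  dfs <- numeric(length(terms))
  if (by == "terms") {
    h_prev <- hat_of(matrix(1, n, 1))
    x_acc <- matrix(1, n, 1)
    for (k in seq_along(terms)) {
      x_acc <- cbind(x_acc, blocks[[k]])
      h_k <- hat_of(x_acc)
      projs[[k]] <- h_k - h_prev
      dfs[k] <- ncol(blocks[[k]])
      h_prev <- h_k
    }
  } else {
    for (k in seq_along(terms)) {
      x_wo <- cbind(1, do.call(cbind, blocks[-k]))
      projs[[k]] <- h_full - hat_of(x_wo)
      dfs[k] <- ncol(blocks[[k]])
    }
  }
  r_proj <- diag(n) - h_full
  df_resid <- n - 1 - sum(dfs)
  if (df_resid < 1) {
    abort_tmr("No residual degrees of freedom.", class = "insufficient_data")
  }

  ss_of <- function(gp) {
    c(vapply(projs, function(p) sum(p * gp), numeric(1)), sum(r_proj * gp))
  }
  obs <- ss_of(g)
  ss_terms <- obs[seq_along(terms)]
  ss_resid <- obs[length(obs)]
  f_obs <- (ss_terms / dfs) / (ss_resid / df_resid)

  # permutation null: relabel samples by permuting G's rows and columns
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    sp <- ss_of(g[perm, perm])
    fp <- (sp[seq_along(terms)] / dfs) / (sp[length(sp)] / df_resid)
    exceed <- exceed + (fp >= f_obs)
  }
  p_values <- (1 + exceed) / (1 + n_perm)

  out <- tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_resid, n - 1),
    sum_of_squares = c(ss_terms, ss_resid, ss_total),
    r_squared = c(ss_terms, ss_resid, ss_total) / ss_total,
    pseudo_F = c(f_obs, NA_real_, NA_real_),
    p_value = c(p_values, NA_real_, NA_real_)
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "by") <- by
  class(out) <- c("tmr_permanova", class(out))
  out
}

#' @method tidy tmr_permanova
#' @export
tidy.tmr_permanova <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tmr_permanova")
  out
}
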