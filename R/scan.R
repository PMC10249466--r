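#' Scan a dataset with the three TMR model categories
#'
#' Fits the covariate-adjusted linear models that define the
#' treatment--measured--response framework and returns every tested
#' association as one row of an edge table:
#'
#' * **Category 1** (treatment on measured): each measured variable is
#'   regressed on the treatment covariates; one edge per covariate.
#' * **Category 2** (measured on measured, controlling treatment): for every
#'   ordered pair of distinct measured groups and every variable pair
#'   `(u, v)` across them, `v ~ u + covariates`; each pair therefore
#'   participates once as predictor and once as response across the two
#'   directions (see [resolve_bidirectional()]).
#' * **Category 3** (measured on response, controlling treatment): each
#'   response variable is regressed on one measured variable plus the
#'   treatment covariates.
#'
#' In categories 2 and 3 a treatment covariate can itself surface as
#' significant while a measured predictor is controlled for; such edges are
#' emitted with `covariate_surfaced = TRUE` and `model_predictor` naming the
#' measured variable that was in the model.
#'
#' @param dataset An aligned `tmr_dataset` with at least one group of each
#'   role; measured groups must already be on their modeling scale (see
#'   [transform_measured()]).
#' @param alpha_report Edges with `p >= alpha_report` are suppressed from
#'   the returned table (default 1: keep everything). Covariate-surfaced
#'   edges are only emitted below this threshold.
#' @param covariate_mode `"joint"` (default): category-1 fits include all
#'   treatment covariates in one model; `"single"`: one model per covariate.
#' @param pairs Optional two-column data frame of measured group names
#'   restricting which ordered category-2 pairs are fit. Self-pairs are an
#'   error: within-group associations are outside the framework.
#' @param categories Integer subset of `c(1, 2, 3)` to run.
#' @param adjust `"none"` (default; networks at raw p-value cutoffs) or
#'   `"BH"` to append a Benjamini-Hochberg FDR-adjusted column `p_adj`
#'   computed over the emitted non-surfaced edges.
#' @return A tibble of class `tmr_edges`: `predictor_group`, `predictor`,
#'   `response_group`, `response`, `beta`, `se`, `t`, `p`, `category`,
#'   `sign`, `covariate_surfaced`, `model_predictor`,
#'   `covariates_controlled` (plus `p_adj` when `adjust = "BH"`).
#' @export
tmr_scan <- function(dataset, alpha_report = 1,
                     covariate_mode = c("joint", "single"),
                     pairs = NULL, categories = c(1, 2, 3),
                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  covariate_mode <- match.arg(covariate_mode)
  if (!inherits(dataset, "tmr_dataset")) {
    abort_tmr("`dataset` must be a tmr_dataset.", class = "config")
  }
  if (!is_scalar_number(alpha_report) || alpha_report <= 0 || alpha_report > 1) {
    abort_tmr("`alpha_report` must be in (0, 1].", class = "parameter")
  }
  treatment <- dataset_groups(dataset, "treatment")
  measured <- dataset_groups(dataset, "measured")
  response <- dataset_groups(dataset, "response")
  if (length(treatment) == 0 || length(measured) == 0) {
    abort_tmr("A TMR scan needs at least one treatment and one measured group.",
              class = "config")
  }
  if (3 %in% categories && length(response) == 0) {
    abort_tmr("Category 3 needs a response group.", class = "config")
  }

  # covariate block: all treatment variables, labeled by their group
  cov_labels <- dplyr::bind_rows(lapply(treatment, function(g) {
    tibble::tibble(group = g$name, variable = vg_vars(g))
  }))
  cov_mat <- do.call(cbind, lapply(treatment, vg_matrix))
  colnames(cov_mat) <- cov_labels$variable
  if (qr(cbind(1, cov_mat))$rank < ncol(cov_mat) + 1) {
    abort_tmr("Treatment covariates are jointly rank-deficient.",
              class = "collinearity")
  }
  cov_string <- paste(cov_labels$variable, collapse = " + ")

  out <- list()
  emit <- function(rows) out[[length(out) + 1L]] <<- rows

  # one labeled OLS fit; returns the per-term rows (no intercept)
  scan_fit <- function(y, xmat) {
    d <- as.data.frame(xmat)
    names(d) <- paste0(".x", seq_len(ncol(xmat)))
    d$.y <- y
    fit <- fit_ols(d, ".y", setdiff(names(d), ".y"))
    fit$coefficients[-1, c("estimate", "std.error", "statistic", "p.value")]
  }

  if (1 %in% categories) {
    for (mg in measured) {
      mm <- vg_matrix(mg)
      for (m in colnames(mm)) {
        if (covariate_mode == "joint") {
          co <- scan_fit(mm[, m], cov_mat)
          emit(tibble::tibble(
            predictor_group = cov_labels$group,
            predictor = cov_labels$variable,
            response_group = mg$name, response = m,
            beta = co$estimate, se = co$std.error,
            t = co$statistic, p = co$p.value,
            category = 1L, covariate_surfaced = FALSE,
            model_predictor = NA_character_
          ))
        } else {
          for (k in seq_len(ncol(cov_mat))) {
            co <- scan_fit(mm[, m], cov_mat[, k, drop = FALSE])
            emit(tibble::tibble(
              predictor_group = cov_labels$group[k],
              predictor = cov_labels$variable[k],
              response_group = mg$name, response = m,
              beta = co$estimate, se = co$std.error,
              t = co$statistic, p = co$p.value,
              category = 1L, covariate_surfaced = FALSE,
              model_predictor = NA_character_
            ))
          }
        }
      }
    }
  }

  # one covariate-adjusted single-predictor model; emits the predictor edge
  # and any covariate edges that surface below alpha_report
  controlled_fit <- function(y, u_vals, u_group, u_var,
                             resp_group, resp_var, category) {
    x <- cbind(u_vals, cov_mat)
    colnames(x) <- c(".u", cov_labels$variable)
    co <- scan_fit(y, x)
    emit(tibble::tibble(
      predictor_group = u_group, predictor = u_var,
      response_group = resp_group, response = resp_var,
      beta = co$estimate[1], se = co$std.error[1],
      t = co$statistic[1], p = co$p.value[1],
      category = category, covariate_surfaced = FALSE,
      model_predictor = NA_character_
    ))
    surfaced <- which(co$p.value[-1] < alpha_report)
    if (length(surfaced) > 0) {
      idx <- surfaced + 1L
      emit(tibble::tibble(
        predictor_group = cov_labels$group[surfaced],
        predictor = cov_labels$variable[surfaced],
        response_group = resp_group, response = resp_var,
        beta = co$estimate[idx], se = co$std.error[idx],
        t = co$statistic[idx], p = co$p.value[idx],
        category = category, covariate_surfaced = TRUE,
        model_predictor = u_var
      ))
    }
  }

  if (2 %in% categories && length(measured) >= 2) {
    mnames <- vapply(measured, function(g) g$name, character(1))
    if (is.null(pairs)) {
      pairs <- expand.grid(i = mnames, j = mnames, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    } else {
      pairs <- as.data.frame(pairs)
      names(pairs)[1:2] <- c("i", "j")
      if (any(pairs$i == pairs$j)) {
        abort_tmr("Category-2 self-pairing (i = j) is not allowed.",
                  class = "parameter")
      }
      unknown <- setdiff(unique(c(pairs$i, pairs$j)), mnames)
      if (length(unknown) > 0) {
        abort_tmr(sprintf("Unknown measured group(s): %s.",
                          paste(unknown, collapse = ", ")),
                  class = "parameter")
      }
    }
    for (r in seq_len(nrow(pairs))) {
      gi <- dataset$groups[[pairs$i[r]]]
      gj <- dataset$groups[[pairs$j[r]]]
      mi <- vg_matrix(gi)
      mj <- vg_matrix(gj)
      for (u in colnames(mi)) {
        for (v in colnames(mj)) {
          controlled_fit(mj[, v], mi[, u], gi$name, u, gj$name, v, 2L)
        }
      }
    }
  }

  if (3 %in% categories) {
    for (rg in response) {
      rm_ <- vg_matrix(rg)
      for (r in colnames(rm_)) {
        for (mg in measured) {
          mm <- vg_matrix(mg)
          for (u in colnames(mm)) {
            controlled_fit(rm_[, r], mm[, u], mg$name, u, rg$name, r, 3L)
          }
        }
      }
    }
  }

  edges <- dplyr::bind_rows(out)
  if (nrow(edges) > 0) {
    edges$sign <- ifelse(edges$beta >= 0, "positive", "negative")
    edges$covariates_controlled <- ifelse(edges$category == 1L & covariate_mode == "single",
                                          edges$predictor, cov_string)
    if (alpha_report < 1) {
      edges <- dplyr::filter(edges, .data$p < alpha_report)
    }
    edges <- dplyr::select(
      edges, "predictor_group", "predictor", "response_group", "response",
      "beta", "se", "t", "p", "category", "sign", "covariate_surfaced",
      "model_predictor", "covariates_controlled"
    )
    if (adjust == "BH") {
      edges$p_adj <- NA_real_
      primary <- !edges$covariate_surfaced
      edges$p_adj[primary] <- stats::p.adjust(edges$p[primary], method = "BH")
    }
  }
  class(edges) <- c("tmr_edges", class(edges))
  edges
}

#' Resolve bidirectional measured-measured associations
#'
#' Category-2 scans fit each cross-group variable pair in both directions.
#' When both directions are significant at the working alpha, only the
#' stronger association is kept: smaller p-value wins, ties broken by larger
#' absolute t-statistic, then by lexicographic direction label. Removals are
#' reported in the `removed` attribute.
#'
#' @param edges A `tmr_edges` table containing category-2 rows.
#' @param alpha Working significance level defining "significant in both
#'   directions" (default 0.05).
#' @return The edge table with the weaker direction of each significant
#'   bidirectional pair removed; `attr(, "removed")` holds the dropped rows.
#' @export
resolve_bidirectional <- function(edges, alpha = 0.05) {
  if (nrow(edges) == 0) return(edges)
  cand <- which(edges$category == 2L & !edges$covariate_surfaced &
                  edges$p < alpha)
  if (length(cand) == 0) {
    attr(edges, "removed") <- edges[0, ]
    return(edges)
  }
  lab_fwd <- paste(edges$predictor_group[cand], edges$predictor[cand],
                   edges$response_group[cand], edges$response[cand],
                   sep = "\r")
  lab_rev <- paste(edges$response_group[cand], edges$response[cand],
                   edges$predictor_group[cand], edges$predictor[cand],
                   sep = "\r")
  pair_key <- ifelse(lab_fwd < lab_rev,
                     paste(lab_fwd, lab_rev), paste(lab_rev, lab_fwd))
  drop_rows <- integer(0)
  for (key in unique(pair_key[duplicated(pair_key)])) {
    rows <- cand[pair_key == key]
    if (length(rows) < 2) next
    ord <- order(edges$p[rows], -abs(edges$t[rows]), lab_fwd[pair_key == key])
    drop_rows <- c(drop_rows, rows[ord[-1]])
  }
  removed <- edges[drop_rows, ]
  out <- if (length(drop_rows) > 0) edges[-drop_rows, ] else edges
  attr(out, "removed") <- removed
  class(out) <- class(edges)
  out
}

#' Build a signed association network at a p-value cutoff
#'
#' Retains edges with `p` strictly below `alpha` and annotates each with its
#' sign (from the coefficient) and each node with its variable group, the
#' form used for network figures where positive associations are drawn as
#' solid lines and negative associations as dotted lines.
#'
#' @param edges A `tmr_edges` table (typically after
#'   [resolve_bidirectional()]).
#' @param alpha Significance cutoff, strictly applied (default 0.005).
#' @return A `tmr_network`: list with `edges` (retained rows), `nodes`
#'   (tibble: `name`, `group`, `variable` — only edge endpoints, no isolated
#'   nodes) and `alpha`.
#' @export
build_network <- function(edges, alpha = 0.005) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_tmr("`alpha` must be in (0, 1).", class = "parameter")
  }
  keep <- dplyr::filter(tibble::as_tibble(edges), is.finite(.data$p),
                        .data$p < alpha)
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(group = keep$predictor_group, variable = keep$predictor),
    tibble::tibble(group = keep$response_group, variable = keep$response)
  ))
  nodes <- dplyr::mutate(nodes,
                         name = paste(.data$group, .data$variable, sep = ":"),
                         .before = 1)
  structure(list(edges = keep, nodes = nodes, alpha = alpha),
            class = "tmr_network")
}

#' @export
print.tmr_network <- function(x, ...) {
  cat(sprintf("<tmr_network> alpha = %g: %d edges over %d nodes\n",
              x$alpha, nrow(x$edges), nrow(x$nodes)))
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 10))
  invisible(x)
}

#' @method tidy tmr_network
#' @export
tidy.tmr_network <- function(x, ...) x$edges

#' @method glance tmr_network
#' @export
glance.tmr_network <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    n_edges = nrow(x$edges),
    n_nodes = nrow(x$nodes),
    n_negative = sum(x$edges$sign == "negative")
  )
}

#' Convert a TMR network to an igraph object
#'
#' Node attribute `group`; edge attributes `beta`, `p`, `sign`, `category`.
#'
#' @param network A `tmr_network`.
#' @return A directed [igraph::graph].
#' @export
as_igraph <- function(network) {
  el <- dplyr::transmute(
    network$edges,
    from = paste(.data$predictor_group, .data$predictor, sep = ":"),
    to = paste(.data$response_group, .data$response, sep = ":"),
    beta = .data$beta, p = .data$p, sign = .data$sign,
    category = .data$category
  )
  igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = network$nodes[, c("name", "group")]
  )
}

#' Write a TMR network as GraphML and an edge-list TSV
#'
#' @param network A `tmr_network`.
#' @param graphml_path,edges_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the written paths.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}
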