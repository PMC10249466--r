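#' Run the end-to-end TMR workflow
#'
#' Composes the full analysis on an aligned dataset (or a synthetic study,
#' or a manifest path): measured-group transformation (relative abundance,
#' top-n pooling and ALR for compositional layers; log for log-normal
#' layers), optional PCA proxy-variable selection, the three-category TMR
#' scan, bidirectional resolution, network construction at the working
#' cutoff, the Mantel/Ward inter-group dendrogram, and MDS plus PERMANOVA on
#' one measured layer's inter-sample distances. When the input is a
#' [generate_study()] result, recovery against the planted edges is scored
#' as well.
#'
#' @param x A `tmr_dataset`, `synthetic_study`, or path to a manifest YAML
#'   (see [read_dataset()]).
#' @param out_dir Optional output directory; when given, all artifacts are
#'   written there as plain files (edge table, GraphML network, Newick
#'   dendrogram, selection report, MDS coordinates, PERMANOVA table and a
#'   YAML run log recording the seed, configuration hash and every default
#'   that was actually applied).
#' @param alpha_report Reporting cutoff for the full edge table (default 1:
#'   keep everything).
#' @param alpha_network Network significance cutoff (default 0.005).
#' @param select Run PCA proxy-variable selection on measured groups?
#'   Default `FALSE` (scan all transformed variables).
#' @param top_n,pseudocount,alr_reference Compositional handling; see
#'   [transform_measured()].
#' @param variance_threshold,normality_alpha Selection thresholds; see
#'   [pca_select()].
#' @param ordination_group Measured group used for MDS/PERMANOVA; default
#'   the first compositional layer (falling back to the first measured
#'   group). Distances for ordination are computed on the group's modeling
#'   scale without re-standardization.
#' @param standardize_dendrogram Z-score variables before the dendrogram's
#'   distance computations (default `TRUE`; groups mix units).
#' @param n_perm,seed PERMANOVA permutations and seed.
#' @param ward_method Dendrogram linkage variant; see [group_dendrogram()].
#' @return A `tmr_run` list: `dataset` (transformed, possibly reduced),
#'   `selection`, `edges` (full scan), `edges_resolved`, `network`,
#'   `dendrogram`, `mds`, `permanova`, `recovery` (when truth was
#'   available), `log`.
#' @export
run_pipeline <- function(x, out_dir = NULL,
                         alpha_report = 1, alpha_network = 0.005,
                         select = FALSE, top_n = 10, pseudocount = 1e-6,
                         alr_reference = NULL,
                         variance_threshold = 0.01, normality_alpha = 0.05,
                         ordination_group = NULL,
                         standardize_dendrogram = TRUE,
                         n_perm = 999, seed = 1,
                         ward_method = c("ward.D", "ward.D2")) {
  ward_method <- match.arg(ward_method)
  truth <- NULL
  if (inherits(x, "synthetic_study")) {
    truth <- x$true_edges
    dataset <- x$dataset
  } else if (inherits(x, "tmr_dataset")) {
    dataset <- x
  } else if (is.character(x) && length(x) == 1) {
    dataset <- read_dataset(x)
  } else {
    abort_tmr("`x` must be a tmr_dataset, synthetic_study or manifest path.",
              class = "config")
  }

  compositional_names <- names(Filter(
    function(g) isTRUE(g$meta$compositional), dataset$groups))
  dataset <- transform_measured(dataset, top_n = top_n,
                                pseudocount = pseudocount,
                                reference = alr_reference)

  selection <- NULL
  if (select) {
    sel <- select_dataset(dataset, variance_threshold = variance_threshold,
                          normality_alpha = normality_alpha)
    dataset <- sel$dataset
    selection <- sel$selection
  }

  edges <- tmr_scan(dataset, alpha_report = alpha_report)
  edges_resolved <- resolve_bidirectional(edges, alpha = alpha_network)
  network <- build_network(edges_resolved, alpha = alpha_network)

  dendrogram <- group_dendrogram(dataset,
                                 standardize = standardize_dendrogram,
                                 method = ward_method)

  measured_names <- names(dataset_groups(dataset, "measured"))
  ordination_group <- ordination_group %||%
    (if (length(compositional_names) > 0 &&
         compositional_names[1] %in% measured_names) compositional_names[1]
     else measured_names[1])
  og <- dataset$groups[[ordination_group]]
  d_ord <- euclidean_distances(og, standardize = FALSE)
  mds <- classical_mds(d_ord, k = 2)
  treatment <- dataset_groups(dataset, "treatment")
  covariates <- dplyr::bind_cols(lapply(treatment, function(g) {
    g$data[vg_vars(g)]
  }))
  perm <- permanova(d_ord, as.data.frame(covariates), n_perm = n_perm,
                    seed = seed)

  recovery <- if (!is.null(truth)) {
    score_recovery(network, truth)
  }

  alr_refs <- lapply(dataset$groups, function(g) g$meta$alr_reference)
  alr_refs <- alr_refs[!vapply(alr_refs, is.null, logical(1))]
  log <- list(
    seed = seed,
    config_hash = rlang::hash(list(
      alpha_report = alpha_report, alpha_network = alpha_network,
      select = select, top_n = top_n, pseudocount = pseudocount,
      alr_reference = alr_reference,
      variance_threshold = variance_threshold,
      normality_alpha = normality_alpha,
      ordination_group = ordination_group,
      standardize_dendrogram = standardize_dendrogram,
      n_perm = n_perm, seed = seed, ward_method = ward_method
    )),
    alpha_network = alpha_network,
    alr_reference_used = alr_refs,
    ordination_group = ordination_group,
    standardize_dendrogram = standardize_dendrogram,
    ward_method = ward_method,
    n_perm = n_perm,
    package_version = as.character(utils::packageVersion("tmrnet")),
    r_version = as.character(getRversion())
  )

  run <- structure(
    list(dataset = dataset, selection = selection, edges = edges,
         edges_resolved = edges_resolved, network = network,
         dendrogram = dendrogram, mds = mds, permanova = perm,
         recovery = recovery, log = log),
    class = "tmr_run"
  )
  if (!is.null(out_dir)) {
    write_run(run, out_dir)
  }
  run
}

#' @export
print.tmr_run <- function(x, ...) {
  cat("<tmr_run>\n")
  print(x$network)
  if (!is.null(x$recovery)) {
    cat("recovery against planted edges:\n")
    print(x$recovery)
  }
  invisible(x)
}

#' Write all pipeline artifacts as plain files
#'
#' @param run A `tmr_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(run$edges, "edges.tsv")
  tsv(run$edges_resolved, "edges_resolved.tsv")
  write_network(run$network,
                graphml_path = file.path(out_dir, "network.graphml"),
                edges_path = file.path(out_dir, "network_edges.tsv"))
  write_dendrogram(run$dendrogram, file.path(out_dir, "dendrogram.nwk"))
  utils::write.table(run$dendrogram$dissimilarity,
                     file.path(out_dir, "group_dissimilarity.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(run$selection)) {
    sel <- dplyr::bind_rows(
      lapply(run$selection, function(s) s$selections), .id = "group")
    tsv(sel, "selection.tsv")
  }
  tsv(run$mds$coordinates, "mds.tsv")
  tsv(as.data.frame(run$permanova), "permanova.tsv")
  if (!is.null(run$recovery)) tsv(run$recovery, "recovery.tsv")
  yaml::write_yaml(run$log, file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
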