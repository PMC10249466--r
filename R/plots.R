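# ggplot2 views of the main result objects. Negative associations are drawn
# dotted magenta, positive solid black, matching the convention of the
# network figures this package produces.

#' @method autoplot tmr_network
#' @export
autoplot.tmr_network <- function(object, layout_seed = 1, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no edges at this cutoff") +
             ggplot2::theme_void())
  }
  g <- as_igraph(object)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  nodes <- dplyr::mutate(object$nodes,
                         x = xy[, 1], y = xy[, 2])
  edges <- dplyr::mutate(
    object$edges,
    from = paste(.data$predictor_group, .data$predictor, sep = ":"),
    to = paste(.data$response_group, .data$response, sep = ":")
  )
  edges <- dplyr::left_join(
    edges, dplyr::select(nodes, "name", x0 = "x", y0 = "y"),
    by = c(from = "name"))
  edges <- dplyr::left_join(
    edges, dplyr::select(nodes, "name", x1 = "x", y1 = "y"),
    by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$sign,
                   colour = .data$sign)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$group),
      shape = 21, size = 4) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$variable),
      vjust = -1, size = 3) +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dotted")) +
    ggplot2::scale_colour_manual(
      values = c(positive = "black", negative = "magenta")) +
    ggplot2::labs(title = sprintf("Associations at p < %g", object$alpha)) +
    ggplot2::theme_void()
}

#' @method autoplot tmr_mds
#' @export
autoplot.tmr_mds <- function(object, annotations = NULL, colour = NULL, ...) {
  d <- object$coordinates
  if (!is.null(annotations)) {
    d <- dplyr::left_join(d, annotations, by = "sample")
  }
  ve <- 100 * object$variance_explained
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$MDS1, y = .data$MDS2))
  p <- if (!is.null(colour) && colour %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("MDS1 (%.1f%%)", ve[1]),
      y = sprintf("MDS2 (%.1f%%)", if (length(ve) > 1) ve[2] else NA)
    ) +
    ggplot2::theme_minimal()
}

# x positions and segments of an hclust tree, for a ggplot dendrogram
dendro_segments <- function(hc) {
  n <- length(hc$labels)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  seg <- list()
  pos <- function(id) {
    if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], node_y[id])
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[k, 1])
    b <- pos(hc$merge[k, 2])
    node_x[k] <- mean(c(a[1], b[1]))
    h <- node_y[k]
    seg[[length(seg) + 1L]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h), yend = c(h, h, h)
    )
  }
  list(segments = dplyr::bind_rows(seg),
       leaves = tibble::tibble(x = leaf_x, label = hc$labels))
}

#' @method autoplot group_dendrogram
#' @export
autoplot.group_dendrogram <- function(object, ...) {
  ds <- dendro_segments(object$hclust)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ds$segments,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend)) +
    ggplot2::geom_text(
      data = ds$leaves,
      ggplot2::aes(x = .data$x, y = -0.02, label = .data$label),
      angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(name = "Ward merge height (1 - |Mantel cor|)") +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank(),
                   plot.margin = ggplot2::margin(10, 10, 60, 10))
}

#' @method autoplot pca_selection
#' @export
autoplot.pca_selection <- function(object, ...) {
  vf <- tibble::tibble(
    pc = seq_along(object$variance_fractions),
    variance_fraction = object$variance_fractions,
    retained = seq_along(object$variance_fractions) %in% object$selections$pc
  )
  ggplot2::ggplot(vf, ggplot2::aes(x = .data$pc, y = .data$variance_fraction,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$variance_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "principal component", y = "variance fraction") +
    ggplot2::theme_minimal()
}
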