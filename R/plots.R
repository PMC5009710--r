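#' Plot a crosstalk network
#'
#' Fruchterman-Reingold layout (seeded, reproducible) with node kind mapped
#' to colour.
#'
#' @param object a [crosstalk_network()].
#' @param seed layout seed.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.crosstalk_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  nodes <- nodes[match(igraph::V(g)$name, nodes$id), ]
  seg <- dplyr::mutate(object$edges,
                       x = nodes$x[match(.data$from, nodes$id)],
                       y = nodes$y[match(.data$from, nodes$id)],
                       xend = nodes$x[match(.data$to, nodes$id)],
                       yend = nodes$y[match(.data$to, nodes$id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind),
                        size = 2.5) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "node kind")
}

#' Plot the top-ranked nodes of a centrality table
#'
#' Dot plot of the `n_top` nodes by number of indices in whose top-`k` list
#' they appear.
#'
#' @param object a `centrality_table` from [compute_centrality()].
#' @param k top-list depth per index.
#' @param n_top nodes shown.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_table <- function(object, k = 10L, n_top = 20L, ...) {
  counts <- stats::setNames(integer(nrow(object)), object$node)
  for (idx in centrality_index_names()) {
    ord <- order(-object[[idx]], object$node)
    top <- object$node[ord][seq_len(min(k, nrow(object)))]
    counts[top] <- counts[top] + 1L
  }
  tab <- tibble::tibble(node = names(counts), n_indices = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$n_indices), .data$node) |>
    utils::head(n_top)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n_indices,
                                    y = stats::reorder(.data$node, .data$n_indices))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("indices with node in top ", k), y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy and glance methods
#'
#' `tidy()` on a cluster set returns one row per cluster-member pair;
#' `glance()` on a centrality table gives a one-row summary.
#'
#' @param x a `cluster_set` or `centrality_table`.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
#' @export
tidy.cluster_set <- function(x, ...) {
  if (!nrow(x)) {
    return(tibble::tibble(cluster = integer(), node = character(),
                          cohesiveness = numeric(), density = numeric()))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i) {
    tibble::tibble(cluster = i, node = x$members[[i]],
                   cohesiveness = x$cohesiveness[i], density = x$density[i])
  }))
}

#' @rdname tidiers
#' @export
glance.centrality_table <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x),
    n_indices = length(centrality_index_names()),
    max_degree = if (nrow(x)) max(x$degree) else NA_real_,
    max_betweenness = if (nrow(x)) max(x$betweenness) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
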