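#' Tidy an open-discovery evaluation
#'
#' @param x An `open_eval` from [evaluate_open()].
#' @param ... Unused.
#' @return `tidy()`: the per-concept precision tibble. `glance()`: a
#'   one-row tibble with `mean_precision`, `sem`, `n_concepts`, `k`, and
#'   `model`.
#' @method tidy open_eval
#' @export
tidy.open_eval <- function(x, ...) x$per_concept

#' @rdname tidy.open_eval
#' @method glance open_eval
#' @export
glance.open_eval <- function(x, ...) {
  tibble(mean_precision = x$mean, sem = x$sem,
         n_concepts = nrow(x$per_concept), k = x$k, model = x$model_tag)
}

#' @rdname tidy.open_eval
#' @method tidy discovery_report
#' @export
tidy.discovery_report <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "discovery_report")
  out
}

#' @rdname tidy.open_eval
#' @method tidy proximity_network
#' @export
tidy.proximity_network <- function(x, ...) x$edges

#' @rdname tidy.open_eval
#' @method glance proximity_network
#' @export
glance.proximity_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         r = x$params$r, q = x$params$q)
}

#' Plot the association-strength profile of an evaluation
#'
#' Bar chart of hit fraction (future co-occurrence among retrieved indirect
#' neighbors) per cosine bin, profiling how predictive strong associations
#' are.
#'
#' @param object An `open_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot open_eval
#' @export
autoplot.open_eval <- function(object, ...) {
  ggplot2::ggplot(object$strength_profile,
                  ggplot2::aes(x = .data$bin_low + 0.05, y = .data$hit_fraction)) +
    ggplot2::geom_col(width = 0.09, fill = "steelblue") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "association strength (cosine)",
                  y = "fraction co-occurring in future slice",
                  title = sprintf("%s: strength vs predictive ability", object$model_tag)) +
    ggplot2::theme_minimal()
}

#' Plot a Pathfinder-scaled network
#'
#' Draws the retained edges with a deterministic force-directed layout;
#' edge opacity tracks association strength when a `cosine` column is
#' present.
#'
#' @param object A `proximity_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot proximity_network
#' @export
autoplot.proximity_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  ed <- object$edges
  ed$x <- nodes$x[match(ed$from, nodes$name)]
  ed$y <- nodes$y[match(ed$from, nodes$name)]
  ed$xend <- nodes$x[match(ed$to, nodes$name)]
  ed$yend <- nodes$y[match(ed$to, nodes$name)]
  p <- ggplot2::ggplot()
  if (nrow(ed)) {
    p <- p + ggplot2::geom_segment(
      data = ed, ggplot2::aes(x = .data$x, y = .data$y,
                              xend = .data$xend, yend = .data$yend),
      color = "grey50")
  }
  p + ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                          size = 2, color = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                       vjust = -0.8, size = 3) +
    ggplot2::theme_void()
}

#' Plot a discovery report
#'
#' Horizontal bar chart of candidate cosine scores, strongest on top.
#'
#' @param object A `discovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discovery_report
#' @export
autoplot.discovery_report <- function(object, ...) {
  df <- tidy(object)
  df$concept <- factor(df$concept, levels = rev(df$concept))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cosine, y = .data$concept)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cosine", y = NULL,
                  title = sprintf("[%s] neighbors of %s", attr(object, "model_tag"),
                                  paste(attr(object, "cues"), collapse = " + "))) +
    ggplot2::theme_minimal()
}
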