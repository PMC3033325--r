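#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom tibble as_tibble
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

#' Tidy the edges of a learned forest
#'
#' One row per edge (latent parent to child) with both endpoints' layers and
#' the edge's scaled mutual information.
#'
#' @param x an `fhlc_forest`.
#' @param ... unused.
#' @return A tibble with columns `parent`, `child`, `parent_layer`,
#'   `child_layer`, `scaled_mi`.
#' @method tidy fhlc_forest
#' @export
tidy.fhlc_forest <- function(x, ...) {
  lay <- setNames(x$nodes$layer, x$nodes$id)
  x$edges %>%
    mutate(
      parent_layer = unname(lay[.data$parent]),
      child_layer = unname(lay[.data$child])
    ) %>%
    dplyr::select(dplyr::all_of(c(
      "parent", "child", "parent_layer", "child_layer", "scaled_mi"
    )))
}

#' One-row summary of a learned forest
#'
#' @param x an `fhlc_forest`.
#' @param ... unused.
#' @return A tibble with `n_markers`, `n_latents`, `n_trees`, `max_layer`,
#'   `drr` (dimension reduction rate) and `reduction_pct`
#'   (`100 * (1 - drr)`).
#' @method glance fhlc_forest
#' @export
glance.fhlc_forest <- function(x, ...) {
  drr <- dimension_reduction_rate(x)
  tibble(
    n_markers = sum(x$nodes$type == "observed"),
    n_latents = sum(x$nodes$type == "latent"),
    n_trees = tree_count(x),
    max_layer = max(x$nodes$layer),
    drr = drr,
    reduction_pct = 100 * (1 - drr)
  )
}

#' Plot a learned forest by layers
#'
#' Observed markers along layer 0, latent variables above, edges drawn from
#' parent to child. A quick structural view; export to GraphML/DOT for
#' interactive inspection of large forests.
#'
#' @param object an `fhlc_forest`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fhlc_forest
#' @export
autoplot.fhlc_forest <- function(object, ...) {
  nodes <- object$nodes
  # horizontal position: observed nodes in input order, latents at the mean
  # position of their observed leaves
  obs <- nodes$id[nodes$type == "observed"]
  pos <- setNames(seq_along(obs), obs)
  for (lv in nodes$id[nodes$type == "latent"][order(nodes$layer[
    nodes$type == "latent"
  ])]) {
    pos[lv] <- mean(pos[subtree_leaves(object, lv)])
  }
  nd <- nodes %>% mutate(x = unname(pos[.data$id]))
  ed <- object$edges %>%
    mutate(
      x = unname(pos[.data$parent]), xend = unname(pos[.data$child]),
      y = unname(setNames(nd$layer, nd$id)[.data$parent]),
      yend = unname(setNames(nd$layer, nd$id)[.data$child])
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      linewidth = 0.3, colour = "grey55"
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$layer, shape = .data$type,
                   colour = .data$type),
      size = 2
    ) +
    ggplot2::scale_shape_manual(values = c(observed = 15, latent = 16)) +
    ggplot2::labs(x = "marker position (index)", y = "layer") +
    ggplot2::theme_minimal()
}

#' Plot median r-squared against MRCA level
#'
#' @param forest an `fhlc_forest`.
#' @param data the [snp_matrix()] the forest was learned from.
#' @return A ggplot object: boxplots of pairwise r-squared per MRCA level,
#'   cross-tree pairs shown as level `N`.
#' @export
plot_mrca_r2 <- function(forest, data) {
  tab <- mrca_r2_table(forest, data) %>%
    mutate(level = factor(
      ifelse(is.na(.data$mrca_level), "N", .data$mrca_level),
      levels = c(sort(unique(stats::na.omit(.data$mrca_level))), "N")
    ))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$level, y = .data$r2)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "MRCA level", y = expression(r^2)) +
    ggplot2::theme_minimal()
}
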