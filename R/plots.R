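#' @importFrom ggplot2 ggplot aes geom_col geom_tile geom_point geom_segment
#'   geom_line geom_text facet_wrap labs scale_fill_viridis_c theme_minimal
#'   autoplot
NULL

#' @export
ggplot2::autoplot

#' Stacked publicness-fraction bars per subject
#'
#' @param object A `tcr_publicness_fractions` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_publicness_fractions <- function(object, ...) {
  ggplot(object, aes(x = .data$subject_id, y = .data$fraction,
                     fill = .data$label)) +
    geom_col() +
    facet_wrap(~ group, scales = "free_x") +
    labs(x = NULL, y = "fraction of clones", fill = "publicness") +
    theme_minimal()
}

#' Heatmap of mean overlap between group-epoch cells
#'
#' @param object A `tcr_overlap_matrix` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_overlap_matrix <- function(object, ...) {
  m <- object$matrix
  df <- tibble(
    a = rep(rownames(m), times = ncol(m)),
    b = rep(colnames(m), each = nrow(m)),
    overlap = as.vector(m)
  )
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$overlap)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.3f", .data$overlap)), size = 3) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Morisita-Horn") +
    theme_minimal()
}

#' Stacked rank-area bars over mouse timepoints
#'
#' @param object A `tcr_rank_area` tibble.
#' @param top_k Sequences colored individually; the rest are pooled as
#'   "other" (default 3).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_rank_area <- function(object, top_k = 3, ...) {
  top <- object |>
    group_by(.data$junction_aa) |>
    summarise(s = sum(.data$share), .groups = "drop") |>
    arrange(desc(.data$s)) |>
    slice_head(n = top_k)
  df <- mutate(object, seq = ifelse(.data$junction_aa %in% top$junction_aa,
                                    .data$junction_aa, "other"))
  ggplot(df, aes(x = factor(.data$timepoint), y = .data$share,
                 fill = .data$seq)) +
    geom_col() +
    labs(x = "timepoint", y = "normalized rank-area share", fill = NULL) +
    theme_minimal()
}

#' Stage-similarity bars
#'
#' @param object A `tcr_stage_similarity` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_stage_similarity <- function(object, ...) {
  ggplot(object, aes(x = .data$stage, y = .data$similarity)) +
    geom_col(fill = "steelblue") +
    labs(x = "disease stage", y = "similarity") +
    theme_minimal()
}

#' Edit-distance network layout
#'
#' Fruchterman-Reingold layout of the distance network; isolated nodes are
#' drawn as points without edges.
#'
#' @param object A `tcr_network` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = object$nodes)
  )
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(name = object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(nodes, by = c(node_a = "name")) |>
    left_join(nodes, by = c(node_b = "name"), suffix = c("", "_b"))
  ggplot() +
    geom_segment(data = edges, aes(x = .data$x, y = .data$y,
                                   xend = .data$x_b, yend = .data$y_b),
                 color = "grey70") +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y),
               color = "firebrick", size = 2) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
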