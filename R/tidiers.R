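#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an identification (or sex-classification) result
#'
#' @param x An `identification_result` or `sex_classification_result`.
#' @param ... Unused.
#' @return One row per randomized run: `run`, `accuracy` (%),
#'   `n_misidentified`, `misidentified` (list-column of subject ids).
#' @exportS3Method generics::tidy
tidy.identification_result <- function(x, ...) x$runs

#' @rdname tidy.identification_result
#' @exportS3Method generics::glance
glance.identification_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 max_misidentifications = x$max_misidentifications,
                 n_targets = x$n_targets, n_runs = x$n_runs,
                 method = x$method, mode = x$mode, seed = x$seed)
}

#' Tidy a dynamic-states object
#'
#' @param x A `dynamic_states`.
#' @param ... Unused.
#' @return One row per state: `state`, `count`, `occupancy` (fraction of
#'   windows).
#' @exportS3Method generics::tidy
tidy.dynamic_states <- function(x, ...) {
  tibble::tibble(state = seq_along(x$counts), count = x$counts,
                 occupancy = x$counts / sum(x$counts))
}

#' Tidy a network-contribution object
#'
#' @param x A `network_contribution`.
#' @param ... Unused.
#' @return The per-network tibble (`network`, `credit`, `percent`).
#' @exportS3Method generics::tidy
tidy.network_contribution <- function(x, ...) x$network

#' Tidy an FC matrix into a long edge table
#'
#' @param x An `fp_fc`.
#' @param ... Unused.
#' @return One row per edge: `edge`, `i`, `j`, `node_i`, `node_j`, `z`.
#' @exportS3Method generics::tidy
tidy.fp_fc <- function(x, ...) {
  emap <- edge_index_map(nrow(x))
  ids <- rownames(x)
  dplyr::mutate(emap, node_i = ids[.data$i], node_j = ids[.data$j],
                z = as.numeric(vectorize_upper(x)))
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(paste0("<identification_result> %s: mean accuracy %.2f%% ",
                     "over %d runs (%d targets); max misidentified %d\n"),
              x$method, x$mean_accuracy, x$n_runs, x$n_targets,
              x$max_misidentifications))
  invisible(x)
}

#' Heat-map of an FC matrix
#'
#' @param object An `fp_fc`.
#' @param ... Unused.
#' @return A ggplot object (tile map of Fisher-z edge strengths).
#' @exportS3Method ggplot2::autoplot
autoplot.fp_fc <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$z <- as.numeric(unclass(object))[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "node", y = "node", fill = "Fisher z",
                  title = sprintf("FC matrix (%s)", method_tag(object))) +
    ggplot2::coord_fixed()
}

#' Per-run accuracy distribution of an identification experiment
#'
#' @param object An `identification_result`.
#' @param ... Unused.
#' @return A ggplot histogram of per-run accuracies with the mean marked.
#' @exportS3Method ggplot2::autoplot
autoplot.identification_result <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_accuracy,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "accuracy (%)", y = "runs",
                  title = sprintf("%s: mean %.2f%%", object$method,
                                  object$mean_accuracy))
}

#' Block-grid plot of network contributions
#'
#' @param object A `network_contribution`.
#' @param ... Unused.
#' @return A ggplot tile map of the within/between-network block
#'   percentages.
#' @exportS3Method ggplot2::autoplot
autoplot.network_contribution <- function(object, ...) {
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(x = .data$network_a, y = .data$network_b,
                               fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "% of selected edges") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
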