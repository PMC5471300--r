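# ggplot2 displays for the result types.

#' Contact-map plot of ranked predictions
#'
#' Predicted pairs in the upper triangle; when a structural contact map is
#' supplied its contacts fill the lower triangle, the conventional
#' predictions-vs-structure display.
#'
#' @param object a `coevo_contacts`.
#' @param structure_map optional `coevo_contact_map` drawn below the
#'   diagonal (alignment-column coordinates assumed shared).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coevo_contacts <- function(object, structure_map = NULL, ...) {
  pred <- dplyr::transmute(object$pairs, x = .data$j, y = .data$i,
                           what = "predicted")
  df <- pred
  if (!is.null(structure_map)) {
    native <- tidy(structure_map) |>
      dplyr::transmute(x = .data$i, y = .data$j, what = "native")
    df <- dplyr::bind_rows(pred, native)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$what)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue position", y = "residue position",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cumulative true-positive-rate curve
#'
#' @param object a `coevo_tpr`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coevo_tpr <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$rank, .data$cum_tpr)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "predictions considered",
                  y = "fraction matching the reference structure") +
    ggplot2::theme_minimal()
}

#' Acceptance-frequency plot for inter-family predictions
#'
#' @param object a `coevo_acceptance`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coevo_acceptance <- function(object, ...) {
  df <- object$table
  df$pair <- stats::reorder(paste0(df$i, "-", df$j), df$frequency)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$pair)) +
    ggplot2::geom_col() +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "acceptance frequency", y = "inter-family pair") +
    ggplot2::theme_minimal()
}

#' Shortest-path class distribution
#'
#' @param object a `coevo_sp`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coevo_sp <- function(object, ...) {
  df <- object$classes
  df$class <- factor(ifelse(is.infinite(df$sp), "unreachable",
                            as.character(df$sp)),
                     levels = c(sort(unique(df$sp[is.finite(df$sp)])),
                                "unreachable"))
  ggplot2::ggplot(df, ggplot2::aes(.data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "shortest path in the structural contact graph",
                  y = "predictions") +
    ggplot2::theme_minimal()
}
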