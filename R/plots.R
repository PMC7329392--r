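# ggplot2 views of the main result types.

#' Plot a repeat score track
#'
#' Per-position vote-fraction scores with the repeat threshold and the
#' cleaned mask shaded.
#'
#' @param object A `kep_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kep_track <- function(object, ...) {
  df <- tidy(object)
  runs <- rle(object$mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  shade <- tibble(xmin = starts[runs$values] - 0.5,
                  xmax = ends[runs$values] + 0.5)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$score))
  if (nrow(shade))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85")
  p +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "mature position", y = "repeat score",
                  title = sprintf("seed %s, %d seeds",
                                  object$seed_length, object$n_seeds)) +
    ggplot2::theme_minimal()
}

#' Plot a vicinity histogram
#'
#' Counts of labelled genes by gene-rank distance from KEP genes.
#'
#' @param object A `kep_vicinity`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kep_vicinity <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$distance, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "gene-rank distance from KEP gene",
                  y = "count", title = object$label,
                  subtitle = sprintf("fraction with hit %.2f; nearest mean %.2f",
                                     object$fraction_of_keps_with_hit,
                                     object$nearest_mean)) +
    ggplot2::theme_minimal()
}

#' Plot type sizes
#'
#' Member counts of KEP types in label order (stand-alone KEPs excluded).
#'
#' @param types A `kep_types` object.
#' @return A ggplot.
#' @export
plot_type_sizes <- function(types) {
  sizes <- types$assignments |>
    filter(.data$type_label != "0") |>
    count(.data$type_label, name = "count")
  sizes$rank <- as.integer(sub("^#", "", sizes$type_label))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "type", y = "KEPs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
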