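#' @importFrom ggplot2 ggplot aes geom_curve geom_segment geom_tile geom_col
#'   geom_text labs theme_minimal scale_y_continuous autoplot
NULL

#' @export
ggplot2::autoplot

#' Arc diagram of a secondary structure
#'
#' @param object A `secondary_structure` from [fold()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot secondary_structure
#' @export
autoplot.secondary_structure <- function(object, ...) {
  n <- nchar(object$seq)
  backbone <- tibble(x = 1:n, base = seq_chars(object$seq))
  p <- ggplot(backbone, aes(x = .data$x, y = 0)) +
    geom_segment(aes(x = 1, xend = n, y = 0, yend = 0), linewidth = 0.3,
                 colour = "grey60") +
    labs(x = "position (nt)", y = NULL,
         title = sprintf("%d nt, %d pairs, score %.0f", n,
                         nrow(object$pairs), object$score)) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (nrow(object$pairs)) {
    arcs <- as_tibble(object$pairs)
    p <- p + geom_curve(data = arcs,
                        aes(x = .data$i, xend = .data$j, y = 0, yend = 0),
                        curvature = -0.5, linewidth = 0.3, colour = "steelblue")
  }
  p
}

#' Virtual-gel plot
#'
#' Renders the band table from [virtual_gel()] the way a denaturing gel lane
#' reads: one lane, length decreasing downward, band darkness proportional to
#' predicted intensity.
#'
#' @param object A `virtual_gel` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot virtual_gel
#' @export
autoplot.virtual_gel <- function(object, ...) {
  df <- mutate(object,
               alpha = ifelse(is.na(.data$intensity), 1, pmax(.data$intensity, 0.15)))
  ggplot(df, aes(x = 1, y = .data$length)) +
    geom_tile(aes(alpha = .data$alpha), width = 0.6, height = 1.5,
              fill = "black") +
    geom_text(aes(label = sprintf("%s (%d nt)", .data$id, .data$length)),
              x = 1.45, hjust = 0, size = 3) +
    scale_y_continuous(trans = "log10") +
    ggplot2::scale_alpha_identity() +
    ggplot2::xlim(0.5, 3) +
    labs(x = NULL, y = "length (nt)", title = "virtual gel (labeled species)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Competition-fraction plot
#'
#' @param scores Competition tibble from [competition()].
#' @return A ggplot of predicted integration fractions per pool member.
#' @export
plot_competition <- function(scores) {
  ggplot(scores, aes(x = .data$id, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "predicted integration fraction") +
    theme_minimal()
}
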