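#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_segment geom_point
#'   scale_fill_gradient scale_fill_manual labs theme_minimal theme
#'   element_text
#' @export
ggplot2::autoplot

#' Heatmap of a clustered identity matrix
#'
#' @param object An `identity_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.identity_matrix <- function(object, ...) {
  long <- tidy(object)
  long$a <- factor(long$a, levels = object$order)
  long$b <- factor(long$b, levels = object$order)
  ggplot(long, aes(x = .data$a, y = .data$b, fill = .data$identity)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        limits = c(0, 100), name = "% identity") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' Tile plot of a presence/absence matrix
#'
#' @param object A `presence_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.presence_matrix <- function(object, ...) {
  long <- tidy(object)
  long$taxon <- factor(long$taxon, levels = rev(object$taxon))
  ggplot(long, aes(x = .data$orthogroup, y = .data$taxon,
                   fill = .data$present)) +
    geom_tile(colour = "grey85") +
    scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "white"),
                      name = "present") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Timeline of gain and loss events
#'
#' Draws each orthogroup's gain (segment over the gain-branch interval) and
#' losses (points at loss-branch midpoints) against time in Myr.
#'
#' @param object A `dollo_events` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dollo_events <- function(object, ...) {
  df <- as_tibble(object)
  gains <- dplyr::filter(df, .data$event == "gain")
  losses <- dplyr::filter(df, .data$event == "loss")
  losses$mid <- (losses$older + losses$younger) / 2
  root_age <- max(c(df$older, df$younger), na.rm = TRUE)
  gains$older <- dplyr::coalesce(gains$older, root_age)
  p <- ggplot(gains, aes(y = .data$orthogroup)) +
    geom_segment(aes(x = .data$older, xend = .data$younger,
                     yend = .data$orthogroup),
                 linewidth = 2, colour = "steelblue") +
    labs(x = "age (Myr)", y = NULL,
         caption = "bars: gain-branch intervals; crosses: losses") +
    ggplot2::scale_x_reverse() +
    theme_minimal()
  if (nrow(losses) > 0) {
    p <- p + geom_point(data = losses,
                        aes(x = .data$mid, y = .data$orthogroup),
                        shape = 4, size = 3, colour = "firebrick")
  }
  p
}
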