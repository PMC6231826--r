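# ggplot2 companions to the SVG renderer: schematic plots of each layout.
# The SVG output is the canonical rendering (it carries the polka-dot
# carrier pattern); these plots mark carrier glyphs with a black outline
# instead, since base ggplot2 has no pattern fills.

#' @importFrom ggplot2 autoplot ggplot aes geom_rect geom_point geom_tile
#'   geom_text coord_polar coord_fixed scale_fill_identity
#'   scale_color_identity theme_void theme_minimal labs
NULL

#' @export
ggplot2::autoplot

carrier_outline <- function(pattern) ifelse(pattern, "black", NA)

#' Plot a sunburst layout
#'
#' @param object A `sunburst_layout`.
#' @param ... Unused.
#' @return A ggplot: concentric rings (one per person, outermost first),
#'   arcs coloured by impact, carrier arcs outlined in black.
#' @export
autoplot.sunburst_layout <- function(object, ...) {
  n <- length(attr(object, "persons"))
  df <- as_tibble(object) %>%
    mutate(
      r_outer = n - .data$ring_index,
      r_inner = n - .data$ring_index - 0.85,
      outline = carrier_outline(.data$pattern)
    )
  ggplot(df) +
    geom_rect(aes(
      xmin = .data$start_angle, xmax = .data$start_angle + .data$extent,
      ymin = .data$r_inner, ymax = .data$r_outer,
      fill = .data$color, color = .data$outline
    ), linewidth = 0.4) +
    coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::xlim(0, 360) +
    ggplot2::ylim(0, n + 0.5) +
    scale_fill_identity() +
    scale_color_identity() +
    theme_void() +
    labs(title = paste(attr(object, "persons"), collapse = " > "))
}

#' Plot a linear layout
#'
#' @param object A `linear_layout`.
#' @param ... Unused.
#' @return A ggplot: one row per person (top first), rectangles coloured
#'   by impact, carrier rects outlined in black.
#' @export
autoplot.linear_layout <- function(object, ...) {
  persons <- attr(object, "persons")
  df <- as_tibble(object) %>%
    mutate(
      ytop = -.data$row_index,
      ybot = -.data$row_index - 0.8,
      outline = carrier_outline(.data$pattern)
    )
  ggplot(df) +
    geom_rect(aes(
      xmin = .data$x_offset, xmax = .data$x_offset + .data$width,
      ymin = .data$ybot, ymax = .data$ytop,
      fill = .data$color, color = .data$outline
    ), linewidth = 0.4) +
    ggplot2::scale_y_continuous(
      breaks = -(seq_along(persons) - 1) - 0.4, labels = persons
    ) +
    scale_fill_identity() +
    scale_color_identity() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}

#' Plot a two-set Venn layout
#'
#' @param object A `venn_layout`.
#' @param ... Unused.
#' @return A ggplot: bubbles in the left / shared / right regions,
#'   coloured by impact; carrier bubbles outlined in black.
#' @export
autoplot.venn_layout <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(outline = carrier_outline(.data$pattern))
  circle_pts <- function(i) {
    t <- seq(0, 2 * pi, length.out = 48)
    tibble(
      px = df$x[i] + df$radius[i] * cos(t),
      py = df$y[i] + df$radius[i] * sin(t),
      id = i, color = df$color[i], outline = df$outline[i]
    )
  }
  circles <- purrr::map_dfr(seq_len(nrow(df)), circle_pts)
  p <- ggplot() +
    geom_rect(
      data = tibble(x0 = c(0, 1, 2)),
      aes(xmin = .data$x0, xmax = .data$x0 + 1, ymin = 0, ymax = 1),
      fill = NA, color = "lightgray"
    )
  if (nrow(circles) > 0) {
    p <- p + ggplot2::geom_polygon(
      data = circles,
      aes(.data$px, .data$py, group = .data$id, fill = .data$color,
          color = .data$outline),
      linewidth = 0.4
    )
  }
  p + coord_fixed() + scale_fill_identity() + scale_color_identity() +
    theme_void() +
    labs(title = sprintf("%s | shared | %s",
                         attr(object, "persons")[1],
                         attr(object, "persons")[2]))
}

#' Plot a table view as a presence grid
#'
#' @param object A `table_layout`.
#' @param ... Unused.
#' @return A ggplot: variants on the y axis, persons on the x axis, marks
#'   coloured by impact, carrier marks shown as rings.
#' @export
autoplot.table_layout <- function(object, ...) {
  persons <- attr(object, "persons")
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(dplyr::all_of(persons), names_to = "person",
                        values_to = "mark") %>%
    filter(.data$mark != "absent") %>%
    mutate(
      color = style_for(ifelse(.data$impact == "carrier", "pathogenic",
                               .data$impact))$color,
      shape = ifelse(.data$mark == "carrier", 21, 19)
    )
  ggplot(df, aes(
    x = factor(.data$person, levels = persons),
    y = factor(.data$variant_name, levels = rev(object$variant_name))
  )) +
    geom_point(aes(color = .data$color, shape = .data$shape), size = 3) +
    ggplot2::scale_shape_identity() +
    scale_color_identity() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}
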