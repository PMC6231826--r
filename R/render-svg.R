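# Standalone SVG 1.1 output for the four layouts. Rendering is
# byte-deterministic: fixed canvas sizes, fixed 6-decimal coordinate
# formatting, no timestamps. Every variant glyph carries class="glyph" so
# element counts can be checked against the conservation formula.

svg_open <- function(width, height) {
  c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(
      paste0(
        "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
        "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">"
      ),
      width, height, width, height
    ),
    svg_pattern_defs()
  )
}

# one polka-dot pattern per impact colour; carrier glyphs fill with the
# pattern of their base colour
svg_pattern_defs <- function() {
  colors <- c("red", "gray", "blue", "purple")
  defs <- vapply(colors, function(col) {
    paste0(
      sprintf(
        paste0(
          "<pattern id=\"polka-%s\" width=\"8\" height=\"8\" ",
          "patternUnits=\"userSpaceOnUse\">"
        ), col
      ),
      sprintf("<rect width=\"8\" height=\"8\" fill=\"%s\"/>", col),
      "<circle cx=\"4\" cy=\"4\" r=\"2\" fill=\"white\"/>",
      "</pattern>"
    )
  }, character(1))
  c("<defs>", unname(defs), "</defs>")
}

glyph_fill <- function(color, pattern) {
  ifelse(pattern, sprintf("url(#polka-%s)", color), color)
}

# annular sector path; angles in degrees, 0 at 12 o'clock, clockwise
arc_path <- function(cx, cy, r_in, r_out, start, extent) {
  pt <- function(r, ang) {
    a <- (ang - 90) * pi / 180
    c(cx + r * cos(a), cy + r * sin(a))
  }
  large <- as.integer(extent > 180)
  p1 <- pt(r_out, start)
  p2 <- pt(r_out, start + extent)
  p3 <- pt(r_in, start + extent)
  p4 <- pt(r_in, start)
  sprintf(
    "M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
    fmt_num(p1[1]), fmt_num(p1[2]), fmt_num(r_out), fmt_num(r_out), large,
    fmt_num(p2[1]), fmt_num(p2[2]), fmt_num(p3[1]), fmt_num(p3[2]),
    fmt_num(r_in), fmt_num(r_in), large, fmt_num(p4[1]), fmt_num(p4[2])
  )
}

#' Render a layout to a standalone SVG file
#'
#' One SVG element per glyph (`class="glyph"`), fill colour from the
#' impact style, carrier glyphs filled with a polka-dot pattern. Output is
#' byte-deterministic for identical inputs and written atomically.
#'
#' @param layout A `sunburst_layout`, `linear_layout`, `venn_layout` or
#'   `table_layout`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
render_svg <- function(layout, file) {
  UseMethod("render_svg")
}

#' @export
render_svg.sunburst_layout <- function(layout, file) {
  n_rings <- max(length(attr(layout, "persons")), 1)
  size <- 500
  c0 <- size / 2
  r_max <- 230
  r_hole <- 60
  band <- (r_max - r_hole) / n_rings
  elements <- character(0)
  if (nrow(layout) > 0) {
    r_out <- r_max - layout$ring_index * band
    r_in <- r_out - band * 0.85
    elements <- sprintf(
      "<path class=\"glyph\" d=\"%s\" fill=\"%s\"><title>%s</title></path>",
      mapply(arc_path, c0, c0, r_in, r_out,
             layout$start_angle, layout$extent),
      glyph_fill(layout$color, layout$pattern),
      xml_escape(paste0(layout$variant_name, " (", layout$person_id, ")"))
    )
  }
  atomic_write(c(svg_open(size, size), elements, "</svg>"), file)
}

#' @export
render_svg.linear_layout <- function(layout, file) {
  n_rows <- max(length(attr(layout, "persons")), 1)
  width <- 1000
  row_h <- 60
  pad <- 20
  elements <- character(0)
  if (nrow(layout) > 0) {
    elements <- sprintf(
      paste0(
        "<rect class=\"glyph\" x=\"%s\" y=\"%s\" width=\"%s\" ",
        "height=\"%s\" fill=\"%s\"><title>%s</title></rect>"
      ),
      fmt_num(pad + layout$x_offset * (width - 2 * pad)),
      fmt_num(layout$row_index * row_h + 6),
      fmt_num(layout$width * (width - 2 * pad)),
      fmt_num(layout$height * n_rows * (row_h - 12)),
      glyph_fill(layout$color, layout$pattern),
      xml_escape(paste0(layout$variant_name, " (", layout$person_id, ")"))
    )
  }
  atomic_write(
    c(svg_open(width, n_rows * row_h), elements, "</svg>"), file
  )
}

#' @export
render_svg.venn_layout <- function(layout, file) {
  unit <- 300
  width <- 3 * unit
  elements <- character(0)
  boxes <- sprintf(
    paste0(
      "<rect x=\"%d\" y=\"0\" width=\"%d\" height=\"%d\" fill=\"none\" ",
      "stroke=\"lightgray\"/>"
    ),
    c(0, unit, 2 * unit), unit, unit
  )
  if (nrow(layout) > 0) {
    elements <- sprintf(
      paste0(
        "<circle class=\"glyph\" cx=\"%s\" cy=\"%s\" r=\"%s\" ",
        "fill=\"%s\"><title>%s</title></circle>"
      ),
      fmt_num(layout$x * unit), fmt_num(layout$y * unit),
      fmt_num(layout$radius * unit),
      glyph_fill(layout$color, layout$pattern),
      xml_escape(layout$variant_name)
    )
  }
  atomic_write(c(svg_open(width, unit), boxes, elements, "</svg>"), file)
}

#' @export
render_svg.table_layout <- function(layout, file) {
  persons <- attr(layout, "persons")
  row_h <- 28
  name_w <- 420
  col_w <- 90
  width <- name_w + col_w * length(persons)
  height <- row_h * (nrow(layout) + 1)
  header <- c(
    sprintf(
      "<text x=\"10\" y=\"%d\" font-weight=\"bold\">variant</text>",
      row_h - 8
    ),
    sprintf(
      "<text x=\"%d\" y=\"%d\" font-weight=\"bold\">%s</text>",
      name_w + (seq_along(persons) - 1L) * col_w + 10, row_h - 8,
      xml_escape(persons)
    )
  )
  rows <- character(0)
  if (nrow(layout) > 0) {
    style <- style_for(ifelse(layout$impact == "carrier",
                              "pathogenic", layout$impact))
    labels <- sprintf(
      "<text x=\"10\" y=\"%d\" fill=\"%s\">%s</text>",
      row_h * (seq_len(nrow(layout)) + 1L) - 8, style$color,
      xml_escape(sprintf("%s [%s]", layout$variant_name, layout$category))
    )
    marks <- unlist(lapply(seq_along(persons), function(j) {
      p <- persons[j]
      i <- which(layout[[p]] != "absent")
      if (length(i) == 0) return(character(0))
      is_carrier <- layout[[p]][i] == "carrier"
      sprintf(
        "<circle class=\"glyph\" cx=\"%d\" cy=\"%d\" r=\"8\" fill=\"%s\"><title>%s</title></circle>",
        name_w + (j - 1L) * col_w + 30, row_h * (i + 1L) - 12,
        glyph_fill(
          style_for(ifelse(layout$impact[i] == "carrier",
                           "pathogenic", layout$impact[i]))$color,
          is_carrier
        ),
        xml_escape(paste0(layout$variant_name[i], " (", p, "): ",
                          layout[[p]][i]))
      )
    }))
    rows <- c(labels, marks)
  }
  atomic_write(c(svg_open(width, height), header, rows, "</svg>"), file)
}

#' Dump a layout as JSON
#'
#' Writes the glyph table under a key named after the layout kind
#' (`arcs`, `rects`, `bubbles` or `rows`), for consumption by any front
#' end.
#'
#' @param layout A layout object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_layout_json <- function(layout, file) {
  key <- switch(
    class(layout)[1],
    sunburst_layout = "arcs", linear_layout = "rects",
    venn_layout = "bubbles", table_layout = "rows",
    stop_varkin("not a layout object", class = "varkin_validation_error")
  )
  payload <- setNames(
    list(lapply(seq_len(nrow(layout)), function(i) {
      as.list(as_tibble(layout)[i, ])
    })),
    key
  )
  payload$persons <- as.list(attr(layout, "persons"))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  atomic_write(as.character(json), file)
}
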