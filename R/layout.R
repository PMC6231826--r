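# Deterministic geometry for the four comparison views: sunburst (arcs),
# linear (rects), two-set Venn (bubbles) and table (rows). All views share
# one slot allocation: every distinct variant gets a global slot whose
# extent is proportional to its rarity size, in shared-first class order,
# so glyphs of a shared variant are radially/vertically aligned.

#' Visual style for a display impact
#'
#' Colour encodes impact — pathogenic red, benign gray, protective blue,
#' pharmacogenetic purple — and carrier findings keep the pathogenic red
#' with a polka-dot pattern.
#'
#' @param display_impact Character vector of display impacts.
#' @return A tibble with columns `color` and `pattern` (logical polka-dot
#'   flag), one row per input.
#' @examples
#' style_for(c("pathogenic", "carrier", "benign"))
#' @export
style_for <- function(display_impact) {
  check_tokens(display_impact, display_impact_levels, "impact")
  colors <- c(
    pathogenic = "red", benign = "gray", protective = "blue",
    pharmacogenetic = "purple", carrier = "red"
  )
  tibble(
    color = unname(colors[display_impact]),
    pattern = display_impact == "carrier"
  )
}

# Allocate one slot per distinct variant along a span. Slot widths are
# proportional to rarity_size; a uniform gap of gap_fraction * mean slot
# width separates slots. `closed = TRUE` (circle): n gaps, widths + gaps
# total `total` exactly; `closed = FALSE` (line): n - 1 interior gaps.
allocate_slots <- function(variants, gap_fraction, total, closed) {
  n <- nrow(variants)
  if (n == 0) {
    return(tibble(
      rsid = character(), risk_allele = character(),
      slot_start = numeric(), slot_extent = numeric()
    ))
  }
  w <- variants$rarity_size
  n_gaps <- if (closed) n else n - 1L
  # gap = gap_fraction * mean(scaled width); solve the scale k from
  # k * sum(w) + n_gaps * gap_fraction * k * mean(w) = total
  k <- total / (sum(w) * (1 + gap_fraction * n_gaps / n))
  extent <- k * w
  gap <- gap_fraction * mean(extent)
  start <- cumsum(c(0, head(extent, -1) + gap))
  tibble(
    rsid = variants$rsid, risk_allele = variants$risk_allele,
    slot_start = start, slot_extent = extent
  )
}

new_layout <- function(df, subclass, ...) {
  out <- bare_tibble(df)
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c(subclass, "varkin_layout", class(tibble()))
  out
}

check_person_order <- function(order, cmp, what) {
  if (length(order) != length(cmp$persons) ||
      !setequal(order, cmp$persons) || anyDuplicated(order)) {
    stop_varkin(
      sprintf("%s must be a permutation of the compared persons (%s)",
              what, paste(cmp$persons, collapse = ", ")),
      class = "varkin_identity_error"
    )
  }
  invisible(order)
}

# long (person x variant) table with slot geometry and style attached
layout_entries <- function(cmp, slots) {
  cmp$entries %>%
    inner_join(slots, by = c("rsid", "risk_allele")) %>%
    inner_join(
      select(cmp$variants, "rsid", "risk_allele", "variant_name"),
      by = c("rsid", "risk_allele")
    ) %>%
    dplyr::bind_cols(style_for(.$display_impact)) %>%
    select(-"zygosity")
}

#' Sunburst layout: concentric rings of arcs
#'
#' Each full circle is one person's report, outermost ring first in
#' `ring_order`; each arc is a variant. Every distinct variant gets one
#' global angular slot (extent proportional to rarity size, shared-first
#' ordering); an arc is emitted in every ring whose person carries the
#' variant, so shared variants are radially aligned across rings. Slots
#' plus uniform gaps total 360 degrees.
#'
#' @param cmp A `comparison_report`.
#' @param ring_order Permutation of the compared persons; first is the
#'   outermost ring. Defaults to comparison order.
#' @param gap_fraction Gap between slots as a fraction of the mean slot
#'   extent. Default 0.2.
#' @return A `sunburst_layout` tibble of arcs: `ring_index` (0 =
#'   outermost), `start_angle`, `extent` (degrees), `color`, `pattern`,
#'   variant key and person columns.
#' @export
sunburst_layout <- function(cmp, ring_order = NULL, gap_fraction = 0.2) {
  stopifnot(inherits(cmp, "comparison_report"))
  ring_order <- ring_order %||% cmp$persons
  check_person_order(ring_order, cmp, "ring_order")
  slots <- allocate_slots(cmp$variants, gap_fraction, 360, closed = TRUE)
  arcs <- layout_entries(cmp, slots) %>%
    mutate(ring_index = match(.data$person_id, ring_order) - 1L) %>%
    rename(start_angle = "slot_start", extent = "slot_extent") %>%
    arrange(.data$ring_index, .data$start_angle) %>%
    select(
      "ring_index", "start_angle", "extent", "color", "pattern",
      "rsid", "risk_allele", "variant_name", "person_id", "display_impact"
    )
  new_layout(arcs, "sunburst_layout",
             persons = ring_order, gap_fraction = gap_fraction)
}

#' Linear layout: one row of rectangles per person
#'
#' Each row is one person's report, top row first in `row_order`; each
#' rectangle is a variant. Every distinct variant gets one global
#' horizontal slot (width proportional to rarity size, shared-first
#' ordering) on a span normalised to 1, so shared variants are vertically
#' aligned across rows.
#'
#' @param cmp A `comparison_report`.
#' @param row_order Permutation of the compared persons; first is the top
#'   row. Defaults to comparison order.
#' @param gap_fraction Gap between slots as a fraction of the mean slot
#'   width. Default 0.2.
#' @return A `linear_layout` tibble of rects: `row_index` (0 = top),
#'   `x_offset`, `width`, `height` (normalised units), `color`, `pattern`,
#'   variant key and person columns.
#' @export
linear_layout <- function(cmp, row_order = NULL, gap_fraction = 0.2) {
  stopifnot(inherits(cmp, "comparison_report"))
  row_order <- row_order %||% cmp$persons
  check_person_order(row_order, cmp, "row_order")
  slots <- allocate_slots(cmp$variants, gap_fraction, 1, closed = FALSE)
  n_rows <- length(row_order)
  rects <- layout_entries(cmp, slots) %>%
    mutate(
      row_index = match(.data$person_id, row_order) - 1L,
      height = 0.8 / n_rows
    ) %>%
    rename(x_offset = "slot_start", width = "slot_extent") %>%
    arrange(.data$row_index, .data$x_offset) %>%
    select(
      "row_index", "x_offset", "width", "height", "color", "pattern",
      "rsid", "risk_allele", "variant_name", "person_id", "display_impact"
    )
  new_layout(rects, "linear_layout",
             persons = row_order, gap_fraction = gap_fraction)
}

# cell size and capacity of the grid a region needs for k circles: a
# ceil(sqrt(k)) x ceil(k / cols) grid of the unit-square region box; the
# radius cap keeps any circle inside its own cell, guaranteeing no
# overlaps and containment
region_grid <- function(k, w = 1, h = 1) {
  cols <- ceiling(sqrt(k))
  rows <- ceiling(k / cols)
  list(cols = cols, rows = rows, cell_w = w / cols, cell_h = h / rows,
       r_cap = 0.475 * min(w / cols, h / rows))
}

# shelf-pack circles (descending radius, row-major) into the box
# [x0, x0 + 1] x [0, 1]; radii come pre-scaled and must respect the
# grid's cap
pack_region <- function(radii, x0, grid) {
  k <- length(radii)
  ord <- order(-radii, seq_along(radii))
  pos <- seq_len(k) - 1L
  tibble(
    x = x0 + (pos %% grid$cols + 0.5) * grid$cell_w,
    y = (pos %/% grid$cols + 0.5) * grid$cell_h,
    r = radii[ord],
    index = ord
  )
}

#' Two-set Venn layout: bubbles in left / shared / right regions
#'
#' Only defined for a two-person comparison. Each bubble is a variant;
#' bubbles in the middle are the variants both persons have in common,
#' left and right regions hold each person's exclusive variants. Radius is
#' proportional to rarity size; packing is deterministic (descending
#' radius, row-major grid within the region box) and overlap-free. The
#' canvas is 3 units wide by 1 high, one unit-square region per column.
#'
#' @param cmp A two-person `comparison_report`.
#' @return A `venn_layout` tibble of bubbles: `region` (left_only /
#'   shared / right_only), `x`, `y`, `radius`, `color`, `pattern` and the
#'   variant key. Shared bubbles take the left (first) person's style.
#' @export
venn_layout <- function(cmp) {
  stopifnot(inherits(cmp, "comparison_report"))
  if (length(cmp$persons) != 2) {
    stop_varkin(
      sprintf("Venn layout is two-set only; comparison has %d persons",
              length(cmp$persons)),
      class = "varkin_arity_error"
    )
  }
  p1 <- cmp$persons[1]
  p2 <- cmp$persons[2]
  v <- cmp$variants
  region <- vapply(v$signature, function(sig) {
    if (all(c(p1, p2) %in% sig)) "shared"
    else if (p1 %in% sig) "left_only"
    else "right_only"
  }, character(1))
  # style from the first carrying person in person order
  styled <- layout_entries(
    cmp, allocate_slots(v, 0, 1, closed = FALSE)
  ) %>%
    mutate(.pidx = match(.data$person_id, cmp$persons)) %>%
    arrange(.data$rsid, .data$risk_allele, .data$.pidx) %>%
    distinct(.data$rsid, .data$risk_allele, .keep_all = TRUE)
  style <- styled[match(paste(v$rsid, v$risk_allele),
                        paste(styled$rsid, styled$risk_allele)), ]
  boxes <- list(left_only = 0, shared = 1, right_only = 2)
  # one global radius scale so radius stays proportional to rarity across
  # regions: the tightest region (largest circle vs its cell cap) decides
  grids <- lapply(boxes, function(x0) NULL)
  scale <- Inf
  for (reg in names(boxes)) {
    idx <- which(region == reg)
    if (length(idx) == 0) next
    grids[[reg]] <- region_grid(length(idx))
    scale <- min(scale, grids[[reg]]$r_cap / max(v$rarity_size[idx]))
  }
  out <- bind_rows(lapply(names(boxes), function(reg) {
    idx <- which(region == reg)
    if (length(idx) == 0) return(NULL)
    packed <- pack_region(v$rarity_size[idx] * scale, boxes[[reg]],
                          grids[[reg]])
    sel <- idx[packed$index]
    tibble(
      region = reg, x = packed$x, y = packed$y, radius = packed$r,
      color = style$color[sel], pattern = style$pattern[sel],
      rsid = v$rsid[sel], risk_allele = v$risk_allele[sel],
      variant_name = v$variant_name[sel]
    )
  }))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(
      region = character(), x = numeric(), y = numeric(),
      radius = numeric(), color = character(), pattern = logical(),
      rsid = character(), risk_allele = character(),
      variant_name = character()
    )
  }
  new_layout(out, "venn_layout", persons = cmp$persons)
}

#' Table view: one row per variant with per-person presence marks
#'
#' The tabular report lists every variant in any of the compared reports,
#' sorted by category then variant name, with one mark per person:
#' `"carrier"` if that person's displayed impact is carrier, `"present"`
#' if otherwise carried, `"absent"` if not.
#'
#' @param cmp A `comparison_report`.
#' @return A `table_layout` tibble: variant fields (`variant_name`,
#'   `category`, `impact`, `certainty`, `allele_frequency`,
#'   `effect_summary`, key columns) followed by one mark column per person
#'   (named by person id).
#' @export
table_view <- function(cmp) {
  stopifnot(inherits(cmp, "comparison_report"))
  v <- arrange(cmp$variants, .data$category, .data$variant_name)
  # the shared effect-level impact: displayed impacts are the base impact
  # except carrier, which implies a pathogenic base
  impact_of <- function(rsid, allele) {
    d <- cmp$entries$display_impact[cmp$entries$rsid == rsid &
                                      cmp$entries$risk_allele == allele]
    ifelse(d[1] == "carrier", "pathogenic", d[1])
  }
  base <- tibble(
    variant_name = v$variant_name, rsid = v$rsid,
    risk_allele = v$risk_allele, category = v$category,
    impact = mapply(impact_of, v$rsid, v$risk_allele, USE.NAMES = FALSE),
    certainty = v$certainty, allele_frequency = v$allele_frequency,
    effect_summary = v$effect_summary
  )
  for (p in cmp$persons) {
    marks <- vapply(seq_len(nrow(v)), function(i) {
      d <- cmp$entries$display_impact[
        cmp$entries$rsid == v$rsid[i] &
          cmp$entries$risk_allele == v$risk_allele[i] &
          cmp$entries$person_id == p
      ]
      if (length(d) == 0) "absent"
      else if (d[1] == "carrier") "carrier"
      else "present"
    }, character(1))
    base[[p]] <- marks
  }
  new_layout(base, "table_layout", persons = cmp$persons)
}
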