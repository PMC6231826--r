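test_that("impact styles are the five distinct encodings", {
  impacts <- c("pathogenic", "benign", "protective", "pharmacogenetic",
               "carrier")
  s <- style_for(impacts)
  expect_equal(s$color, c("red", "gray", "blue", "purple", "red"))
  expect_equal(s$pattern, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # total and injective over (color, pattern)
  expect_equal(dplyr::n_distinct(paste(s$color, s$pattern)), 5)
  expect_error(style_for("unknown"), class = "varkin_validation_error")
})

test_that("a lone variant gets a single arc in its carrier's ring", {
  r1 <- person_report(report_row("A-1", "rs1", "A", "heterozygous",
                                 "benign"), "P1")
  r2 <- person_report(report_row("A-1", "rs1", "A", "heterozygous",
                                 "benign")[0, ], "P2")
  cmp <- compare_reports(list(r1, r2))
  arcs <- sunburst_layout(cmp)
  expect_equal(nrow(arcs), 1)
  expect_equal(arcs$ring_index, 0L)   # P1 outermost by default
  expect_equal(arcs$person_id, "P1")
  expect_gt(arcs$extent, 0)
})

test_that("shared variants are radially aligned across rings", {
  for (seed in c(3, 14)) {
    cmp <- random_comparison(3, seed)
    arcs <- sunburst_layout(cmp)
    by_key <- split(arcs, paste(arcs$rsid, arcs$risk_allele))
    for (grp in by_key) {
      expect_equal(length(unique(grp$start_angle)), 1)
      expect_equal(length(unique(grp$extent)), 1)
      expect_equal(length(unique(grp$ring_index)), nrow(grp))
    }
  }
})

test_that("arc slots plus gaps close the circle to within 1e-9 degrees", {
  for (seed in 1:10) {
    cmp <- random_comparison(sample(2:4, 1), 200 + seed)
    arcs <- sunburst_layout(cmp)
    slots <- dplyr::distinct(as.data.frame(arcs)[c("rsid", "risk_allele",
                                                   "start_angle",
                                                   "extent")])
    slots <- slots[order(slots$start_angle), ]
    n <- nrow(slots)
    gaps <- c(slots$start_angle[-1], 360) -
      (slots$start_angle + slots$extent)
    expect_true(all(gaps > 0))
    expect_equal(length(unique(round(gaps, 9))), 1)
    expect_lt(abs(sum(slots$extent) + sum(gaps) - 360), 1e-9)
  }
})

test_that("ring order is an explicit, validated parameter", {
  cmp <- random_comparison(3, 8)
  rev_arcs <- sunburst_layout(cmp, ring_order = rev(cmp$persons))
  expect_equal(
    unique(rev_arcs$person_id[rev_arcs$ring_index == 0]),
    cmp$persons[3]
  )
  expect_error(sunburst_layout(cmp, ring_order = c("P1", "P2")),
               class = "varkin_identity_error")
  expect_error(sunburst_layout(cmp, ring_order = c(cmp$persons[1:2],
                                                   cmp$persons[2])),
               class = "varkin_identity_error")
})

test_that("fully shared comparisons produce identical rows in the linear view", {
  kb <- generate_kb(n_variants = 12, seed = 5)
  r1 <- random_report("P1", kb, 7, 5)
  r2 <- person_report(as.data.frame(r1), "P2")
  rects <- linear_layout(compare_reports(list(r1, r2)))
  top <- rects[rects$row_index == 0, c("x_offset", "width", "rsid")]
  bottom <- rects[rects$row_index == 1, c("x_offset", "width", "rsid")]
  expect_equal(as.data.frame(top), as.data.frame(bottom))
})

test_that("shared slots precede singleton slots in sunburst and linear views", {
  shared <- dplyr::bind_rows(
    report_row("S-1", "rs1", "A", "heterozygous", "benign",
               allele_frequency = 0.3),
    report_row("S-2", "rs2", "C", "heterozygous", "protective",
               allele_frequency = 0.01)
  )
  r1 <- person_report(dplyr::bind_rows(
    shared, report_row("U-1", "rs3", "G", "homozygous", "pathogenic")
  ), "P1")
  r2 <- person_report(shared, "P2")
  cmp <- compare_reports(list(r1, r2))
  rects <- linear_layout(cmp)
  shared_x <- rects$x_offset[rects$rsid %in% c("rs1", "rs2")]
  unique_x <- rects$x_offset[rects$rsid == "rs3"]
  expect_true(max(shared_x) < min(unique_x))
  arcs <- sunburst_layout(cmp)
  expect_true(max(arcs$start_angle[arcs$rsid %in% c("rs1", "rs2")]) <
                min(arcs$start_angle[arcs$rsid == "rs3"]))
})

test_that("no two rectangles in a row overlap on random inputs", {
  for (seed in 1:8) {
    cmp <- random_comparison(sample(2:4, 1), 300 + seed)
    rects <- linear_layout(cmp)
    expect_equal(oracle_row_overlaps(as.data.frame(rects)), 0L)
    expect_true(all(rects$width > 0))
    expect_true(all(rects$x_offset >= 0 &
                      rects$x_offset + rects$width <= 1 + 1e-12))
  }
})

test_that("venn regions follow membership and bubbles never collide", {
  fix <- list(
    person_report(dplyr::bind_rows(
      report_row("S-1", "rs1", "A", "heterozygous", "benign"),
      report_row("L-1", "rs2", "C", "heterozygous", "pathogenic")
    ), "Morgan"),
    person_report(dplyr::bind_rows(
      report_row("S-1", "rs1", "A", "homozygous", "benign"),
      report_row("R-1", "rs3", "G", "heterozygous", "protective")
    ), "Riley")
  )
  bubbles <- venn_layout(compare_reports(fix))
  expect_equal(bubbles$region[bubbles$rsid == "rs1"], "shared")
  expect_equal(bubbles$region[bubbles$rsid == "rs2"], "left_only")
  expect_equal(bubbles$region[bubbles$rsid == "rs3"], "right_only")
  boxes <- c(left_only = 0, shared = 1, right_only = 2)
  expect_true(all(bubbles$x - bubbles$radius >= boxes[bubbles$region]))
  expect_true(all(bubbles$x + bubbles$radius <= boxes[bubbles$region] + 1))
  for (seed in 1:8) {
    cmp <- random_comparison(2, 400 + seed)
    b <- venn_layout(cmp)
    expect_equal(oracle_bubble_overlaps(as.data.frame(b)), 0L)
    expect_true(all(b$radius > 0))
  }
})

test_that("venn is two-set only", {
  cmp <- random_comparison(4, 9)
  expect_error(venn_layout(cmp), class = "varkin_arity_error")
})

test_that("the table view lists each variant once with per-person marks", {
  cmp <- random_comparison(3, 23)
  rows <- table_view(cmp)
  expect_equal(nrow(rows), nrow(cmp$variants))
  expect_false(is.unsorted(paste(rows$category, rows$variant_name)))
  for (p in cmp$persons) {
    expect_true(all(rows[[p]] %in% c("present", "carrier", "absent")))
  }
  # marks agree with the underlying entries
  for (i in seq_len(nrow(rows))) {
    for (p in cmp$persons) {
      d <- cmp$entries$display_impact[
        cmp$entries$rsid == rows$rsid[i] &
          cmp$entries$risk_allele == rows$risk_allele[i] &
          cmp$entries$person_id == p
      ]
      want <- if (length(d) == 0) "absent"
              else if (d == "carrier") "carrier" else "present"
      expect_equal(rows[[p]][i], want)
    }
  }
})

test_that("glyph sizes track rarity: rarer variants draw larger", {
  freqs <- c(0.4, 0.05, 0.005)
  rows <- dplyr::bind_rows(lapply(seq_along(freqs), function(i) {
    report_row(sprintf("V-%d", i), sprintf("rs%d", i), "A",
               "heterozygous", "benign", allele_frequency = freqs[i])
  }))
  r1 <- person_report(rows, "P1")
  r2 <- person_report(rows, "P2")
  cmp <- compare_reports(list(r1, r2))
  freq_of <- function(rsid) freqs[match(rsid, sprintf("rs%d", 1:3))]
  arcs <- sunburst_layout(cmp)
  expect_equal(order(arcs$extent), order(-freq_of(arcs$rsid)))
  rects <- linear_layout(cmp)
  expect_equal(order(rects$width), order(-freq_of(rects$rsid)))
  bubbles <- venn_layout(cmp)
  expect_equal(order(bubbles$radius), order(-freq_of(bubbles$rsid)))
})

test_that("glyph counts obey the conservation formula", {
  for (seed in c(2, 19)) {
    cmp <- random_comparison(3, 500 + seed)
    expected <- sum(lengths(cmp$variants$signature))
    expect_equal(nrow(sunburst_layout(cmp)), expected)
    expect_equal(nrow(linear_layout(cmp)), expected)
    expect_equal(nrow(table_view(cmp)), nrow(cmp$variants))
  }
})

test_that("empty comparisons lay out to empty geometry", {
  empty <- person_report(report_row("a", "rs1", "A", "heterozygous",
                                    "benign")[0, ], "P1")
  empty2 <- person_report(report_row("a", "rs1", "A", "heterozygous",
                                     "benign")[0, ], "P2")
  cmp <- compare_reports(list(empty, empty2))
  expect_equal(nrow(sunburst_layout(cmp)), 0)
  expect_equal(nrow(linear_layout(cmp)), 0)
  expect_equal(nrow(venn_layout(cmp)), 0)
  expect_equal(nrow(table_view(cmp)), 0)
})

test_that("autoplot methods return ggplot objects", {
  cmp <- random_comparison(2, 66)
  expect_s3_class(ggplot2::autoplot(sunburst_layout(cmp)), "ggplot")
  expect_s3_class(ggplot2::autoplot(linear_layout(cmp)), "ggplot")
  expect_s3_class(ggplot2::autoplot(venn_layout(cmp)), "ggplot")
  expect_s3_class(ggplot2::autoplot(table_view(cmp)), "ggplot")
})
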