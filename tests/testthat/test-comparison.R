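test_that("identical reports land entirely in the full-sharing class", {
  kb <- generate_kb(n_variants = 15, seed = 1)
  r <- random_report("P1", kb, 8, 1)
  r2 <- person_report(as.data.frame(r), "P2")
  cmp <- compare_reports(list(r, r2))
  cls <- comparison_classes(cmp)
  expect_equal(nrow(cls), 1)
  expect_equal(cls$signature_id, "P1+P2")
  expect_equal(cls$n_variants, nrow(r))
})

test_that("disjoint reports populate only singleton classes", {
  kb <- generate_kb(n_variants = 20, seed = 2)
  keys <- paste(kb$rsid, kb$risk_allele, sep = "/")
  r1 <- random_report("P1", kb[1:8, ], 8, 3)
  r2 <- random_report("P2", kb[9:16, ], 8, 4)
  cmp <- compare_reports(list(r1, r2))
  cls <- comparison_classes(cmp)
  expect_setequal(cls$signature_id, c("P1", "P2"))
  expect_equal(sum(cls$n_variants), 16)
})

test_that("the partition matches the powerset oracle for N = 2, 3, 4", {
  for (n_persons in 2:4) {
    for (seed in 1:10) {
      cmp <- random_comparison(n_persons, seed * 17 + n_persons)
      key_sets <- lapply(setNames(cmp$persons, cmp$persons), function(p) {
        keep <- vapply(cmp$entries$person_id, identical, logical(1), p)
        paste(cmp$entries$rsid[keep], cmp$entries$risk_allele[keep],
              sep = "/")
      })
      expect_identical(partition_of(cmp), oracle_partition(key_sets))
      # every key in exactly one class; union of classes == union of inputs
      keys <- paste(cmp$variants$rsid, cmp$variants$risk_allele, sep = "/")
      expect_false(anyDuplicated(keys) > 0)
      expect_setequal(keys, unique(unlist(key_sets)))
      n_classes <- dplyr::n_distinct(cmp$variants$class_index)
      expect_gte(n_classes, 1)
      expect_lte(n_classes, 2^n_persons - 1)
    }
  }
})

test_that("classes are ordered shared-first, then by size, ties by person order", {
  cmp <- random_comparison(4, 99)
  cls <- comparison_classes(cmp)
  sizes <- lengths(cls$signature)
  if (sizes[1] == length(cmp$persons)) {
    expect_true(all(diff(sizes) <= 0))
  }
  # among equal-sized signatures, earlier persons come first
  for (s in unique(sizes)) {
    idx <- which(sizes == s)
    if (length(idx) > 1) {
      ranks <- vapply(cls$signature[idx], function(sig) {
        paste(sprintf("%02d", sort(match(sig, cmp$persons))),
              collapse = "")
      }, character(1))
      expect_false(is.unsorted(ranks))
    }
  }
})

test_that("comparison is symmetric under report reordering", {
  kb <- generate_kb(n_variants = 18, seed = 6)
  reports <- lapply(1:3, function(i) {
    random_report(paste0("P", i), kb, 9, 600 + i)
  })
  cmp_a <- compare_reports(reports)
  cmp_b <- compare_reports(rev(reports))
  # signature ids follow each comparison's person order; normalise before
  # comparing the partitions themselves
  canonical <- function(cmp) {
    part <- partition_of(cmp)
    names(part) <- vapply(strsplit(names(part), "+", fixed = TRUE),
                          function(m) paste(sort(m), collapse = "+"),
                          character(1))
    part[order(names(part))]
  }
  expect_identical(canonical(cmp_a), canonical(cmp_b))
  expect_equal(sort(cmp_a$persons), sort(cmp_b$persons))
})

test_that("arity and identity preconditions are enforced", {
  kb <- generate_kb(n_variants = 10, seed = 7)
  r <- lapply(1:5, function(i) random_report(paste0("P", i), kb, 5, i))
  expect_error(compare_reports(r[1]), class = "varkin_arity_error")
  expect_error(compare_reports(r), class = "varkin_arity_error")
  dup <- list(r[[1]], person_report(as.data.frame(r[[2]]), "P1"))
  expect_error(compare_reports(dup), class = "varkin_identity_error")
})

test_that("shared_count matches direct set intersection over all subsets", {
  for (seed in c(5, 21)) {
    cmp <- random_comparison(4, seed)
    key_sets <- lapply(setNames(cmp$persons, cmp$persons), function(p) {
      keep <- cmp$entries$person_id == p
      paste(cmp$entries$rsid[keep], cmp$entries$risk_allele[keep],
            sep = "/")
    })
    subsets <- unlist(lapply(2:4, function(k) {
      utils::combn(cmp$persons, k, simplify = FALSE)
    }), recursive = FALSE)
    for (s in subsets) {
      expect_equal(shared_count(cmp, s),
                   length(Reduce(intersect, key_sets[s])))
    }
  }
  cmp <- random_comparison(2, 31)
  expect_error(shared_count(cmp, c("P1", "nope")),
               class = "varkin_identity_error")
  expect_error(shared_count(cmp, "P1"), class = "varkin_validation_error")
})

test_that("a family query: which child shares most cancer variants with Parent 1", {
  # crafted family: Child1 shares 2 cancer variants with Parent1, Child2
  # shares 1; the argmax answers the comprehension query
  cancer <- function(name, rsid) {
    report_row(name, rsid, "A", "heterozygous", "pathogenic",
               category = "Cancer")
  }
  p1 <- person_report(dplyr::bind_rows(
    cancer("CA-1", "rs1"), cancer("CA-2", "rs2"), cancer("CA-3", "rs3")
  ), "Parent1")
  p2 <- person_report(cancer("CA-4", "rs4"), "Parent2")
  c1 <- person_report(dplyr::bind_rows(
    cancer("CA-1", "rs1"), cancer("CA-2", "rs2")
  ), "Child1")
  c2 <- person_report(dplyr::bind_rows(
    cancer("CA-3", "rs3"), cancer("CA-4", "rs4")
  ), "Child2")
  cmp <- compare_reports(list(p1, p2, c1, c2))
  spec <- filter_spec(categories = "Cancer")
  counts <- vapply(c("Child1", "Child2"), function(ch) {
    shared_count(cmp, c("Parent1", ch), spec)
  }, numeric(1))
  expect_equal(unname(counts), c(2, 1))
  expect_equal(names(which.max(counts)), "Child1")
})

test_that("compare_counts is antisymmetric and filter-aware", {
  mk <- function(person, n_cancer, n_other) {
    rows <- c(
      lapply(seq_len(n_cancer), function(i) {
        report_row(sprintf("%s-CA%d", person, i),
                   sprintf("rs%s%d", person, i), "A", "heterozygous",
                   "pathogenic", category = "Cancer")
      }),
      lapply(seq_len(n_other), function(i) {
        report_row(sprintf("%s-OT%d", person, i),
                   sprintf("rs%sx%d", person, i), "A", "heterozygous",
                   "benign", category = "Blood")
      })
    )
    person_report(dplyr::bind_rows(rows), person)
  }
  cmp <- compare_reports(list(mk("A", 3, 1), mk("B", 1, 5)))
  spec <- filter_spec(categories = "Cancer")
  expect_equal(compare_counts(cmp, "A", "B", spec), "more")
  expect_equal(compare_counts(cmp, "B", "A", spec), "fewer")
  expect_equal(compare_counts(cmp, "A", "A", spec), "same")
  # without the filter B has more variants overall
  expect_equal(compare_counts(cmp, "A", "B"), "fewer")
  expect_error(compare_counts(cmp, "A", "ghost"),
               class = "varkin_identity_error")
})

test_that("carrier outlook returns exactly the carrier findings, in order", {
  r <- person_report(dplyr::bind_rows(
    report_row("A-1", "rs1", "A", "heterozygous", "carrier"),
    report_row("B-1", "rs2", "A", "homozygous", "pathogenic"),
    report_row("C-1", "rs3", "A", "heterozygous", "carrier",
               category = "Blood"),
    report_row("D-1", "rs4", "A", "heterozygous", "benign")
  ), "kid")
  out <- carrier_outlook(r)
  expect_equal(out$rsid, c("rs1", "rs3"))
  expect_true(all(out$display_impact == "carrier"))
  none <- person_report(report_row("E-1", "rs9", "A", "homozygous",
                                   "pathogenic"), "none")
  expect_equal(nrow(carrier_outlook(none)), 0)
})

test_that("the same variant can be carrier in one person and pathogenic in another", {
  shared_effect <- function(zyg, who) {
    person_report(report_row("CFTR-F508del", "rs101", "D", zyg,
                             derive_display_impact("pathogenic",
                                                   "recessive", zyg),
                             category = "Metabolism"), who)
  }
  cmp <- compare_reports(list(shared_effect("heterozygous", "Child1"),
                              shared_effect("homozygous", "Child2")))
  expect_equal(comparison_classes(cmp)$signature_id, "Child1+Child2")
  marks <- table_view(cmp)
  expect_equal(marks$Child1, "carrier")
  expect_equal(marks$Child2, "present")
})

test_that("comparison JSON round-trips field-exactly", {
  for (seed in c(4, 8)) {
    cmp <- random_comparison(3, seed)
    f <- withr::local_tempfile(fileext = ".json")
    write_comparison_json(cmp, f)
    back <- read_comparison_json(f)
    expect_equal(back$persons, cmp$persons)
    expect_equal(as.data.frame(back$variants),
                 as.data.frame(cmp$variants))
    expect_equal(
      dplyr::arrange(back$entries, person_id, rsid),
      dplyr::arrange(cmp$entries, person_id, rsid)
    )
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"foo": 1}', bad)
  expect_error(read_comparison_json(bad), class = "varkin_format_error")
})
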