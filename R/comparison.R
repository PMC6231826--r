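# Partition annotated variants across 2-4 persons into membership classes
# (who carries what) and answer the comparative queries the views support.

signature_id <- function(persons) paste(persons, collapse = "+")

# order classes: full-sharing first, then descending signature size,
# ties broken by the positions of the members in the person order
order_signatures <- function(signatures, persons) {
  n <- length(persons)
  keys <- vapply(signatures, function(sig) {
    idx <- match(sig, persons)
    pad <- c(sort(idx), rep(n + 1L, n - length(idx)))
    sprintf(
      "%d-%02d-%s",
      as.integer(length(sig) != n),       # full signature first
      n - length(sig),                    # then larger signatures
      paste(sprintf("%02d", pad), collapse = "")
    )
  }, character(1))
  order(keys)
}

# rebuild a comparison_report from a long entries table; used by compare()
# and by the person-facet filter (which recomputes the partition over the
# visible persons)
build_comparison <- function(entries, persons) {
  entries <- bare_tibble(entries) %>%
    mutate(.pidx = match(.data$person_id, persons)) %>%
    arrange(.data$rsid, .data$risk_allele, .data$.pidx)
  key <- paste(entries$rsid, entries$risk_allele, sep = "/")
  sig_by_key <- split(entries$person_id, factor(key, levels = unique(key)))
  variants <- entries %>%
    distinct(.data$rsid, .data$risk_allele, .keep_all = TRUE) %>%
    select(
      "rsid", "risk_allele", "variant_name", "category", "certainty",
      "allele_frequency", "rarity_size", "clinical_importance",
      "effect_summary"
    )
  variants$signature <- unname(sig_by_key[paste(variants$rsid,
                                                variants$risk_allele,
                                                sep = "/")])
  sigs <- unique(variants$signature)
  sigs <- sigs[order_signatures(sigs, persons)]
  sig_rank <- setNames(seq_along(sigs),
                       vapply(sigs, signature_id, character(1)))
  variants <- variants %>%
    mutate(class_index = unname(
      sig_rank[vapply(.data$signature, signature_id, character(1))]
    )) %>%
    arrange(.data$class_index, .data$category, .data$variant_name)
  structure(
    list(
      persons = persons,
      variants = variants,
      entries = select(
        entries, "person_id", "rsid", "risk_allele", "zygosity",
        "display_impact"
      )
    ),
    class = "comparison_report"
  )
}

#' Compare 2-4 person reports
#'
#' Partitions the union of annotated variants into membership classes: each
#' distinct variant key (rsid, risk allele) is assigned to the signature of
#' exactly the persons whose reports contain it. Per-person zygosity and
#' display impact are retained — the same variant may be a carrier finding
#' in one person and pathogenic in another, and still counts as shared.
#' Classes are ordered with the full-sharing signature first, then by
#' descending signature size, ties by person order, so downstream layouts
#' place shared variants first.
#'
#' @param reports A list of 2 to 4 `person_report` objects with distinct
#'   person ids (or the reports themselves via `...`).
#' @param ... Additional reports, if `reports` is a single report.
#' @return A `comparison_report`: person order, a `variants` tibble (one
#'   row per distinct key with its membership `signature` list-column and
#'   `class_index`), and an `entries` tibble of per-person annotations.
#' @examples
#' kb <- generate_kb(n_variants = 20, seed = 7)
#' fam <- simulate_family(kb, seed = 7)
#' reports <- lapply(fam, annotate_genotypes, kb = kb)
#' cmp <- compare_reports(reports)
#' glance(cmp)
#' @export
compare_reports <- function(reports, ...) {
  if (inherits(reports, "person_report")) reports <- c(list(reports), list(...))
  stopifnot(is.list(reports))
  if (!all(vapply(reports, inherits, logical(1), "person_report"))) {
    stop_varkin("all elements must be person_report objects",
                class = "varkin_validation_error")
  }
  if (length(reports) < 2 || length(reports) > 4) {
    stop_varkin(
      sprintf("comparison requires 2 to 4 reports, got %d", length(reports)),
      class = "varkin_arity_error"
    )
  }
  persons <- vapply(reports, person_id, character(1))
  if (anyDuplicated(persons)) {
    stop_varkin(
      sprintf("duplicate person_id(s): %s",
              paste(unique(persons[duplicated(persons)]), collapse = ", ")),
      class = "varkin_identity_error"
    )
  }
  entries <- bind_rows(lapply(reports, tidy))
  build_comparison(entries, persons)
}

#' Membership classes of a comparison
#'
#' @param cmp A `comparison_report`.
#' @return A tibble with one row per populated membership class, in class
#'   order: `class_index`, `signature` (list of person ids), `signature_id`
#'   (persons joined by `+`), and `n_variants`.
#' @export
comparison_classes <- function(cmp) {
  stopifnot(inherits(cmp, "comparison_report"))
  cmp$variants %>%
    group_by(.data$class_index) %>%
    summarise(
      signature = .data$signature[1],
      n_variants = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(signature_id = vapply(.data$signature, signature_id,
                                 character(1))) %>%
    select("class_index", "signature", "signature_id", "n_variants")
}

check_persons_known <- function(persons, cmp) {
  unknown <- setdiff(persons, cmp$persons)
  if (length(unknown) > 0) {
    stop_varkin(
      sprintf("unknown person(s): %s", paste(unknown, collapse = ", ")),
      class = "varkin_identity_error"
    )
  }
  invisible(persons)
}

#' Count variants shared by every person in a subset
#'
#' Answers queries like "which child shares the most cancer-related
#' variants with Parent 1?": the count of distinct variant keys (after
#' optional filtering) present in every member of `persons`, i.e. summed
#' over all membership signatures that contain the subset.
#'
#' @param cmp A `comparison_report`.
#' @param persons Character vector of at least 2 person ids from the
#'   comparison.
#' @param filter Optional [filter_spec()] applied before counting.
#' @return An integer count.
#' @export
shared_count <- function(cmp, persons, filter = NULL) {
  stopifnot(inherits(cmp, "comparison_report"))
  check_persons_known(persons, cmp)
  if (length(unique(persons)) < 2) {
    stop_varkin("shared_count needs at least 2 distinct persons",
                class = "varkin_validation_error")
  }
  if (!is.null(filter)) cmp <- apply_filter(cmp, filter)
  # persons may have been hidden by the filter's person facet
  persons <- intersect(persons, cmp$persons)
  if (length(persons) < 2) return(0L)
  sum(vapply(cmp$variants$signature,
             function(sig) all(persons %in% sig), logical(1)))
}

#' Compare two persons' variant counts
#'
#' @param cmp A `comparison_report`.
#' @param person_a,person_b Person ids from the comparison.
#' @param filter Optional [filter_spec()] applied before counting.
#' @return `"more"`, `"fewer"` or `"same"`: whether `person_a` has more,
#'   fewer or the same number of (filtered) variants than `person_b`.
#'   Antisymmetric under argument swap.
#' @export
compare_counts <- function(cmp, person_a, person_b, filter = NULL) {
  stopifnot(inherits(cmp, "comparison_report"))
  check_persons_known(c(person_a, person_b), cmp)
  if (!is.null(filter)) cmp <- apply_filter(cmp, filter)
  count_for <- function(p) {
    if (!p %in% cmp$persons) return(0L)
    sum(vapply(cmp$variants$signature, function(sig) p %in% sig, logical(1)))
  }
  a <- count_for(person_a)
  b <- count_for(person_b)
  if (a > b) "more" else if (a < b) "fewer" else "same"
}

#' Variants relevant to offspring rather than the person themselves
#'
#' Returns exactly the carrier findings of a report: variants the person is
#' heterozygous for with recessive pathogenic effect — not expected to
#' affect the person, but transmissible to their children.
#'
#' @param report A `person_report`.
#' @return The carrier rows of the report, in report order.
#' @export
carrier_outlook <- function(report) {
  stopifnot(inherits(report, "person_report"))
  new_person_report(
    as_tibble(report)[report$display_impact == "carrier", , drop = FALSE],
    person_id(report)
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report: %d persons (%s), %d variants in %d classes>\n",
    length(x$persons), paste(x$persons, collapse = ", "),
    nrow(x$variants), dplyr::n_distinct(x$variants$class_index)
  ))
  invisible(x)
}

#' Tidy a comparison into one row per variant
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return The `variants` tibble with a `signature_id` column (persons
#'   joined by `+`).
#' @export
tidy.comparison_report <- function(x, ...) {
  mutate(x$variants, signature_id = vapply(.data$signature, signature_id,
                                           character(1)))
}

#' Summarise a comparison
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return One-row tibble: number of persons, distinct variants, populated
#'   classes, variants shared by everyone, and carrier findings.
#' @export
glance.comparison_report <- function(x, ...) {
  full <- vapply(x$variants$signature,
                 function(sig) length(sig) == length(x$persons), logical(1))
  tibble(
    n_persons = length(x$persons),
    n_variants = nrow(x$variants),
    n_classes = dplyr::n_distinct(x$variants$class_index),
    n_shared_by_all = sum(full),
    n_carrier_entries = sum(x$entries$display_impact == "carrier")
  )
}

#' Serialize a comparison report to JSON
#'
#' Schema-versioned JSON with the person order and one object per
#' membership class: the class signature (array of person ids) and its
#' variants, each carrying the per-person zygosity and display impact.
#' [read_comparison_json()] is the exact inverse.
#'
#' @param cmp A `comparison_report`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_comparison_json <- function(cmp, file) {
  stopifnot(inherits(cmp, "comparison_report"))
  variant_obj <- function(i) {
    v <- cmp$variants[i, ]
    per <- cmp$entries %>%
      filter(.data$rsid == v$rsid, .data$risk_allele == v$risk_allele) %>%
      select("person_id", "zygosity", "display_impact")
    list(
      rsid = v$rsid, risk_allele = v$risk_allele,
      variant_name = v$variant_name, category = v$category,
      certainty = v$certainty, allele_frequency = v$allele_frequency,
      rarity_size = v$rarity_size,
      clinical_importance = v$clinical_importance,
      effect_summary = v$effect_summary,
      per_person = lapply(seq_len(nrow(per)), function(j) as.list(per[j, ]))
    )
  }
  classes <- lapply(
    split(seq_len(nrow(cmp$variants)), cmp$variants$class_index),
    function(rows) list(
      signature = as.list(cmp$variants$signature[[rows[1]]]),
      variants = lapply(rows, variant_obj)
    )
  )
  payload <- list(
    schema_version = "1.0",
    persons = as.list(cmp$persons),
    classes = unname(classes)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  atomic_write(as.character(json), file)
}

#' Read a comparison report from JSON
#'
#' @param file Path written by [write_comparison_json()].
#' @return A `comparison_report`.
#' @export
read_comparison_json <- function(file) {
  payload <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (is.null(payload$schema_version) || is.null(payload$persons) ||
      is.null(payload$classes)) {
    stop_varkin("not a comparison report JSON (missing schema fields)",
                class = "varkin_format_error")
  }
  persons <- unlist(payload$persons)
  rows <- purrr::map_dfr(payload$classes, function(cl) {
    purrr::map_dfr(cl$variants, function(v) {
      purrr::map_dfr(v$per_person, function(p) tibble(
        person_id = p$person_id,
        rsid = v$rsid, risk_allele = v$risk_allele,
        variant_name = v$variant_name, category = v$category,
        certainty = v$certainty,
        allele_frequency = v$allele_frequency,
        rarity_size = v$rarity_size,
        clinical_importance = v$clinical_importance,
        effect_summary = v$effect_summary,
        zygosity = p$zygosity, display_impact = p$display_impact
      ))
    })
  })
  build_comparison(rows, persons)
}
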