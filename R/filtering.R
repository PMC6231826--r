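# Combinable facet filters and text search over person reports and
# comparison reports. Semantics: a variant survives iff it satisfies every
# nonempty facet (AND across facets); within a facet, membership in any
# selected token suffices (OR within a facet). An empty facet imposes no
# constraint.

#' Build a filter specification
#'
#' Facets combine conjunctively: a variant survives only if it satisfies
#' every nonempty facet. Within one facet, any selected token suffices.
#' The person facet hides non-selected persons and drops variants carried
#' only by hidden persons; on a comparison the partition is recomputed over
#' the visible persons. The search term matches as a case-insensitive
#' substring over variant name, category, clinical importance and effect
#' summary.
#'
#' @param persons Person ids to keep (empty = all).
#' @param categories Health-category labels to keep (empty = all).
#' @param impacts Display impacts to keep, from pathogenic / benign /
#'   protective / pharmacogenetic / carrier.
#' @param certainties Certainty levels to keep, from well_established /
#'   likely / uncertain.
#' @param search Search term ("" = none).
#' @return A `filter_spec`.
#' @examples
#' filter_spec(categories = "Cancer", certainties = "well_established")
#' @export
filter_spec <- function(persons = character(), categories = character(),
                        impacts = character(), certainties = character(),
                        search = "") {
  impacts <- as.character(impacts)
  certainties <- as.character(certainties)
  check_tokens(impacts, display_impact_levels, "impact")
  check_tokens(certainties, certainty_levels, "certainty")
  stopifnot(is.character(search), length(search) == 1)
  structure(
    list(
      persons = as.character(persons),
      categories = as.character(categories),
      impacts = impacts,
      certainties = certainties,
      search = search
    ),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  facet <- function(name, v) {
    if (length(v) == 0 || identical(v, "")) NULL
    else sprintf("%s: %s", name, paste(v, collapse = ", "))
  }
  parts <- c(
    facet("persons", x$persons), facet("categories", x$categories),
    facet("impacts", x$impacts), facet("certainties", x$certainties),
    facet("search", if (nzchar(x$search)) x$search else character())
  )
  if (length(parts) == 0) parts <- "(no constraints)"
  cat("<filter_spec>", paste(" ", parts), sep = "\n")
  invisible(x)
}

search_hit <- function(term, ...) {
  fields <- cbind(...)
  hits <- matrix(
    grepl(tolower(term), tolower(fields), fixed = TRUE),
    nrow = nrow(fields)
  )
  rowSums(hits) > 0
}

# variant-level facets (everything except the person facet); df must carry
# category, certainty, variant_name, clinical_importance, effect_summary
# and an impact vector supplied separately (report rows vs comparison
# variants differ in where impact lives)
variant_facet_keep <- function(df, impacts_of_row, spec) {
  keep <- rep(TRUE, nrow(df))
  if (length(spec$categories) > 0) {
    keep <- keep & df$category %in% spec$categories
  }
  if (length(spec$certainties) > 0) {
    keep <- keep & df$certainty %in% spec$certainties
  }
  if (length(spec$impacts) > 0) {
    keep <- keep & impacts_of_row
  }
  if (nzchar(spec$search)) {
    keep <- keep & search_hit(
      spec$search, df$variant_name, df$category,
      df$clinical_importance, df$effect_summary
    )
  }
  keep
}

#' Apply a filter to a report or comparison
#'
#' @param view A `person_report` or `comparison_report`.
#' @param spec A [filter_spec()].
#' @return A filtered object of the same kind. For a comparison, hidden
#'   persons are removed and the membership partition is recomputed over
#'   the visible persons.
#' @export
apply_filter <- function(view, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  UseMethod("apply_filter")
}

#' @export
apply_filter.person_report <- function(view, spec) {
  pid <- person_id(view)
  df <- as_tibble(view)
  if (length(spec$persons) > 0 && !pid %in% spec$persons) {
    return(new_person_report(df[0, , drop = FALSE], pid))
  }
  keep <- variant_facet_keep(
    df, df$display_impact %in% spec$impacts, spec
  )
  new_person_report(df[keep, , drop = FALSE], pid)
}

#' @export
apply_filter.comparison_report <- function(view, spec) {
  visible <- view$persons
  if (length(spec$persons) > 0) {
    check_persons_known(spec$persons, view)
    visible <- intersect(view$persons, spec$persons)
  }
  entries <- filter(view$entries, .data$person_id %in% visible)
  # for the impact facet a variant survives if ANY visible person's
  # displayed impact matches a selected token
  key <- paste(view$variants$rsid, view$variants$risk_allele, sep = "/")
  ekey <- paste(entries$rsid, entries$risk_allele, sep = "/")
  impact_hit <- vapply(
    key,
    function(k) any(entries$display_impact[ekey == k] %in% spec$impacts),
    logical(1)
  )
  keep <- variant_facet_keep(view$variants, impact_hit, spec)
  kept_keys <- key[keep]
  entries <- entries[ekey %in% kept_keys, , drop = FALSE]
  # variants carried only by hidden persons drop out with their entries
  fields <- select(
    view$variants, "rsid", "risk_allele", "variant_name", "category",
    "certainty", "allele_frequency", "rarity_size", "clinical_importance",
    "effect_summary"
  )
  long <- inner_join(entries, fields, by = c("rsid", "risk_allele"))
  build_comparison(long, visible)
}

#' Enumerate the facet values present in a view
#'
#' @param view A `person_report` or `comparison_report`.
#' @return A list with sorted character vectors `persons`, `categories`,
#'   `impacts`, `certainties` — the distinct values actually present, for
#'   populating filter controls.
#' @export
available_facets <- function(view) {
  UseMethod("available_facets")
}

#' @export
available_facets.person_report <- function(view) {
  list(
    persons = if (nrow(view) > 0) person_id(view) else character(),
    categories = sort(unique(view$category)),
    impacts = sort(unique(view$display_impact)),
    certainties = sort(unique(view$certainty))
  )
}

#' @export
available_facets.comparison_report <- function(view) {
  list(
    persons = view$persons[view$persons %in% view$entries$person_id],
    categories = sort(unique(view$variants$category)),
    impacts = sort(unique(view$entries$display_impact)),
    certainties = sort(unique(view$variants$certainty))
  )
}
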