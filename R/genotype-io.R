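# Readers and writers for the formats the pipeline touches:
# raw consumer genotype files (23andMe tab-separated dialect),
# the variant-effect knowledge base CSV, and per-person report CSVs.

report_columns <- c(
  "variant_name", "rsid", "risk_allele", "zygosity", "display_impact",
  "certainty", "allele_frequency", "rarity_size", "category",
  "clinical_importance", "effect_summary"
)

kb_columns <- c(
  "variant_name", "rsid", "risk_allele", "base_impact", "inheritance",
  "certainty", "allele_frequency", "category", "clinical_importance",
  "effect_summary"
)

new_genotype_set <- function(df, person_id) {
  out <- bare_tibble(df)
  attr(out, "person_id") <- person_id
  class(out) <- c("genotype_set", class(tibble()))
  out
}

new_person_report <- function(df, person_id) {
  out <- bare_tibble(as_tibble(df)[report_columns])
  attr(out, "person_id") <- person_id
  class(out) <- c("person_report", class(tibble()))
  out
}

new_effect_kb <- function(df, source_label) {
  out <- bare_tibble(as_tibble(df)[kb_columns])
  attr(out, "source_label") <- source_label
  class(out) <- c("effect_kb", class(tibble()))
  out
}

#' Construct a genotype set from a data frame
#'
#' @param records Data frame with columns `rsid`, `chromosome`,
#'   `position`, `genotype`.
#' @param person_id Label for the person.
#' @return A validated `genotype_set`.
#' @export
genotype_set <- function(records, person_id) {
  df <- as_tibble(records)
  missing_cols <- setdiff(c("rsid", "chromosome", "position", "genotype"),
                          names(df))
  if (length(missing_cols) > 0) {
    stop_varkin(
      sprintf("genotype records are missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "varkin_format_error"
    )
  }
  df <- mutate(
    df,
    chromosome = as.character(.data$chromosome),
    position = as.integer(.data$position),
    genotype = toupper(.data$genotype)
  )
  validate_genotype_records(df)
  new_genotype_set(df[c("rsid", "chromosome", "position", "genotype")],
                   person_id)
}

#' Construct an effect knowledge base from a data frame
#'
#' @param records Data frame with the knowledge-base columns (see
#'   [read_effect_kb()]).
#' @param source_label Provenance string.
#' @return A validated `effect_kb`.
#' @export
effect_kb <- function(records, source_label = "in-memory") {
  df <- as_tibble(records)
  validate_effect_kb(df)
  new_effect_kb(df, source_label)
}

#' Construct a person report from a data frame
#'
#' @param variants Data frame with the report columns (see
#'   [write_report_csv()]).
#' @param person_id Label for the person.
#' @return A validated `person_report`.
#' @export
person_report <- function(variants, person_id) {
  df <- as_tibble(variants)
  validate_report_df(df)
  new_person_report(df, person_id)
}

#' Person id of a genotype set or report
#'
#' @param x A `genotype_set` or `person_report`.
#' @return A length-1 character label.
#' @export
person_id <- function(x) attr(x, "person_id")

validate_genotype_records <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$position)) || any(df$position < 1)) {
    stop_varkin("genotype positions must be integers >= 1",
                class = "varkin_parse_error")
  }
  geno <- df$genotype
  ok_len <- nchar(geno) >= 1 & nchar(geno) <= 2
  ok_chr <- grepl("^[ACGTID-]+$", geno)
  if (!all(ok_len & ok_chr)) {
    bad <- which(!(ok_len & ok_chr))[1]
    stop_varkin(
      sprintf("invalid genotype '%s' at rsid %s", geno[bad], df$rsid[bad]),
      class = "varkin_parse_error"
    )
  }
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup) > 0) {
    stop_varkin(
      sprintf("duplicate rsid(s) in genotype file: %s",
              paste(unique(dup), collapse = ", ")),
      class = "varkin_duplicate_error"
    )
  }
  invisible(df)
}

#' Read a raw genotype file in the 23andMe tab-separated dialect
#'
#' The dialect is UTF-8 text; lines starting with `#` are comments; every
#' data line has exactly four tab-separated fields: rsid, chromosome,
#' 1-based position, and a genotype string of one or two alleles over
#' `A C G T I D -` (`--` is a no-call, `I`/`D` are insertion/deletion
#' alleles). Genotypes are uppercased on read; input order is preserved.
#'
#' @param file Path to the raw file (or a connection).
#' @param person_id Label identifying the person the file belongs to.
#'   Defaults to the file name without extension.
#' @return A `genotype_set`: a tibble with columns `rsid`, `chromosome`,
#'   `position`, `genotype` and a `person_id` attribute (see [person_id()]).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# comment", "rs1\t1\t1001\tAG"), f)
#' read_raw_genotypes(f, person_id = "demo")
#' @export
read_raw_genotypes <- function(file, person_id = NULL) {
  if (is.character(file) && length(file) == 1 && is.null(person_id)) {
    person_id <- sub("\\.[^.]*$", "", basename(file))
  }
  if (is.null(person_id)) person_id <- "person"
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  is_comment <- startsWith(lines, "#")
  is_blank <- !nzchar(trimws(lines))
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) == 0) {
    empty <- tibble(
      rsid = character(), chromosome = character(),
      position = integer(), genotype = character()
    )
    return(new_genotype_set(empty, person_id))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop_varkin(
      sprintf("malformed genotype line %d: expected 4 tab-separated fields, got %d",
              data_idx[bad], nf[bad]),
      class = "varkin_parse_error"
    )
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop_varkin(
      sprintf("malformed genotype line %d: position '%s' is not an integer",
              data_idx[bad], m[bad, 3]),
      class = "varkin_parse_error"
    )
  }
  df <- tibble(
    rsid = m[, 1],
    chromosome = m[, 2],
    position = pos,
    genotype = toupper(m[, 4])
  )
  validate_genotype_records(df)
  new_genotype_set(df, person_id)
}

#' Write a genotype set in the 23andMe tab-separated dialect
#'
#' @param genotypes A `genotype_set`.
#' @param file Output path. Written atomically (temp file + rename).
#' @return The path, invisibly.
#' @export
write_raw_genotypes <- function(genotypes, file) {
  header <- c(
    "# synthetic raw genotype data",
    sprintf("# person: %s", person_id(genotypes) %||% "unknown"),
    "# rsid\tchromosome\tposition\tgenotype"
  )
  body <- sprintf(
    "%s\t%s\t%d\t%s",
    genotypes$rsid, genotypes$chromosome, genotypes$position, genotypes$genotype
  )
  atomic_write(c(header, body), file)
}

validate_effect_kb <- function(df) {
  required <- setdiff(kb_columns, names(df))
  if (length(required) > 0) {
    stop_varkin(
      sprintf("knowledge base is missing column(s): %s",
              paste(required, collapse = ", ")),
      class = "varkin_format_error"
    )
  }
  check_row <- function(ok, what) {
    if (!all(ok)) {
      stop_varkin(
        sprintf("knowledge base row %d: %s", which(!ok)[1], what),
        class = "varkin_validation_error"
      )
    }
  }
  check_row(df$base_impact %in% base_impact_levels,
            sprintf("base_impact must be one of %s",
                    paste(base_impact_levels, collapse = ", ")))
  check_row(df$inheritance %in% inheritance_levels,
            sprintf("inheritance must be one of %s",
                    paste(inheritance_levels, collapse = ", ")))
  check_row(df$certainty %in% certainty_levels,
            sprintf("certainty must be one of %s",
                    paste(certainty_levels, collapse = ", ")))
  check_row(is.finite(df$allele_frequency) &
              df$allele_frequency > 0 & df$allele_frequency <= 1,
            "allele_frequency must lie in (0, 1]")
  check_row(df$risk_allele %in% allele_alphabet,
            "risk_allele must be a single character in A, C, G, T, I, D")
  check_row(nzchar(df$category) & !is.na(df$category),
            "category must be nonempty")
  key <- paste(df$rsid, df$risk_allele, sep = "/")
  if (anyDuplicated(key)) {
    stop_varkin(
      sprintf("duplicate (rsid, risk_allele) key(s) in knowledge base: %s",
              paste(unique(key[duplicated(key)]), collapse = ", ")),
      class = "varkin_duplicate_error"
    )
  }
  invisible(df)
}

#' Read a variant-effect knowledge base CSV
#'
#' The knowledge base is the report's universe of known effects, one row per
#' (rsid, risk allele), with the fields of a GET-Evidence-style gene variant
#' report: `variant_name` (GENE-change), `rsid`, `risk_allele`,
#' `base_impact` (pathogenic / benign / protective / pharmacogenetic),
#' `inheritance` (dominant / recessive / unknown), `certainty`
#' (well_established / likely / uncertain), `allele_frequency` in (0, 1],
#' `category` (health category), `clinical_importance` and `effect_summary`.
#'
#' @param file CSV path or connection.
#' @param source_label Provenance string stored on the result.
#' @return An `effect_kb` tibble.
#' @export
read_effect_kb <- function(file, source_label = NULL) {
  if (is.null(source_label)) {
    source_label <- if (is.character(file)) basename(file) else "effect_kb"
  }
  df <- readr::read_csv(
    file, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if ("allele_frequency" %in% names(df)) {
    df$allele_frequency <- suppressWarnings(as.numeric(df$allele_frequency))
  }
  validate_effect_kb(df)
  new_effect_kb(df, source_label)
}

#' Write a variant-effect knowledge base CSV
#'
#' @param kb An `effect_kb`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_effect_kb <- function(kb, file) {
  readr::write_csv(as_tibble(kb)[kb_columns], file, progress = FALSE)
  invisible(file)
}

#' Write a person report as CSV
#'
#' One row per annotated variant, RFC-4180 quoting, header always written.
#' [read_report_csv()] is the exact inverse.
#'
#' @param report A `person_report` from [annotate_genotypes()].
#' @param file Output path or connection.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, file) {
  stopifnot(inherits(report, "person_report"))
  readr::write_csv(as_tibble(report)[report_columns], file, progress = FALSE)
  invisible(file)
}

validate_report_df <- function(df) {
  missing_cols <- setdiff(report_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_varkin(
      sprintf("report is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "varkin_format_error"
    )
  }
  if (nrow(df) == 0) return(invisible(df))
  check_tokens(df$zygosity, zygosity_levels, "zygosity")
  check_tokens(df$display_impact, display_impact_levels, "impact")
  check_tokens(df$certainty, certainty_levels, "certainty")
  key <- paste(df$rsid, df$risk_allele, sep = "/")
  if (anyDuplicated(key)) {
    stop_varkin("duplicate (rsid, risk_allele) key in report",
                class = "varkin_duplicate_error")
  }
  invisible(df)
}

#' Read a person report CSV
#'
#' @param file CSV path or connection produced by [write_report_csv()].
#' @param person_id Label for the person; defaults to the file name stem.
#' @return A `person_report` tibble.
#' @export
read_report_csv <- function(file, person_id = NULL) {
  if (is.character(file) && length(file) == 1 && is.null(person_id)) {
    person_id <- sub("\\.[^.]*$", "", basename(file))
  }
  if (is.null(person_id)) person_id <- "person"
  df <- readr::read_csv(
    file, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in intersect(c("allele_frequency", "rarity_size"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  validate_report_df(df)
  new_person_report(df, person_id)
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set: %s, %d records>\n", person_id(x), nrow(x)))
  NextMethod()
}

#' @export
print.person_report <- function(x, ...) {
  cat(sprintf("<person_report: %s, %d annotated variants>\n",
              person_id(x), nrow(x)))
  NextMethod()
}

#' @export
print.effect_kb <- function(x, ...) {
  cat(sprintf("<effect_kb: %s, %d records>\n",
              attr(x, "source_label"), nrow(x)))
  NextMethod()
}
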