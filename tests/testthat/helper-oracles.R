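# Independent oracles the tests check the implementation against. These
# deliberately use brute-force enumeration / direct set algebra rather than
# the package's own code paths.

# zygosity by literal allele counting over the split genotype string
oracle_zygosity <- function(genotype, risk_allele) {
  alleles <- strsplit(genotype, "")[[1]]
  if ("-" %in% alleles) return(NA_character_)
  hits <- sum(alleles == risk_allele)
  if (length(alleles) == 2) {
    if (hits == 2) "homozygous" else if (hits == 1) "heterozygous"
    else NA_character_
  } else {
    if (hits == 1) "hemizygous" else NA_character_
  }
}

# the full 36-row display-impact truth table, written out explicitly:
# exactly one cell (pathogenic, recessive, heterozygous) maps to carrier
oracle_impact_table <- function() {
  tab <- expand.grid(
    base_impact = c("pathogenic", "benign", "protective",
                    "pharmacogenetic"),
    inheritance = c("dominant", "recessive", "unknown"),
    zygosity = c("heterozygous", "homozygous", "hemizygous"),
    stringsAsFactors = FALSE
  )
  tab$expected <- tab$base_impact
  carrier_cell <- tab$base_impact == "pathogenic" &
    tab$inheritance == "recessive" & tab$zygosity == "heterozygous"
  stopifnot(sum(carrier_cell) == 1)
  tab$expected[carrier_cell] <- "carrier"
  tab
}

# naive double-loop join of genotypes against a KB data frame
oracle_annotate_keys <- function(genotypes, kb) {
  keys <- character(0)
  for (i in seq_len(nrow(kb))) {
    for (j in seq_len(nrow(genotypes))) {
      if (kb$rsid[i] == genotypes$rsid[j]) {
        z <- oracle_zygosity(genotypes$genotype[j], kb$risk_allele[i])
        if (!is.na(z)) {
          keys <- c(keys, paste(kb$rsid[i], kb$risk_allele[i], sep = "/"))
        }
      }
    }
  }
  sort(unique(keys))
}

# powerset membership: for each key, the exact subset of persons whose
# key set contains it; returns a named list signature_id -> sorted keys
oracle_partition <- function(key_sets) {
  persons <- names(key_sets)
  all_keys <- sort(unique(unlist(key_sets)))
  out <- list()
  for (k in all_keys) {
    members <- persons[vapply(key_sets, function(s) k %in% s, logical(1))]
    id <- paste(members, collapse = "+")
    out[[id]] <- sort(c(out[[id]], k))
  }
  out[order(names(out))]
}

# signature map of a comparison_report in the same shape as
# oracle_partition's output
partition_of <- function(cmp) {
  keys <- paste(cmp$variants$rsid, cmp$variants$risk_allele, sep = "/")
  ids <- vapply(cmp$variants$signature, paste, character(1), collapse = "+")
  out <- lapply(split(keys, ids), sort)
  out[order(names(out))]
}

# direct set-algebra filter over a report data frame; mirrors the
# contract's AND-across / OR-within semantics with plain vector operations
oracle_filter_keys <- function(df, impacts_by_key, spec) {
  keep <- rep(TRUE, nrow(df))
  if (length(spec$categories) > 0) {
    keep <- keep & df$category %in% spec$categories
  }
  if (length(spec$certainties) > 0) {
    keep <- keep & df$certainty %in% spec$certainties
  }
  if (length(spec$impacts) > 0) {
    key <- paste(df$rsid, df$risk_allele, sep = "/")
    keep <- keep & vapply(
      key, function(k) any(impacts_by_key[[k]] %in% spec$impacts),
      logical(1)
    )
  }
  if (nzchar(spec$search)) {
    hay <- tolower(paste(df$variant_name, df$category,
                         df$clinical_importance, df$effect_summary))
    keep <- keep & grepl(tolower(spec$search), hay, fixed = TRUE)
  }
  sort(unique(paste(df$rsid, df$risk_allele, sep = "/")[keep]))
}

# all-pairs interval overlap within each row of a rect layout
oracle_row_overlaps <- function(rects, tol = 1e-12) {
  bad <- 0L
  for (row in unique(rects$row_index)) {
    r <- rects[rects$row_index == row, ]
    if (nrow(r) < 2) next
    for (i in seq_len(nrow(r) - 1)) {
      for (j in seq(i + 1, nrow(r))) {
        lo <- max(r$x_offset[i], r$x_offset[j])
        hi <- min(r$x_offset[i] + r$width[i], r$x_offset[j] + r$width[j])
        if (hi - lo > tol) bad <- bad + 1L
      }
    }
  }
  bad
}

# all-pairs center distance vs radius sum for a venn layout
oracle_bubble_overlaps <- function(bubbles, tol = 1e-12) {
  n <- nrow(bubbles)
  bad <- 0L
  if (n < 2) return(bad)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt((bubbles$x[i] - bubbles$x[j])^2 +
                  (bubbles$y[i] - bubbles$y[j])^2)
      if (d + tol < bubbles$radius[i] + bubbles$radius[j]) bad <- bad + 1L
    }
  }
  bad
}

# Mendelian consistency: child genotype explainable as one allele from
# each parent (order unknown because genotypes are stored sorted)
oracle_mendel_ok <- function(child, p1, p2) {
  c1 <- substr(child, 1, 1); c2 <- substr(child, 2, 2)
  in_geno <- function(a, g) a == substr(g, 1, 1) | a == substr(g, 2, 2)
  (in_geno(c1, p1) & in_geno(c2, p2)) | (in_geno(c1, p2) & in_geno(c2, p1))
}

svg_glyph_count <- function(path) {
  doc <- xml2::read_xml(path)
  length(xml2::xml_find_all(doc, "//*[@class='glyph']"))
}
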