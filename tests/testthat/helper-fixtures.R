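# Fixture builders used across the suite. Everything is generated in code;
# randomised fixtures always take an explicit seed.

kb_row <- function(variant_name = "GENE1-X1Y", rsid = "rs1",
                   risk_allele = "A", base_impact = "benign",
                   inheritance = "unknown", certainty = "likely",
                   allele_frequency = 0.1, category = "Metabolism",
                   clinical_importance = "low",
                   effect_summary = "synthetic effect") {
  tibble::tibble(
    variant_name = variant_name, rsid = rsid, risk_allele = risk_allele,
    base_impact = base_impact, inheritance = inheritance,
    certainty = certainty, allele_frequency = allele_frequency,
    category = category, clinical_importance = clinical_importance,
    effect_summary = effect_summary
  )
}

# a small hand-crafted KB covering all impacts, a recessive pathogenic
# variant (carrier candidate) and two health categories
fixture_kb <- function() {
  effect_kb(dplyr::bind_rows(
    kb_row("CFTR-F508del", "rs101", "D", "pathogenic", "recessive",
           "well_established", 0.016, "Metabolism", "high",
           "Recessive pathogenic variant; carriers are unaffected"),
    kb_row("BRCA2-K3326X", "rs102", "T", "pathogenic", "dominant",
           "likely", 0.008, "Cancer", "high",
           "Dominant cancer-risk variant"),
    kb_row("FUT2-W154X", "rs103", "A", "protective", "unknown",
           "well_established", 0.45, "Immune", "moderate",
           "Protective against norovirus infection"),
    kb_row("CYP2C19-star2", "rs104", "G", "pharmacogenetic", "unknown",
           "likely", 0.15, "Metabolism", "moderate",
           "Alters clopidogrel drug response"),
    kb_row("APOE-e2", "rs105", "C", "benign", "unknown", "uncertain",
           0.30, "Neurological", "low",
           "Benign variant discussed in Alzheimer disease literature")
  ), source_label = "fixture")
}

report_row <- function(variant_name, rsid, risk_allele, zygosity,
                       display_impact, certainty = "likely",
                       allele_frequency = 0.1, category = "Metabolism",
                       clinical_importance = "low",
                       effect_summary = "synthetic effect") {
  tibble::tibble(
    variant_name = variant_name, rsid = rsid, risk_allele = risk_allele,
    zygosity = zygosity, display_impact = display_impact,
    certainty = certainty, allele_frequency = allele_frequency,
    rarity_size = rarity_size(allele_frequency), category = category,
    clinical_importance = clinical_importance,
    effect_summary = effect_summary
  )
}

# random person report drawing variants from a shared KB so that reports
# built from the same KB overlap; all randomness under `seed`
random_report <- function(person, kb, n, seed) {
  withr::with_seed(seed, {
    rows <- as.data.frame(kb)[sample(nrow(kb), min(n, nrow(kb))), ]
    zyg <- sample(c("heterozygous", "homozygous"), nrow(rows),
                  replace = TRUE)
    df <- tibble::tibble(
      variant_name = rows$variant_name, rsid = rows$rsid,
      risk_allele = rows$risk_allele, zygosity = zyg,
      display_impact = derive_display_impact(rows$base_impact,
                                             rows$inheritance, zyg),
      certainty = rows$certainty,
      allele_frequency = rows$allele_frequency,
      rarity_size = rarity_size(rows$allele_frequency),
      category = rows$category,
      clinical_importance = rows$clinical_importance,
      effect_summary = rows$effect_summary
    )
    person_report(dplyr::arrange(df, category, variant_name), person)
  })
}

# random comparison of n_persons reports over a fresh generated KB
random_comparison <- function(n_persons, seed, kb_size = 20,
                              report_size = 10) {
  kb <- generate_kb(n_variants = kb_size, seed = seed)
  reports <- lapply(seq_len(n_persons), function(i) {
    random_report(paste0("P", i), kb, report_size, seed * 100 + i)
  })
  compare_reports(reports)
}

# plain data.frame with provenance/class attributes dropped, for
# content-only comparisons
bare_df <- function(x) {
  out <- as.data.frame(x)
  for (nm in setdiff(names(attributes(out)),
                     c("names", "row.names", "class"))) {
    attr(out, nm) <- NULL
  }
  out
}

report_keys <- function(report) {
  paste(report$rsid, report$risk_allele, sep = "/")
}

write_raw_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
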