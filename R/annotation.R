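# Classify one person's genotypes against the effect knowledge base:
# zygosity calling, displayed impact (carrier derivation), rarity sizing,
# and the join that produces a person report.

#' Call zygosity of a genotype with respect to a risk allele
#'
#' Vectorised over `genotype`. A genotype containing the no-call character
#' `-` yields `NA`. For two-allele genotypes, one matching allele is
#' `"heterozygous"` and two are `"homozygous"`; a single-allele genotype
#' (X/Y/MT hemizygous call) that matches is `"hemizygous"`. No match yields
#' `NA` (the variant is absent).
#'
#' @param genotype Character vector of genotype strings (1 or 2 alleles over
#'   `A C G T I D -`).
#' @param risk_allele Single risk allele character (or vector recycled
#'   against `genotype`).
#' @return Character vector over heterozygous / homozygous / hemizygous,
#'   with `NA` where the person does not carry the risk allele.
#' @examples
#' call_zygosity(c("AG", "AA", "--", "A"), "A")
#' @export
call_zygosity <- function(genotype, risk_allele) {
  n <- max(length(genotype), length(risk_allele))
  genotype <- rep_len(toupper(genotype), n)
  risk_allele <- rep_len(toupper(risk_allele), n)
  len <- nchar(genotype)
  a1 <- substr(genotype, 1, 1)
  a2 <- substr(genotype, 2, 2)
  nocall <- a1 == "-" | (len == 2 & a2 == "-")
  matches <- (a1 == risk_allele) + (len == 2) * (a2 == risk_allele)
  out <- rep(NA_character_, n)
  two <- !nocall & len == 2
  one <- !nocall & len == 1
  out[two & matches == 1] <- "heterozygous"
  out[two & matches == 2] <- "homozygous"
  out[one & matches == 1] <- "hemizygous"
  out
}

#' Derive the displayed impact of a variant for one person
#'
#' The knowledge base records a variant's base impact; what a report shows
#' also depends on the person. A heterozygote for a *recessive pathogenic*
#' variant is unaffected themselves but can transmit the allele, so the
#' displayed impact becomes `"carrier"`. Homozygous or hemizygous recessive
#' pathogenic stays `"pathogenic"`, as does dominant (or
#' unknown-inheritance) pathogenic at any zygosity; non-pathogenic base
#' impacts pass through unchanged.
#'
#' @param base_impact One of pathogenic, benign, protective,
#'   pharmacogenetic (vectorised).
#' @param inheritance One of dominant, recessive, unknown.
#' @param zygosity One of heterozygous, homozygous, hemizygous.
#' @return Character vector over the five display impacts.
#' @examples
#' derive_display_impact("pathogenic", "recessive", "heterozygous")
#' @export
derive_display_impact <- function(base_impact, inheritance, zygosity) {
  if (length(base_impact) == 0) return(character(0))
  n <- max(length(base_impact), length(inheritance), length(zygosity))
  base_impact <- rep_len(base_impact, n)
  inheritance <- rep_len(inheritance, n)
  zygosity <- rep_len(zygosity, n)
  check_tokens(base_impact, base_impact_levels, "impact")
  check_tokens(inheritance, inheritance_levels, "inheritance")
  check_tokens(zygosity, zygosity_levels, "zygosity")
  ifelse(
    base_impact == "pathogenic" & inheritance == "recessive" &
      zygosity == "heterozygous",
    "carrier",
    base_impact
  )
}

#' Rarity size of a variant from its allele frequency
#'
#' Glyph size encodes rarity: the rarer the variant, the larger its
#' representation. The size is a log-frequency scale rescaled to
#' `[s_min, 1]`:
#' \deqn{s(f) = s_{min} + (1 - s_{min})
#'   \frac{\log_{10}(1/\max(f, f_{min}))}{\log_{10}(1/f_{min})}}
#' so `f = f_min` (or rarer, clamped) maps to 1, `f = 1` maps to `s_min`,
#' and the scale is strictly decreasing in between.
#'
#' @param allele_frequency Numeric vector of frequencies in (0, 1].
#' @param f_min Frequency floor; rarer frequencies are clamped. Default 1e-4.
#' @param s_min Size of the commonest possible variant (f = 1). Default 0.05.
#' @return Numeric vector of sizes in `(0, 1]`.
#' @examples
#' rarity_size(c(1e-4, 0.001, 0.1, 1))
#' @export
rarity_size <- function(allele_frequency, f_min = 1e-4, s_min = 0.05) {
  if (any(!is.finite(allele_frequency)) ||
      any(allele_frequency <= 0) || any(allele_frequency > 1)) {
    stop_varkin("allele_frequency must lie in (0, 1]",
                class = "varkin_domain_error")
  }
  stopifnot(f_min > 0, f_min < 1, s_min > 0, s_min < 1)
  f <- pmax(allele_frequency, f_min)
  s_min + (1 - s_min) * log10(1 / f) / log10(1 / f_min)
}

#' Annotate a person's genotypes against the effect knowledge base
#'
#' Joins the genotype set with the knowledge base on rsid and keeps exactly
#' the knowledge-base entries whose risk allele the person carries at least
#' once. Only variants with known effects are represented; genotypes at
#' rsids unknown to the knowledge base are silently ignored, as are
#' no-calls. Each kept entry is classified (zygosity, display impact,
#' rarity size) and the report is ordered by category then variant name.
#'
#' @param genotypes A `genotype_set` from [read_raw_genotypes()].
#' @param kb An `effect_kb` from [read_effect_kb()] or [generate_kb()].
#' @param f_min,s_min Rarity-scale parameters passed to [rarity_size()].
#' @return A `person_report` tibble, one row per carried known variant.
#' @examples
#' kb <- generate_kb(n_variants = 10, seed = 1)
#' fam <- simulate_family(kb, seed = 1)
#' annotate_genotypes(fam$Parent1, kb)
#' @export
annotate_genotypes <- function(genotypes, kb, f_min = 1e-4, s_min = 0.05) {
  stopifnot(inherits(genotypes, "genotype_set"), inherits(kb, "effect_kb"))
  joined <- inner_join(
    as_tibble(kb),
    as_tibble(genotypes)[c("rsid", "genotype")],
    by = "rsid"
  )
  zyg <- call_zygosity(joined$genotype, joined$risk_allele)
  joined <- joined[!is.na(zyg), , drop = FALSE]
  zyg <- zyg[!is.na(zyg)]
  out <- joined %>%
    mutate(
      zygosity = zyg,
      display_impact = derive_display_impact(
        .data$base_impact, .data$inheritance, .data$zygosity
      ),
      rarity_size = rarity_size(.data$allele_frequency, f_min, s_min)
    ) %>%
    arrange(.data$category, .data$variant_name)
  new_person_report(out, person_id(genotypes))
}

#' @export
tidy.person_report <- function(x, ...) {
  out <- mutate(as_tibble(x), person_id = person_id(x), .before = 1)
  attr(out, "person_id") <- NULL
  class(out) <- class(tibble())
  out
}

#' Summarise a person report
#'
#' @param x A `person_report`.
#' @param ... Unused.
#' @return A one-row tibble: person, variant count, counts per display
#'   impact, and number of distinct health categories.
#' @export
glance.person_report <- function(x, ...) {
  counts <- table(factor(x$display_impact, levels = display_impact_levels))
  tibble(
    person_id = person_id(x),
    n_variants = nrow(x),
    n_pathogenic = as.integer(counts[["pathogenic"]]),
    n_benign = as.integer(counts[["benign"]]),
    n_protective = as.integer(counts[["protective"]]),
    n_pharmacogenetic = as.integer(counts[["pharmacogenetic"]]),
    n_carrier = as.integer(counts[["carrier"]]),
    n_categories = dplyr::n_distinct(x$category)
  )
}
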