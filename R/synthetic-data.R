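# Seeded generators: a synthetic variant-effect knowledge base and a
# Mendelian family (Hardy-Weinberg parents, children assembled by random
# transmission), so the whole pipeline runs offline. The default scenario
# is the four-member family used throughout the comparison views: two
# parents and two siblings.

default_categories <- c(
  "Cancer", "Metabolism", "Cardiovascular", "Neurological", "Immune",
  "Blood"
)

default_impact_mix <- c(
  pathogenic = 0.4, benign = 0.3, protective = 0.15, pharmacogenetic = 0.15
)

# run code under a local RNG state derived from `seed`, restoring the
# caller's state afterwards
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Generate a synthetic variant-effect knowledge base
#'
#' Produces `n_variants` effect records with names `GENE{i}-X{i}Y`,
#' allele frequencies log-uniform over `frequency_range`, base impacts
#' sampled from `impact_mix`, certainty levels sampled uniformly, and
#' health categories cycled from `category_pool`. Pathogenic variants are
#' assigned recessive or dominant inheritance (at least one recessive is
#' guaranteed whenever any variant is pathogenic, so carrier findings can
#' arise); non-pathogenic variants get inheritance `"unknown"`.
#'
#' @param n_variants Number of records. Default 50, the size of the
#'   family-comparison scenario.
#' @param seed Integer seed fixing all randomness.
#' @param impact_mix Named proportions over the four base impacts; must
#'   sum to 1.
#' @param frequency_range Length-2 numeric, `0 < min < max <= 1`.
#' @param category_pool Health-category labels to cycle through.
#' @return An `effect_kb` tibble.
#' @examples
#' generate_kb(n_variants = 5, seed = 1)
#' @export
generate_kb <- function(n_variants = 50, seed = 1,
                        impact_mix = default_impact_mix,
                        frequency_range = c(0.005, 0.5),
                        category_pool = default_categories) {
  stopifnot(n_variants >= 1, length(frequency_range) == 2)
  if (!setequal(names(impact_mix), base_impact_levels) ||
      abs(sum(impact_mix) - 1) > 1e-8 || any(impact_mix < 0)) {
    stop_varkin(
      "impact_mix must be nonnegative proportions over pathogenic, benign, protective, pharmacogenetic summing to 1",
      class = "varkin_config_error"
    )
  }
  if (!(frequency_range[1] > 0 && frequency_range[1] < frequency_range[2] &&
        frequency_range[2] <= 1)) {
    stop_varkin("frequency_range must satisfy 0 < min < max <= 1",
                class = "varkin_config_error")
  }
  with_local_seed(seed, {
    i <- seq_len(n_variants)
    impacts <- sample(base_impact_levels, n_variants, replace = TRUE,
                      prob = impact_mix[base_impact_levels])
    inheritance <- rep("unknown", n_variants)
    path <- which(impacts == "pathogenic")
    if (length(path) > 0) {
      inheritance[path] <- sample(c("recessive", "dominant"), length(path),
                                  replace = TRUE, prob = c(0.6, 0.4))
      if (!any(inheritance[path] == "recessive")) {
        inheritance[path[1]] <- "recessive"
      }
    }
    freq <- 10 ^ runif(n_variants, log10(frequency_range[1]),
                       log10(frequency_range[2]))
    category <- rep_len(category_pool, n_variants)
    df <- tibble(
      variant_name = sprintf("GENE%d-X%dY", i, i),
      rsid = sprintf("rs%d", 100000 + i),
      risk_allele = sample(c("A", "C", "G", "T"), n_variants,
                           replace = TRUE),
      base_impact = impacts,
      inheritance = inheritance,
      certainty = sample(certainty_levels, n_variants, replace = TRUE),
      allele_frequency = freq,
      category = category,
      clinical_importance = sprintf("%s finding of %s clinical importance",
                                    category,
                                    sample(c("high", "moderate", "low"),
                                           n_variants, replace = TRUE)),
      effect_summary = sprintf(
        "Synthetic %s effect in gene GENE%d relevant to %s.",
        impacts, i, category
      )
    )
    validate_effect_kb(df)
    new_effect_kb(df, sprintf("synthetic kb (seed %d)", seed))
  })
}

# the non-risk allele at a site: first base differing from the risk
# allele, or the opposite indel token
reference_allele <- function(risk_allele) {
  vapply(risk_allele, function(a) {
    if (a == "I") "D"
    else if (a == "D") "I"
    else setdiff(c("A", "C", "G", "T"), a)[1]
  }, character(1), USE.NAMES = FALSE)
}

genotype_from_alleles <- function(a1, a2) {
  paste0(pmin(a1, a2), pmax(a1, a2))
}

#' Simulate a Mendelian family's raw genotypes
#'
#' For every knowledge-base site, each parent's two alleles are drawn
#' independently as risk/reference Bernoulli trials at the site's allele
#' frequency (Hardy-Weinberg); each child then receives one allele drawn
#' uniformly from each parent's pair, independently per site. Sites are
#' autosomal and unlinked; no de novo mutations are introduced, so a
#' child's alleles are always elements of the respective parent's
#' genotype. Positions are synthetic and chromosomes cycle over 1-22.
#'
#' @param kb An `effect_kb` giving the sites and frequencies.
#' @param n_children Number of children, 0-2. Default 2 (the two-sibling
#'   scenario).
#' @param seed Integer seed fixing all randomness.
#' @return A named list of `genotype_set` objects: `Parent1`, `Parent2`,
#'   then `Child1` and `Child2` as requested.
#' @examples
#' kb <- generate_kb(n_variants = 5, seed = 1)
#' simulate_family(kb, n_children = 2, seed = 1)
#' @export
simulate_family <- function(kb, n_children = 2, seed = 1) {
  stopifnot(inherits(kb, "effect_kb"))
  if (!(n_children %in% 0:2)) {
    stop_varkin("n_children must be 0, 1 or 2",
                class = "varkin_config_error")
  }
  n <- nrow(kb)
  risk <- kb$risk_allele
  ref <- reference_allele(risk)
  freq <- kb$allele_frequency
  with_local_seed(seed, {
    draw_parent <- function() {
      a1 <- ifelse(rbinom(n, 1, freq) == 1, risk, ref)
      a2 <- ifelse(rbinom(n, 1, freq) == 1, risk, ref)
      list(a1 = a1, a2 = a2)
    }
    parents <- list(draw_parent(), draw_parent())
    children <- lapply(seq_len(n_children), function(k) {
      from1 <- ifelse(rbinom(n, 1, 0.5) == 1, parents[[1]]$a1,
                      parents[[1]]$a2)
      from2 <- ifelse(rbinom(n, 1, 0.5) == 1, parents[[2]]$a1,
                      parents[[2]]$a2)
      list(a1 = from1, a2 = from2)
    })
    members <- c(parents, children)
    names(members) <- c("Parent1", "Parent2",
                        if (n_children > 0) paste0("Child", seq_len(n_children)))
    base <- tibble(
      rsid = kb$rsid,
      chromosome = as.character(rep_len(1:22, n)),
      position = 1000000L + seq_len(n) * 1000L
    )
    lapply(setNames(names(members), names(members)), function(nm) {
      al <- members[[nm]]
      df <- mutate(base, genotype = genotype_from_alleles(al$a1, al$a2))
      new_genotype_set(df, nm)
    })
  })
}

#' Write a simulated family dataset to a directory
#'
#' Emits one 23andMe-dialect raw genotype file per family member
#' (`<person>.txt`), the knowledge base as `kb.csv`, and `manifest.json`
#' recording the generating configuration. Output is byte-deterministic
#' for a fixed configuration.
#'
#' @param family Named list of `genotype_set` from [simulate_family()].
#' @param kb The `effect_kb` the family was simulated from.
#' @param dir Output directory (created if needed).
#' @param config Optional list recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_family_dataset <- function(family, kb, dir, config = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(family, function(gs) {
    path <- file.path(dir, paste0(person_id(gs), ".txt"))
    write_raw_genotypes(gs, path)
    basename(path)
  }, character(1))
  write_effect_kb(kb, file.path(dir, "kb.csv"))
  manifest <- list(
    format = "varkin-family/1.0",
    persons = as.list(unname(vapply(family, person_id, character(1)))),
    genotype_files = as.list(unname(files)),
    kb_file = "kb.csv",
    n_variants = nrow(kb),
    config = config
  )
  path <- file.path(dir, "manifest.json")
  atomic_write(
    as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                  pretty = TRUE)),
    path
  )
  invisible(path)
}
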