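# varkin

Annotate direct-to-consumer genotype data against a variant-effect
knowledge base and compare the resulting gene-variant reports across two
to four people — typically a family.

Consumer genotyping services hand non-experts a raw file of hundreds of
thousands of genotype calls. Making sense of it means joining those calls
against curated knowledge about variants with known effects, and the
questions people actually ask are comparative: *which variants do my
sister and I share? which child shares the most cancer-related variants
with which parent? which variants won't affect my child but could affect
their children?* `varkin` is a headless toolkit for exactly that workflow:
parsing raw genotype files, building per-person annotated reports,
partitioning variants across people by who carries them, filtering and
searching, and computing deterministic geometry for four comparison views
(table, linear, sunburst, two-set Venn) rendered to SVG.

## The model

For each person and each knowledge-base entry (keyed by rsid and risk
allele), the package classifies:

* **Zygosity** — heterozygous (1 of 2 alleles match the risk allele),
  homozygous (2 of 2), or hemizygous (a single-allele call on X/Y/MT that
  matches); `--` is a no-call.
* **Displayed impact** — the knowledge base records a base impact
  (pathogenic, benign, protective, pharmacogenetic) and an inheritance
  mode. A heterozygote for a *recessive pathogenic* variant is shown as a
  **carrier**: unaffected themselves, but able to transmit the allele.
  All other combinations display the base impact.
* **Rarity size** — glyph size encodes rarity on a log-frequency scale
  rescaled to `[s_min, 1]`:

  `s(f) = s_min + (1 − s_min) · log10(1/max(f, f_min)) / log10(1/f_min)`

  so the rarest representable variant (`f = f_min`, default 1e-4) draws at
  size 1 and the commonest (`f = 1`) at `s_min` (default 0.05), strictly
  decreasing in between.

A comparison of N ∈ {2, 3, 4} reports partitions the union of variant
keys into membership classes — each variant belongs to the signature of
exactly the persons carrying it — ordered shared-first so every layout
places fully shared variants before partially shared and private ones.
Visual encodings follow the report convention: impact as colour
(pathogenic red, benign gray, protective blue, pharmacogenetic purple,
carrier red polka-dot), rarity as size, shared variants aligned across
rings/rows.

A seeded simulator generates the fixture data: a synthetic effect
knowledge base and a Mendelian family (parents drawn per-site under
Hardy–Weinberg at the knowledge-base allele frequency; each child allele
drawn uniformly from the corresponding parent's pair), so the whole
pipeline runs offline.

## Worked example

```r
library(varkin)

kb      <- generate_kb(n_variants = 50, seed = 42)
family  <- simulate_family(kb, n_children = 2, seed = 42)
reports <- lapply(family, annotate_genotypes, kb = kb)

cmp <- compare_reports(reports)
cmp
#> <comparison_report: 4 persons (Parent1, Parent2, Child1, Child2), 16 variants in 10 classes>

comparison_classes(cmp)
#> # A tibble: 10 × 4
#>    class_index signature signature_id                  n_variants
#>          <int> <list>    <chr>                              <int>
#>  1           1 <chr [4]> Parent1+Parent2+Child1+Child2          2
#>  2           2 <chr [3]> Parent1+Parent2+Child2                 1
#>  3           3 <chr [3]> Parent1+Child1+Child2                  1
#>  4           4 <chr [3]> Parent2+Child1+Child2                  2
#>  5           5 <chr [2]> Parent1+Child1                         2
#>  ...
```

Of the 50 knowledge-base variants, 16 distinct ones occur somewhere in
this family; 2 are shared by all four members, and the classes are
ordered full-sharing first. The comparative queries read straight off the
comparison:

```r
shared_count(cmp, c("Parent1", "Child1"))
#> [1] 5
compare_counts(cmp, "Parent1", "Parent2", filter_spec(categories = "Cancer"))
#> [1] "more"
carrier_outlook(reports$Child1)[, c("variant_name", "category", "zygosity")]
#> # A tibble: 1 × 3
#>   variant_name category zygosity
#> 1 GENE37-X37Y  Cancer   heterozygous
```

Child1 carries one recessive pathogenic variant heterozygously — not
expected to affect Child1, but relevant to Child1's future children.
Layouts and rendering:

```r
render_svg(sunburst_layout(cmp), "family-sunburst.svg")
render_svg(table_view(cmp), "family-table.svg")
render_svg(venn_layout(compare_reports(reports[c("Parent1", "Parent2")])),
           "parents-venn.svg")
ggplot2::autoplot(linear_layout(cmp))   # quick-look ggplot versions
```

The same pipeline is scriptable from a shell via the wrapper in
`inst/cli/varkin` (`simulate`, `annotate`, `compare`, `render`
subcommands; `--help` for usage).

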