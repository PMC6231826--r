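---
title: "Comparing annotated genotype reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing annotated genotype reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varkin)
```

`varkin` turns raw direct-to-consumer genotype downloads into annotated
gene-variant reports and compares those reports across two to four
people. This vignette is the package's account of how each step works,
which parameters matter, and where genuinely open design choices were
resolved.

## The annotation model

A person's raw data is a table of genotype calls: rsid, chromosome,
1-based position, and a one- or two-allele genotype over
`A C G T I D -` (the tab-separated dialect of consumer raw downloads;
`I`/`D` are insertion/deletion alleles and `--` a no-call). The
knowledge base is the universe of *variants with known effects*, one row
per (rsid, risk allele), carrying base impact, inheritance mode,
certainty of evidence, allele frequency, health category and free-text
summaries — the field structure of a GET-Evidence-style gene variant
report. Only knowledge-base variants appear in a report: a genotype at
an unknown rsid is silently ignored, as is a genotype without the risk
allele. This is an interpretation boundary, not a data loss — the
package deliberately does not predict effects of unannotated variants.

**Zygosity** is allele counting: one matching allele of two is
heterozygous, two are homozygous, a matching single-allele call
(X, Y, MT) is hemizygous. No-calls are treated as absence.

**Carrier derivation.** Knowledge bases record what a variant *does*;
what a report should *display* also depends on the person. We derive the
displayed impact from the triple (base impact, inheritance, zygosity):

* carrier ⇔ pathogenic ∧ recessive ∧ heterozygous;
* pathogenic is retained for homozygous or hemizygous recessive, and for
  dominant at any zygosity;
* non-pathogenic impacts pass through unchanged.

Inheritance `unknown` is treated as dominant-like (never carrier): when
the mode is not established, suppressing the pathogenic flag for
heterozygotes would understate risk. This truth table reproduces the
familiar counselling semantics — a carrier is unaffected themselves but
can pass the allele to offspring — and `carrier_outlook()` returns
exactly those findings.

**Rarity size.** Size encodes rarity: the rarer the variant, the larger
its glyph. The scale is logarithmic in frequency and affinely rescaled,

$$s(f) = s_{\min} + (1 - s_{\min})\,
  \frac{\log_{10}(1/\max(f, f_{\min}))}{\log_{10}(1/f_{\min})},$$

with defaults $f_{\min} = 10^{-4}$ (frequencies below the floor are
clamped) and $s_{\min} = 0.05$. A pure log scale with a hard floor at
$s_{\min}$ would flatten for common variants and break strict
monotonicity; the affine rescale keeps the intended endpoints —
$s(f_{\min}) = 1$, $s(1) = s_{\min}$ — while remaining strictly
decreasing over the whole domain, which the layouts rely on (size
ordering must mirror frequency ordering exactly). Both constants are
arguments (`rarity.f_min` / `rarity.s_min` in CLI config), not baked-in.

Allele matching is literal: a variant is present iff the named risk
allele appears in the genotype string. Strand flipping and genome-build
liftover are out of scope — without build metadata the ambiguity is not
resolvable, and silently complement-matching would manufacture false
positives.

## The comparison partition

`compare_reports()` partitions the union of variant keys over 2–4
persons into membership classes. Identity across persons is the
(rsid, risk allele) key, *not* zygosity: a variant that is a carrier
finding in one sibling and pathogenic in the other is still one shared
variant, with per-person classifications retained. This matches how a
family reads a comparison — "do we both have it?" — and the per-person
detail is still available in every view (the table shows a carrier mark
vs a present mark on the same row).

Classes are ordered full-sharing signature first, then by decreasing
signature size, ties broken by person order. The ordering is part of the
contract because the layouts realise "shared variants first" directly
from class order without re-sorting.

Query helpers answer the standard comparative questions:
`shared_count()` (variants present in every member of a subset, summed
over all signatures containing it), `compare_counts()` (more / fewer /
same between two persons, antisymmetric by construction), both
filter-aware.

## Filters and search

Filters are combinable facets over persons, health categories, displayed
impacts and certainty levels, plus a free-text search. Semantics: a
variant survives iff it satisfies **every** nonempty facet, and within a
facet membership in **any** selected token suffices (AND across facets,
OR within). Search is a case-insensitive literal substring over variant
name, category, clinical importance and effect summary — deliberately
not tokenised or fuzzy; it is one more conjunctive facet, not a separate
mode.

Two validation regimes coexist deliberately. Person, impact and
certainty tokens come from closed vocabularies and unknown tokens raise
errors naming the facet. Category labels and search terms are free text
and simply match nothing when absent. Validating categories against a
view's current inventory would break idempotence — a first application
can legitimately empty the inventory, making the identical second
application an error — so the algebraic laws (idempotence, AND-
equivalence of stepwise application, monotonicity) force the free-text
treatment.

The person facet is structural: hidden persons lose their rows/rings,
variants carried only by hidden persons drop out, and the membership
partition is recomputed over the visible persons.

## Layout geometry

All three geometric views share one slot allocation. Every distinct
variant gets a global slot in class order (shared first, then category,
then variant name — the within-group ordering is a convention, chosen
for stable, readable grouping); slot extent is proportional to rarity
size; a uniform gap of `gap_fraction` (default 0.2) times the mean slot
width separates slots. The scale factor is solved in closed form so that
slots plus gaps exactly exhaust the span — 360° for the sunburst
(n gaps around the circle), a unit width for the linear view (n − 1
interior gaps) — making "arc extents + gaps = 360°" an exact identity
up to floating-point summation rather than an approximation. Because the
slot is global, a shared variant's glyphs are radially (sunburst) or
vertically (linear) aligned across persons by construction.

Ring order is an explicit parameter defaulting to *first person
outermost*; both conventions appear in practice for concentric
comparison views, so the package fixes one default and exposes the
permutation rather than hard-coding either.

The two-set Venn view assigns each variant to left-only / shared /
right-only by its signature. Packing is deterministic: per region, a
⌈√k⌉-column grid of the unit-square region box, circles placed row-major
in descending radius. One global radius scale is chosen as the tightest
region's cap so that radius stays proportional to rarity *across*
regions and every circle sits strictly inside its own grid cell —
overlap-freedom and containment hold by construction, not by iterative
relaxation. The Venn is intentionally two-set only; three- and four-set
region geometry stops being readable as bubbles and the table, linear
and sunburst views carry the N > 2 cases. A shared bubble's colour comes
from the first (left) person's displayed impact — a convention, noted
because the two persons can legitimately differ (carrier vs pathogenic).

Impact styling is fixed: pathogenic red, benign gray, protective blue,
pharmacogenetic purple, carrier red with a polka-dot pattern (carrier is
pathogenic lineage, so it keeps the red base). Certainty has no
positional encoding in these comparison views; it is exposed through
filtering and the table/detail fields.

`render_svg()` writes standalone SVG 1.1 with one element per glyph
(`class="glyph"`, title tooltips, pattern fills for carriers), formatted
with fixed 6-decimal coordinates and no timestamps so identical input
yields byte-identical output. The `autoplot()` methods are quick-look
ggplot2 companions; base ggplot2 has no pattern fills, so they mark
carriers with a black outline instead.

## The synthetic family generator

`generate_kb()` and `simulate_family()` emulate the fictional
four-member family (two parents, two siblings) that the comparison
views are designed around. Defaults, chosen once as a realistic
scenario:

* **50 variants** in the knowledge base — the scale of a curated
  personal gene-variant report, and enough for every membership class to
  be populated in a typical run.
* **Allele frequencies log-uniform on [0.005, 0.5]** — variants curated
  into an effect knowledge base skew common (that is how they became
  well-studied); this range gives each person a report of roughly 8–15
  variants and the family a union of 15–25, so comparisons have
  substance without saturating.
* **Impact mix 0.40 / 0.30 / 0.15 / 0.15** (pathogenic / benign /
  protective / pharmacogenetic), with pathogenic variants assigned
  recessive inheritance with probability 0.6 (at least one recessive
  guaranteed) so carrier findings reliably arise.
* **Six health categories** cycled deterministically (Cancer,
  Metabolism, Cardiovascular, Neurological, Immune, Blood).

Parents are drawn per site under Hardy–Weinberg at the knowledge-base
frequency; each child allele is drawn uniformly from the corresponding
parent's pair, independently per site. Sites are autosomal, unlinked,
and mutation-free, which is what makes the Mendelian oracle exhaustive:
every child allele must literally be an element of the respective
parent's genotype, with zero tolerance.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and shared haplotypes,
de novo mutations, X-hemizygosity (the simulator is autosomal-only,
though the annotation path fully supports hemizygous calls from real
files), genotyping error and missingness, and population structure. The
generator exists to give the comparison machinery controllable sharing
structure, not to be a population-genetics simulator.

## Numerical and degenerate-input choices

* Slot scale solved in closed form (see above); geometry tests assert
  closure at 1e-9 degrees.
* CSV I/O uses shortest-round-trip double formatting, so report round
  trips are field-exact; JSON serialisation writes full precision
  (`digits = NA`).
* Empty inputs flow through: an empty genotype file annotates to an
  empty report, an all-empty comparison lays out to empty geometry, and
  empty layouts render to valid SVG with zero glyphs.
* Duplicate rsids in a raw file are an error, not last-wins — a silent
  overwrite could flip zygosity.
* The report CSV schema includes `risk_allele` alongside the display
  fields: reports are keyed by (rsid, risk allele), and omitting the
  allele would make the round trip ambiguous at multi-allelic sites.
* All generator and simulator randomness is local to an explicit seed
  (the caller's RNG state is saved and restored), so identical
  configurations produce byte-identical datasets.

## Problem sizes used by the test suite

The property suite runs the partition oracle on 200 seeded comparisons
per arity (N = 2, 3, 4), filter algebra on 500 seeded view/filter pairs,
layout geometry on 100 seeded comparisons, and Mendelian consistency
over 10,000 sites × 2 children × 20 seeds — sizes at which every
membership signature, facet combination and packing branch is exercised
many times over while the whole suite stays fast enough to run on every
change.

## Known limitations

* No strand normalisation or build liftover; the risk allele is assumed
  reported on the knowledge base's strand.
* No compound-heterozygote reasoning across different rsids in a gene;
  carrier status is per-variant.
* Search is literal substring matching; no synonyms or stemming.
* Comparisons are capped at four persons — the views are designed for a
  family-sized N, and the table is the only view that would scale
  further.
* The Venn view is two-set only.
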