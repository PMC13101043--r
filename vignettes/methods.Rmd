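---
title: "Methods: curation, classification and representation-gap analysis of Natura 2000 freshwater habitats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, classification and representation-gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2kgap)
```

## The problem and the data model

Natura 2000 is the EU's network of protected sites designated under the
Habitats Directive (HD; SCIs and SACs) and the Birds Directive (BD; SPAs).
Its tabular database describes each site (code, designation type, total
area in hectares), each (site, Annex I habitat) pair with the habitat's
cover in hectares, and each (site, biogeographic region) pair with the
percentage of the site's area in that region. Annex I habitats are
identified by 4-character codes; a trailing `*` marks priority habitats
and is treated as metadata, never as part of the key — results cite codes
like `7310*` while joins use `7310`.

`n2kgap` asks two things of these tables: how much of the HD-designated
area is mapped as protected habitat (and how much of that is freshwater),
and whether each freshwater habitat type is designated in every
terrestrial biogeographic region of its natural range. The second question
operationalises the spatial side of the "favorable reference area" idea:
representation across the natural range is a supportive condition for
long-term persistence, not a demographic viability assessment.

Everything is tabular. There is deliberately no geometry: BD-only sites
are detected by the designation-type field, not by boundary overlap, and
regions come from the database's own percentage records.

## Curation

Filtering happens in a fixed order, each stage logging
`in − dropped = out` with a per-record reason:

1. **Site areas.** Sites with missing area or area `< min_area_ha` are
   removed. The default threshold is 0.0001 ha (1 m²) — below the
   database's own precision, so anything smaller is an artefact, not a
   site. The comparison is strict: a site of exactly 0.0001 ha stays.
2. **Habitat covers.** The same rule applied to entry covers.
3. **Join and prune.** Entries whose site did not survive are dropped
   (orphans); sites whose total area is zero are dropped defensively (the
   cover percentage is undefined); sites whose covers sum to more than
   `max_habitat_sum_percent` (default 100.01) of the site area are
   internally inconsistent and removed with their entries; finally BD-only
   sites are removed with their entries, because Annex I habitats are not
   part of a BD designation. Sites with *zero* habitat entries are kept:
   unmapped designated area is a result, not an error.

The habitat-sum rule is computed as `100 × Σ cover_ha / total_area_ha`
from the already-filtered entries, and the quotient is rounded to six
decimals before the strict `>` comparison so binary floating-point noise
cannot flip a verdict at the 100.01 boundary (a site of 100 ha with covers
60 + 40.01 sums to exactly 100.01 % and stays). The order matters —
filtering entries after the join could change habitat sums — so `curate()`
fixes it; running curation on already-curated data drops nothing
(idempotence), which the tests assert across seeds.

Duplicate (site, habitat) pairs are collapsed by summing covers before the
join stage, so the curated dataset satisfies the uniqueness invariant its
consumers assume.

## Habitat classification

Each of the 233 Annex I codes carries one of three classes — freshwater,
marine & coastal, terrestrial — and each freshwater code one of five
groups (running water, standing water, peatland, forest,
grassland–heathland–coastal) and one nutrient level (oligo-, meso-,
eutrophic). Freshwater is defined broadly: beyond the `3xxx` codes it
includes groundwater-dependent terrestrial ecosystems — all `7xxx`
mires/bogs/fens, eight wet-forest types (`9080`, `91D0`, `91E0`, `91F0`,
`92A0`–`92D0`), and a grass/heath/coastal set including estuaries (`1130`)
and Boreal Baltic inlets (`1650`).

These assignments are expert judgement, so they live in a shipped,
versioned CSV (`annex1_taxonomy.csv`), not in code, and every row carries
a `source_note`. The shipped table is a **reconstruction**: class
membership follows the directive's code-range conventions and the
documented group sizes (10 running and 10 standing `3xxx` types, 12
peatland types, 8 wet-forest types); nutrient levels are fixed by
published statements only for `3150`, `91E0` and `6430` (eutrophic) and
are otherwise ecological defaults flagged `reconstructed`. Users with the
authoritative expert table can drop it in via `read_taxonomy(path)` —
validation (233 unique codes, complete freshwater rows, no stray
group/nutrient on other classes) is enforced at load, and lookups of
unknown codes return a typed unclassified outcome, never a silent default.
Two codes (`32A0`, `6540`) occur only in Croatia, whose cover data are
missing in the 2021 database; they are classified in the table and simply
absent from curated data.

## Region assignment

The `BIOREGION` table is incomplete and partly wrong: some sites lack
records, some sole-region sites are recorded as 0 % instead of 100 %, and
some sites genuinely span regions. The rules, in order:

- **Correction.** A site whose records consist of exactly one distinct
  region at (summed) 0 % is set to 100 %. An override CSV takes
  precedence; the shipped default holds the one documented exception,
  `BE2200036` → Atlantic 79 %. The original analysis corrected such sites
  after visual inspection; the deterministic sole-region rule replaces the
  inspection, and any site where inspection would disagree belongs in the
  override file.
- **Assignment.** Duplicate (site, region) rows are summed. If the maximum
  candidate percentage is exactly 100, that region is assigned (`MAX100`);
  two regions both at 100 is a data error and resolves to `NA`. Otherwise
  the region holding at least `min_fraction` (default 70) per cent is
  assigned (`GE70`). Otherwise `NA`. In the gap analysis only the six main
  terrestrial regions (Alpine, Atlantic, Boreal, Continental,
  Mediterranean, Pannonian) are candidates — a site 80 % in the Marine
  Baltic region is `NA` terrestrially — while the descriptive "extended"
  mode admits all 14 regions. The 100-first ordering makes the rule label
  informative and the tie-at-100 case safe; it changes no assignment
  relative to threshold-first ordering, since 100 ≥ 70. Raising
  `min_fraction` can only turn assignments into `NA`, never flip one
  region to another (`MAX100` is threshold-independent); the tests assert
  this monotone refinement.

`NA`-region entries are excluded from per-region tallies only; they keep
contributing to areas and counts.

## Natural ranges from the Red List crosswalk

Annex I habitats are crosslinked to European Red List of Habitats types by
expert-assigned relation categories (`same`, `close`, `narrower`, `wider`,
`overlap`, `low_importance` — the label set is validated at load but
data-driven, to absorb wording differences in crosswalk releases). The
inferred natural range of an Annex I habitat is the union of the
terrestrial region sets of its included links; a linked Red List habitat
with no indicated region (`UNSPECIFIED`) is assumed to occur in all six
regions. Low-importance links are included by default — the inclusive
approach deliberately over- rather than under-estimates ranges — and a
`strict` mode (same/close only) bounds that overestimation. Two special
rules: habitats linked to more than 20 Red List types (estuaries `1130`,
Boreal Baltic inlets `1650`) use a shipped pre-aggregated terrestrial
union, and Baltic-associated habitats always include the Boreal and
Continental regions.

The shipped crosswalk files are **synthetic stand-ins** (flagged
`_synthetic` in their filenames): they encode the handful of documented
crosslinks exactly (`3160`↔`C1.4` same; `92D0`↔`F9.3` close;
`3190`↔`C1.6a` wider; `3120`↔`C1.1b`{Atlantic, Boreal} +
`C1.6b`{Mediterranean}; the `1130`/`1650` aggregations) and plausible
expert-style rows for the remaining freshwater codes. Range inferences on
real data therefore require substituting the authoritative crosswalk via
`read_crosswalk()`'s path arguments; the inference machinery, its
invariants (union oracle equivalence, monotone inclusiveness,
six-region boundedness) and all tests are independent of which file is
supplied.

## Summaries and the gap statistic

All percentages are computed at full precision and rendered to one decimal
only at print time. Denominators are explicit because conflating them is
the likeliest error: per-class coverage uses total HD-designated site area
(HD-only plus both-directive sites); the whole-network freshwater share
additionally includes the BD-only area removed by curation, which the
pipeline captures as the post-area-filter site total before pruning.
Nutrient site counts record (site, nutrient) presence, so one site can
contribute to several counters. Size classes are half-open —
`[0, 50)`, `[50, 500)`, `[500, ∞)` hectares — putting boundary sites in
the upper class.

Per habitat *h* the gap statistic compares the observed terrestrial
regions (distinct non-`NA` assignments over its entries) with the inferred
natural range:

$$p(h) = \frac{|\,\mathrm{obs}(h) \cap \mathrm{nat}(h)\,|}{|\,\mathrm{nat}(h)\,|},
\qquad p(h) = 1 \iff \mathrm{nat}(h) \subseteq \mathrm{obs}(h).$$

Habitats with no usable crosslink have an undefined range and are excluded
from the per-group tallies, reported separately. The descriptive
extended-mode region count (`n_observed_extended`) is a different quantity
from `n_observed` and deliberately a separate column — marine regions can
describe where a habitat sits but never count toward terrestrial
representation.

## The synthetic generator

`generate_n2k()` produces the three tables plus ground truth known **by
construction**: anomalies are planted disjointly (at most one site-level
anomaly class per site; entry-level anomalies only on sites with no
site-level anomaly and not BD-only), so every expected post-curation count
is bookkeeping over planted labels, not a re-run of the pipeline. Defaults
were chosen once to emulate the 2021 database's shape: log-normal site
areas (median 120 ha, σ(log) = 1.9, clamped to ≥ 1 ha), a site-type mix of
17 % BD-only / 48 % HD-only / 35 % both, Poisson(4) habitat entries per
site drawn from the shipped code pool with freshwater upweighted 2×, cover
fractions summing to at most 95 % of the site area for non-anomalous
sites, and anomaly rates at roughly the real database's frequencies
(missing site areas a few per thousand, missing covers a few per cent,
overfilled sites ~2 %, sole-region 0 % records ~1.5 %, multi-region sites
8 %). Multi-region sites are planted at 55/45 — unresolvable at the 70 %
threshold — and single regions are drawn from a mix dominated by the six
main terrestrial regions, with small marine/other mass producing sites
that resolve only in extended mode.

What the generator does **not** emulate: country structure, spatial
autocorrelation, the real joint distribution of habitat composition and
site size, and realistic per-habitat region specialisation (regions are
sampled independently of habitat identity, so at large `n_sites` every
habitat tends to be observed in all six regions and gap proportions
saturate at 1). Passing tests therefore demonstrate the pipeline's
correctness and auditability, not empirical conclusions about the real
network.

`make_worked_fixture()` is the complementary miniature: six hand-built
sites exercising every rule exactly once, with fully hand-computed
expectations (the README walks through its arithmetic).

## Numerical and design choices

- Strict `<`/`>` at every threshold; equality always keeps.
- Habitat-sum percentages rounded to 6 decimals pre-comparison (above).
- The `>100.01 %` rule is computed from covers in hectares over site area,
  not from any relative-surface column; a schema option
  (`cover_unit = "percent"`) accommodates exports storing covers as
  percentages.
- Unknown region spellings load as `UNKNOWN` (reported), unknown site-type
  codes as `NA` (reported); loading never filters — all exclusions happen
  in curation so the audit is complete.
- Region assignment ties: two regions at 100 % → `NA`, logged; ties at the
  ≥ 70 rule are impossible for clean data (percentages sum to ≤ 100) and
  resolve by maximum.
- Degenerate inputs: empty tables flow through every stage and produce an
  empty report; a zero total HD area is an error in `class_coverage()` but
  is intercepted by `run_pipeline()` for the empty case.
- Randomness: the generator takes one integer seed, restores the caller's
  RNG state, and identical configuration yields byte-identical tables.

## Problem sizes

The test suite runs the generator at 120–250 sites per case (20 seeds × 5
anomaly-rate mixes for the planted-truth property) and one
integration-scale run at 2,000 sites; the acceptance script uses 5,000
sites. These sizes give every anomaly class double-digit expected counts
while keeping a full run in seconds.

## Limitations

- The shipped taxonomy and crosswalk are reconstructions/stand-ins;
  conclusions about the real network require the authoritative expert
  tables, dropped in through the documented CSV interfaces.
- BD-only detection uses the designation-type field; SPAs that partially
  overlap SCIs/SACs geometrically are whatever the type field says.
- The inclusive crosswalk mode overestimates natural ranges by design;
  gap proportions under it are indicative, and `strict` mode provides the
  lower envelope.
- No statistical testing is performed anywhere — every output is a
  descriptive quantity of the curated dataset.
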