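---
title: "cellviews: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellviews: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cellviews` renders transcriptomic measurements onto three biological
views — a subcellular map, a compartment-by-pathway treemap, and Gene
Ontology hierarchy treemaps — as deterministic SVG. This vignette explains
the underlying procedures, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The displayed quantity

Every view colors icons by one value per entity: either a single sample's
measurement or a two-sample comparison. The three comparison statistics
between a first condition $a$ and second condition $b$ are the difference
$v_a - v_b$, the fold change $v_a / v_b$, and the difference fold
$(v_a - v_b)/v_b$. The two ratio statistics are undefined at $v_b = 0$;
such entities are *excluded* (not mapped to $\pm\infty$, not an error) so
the color range stays finite, and the exclusion count is logged — the
identity difference fold $=$ fold $- 1$ holds on every retained entity and
is asserted in the tests to $10^{-12}$.

Filtering follows the same convention throughout: the min-value filter
keeps entities whose maximum present value across samples is *strictly
greater* than the threshold ("over" the cutoff), and missing cells never
participate in filters, comparisons, or color ranges — an entity missing
in the displayed sample is simply absent from that view.

## Color scale

Values map to one of `n_bins` equal-width, half-open bins over
$[v_{\min}, v_{\max}]$: bin $i$ covers $[v_{\min} + iw, v_{\min} + (i+1)w)$
with $w = (v_{\max}-v_{\min})/n_{\text{bins}}$, the top bin closed, and
out-of-range values saturating at the end bins (so a user-narrowed range
spends the whole palette on the interesting interval). The palette is the
ColorBrewer sequential YlOrRd family; the 9-class anchors are embedded and
linearly interpolated per RGB channel for other bin counts. Defaults:
`n_bins = 9` (the maximal YlOrRd class count), automatic range from the
displayed values, higher values darker (`reversed = FALSE` flips to the
opposite reading when set). A constant value vector yields a degenerate
scale that maps everything to the middle bin, implying neither high nor
low signal.

## Chunking (automatic scaling)

Icons are squares/discs of `icon_size` canvas units (default 8) separated
by `padding` units (default 2) on a grid inside each region; a region of
size $W \times H$ holds
$\lfloor (W-2p)/(s+p) \rfloor \cdot \lfloor (H-2p)/(s+p) \rfloor$ icons.
When entities outnumber capacity, one icon represents $g$ entities with

$$g = \max_c \lceil n_c / \text{cap}_c \rceil,$$

the smallest factor under which *every* compartment can display all of its
entities. $g$ is solved once per view (shared across compartments), which
is how we read the "view-scope minimum"; a per-compartment factor would
make icon semantics inconsistent within one picture. Inside a compartment,
entities are sorted ascending by value (ties broken lexicographically by
id, for determinism) and chunked into consecutive runs of $g$; each
group's representative value is the arithmetic mean of its members, single
entities draw as discs, groups as rectangles. Placement is row-major on
the capacity grid — the sources give no numeric placement rule, so the
simplest deterministic one is used. A user `max_per_icon` below the solved
minimal $g$ is an error rather than a silent overflow.

Treemap leaves add one wrinkle: proportional subdivision can produce
slivers too small to hold even one icon, which no $g$ can fix (capacity
zero). The pipeline driver then halves the icon size, down to a floor of 2
units, until every populated leaf holds at least one icon, and logs each
step (`stage=autoscale`). The low-level placement functions keep the
strict overflow error so the invariant remains testable.

## Treemap layout

The pathway view nests cell → compartments → pathway leaves; a leaf's
weight is the number of displayed entities annotated to that pathway, and
an entity in $m$ pathways spread over $k$ compartments contributes to all
$m \cdot k$ leaves — multi-membership is shown, not collapsed, and
duplicated counting (not unique-entity counting) sizes the rectangles,
matching the view's "entities appear multiple times" semantics.
Zero-weight pathways are dropped entirely rather than drawn as slivers.

Subdivision uses the squarified heuristic: children sorted by descending
weight (ties by name), packed into rows along the shorter side of the
remaining rectangle, closing a row as soon as adding the next child would
worsen its worst aspect ratio. Squarified was chosen over slice-and-dice
or ordered variants for readability, and because it is oracle-testable: a
direct transcription of the published algorithm lives in the test helpers,
and layouts must match it exactly on flat instances. An `inner_pad`
(default 4 units) separates each parent's border from its children;
proportionality (child area share = weight share, to $10^{-9}$ relative)
holds on the padded interior. Compartment labels are drawn as render-level
overlays rather than reserving a strip inside the rectangle, keeping the
tiling and proportionality invariants exact at every level.

## Over-representation testing

Each pathway containing at least one displayed gene is tested with the
one-sided Fisher exact (hypergeometric upper-tail) probability

$$p = \sum_{j=k}^{\min(K,n)} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

where $N$ is the genome background ("universe") supplied as a file — not
the union of annotations — $K$ the pathway's genes within it, $n$ the
displayed genes, and $k$ their intersection. The sum is computed from log
binomial coefficients, stable at genome scale, and validated two ways:
against exact integer enumeration for all $(N,K,n,k)$ with $N \le 30$ (to
$10^{-12}$), and against an independent upper-tail implementation at
genome scale. The "input list" for $n$ is the *post-filter displayed* set
(logged), since that is what the views show. One-sided testing matches the
over-representation question; under-representation is not flagged.

Highlighting is a strict inequality — $p$ exactly at the threshold
(default 0.05) is not highlighted — drawn as a 2-unit red border on the
pathway rectangle, with the p-value in the rectangle's `<title>` (the
static analog of mouse-over text). Raw p-values are used by default, as a
single user-configured threshold; an optional Benjamini–Hochberg mode
(`fdr = TRUE`) switches the highlight criterion to adjusted values while
still reporting raw p.

## Gene Ontology views

The ontology is read from OBO 1.2, keeping `id`, `name`, `namespace`, and
`is_a` edges only; obsolete terms are dropped and acyclicity is verified.
`part_of` and other relationships are not traversed — `is_a` is the
conservative core of the true-path rule; the cellular-component namespace
is parsed but not offered as a view (the cellular map already shows
location). Annotations come from GAF 2.x (skipping `NOT`-qualified rows)
or a 2-column TSV; annotations to unknown terms are skipped with a count.

Entities at a term are those annotated to the term or any descendant,
counted once per term (set semantics, even with several annotated
descendants), so counts are monotone along `is_a` edges and the namespace
root holds every annotated displayed entity. The view state is an
expansion frontier: the root alone at first, each expanded term showing
one rectangle per child with at least one displayed entity. Because a DAG
parent's entity set can exceed the union of its shown children, every
expanded rectangle also gets a *residual leaf* ("… (other)") holding
entities not covered by any shown child — this keeps entity conservation
exact inside every rectangle. Collapsing a term recursively collapses its
expanded descendants, so expanded terms always remain reachable through
expanded ancestors. The static renderer exposes both whole-level expansion
(`expand_depth`, breadth-first on populated terms, default 2) and scripted
per-term expansion through `go_expand()`/`go_collapse()`. Rectangle fills
vary by depth on a blue ramp, deliberately distinct from the YlOrRd icon
colors.

## Synthetic fixtures: the stated world

The generator emulates the role of a curated annotation database plus a
demo dataset, with one integer seed driving a single RNG stream
(byte-identical outputs per seed). Defaults, fixed once:

- 2000 entities, 4 samples, 20 pathways, the 10 built-in compartments,
  120 GO terms split evenly between biological process and molecular
  function; 80% of entities receive location and GO annotation, 1–2
  compartments per annotated entity and per pathway, 1–2 `is_a` parents
  per non-root term.
- Pathway membership is independent per (entity, pathway) with expected
  pathway size 30 — typical of curated plant pathway collections.
- Expression: each entity has a latent "high" flag (baseline probability
  0.2) and one base level, lognormal with `meanlog` 3 (+2 for high
  entities) and `sdlog` 1; per-sample values multiply the base by
  lognormal replicate noise with `sdlog` 0.25, so entity-to-entity
  variance dominates replicate variance as in real expression data. A
  min-value filter at 50 (the conventional display cutoff for such data)
  then separates predominantly high entities.
- Planting: for members of a planted pathway the odds of the high flag are
  multiplied by the stated factor (the "odds multiplier"), so a multiplier
  of 1 is exactly the null — membership independent of value — under
  which enrichment p-values are uniform or super-uniform.

What a green test on fixtures does establish: parsing/round-trip fidelity,
conservation and duplication rules, detectability of a strongly planted
signal, and null calibration of the test. What it does not: realistic
microarray noise, RNA-Seq count distributions, correlated pathways or
hub genes, or the shape of real GO (fixture DAGs are shallower and more
regular).

## Numerical and degenerate-input conventions

- Bins are half-open with the top bin closed; interpolated palette
  channels round to the nearest integer.
- Layout tolerances: tiling and proportionality hold to $10^{-9}$
  relative; tie-breaks everywhere are lexicographic by name/id.
- A constant value vector maps to the middle bin; an empty sample is a
  warning (empty view), not an error.
- SVG numbers are printed with fixed, locale-independent formatting, so
  identical inputs give byte-identical files — asserted in the tests.
- Validation errors name the offending file, line, and identifier.

## Known limitations

Regions are rectangles (no organelle silhouettes or packed-circle
placement); one shared color scale per document (users pre-transform, e.g.
log, before input); no multiple-testing correction by default; GO term
enrichment is out of scope (pathways only); the SVG is static — the
machine-readable `data-entities`, `data-value`, and `data-bin` attributes
on every icon are the extension point for interactive front ends.
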