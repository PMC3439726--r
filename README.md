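# cellviews

Batch "bird's-eye" visualization of transcriptomic measurements in their
biological context. `cellviews` maps an entity-by-sample expression matrix
(genes, loci, or probe-mapped genes; RNA-Seq or microarray summaries) onto
three views rendered as deterministic SVG:

1. **Cellular map** — entities placed as color-coded icons inside the ten
   compartments of a plant-cell diagram (nucleus, vacuole,
   mitochondria/cristae, golgi apparatus, endoplasmic reticulum, apoplast,
   plastids/thylakoids, chloroplast, cytosol, plasma membrane). Entities
   with several annotated locations appear in each; entities with unknown
   location are not displayed.
2. **Pathway treemap** — nested rectangles (cell → compartments →
   pathways) with areas proportional to the number of displayed entities,
   plus a one-sided Fisher exact over-representation test per pathway,
   highlighted in red below a user threshold.
3. **Gene Ontology treemaps** — the biological-process and
   molecular-function hierarchies as nested rectangles with true-path
   propagation (an entity annotated to a term counts at every ancestor),
   expanded level by level.

Values (a single sample, or a two-sample comparison) drive a binned
ColorBrewer **YlOrRd** scale — light yellow for low to dark red for high —
with automatic or user-set range. When a compartment cannot fit one icon
per entity, entities are **chunked**: the minimal view-wide group size `g`
is solved so every compartment can display all of its entities; single
entities draw as discs, groups as rectangles colored by the group mean.

## The statistics

For a pathway with `K` genes in a genome background ("universe") of `N`
genes, and `k` of the `n` displayed genes in the pathway, the
over-representation p-value is the hypergeometric upper tail

```
p = sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)
```

(the one-sided Fisher exact test), computed stably via log binomial
coefficients. Two-sample comparisons are `difference = v1 − v2`,
`fold = v1 / v2`, and `difference_fold = (v1 − v2)/v2`; entities with a
zero denominator are excluded and tallied.

## Worked example

Generate a 2000-gene synthetic experiment with over-representation planted
in pathway `pw07` (odds multiplier 10), keep transcripts with a value over
50 in at least one sample, compare samples S1 and S2 by fold change, and
render the pathway treemap:

```r
library(cellviews)
d <- "demo"
generate_fixtures(fixture_spec(n_entities = 2000, seed = 1,
  enriched_pathways = list(list(index = 7, multiplier = 10))), d)
cfg <- run_config(view = "pathways",
  matrix_path = file.path(d, "matrix.tsv"),
  samples_path = file.path(d, "samples.txt"),
  loc_path = file.path(d, "locations.tsv"),
  pw_path = file.path(d, "pathways.tsv"),
  pwcomp_path = file.path(d, "pathway_compartments.tsv"),
  universe_path = file.path(d, "universe.txt"),
  compare = c("S1", "S2"), mode = "fold", min_value = 50,
  out = "pathways.svg", report = "enrichment.tsv")
res <- run(cfg)
head(res$enrichment, 3)
```

The log prints the pipeline stages:

```
stage=read entities=2000 samples=4
stage=min_value threshold=     50 entities=763
stage=values label='S1 vs S2 (fold)' entities=763 excluded=0
stage=scale vmin=0.317606 vmax=2.78391 bins=9
stage=enrich pathways=20 highlighted=1 n=763
stage=chunk view=pathways g=1 icons=294
```

763 of 2000 transcripts pass the min-value filter; all 20 pathways contain
at least one displayed gene and are tested; one is highlighted. The
enrichment table (also written to `enrichment.tsv`) recovers the planted
pathway:

```
  pathway    N  K   n  k      p_value highlighted
1    pw07 2000 29 763 22 3.617422e-05        TRUE
2    pw17 2000 22 763 12 8.670079e-02       FALSE
3    pw13 2000 30 763 14 2.167200e-01       FALSE
```

`pw07` holds 29 of the 2000 background genes; 22 of the 763 displayed
genes fall in it where about 11 would be expected by chance, giving
p ≈ 3.6e-05 — highlighted in red in `pathways.svg`, with the p-value in
the rectangle's `<title>`. `g=1` means no chunking was needed: every icon
is a single-entity disc.

Other views use the same configuration surface:
`view = "cellmap"`, `"go-bp"`, `"go-mf"`, or `"combined"` (cell map and
pathway treemap side by side, with chunking re-solved at the halved area).
A thin CLI wrapper lives at `inst/scripts/cellviews.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package: it generates the seeded 2000-entity fixture world,
renders all five views, writes the enrichment report, and emits the
results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/data_io.R` — readers/writers and validated containers (expression
  dataset, annotation catalog, cell layout)
- `R/values.R` — comparisons, filters, YlOrRd color scale
- `R/chunking.R` — capacity, minimal group size, grouping, grid placement
- `R/treemap.R` — squarified treemap layout and pathway tree building
- `R/enrichment.R` — hypergeometric tail and per-pathway testing
- `R/go_view.R` — OBO/GAF parsing, true-path propagation, expand/collapse
- `R/render.R` — deterministic SVG and TSV reports
- `R/fixtures.R` — seeded synthetic input generator
- `R/run.R` — pipeline driver (`run_config()` / `run()`)

See `vignettes/cellviews-methods.Rmd` for the model, parameter defaults,
and design decisions.
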