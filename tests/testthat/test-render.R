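scene <- function(seed = 30, n = 40) {
  set.seed(seed)
  ents <- sprintf("g%02d", 1:n)
  comps <- default_cell_layout()$compartments$name
  cat <- annotation_catalog(
    stats::setNames(lapply(ents[1:(n - 5)], function(e)
      sort(sample(comps, sample(1:2, 1)))), ents[1:(n - 5)]),
    stats::setNames(lapply(ents[1:(n - 10)], function(e)
      sort(sample(c("pA", "pB", "pC"), sample(1:2, 1)))), ents[1:(n - 10)]),
    list(pA = "cytosol", pB = c("nucleus", "cytosol"), pC = "vacuole"),
    universe = ents)
  v <- value_vector(ents, rlnorm(n, 3, 1))
  list(cat = cat, v = v, scale = auto_scale(v), layout = default_cell_layout())
}

test_that("cell view SVG carries every placed icon with data attributes", {
  sc <- scene()
  cg <- build_cell_groups(sc$v, sc$cat, sc$layout, sc$scale)
  doc <- render_cell_view(sc$layout, cg$groups, sc$scale, cg$plan)
  txt <- as.character(doc)
  expect_equal(sum(grepl("data-entities=", txt)), length(cg$groups))
  # an entity with two compartments appears in two icon elements
  two_loc <- names(sc$cat$entity_compartments)[
    lengths(sc$cat$entity_compartments) == 2][1]
  expect_equal(sum(grepl(paste0("\\b", two_loc, "\\b"),
                         grep("data-entities", txt, value = TRUE))), 2L)
  # unannotated entities appear in no icon element
  missing <- setdiff(sc$v$entity_ids, names(sc$cat$entity_compartments))
  for (m in missing)
    expect_false(any(grepl(m, grep("data-entities", txt, value = TRUE))))
  # empty dataset: regions and legend only
  empty <- render_cell_view(sc$layout, list(), sc$scale, cg$plan)
  expect_false(any(grepl("data-entities", as.character(empty))))
  expect_true(any(grepl("legend", as.character(empty))))
})

test_that("treemap view highlights exactly the flagged pathways", {
  sc <- scene(31)
  root <- build_pathway_tree(sc$cat, sc$v, sc$layout)
  laid <- treemap_layout(root, canvas = c(0, 0, 1000, 700))
  pl <- place_leaf_icons(laid, sc$v, sc$scale)
  enr <- test_all_pathways(sc$cat, sc$v$entity_ids, threshold = 0.6)
  doc <- render_treemap_view(laid, pl$groups, sc$scale, pl$plan,
                             enrichment = enr)
  txt <- as.character(doc)
  n_leaves <- length(unique(enr$pathway[enr$highlighted]))
  # one red overlay per highlighted pathway per compartment it occupies
  leaf_names <- vapply(Filter(function(x) x$is_leaf, laid), `[[`, "", "name")
  want <- sum(leaf_names %in% enr$pathway[enr$highlighted])
  expect_equal(sum(grepl('class="highlight"', txt)), want)
  # p-values surface as title text
  expect_true(any(grepl("p=", grep("<title>", txt, value = TRUE))))
  # no pathway under threshold -> zero overlays
  enr0 <- enr; enr0$highlighted <- FALSE
  doc0 <- render_treemap_view(laid, pl$groups, sc$scale, pl$plan,
                              enrichment = enr0)
  expect_equal(sum(grepl('class="highlight"', as.character(doc0))), 0L)
})

test_that("combined view shares one scale and conserves both halves", {
  sc <- scene(32)
  cg <- build_cell_groups(sc$v, sc$cat, sc$layout, sc$scale)
  left <- render_cell_view(sc$layout, cg$groups, sc$scale, cg$plan,
                           legend = FALSE)
  both <- render_combined(left, left, g = cg$plan$g)
  txt <- as.character(both)
  expect_equal(sum(grepl("data-entities", txt)), 2L * length(cg$groups))
  other <- color_scale(-1, 1)
  right <- render_cell_view(sc$layout, cg$groups, other, cg$plan,
                            legend = FALSE)
  right$scale <- other
  expect_error(render_combined(left, right), "different color scales")
})

test_that("entity description table de-duplicates and tolerates unknowns", {
  sc <- scene(33)
  ds <- make_ds(matrix(sc$v$v, ncol = 1), entities = sc$v$entity_ids,
                samples = "S1")
  df <- describe_entities(c("g01", "g01", "g02", "zz"), sc$cat, ds)
  expect_equal(nrow(df), 3L)
  expect_equal(df$flag[df$id == "zz"], "unknown id")
  expect_equal(df$compartments[df$id == "g01"],
               paste(sc$cat$entity_compartments[["g01"]], collapse = "; "))
  expect_equal(df$pathways[df$id == "g02"],
               paste(sc$cat$entity_pathways[["g02"]], collapse = "; "))
  p <- tempfile()
  write_tsv_report(df, p)
  expect_equal(nrow(read.delim(p)), 3L)
})

test_that("rendering is byte-deterministic", {
  for (seed in c(40, 41)) {
    sc <- scene(seed)
    render_once <- function() {
      cg <- build_cell_groups(sc$v, sc$cat, sc$layout, sc$scale)
      p <- tempfile(fileext = ".svg")
      write_svg(render_cell_view(sc$layout, cg$groups, sc$scale, cg$plan), p)
      readBin(p, "raw", file.size(p))
    }
    expect_identical(render_once(), render_once())
  }
})
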