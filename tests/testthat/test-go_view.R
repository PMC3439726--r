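toy_obo <- function() {
  write_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child b",
    "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: grandchild c",
    "namespace: biological_process", "is_a: GO:0000002 ! child b", "",
    "[Term]", "id: GO:0000004", "name: child d",
    "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: biological_process", "is_obsolete: true",
    "is_a: GO:0000001 ! root process"), ext = ".obo")
}

test_that("OBO parsing: chains, obsolete terms, cycles, roots", {
  g <- read_obo(toy_obo())
  expect_setequal(g$terms$id, sprintf("GO:000000%d", 1:4))
  expect_equal(g$parents[["GO:0000002"]], "GO:0000001")
  expect_equal(g$parents[["GO:0000003"]], "GO:0000002")
  expect_false("GO:0000009" %in% g$terms$id)
  expect_equal(go_root(g, "biological_process"), "GO:0000001")

  cyc <- write_tmp(c("[Term]", "id: GO:1", "name: a",
                     "namespace: biological_process", "is_a: GO:2", "",
                     "[Term]", "id: GO:2", "name: b",
                     "namespace: biological_process", "is_a: GO:1"),
                   ext = ".obo")
  expect_error(read_obo(cyc), "cycle")
})

test_that("OBO round-trips through the fixture generator", {
  fx <- generate_fixture_data(fixture_spec(n_entities = 50, n_go_terms = 200,
                                           seed = 21))
  d <- tempdir()
  path <- file.path(d, "rt.obo")
  writeLines(cellviews:::obo_lines(fx$go), path)
  back <- read_obo(path)
  expect_setequal(back$terms$id, fx$go$terms$id)
  edge_str <- function(g) sort(unlist(lapply(names(g$parents), function(ch)
    paste(ch, g$parents[[ch]]))))
  expect_equal(edge_str(back), edge_str(fx$go))
})

test_that("GAF and 2-column annotation reading", {
  g <- read_obo(toy_obo())
  gaf_row <- function(ent, term, qual = "") paste(
    c("DB", ent, ent, qual, term, "REF", "IEA", "", "P", ent, "", "protein",
      "taxon:1", "20200101", "DB", "", ""), collapse = "\t")
  gaf <- write_tmp(c("!gaf-version: 2.1",
                     gaf_row("g1", "GO:0000003"),
                     gaf_row("g2", "GO:0000002", qual = "NOT"),
                     gaf_row("g3", "GO:9999999")), ext = ".gaf")
  got <- suppressMessages(read_annotations_gaf(gaf, g))
  expect_equal(got$annotations, list(g1 = "GO:0000003"))
  expect_equal(attr(got, "n_unknown_terms"), 1L)

  tsv <- write_tmp(c("g1\tGO:0000004", "g4\tGO:0000002"))
  got2 <- read_annotations_gaf(tsv, g)
  expect_setequal(got2$annotations[["g4"]], "GO:0000002")

  bad <- write_tmp(c("a\tb\tc"))
  expect_error(read_annotations_gaf(bad, g), "line 1")

  # fixture GAF round-trips the annotation multimap
  fx <- generate_fixture_data(fixture_spec(n_entities = 60, n_go_terms = 30,
                                           seed = 22))
  gp <- tempfile(fileext = ".gaf")
  writeLines(cellviews:::gaf_lines(fx$go), gp)
  empty <- fx$go; empty$annotations <- list()
  back <- read_annotations_gaf(gp, empty)
  expect_equal(back$annotations[order(names(back$annotations))],
               fx$go$annotations[order(names(fx$go$annotations))])
})

test_that("true-path propagation matches the closure oracle", {
  g <- read_obo(toy_obo())
  tsv <- write_tmp(c("g1\tGO:0000003", "g2\tGO:0000002", "g3\tGO:0000004",
                     "g4\tGO:0000001"))
  g <- read_annotations_gaf(tsv, g)
  shown <- c("g1", "g2", "g3", "g4")
  expect_setequal(entities_at_term(g, "GO:0000001", shown), shown)
  expect_equal(entities_at_term(g, "GO:0000003", shown), "g1")
  expect_setequal(entities_at_term(g, "GO:0000002", shown), c("g1", "g2"))
  expect_error(entities_at_term(g, "GO:77", shown), "unknown term")

  # random DAGs: every term equals the reachability oracle, and counts are
  # monotone along is_a edges
  fx <- generate_fixture_data(fixture_spec(n_entities = 80, n_go_terms = 60,
                                           seed = 23))
  go <- fx$go
  shown <- sample(names(go$annotations), 50)
  for (term in go$terms$id) {
    closure <- ref_descendants(go$terms$id, go$parents, term)
    oracle <- sort(shown[vapply(shown, function(e)
      any(go$annotations[[e]] %in% closure), logical(1))])
    expect_equal(entities_at_term(go, term, shown), oracle)
  }
  for (ch in names(go$parents)) for (pa in go$parents[[ch]])
    expect_gte(length(entities_at_term(go, pa, shown)),
               length(entities_at_term(go, ch, shown)))
})

test_that("expand/collapse state transitions preserve the invariant", {
  g <- read_obo(toy_obo())
  st <- go_view_state(g, "biological_process")
  expect_equal(visible_terms(st, g), "GO:0000001")

  st1 <- go_expand(st, "GO:0000001", g)
  expect_setequal(visible_terms(st1, g), sprintf("GO:000000%d", 1:2) |>
                    c("GO:0000004"))
  st2 <- go_expand(st1, "GO:0000002", g)
  expect_true("GO:0000003" %in% visible_terms(st2, g))
  # collapsing the root removes expanded descendants too
  st3 <- go_collapse(st2, "GO:0000001", g)
  expect_equal(st3$expanded, character(0))
  # expand then collapse is the identity on a single term
  expect_equal(go_collapse(st1, "GO:0000001", g)$expanded, st$expanded)
  # leaf expansion is a no-op with a notice
  expect_message(go_expand(st2, "GO:0000003", g), "no children")
  expect_error(go_expand(st, "GO:0000003", g), "not currently visible")

  # fuzz: random expand/collapse sequences keep every expanded term
  # reachable from the root through expanded ancestors
  fx <- generate_fixture_data(fixture_spec(n_entities = 30, n_go_terms = 40,
                                           seed = 24))
  go <- fx$go
  st <- go_view_state(go, "biological_process")
  set.seed(25)
  for (i in 1:200) {
    vis <- visible_terms(st, go)
    if (runif(1) < 0.6 || !length(st$expanded)) {
      t <- sample(vis, 1)
      if (length(go$children[[t]])) st <- go_expand(st, t, go)
    } else {
      st <- go_collapse(st, sample(st$expanded, 1), go)
    }
    for (e in st$expanded) {
      anc_ok <- e == st$root || any(go$parents[[e]] %in% st$expanded) ||
        any(go$parents[[e]] == st$root & st$root %in% st$expanded)
      expect_true(e %in% visible_terms(st, go))
    }
  }
})

test_that("GO tree mirrors the frontier with residual leaves", {
  g <- read_obo(toy_obo())
  tsv <- write_tmp(c("g1\tGO:0000003", "g2\tGO:0000002", "g3\tGO:0000001"))
  g <- read_annotations_gaf(tsv, g)
  shown <- c("g1", "g2", "g3")
  st <- go_view_state(g, "biological_process")

  # nothing expanded: one rectangle holding every annotated entity
  t0 <- build_go_tree(g, st, shown)
  expect_equal(t0$weight, 3)
  expect_equal(length(t0$children), 0L)

  # expanded root: child b covers g1, g2; g3 (annotated to the root only)
  # lands in the residual leaf; child d has no entities and is dropped
  st1 <- go_expand(st, "GO:0000001", g)
  t1 <- build_go_tree(g, st1, shown)
  kid_names <- vapply(t1$children, `[[`, "", "name")
  expect_setequal(kid_names, c("child b", "root process (other)"))
  res_leaf <- t1$children[[which(kid_names == "root process (other)")]]
  expect_equal(res_leaf$entities, "g3")
  expect_equal(t1$weight, 3)

  # random states: node weights equal the oracle and children + residual
  # cover the parent's entity set
  fx <- generate_fixture_data(fixture_spec(n_entities = 60, n_go_terms = 50,
                                           seed = 26))
  go <- fx$go
  shown <- names(go$annotations)
  st <- go_view_state(go, "biological_process")
  st <- expand_to_depth(st, go, shown, 3L)
  tr <- build_go_tree(go, st, shown)
  nm2id <- stats::setNames(go$terms$id, go$terms$name)
  check <- function(nd) {
    if (!length(nd$children)) return(invisible())
    kid_ents <- lapply(nd$children, function(ch)
      if (length(ch$children)) attr(check(ch), "ents") else ch$entities)
    expect_equal(nd$weight, sum(vapply(nd$children, `[[`, 0, "weight")))
    if (nd$name %in% names(nm2id)) {
      own <- entities_at_term(go, nm2id[[nd$name]], shown)
      expect_setequal(unique(unlist(kid_ents)), own)
    }
    structure(invisible(nd), ents = unique(unlist(kid_ents)))
  }
  check(tr)
})
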