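test_that("pathway tree duplicates entities per (pathway, compartment)", {
  cat <- make_catalog()
  v <- value_vector(sprintf("g%d", 1:4), c(1, 2, 3, 4))
  root <- build_pathway_tree(cat, v)
  # pA in cytosol: {g1, g2}; pB in cytosol and nucleus: {g1, g4} each
  leaves <- list()
  walk <- function(nd, comp) {
    if (!length(nd$children)) leaves[[paste(comp, nd$name)]] <<- nd
    else for (ch in nd$children) walk(ch, nd$name)
  }
  for (ch in root$children) walk(ch, ch$name)
  expect_equal(leaves[["cytosol pA"]]$weight, 2)
  expect_equal(leaves[["cytosol pB"]]$weight, 2)
  expect_equal(leaves[["nucleus pB"]]$weight, 2)
  expect_equal(root$weight, 6)

  # entity in 2 pathways each in 1 compartment -> total weight 2
  cat2 <- annotation_catalog(list(e1 = "cytosol"),
                             list(e1 = c("pA", "pB")),
                             list(pA = "cytosol", pB = "nucleus"),
                             universe = "e1")
  r2 <- build_pathway_tree(cat2, value_vector("e1", 1))
  expect_equal(r2$weight, 2)

  # no pathway annotation at all -> empty root
  r3 <- build_pathway_tree(cat, value_vector("g6", 1))
  expect_equal(length(r3$children), 0L)

  # random catalogs: leaf weights equal the triple-loop counting oracle
  set.seed(10)
  for (rep in 1:10) {
    ents <- sprintf("e%02d", 1:30)
    pws <- sprintf("p%d", 1:5)
    comps <- c("c1", "c2", "c3")
    ep <- lapply(ents, function(e) sample(pws, sample(0:2, 1)))
    names(ep) <- ents
    ep <- ep[lengths(ep) > 0]
    pc <- lapply(pws, function(p) sample(comps, sample(1:2, 1)))
    names(pc) <- pws
    cc <- annotation_catalog(list(e01 = "c1"), ep, pc, universe = ents)
    shown <- sample(ents, 20)
    vv <- value_vector(shown, seq_along(shown))
    rt <- build_pathway_tree(cc, vv)
    for (comp_nd in rt$children) for (leaf in comp_nd$children) {
      oracle <- sum(vapply(shown, function(e)
        leaf$name %in% (ep[[e]] %||% character(0)) &&
          comp_nd$name %in% pc[[leaf$name]], logical(1)))
      expect_equal(leaf$weight, oracle)
    }
  }
})

test_that("squarified layout: simple cases and reference transcription", {
  # two equal children in a unit square -> two congruent halves
  root <- tree_node("r", children = list(tree_node("a", weight = 1),
                                         tree_node("b", weight = 1)))
  laid <- treemap_layout(root, canvas = c(0, 0, 1, 1), inner_pad = 0)
  kids <- Filter(function(x) x$depth == 1L, laid)
  expect_equal(sort(sapply(kids, function(k) k$w * k$h)), c(0.5, 0.5))
  expect_equal(sapply(kids, function(k) sort(c(k$w, k$h))),
               matrix(c(0.5, 1, 0.5, 1), 2))

  # single child fills the parent interior
  one <- tree_node("r", children = list(tree_node("a", weight = 3)))
  l1 <- treemap_layout(one, canvas = c(0, 0, 100, 60), inner_pad = 4)
  kid <- Filter(function(x) x$depth == 1L, l1)[[1]]
  expect_equal(c(kid$x, kid$y, kid$w, kid$h), c(4, 4, 92, 52))

  # flat weight sets against the independently transcribed reference
  wts <- c(6, 6, 4, 3, 2, 2, 1)
  root <- tree_node("r", children = lapply(seq_along(wts), function(i)
    tree_node(sprintf("c%02d", i), weight = wts[i])))
  laid <- treemap_layout(root, canvas = c(0, 0, 600, 400), inner_pad = 0)
  kids <- Filter(function(x) x$depth == 1L, laid)
  got <- t(sapply(kids, function(k) c(k$x, k$y, k$w, k$h)))
  areas <- wts / sum(wts) * 600 * 400   # already descending
  want <- ref_squarify(areas, 0, 0, 600, 400)
  expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)

  # padding too aggressive for a small rectangle
  deep <- tree_node("r", children = list(
    tree_node("m", children = list(tree_node("x", weight = 1)))))
  expect_error(treemap_layout(deep, canvas = c(0, 0, 10, 10), inner_pad = 4),
               "smaller inner_pad")
})

test_that("icons inside treemap leaves conserve entities and solve one g", {
  cat <- make_catalog()
  v <- value_vector(sprintf("g%d", 1:4), c(9, 2, 3, 4))
  root <- build_pathway_tree(cat, v)
  laid <- treemap_layout(root, canvas = c(0, 0, 800, 600), inner_pad = 4)
  res <- place_leaf_icons(laid, v, auto_scale(v))
  expect_equal(res$plan$g, 1L)
  expect_true(all(sapply(res$groups, `[[`, "shape") == "disc"))
  # per-leaf membership equals the catalog's
  by_leaf <- split(unlist(lapply(res$groups, `[[`, "members")),
                   rep(sapply(res$groups, `[[`, "region"),
                       sapply(res$groups, function(g) length(g$members))))
  expect_setequal(by_leaf[["cell / cytosol / pA"]], c("g1", "g2"))
  expect_setequal(by_leaf[["cell / nucleus / pB"]], c("g1", "g4"))

  # a tiny leaf forces g > 1 and rectangular icons
  tiny_root <- tree_node("r", children = list(
    tree_node("leaf", weight = 30, entities = sprintf("e%02d", 1:30))))
  tl <- treemap_layout(tiny_root, canvas = c(0, 0, 40, 40), inner_pad = 2)
  vv <- value_vector(sprintf("e%02d", 1:30), 1:30)
  res2 <- place_leaf_icons(tl, vv, auto_scale(vv))
  expect_gt(res2$plan$g, 1L)
  expect_true(any(sapply(res2$groups, `[[`, "shape") == "rectangle"))
  expect_setequal(unlist(lapply(res2$groups, `[[`, "members")),
                  sprintf("e%02d", 1:30))
})
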