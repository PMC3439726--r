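# Independent oracles and small in-code fixture builders shared by the
# test files. Oracles deliberately take a different computational route
# from the package implementation.

# Exact hypergeometric upper tail via integer binomial-coefficient ratios;
# choose() is exact in double precision for N <= 30, so this equals full
# enumeration of the C(N, n) draws.
ref_hyper_tail <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Direct transcription of the published squarified-treemap algorithm in its
# recursive squarify(children, row, w) form. Areas must sum to w * h.
ref_squarify <- function(areas, x0, y0, w0, h0) {
  res <- matrix(NA_real_, length(areas), 4L)
  free <- c(x0, y0, w0, h0)
  worst <- function(row) {
    side <- min(free[3L], free[4L])
    s <- sum(row)
    max(side^2 * max(row) / s^2, s^2 / (side^2 * min(row)))
  }
  layoutrow <- function(idx) {
    s <- sum(areas[idx])
    if (free[3L] >= free[4L]) {
      thick <- s / free[4L]
      off <- free[2L]
      for (i in idx) {
        res[i, ] <<- c(free[1L], off, thick, areas[i] / thick)
        off <- off + areas[i] / thick
      }
      free <<- c(free[1L] + thick, free[2L], free[3L] - thick, free[4L])
    } else {
      thick <- s / free[3L]
      off <- free[1L]
      for (i in idx) {
        res[i, ] <<- c(off, free[2L], areas[i] / thick, thick)
        off <- off + areas[i] / thick
      }
      free <<- c(free[1L], free[2L] + thick, free[3L], free[4L] - thick)
    }
  }
  squarify <- function(children, row) {
    if (!length(children)) {
      if (length(row)) layoutrow(row)
      return(invisible())
    }
    c1 <- children[[1L]]
    if (!length(row) || worst(areas[row]) >= worst(areas[c(row, c1)])) {
      squarify(children[-1L], c(row, c1))
    } else {
      layoutrow(row)
      squarify(children, integer(0))
    }
  }
  squarify(seq_along(areas), integer(0))
  res
}

# Slice-and-dice layout (alternating direction by depth 0) of one level,
# used for the squarified-quality comparison.
slice_dice_rects <- function(areas, x0, y0, w0, h0) {
  total <- sum(areas)
  res <- matrix(NA_real_, length(areas), 4L)
  if (w0 >= h0) {
    off <- x0
    for (i in seq_along(areas)) {
      wi <- w0 * areas[i] / total
      res[i, ] <- c(off, y0, wi, h0)
      off <- off + wi
    }
  } else {
    off <- y0
    for (i in seq_along(areas)) {
      hi <- h0 * areas[i] / total
      res[i, ] <- c(x0, off, w0, hi)
      off <- off + hi
    }
  }
  res
}

worst_aspect <- function(rects) {
  max(apply(rects, 1L, function(r) max(r[3L] / r[4L], r[4L] / r[3L])))
}

# Reachability oracle for the GO DAG: boolean adjacency closure by
# iterated expansion over the raw edge list (independent of the package's
# children-map DFS).
ref_descendants <- function(terms, parents, term) {
  reach <- terms == term
  names(reach) <- terms
  repeat {
    grew <- FALSE
    for (ch in names(parents)) {
      if (!reach[[ch]] && any(reach[parents[[ch]]])) {
        reach[[ch]] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  sort(terms[reach])
}

# --- tiny in-code builders ------------------------------------------------

make_ds <- function(values, entities = NULL, samples = NULL) {
  values <- as.matrix(values)
  entities <- entities %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("S%d", seq_len(ncol(values)))
  expression_dataset(values, entities, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

make_catalog <- function() {
  annotation_catalog(
    entity_compartments = list(g1 = c("cytosol", "nucleus"), g2 = "cytosol",
                               g3 = "nucleus"),
    entity_pathways = list(g1 = c("pA", "pB"), g2 = "pA", g4 = "pB"),
    pathway_compartments = list(pA = "cytosol", pB = c("cytosol", "nucleus")),
    universe = sprintf("g%d", 1:6))
}

# random weighted tree for treemap property tests
random_tree <- function(depth, max_children = 4, p_leaf = 0.4, prefix = "n") {
  if (depth == 0L || stats::runif(1) < p_leaf)
    return(tree_node(prefix, weight = stats::runif(1, 0.5, 10)))
  kids <- lapply(seq_len(sample(2:max_children, 1L)), function(i)
    random_tree(depth - 1L, max_children, p_leaf, paste0(prefix, ".", i)))
  tree_node(prefix, children = kids)
}

# For every internal node of a layout: children must tile the node's
# inner_pad-shrunk interior (areas sum to the interior area), each child's
# area share must equal its weight share, and no two children may overlap.
collect_layout_checks <- function(laid, inner_pad) {
  ok_area <- TRUE; ok_prop <- TRUE; ok_overlap <- TRUE
  for (nd in laid) {
    if (nd$is_leaf) next
    key <- paste(nd$path, collapse = "\r")
    kids <- laid[vapply(laid, function(x)
      length(x$path) == length(nd$path) + 1L &&
        paste(x$path[-length(x$path)], collapse = "\r") == key, logical(1))]
    if (!length(kids)) next
    areas <- vapply(kids, function(k) k$w * k$h, 0)
    wts <- vapply(kids, `[[`, 0, "weight")
    interior <- (nd$w - 2 * inner_pad) * (nd$h - 2 * inner_pad)
    ok_area <- ok_area && abs(sum(areas) - interior) <= 1e-9 * interior
    ok_prop <- ok_prop && all(abs(areas / interior - wts / sum(wts)) < 1e-9)
    if (length(kids) > 1L) {
      for (i in seq_len(length(kids) - 1L)) for (j in (i + 1L):length(kids)) {
        a <- kids[[i]]; b <- kids[[j]]
        ox <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
        oy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
        if (ox * oy > 1e-9 * interior) ok_overlap <- FALSE
      }
    }
  }
  c(area = ok_area, prop = ok_prop, overlap = ok_overlap)
}
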