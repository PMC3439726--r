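# Treemap engine: weighted trees (view -> compartments -> pathways, or the
# GO hierarchy) laid out as nested rectangles with areas proportional to
# entity counts, using the squarified heuristic.

#' Construct a tree node
#'
#' @param name Node name.
#' @param weight Non-negative weight (entity count at leaves; internal nodes
#'   take the sum of their children).
#' @param children List of child `TreeNode`s.
#' @param fill Fill color (hex) or `NA`.
#' @param highlight Logical flag (red over-representation highlight).
#' @param entities Optional character vector of the entities behind a leaf.
#' @return An object of class `TreeNode`.
#' @export
tree_node <- function(name, weight = 0, children = list(), fill = NA_character_,
                      highlight = FALSE, entities = NULL) {
  if (length(children)) weight <- sum(vapply(children, `[[`, 0, "weight"))
  if (weight < 0) stop2("negative weight at node '%s'", name)
  structure(list(name = as.character(name), weight = as.numeric(weight),
                 children = children, fill = fill,
                 highlight = isTRUE(highlight), entities = entities),
            class = "TreeNode")
}

# Drop zero-weight subtrees (never rendered as slivers).
prune_tree <- function(node) {
  if (length(node$children)) {
    kept <- Filter(function(ch) ch$weight > 0,
                   lapply(node$children, prune_tree))
    node$children <- kept
    node$weight <- sum(vapply(kept, `[[`, 0, "weight"))
  }
  node
}

#' Build the compartment/pathway tree for the pathway view
#'
#' Root -> one child per compartment hosting at least one populated pathway
#' -> one leaf per (pathway, compartment) pair. A leaf's weight is the
#' number of displayed entities annotated to that pathway; an entity in m
#' pathways located in k compartments therefore contributes to all m*k
#' leaves, so multi-membership entities appear multiple times, and pathway
#' rectangles grow with the number of entities they contain.
#'
#' @param catalog An `AnnotationCatalog`.
#' @param v The displayed `ValueVector`.
#' @param layout A `CellLayout`; compartment fills are reused so the pathway
#'   view is colored consistently with the cellular map.
#' @return The root `TreeNode` (zero children if nothing is annotated).
#' @export
build_pathway_tree <- function(catalog, v, layout = default_cell_layout()) {
  fills <- stats::setNames(layout$compartments$fill, layout$compartments$name)
  # pathway -> sorted displayed member entities
  members <- list()
  for (e in v$entity_ids) {
    for (p in catalog$entity_pathways[[e]] %||% character(0))
      members[[p]] <- c(members[[p]], e)
  }
  comp_children <- list()
  for (p in sort(names(members))) {
    ents <- sort(unique(members[[p]]))
    for (cn in catalog$pathway_compartments[[p]])
      comp_children[[cn]] <- c(comp_children[[cn]], list(
        tree_node(p, weight = length(ents), entities = ents)))
  }
  comps <- lapply(sort(names(comp_children)), function(cn)
    tree_node(cn, children = comp_children[[cn]],
              fill = if (cn %in% names(fills)) fills[[cn]] else "#DDDDDD"))
  prune_tree(tree_node("cell", children = comps))
}

# Squarified subdivision (Bruls, Huizing & van Wijk): areas (descending)
# are packed into rows along the shorter side of the remaining rectangle,
# a row is closed as soon as adding the next area would worsen the row's
# worst aspect ratio. Returns an n x 4 matrix (x, y, w, h) in input order.
squarify_rects <- function(areas, x, y, w, h) {
  n <- length(areas)
  out <- matrix(NA_real_, n, 4L, dimnames = list(NULL, c("x", "y", "w", "h")))
  worst <- function(row, side) {
    s <- sum(row)
    max((side^2) * max(row) / s^2, s^2 / ((side^2) * min(row)))
  }
  lay_row <- function(row_idx, x, y, w, h) {
    s <- sum(areas[row_idx])
    if (w >= h) {              # column strip against the left edge
      t <- s / h
      ys <- y + c(0, cumsum(areas[row_idx] / t))
      for (j in seq_along(row_idx))
        out[row_idx[j], ] <<- c(x, ys[j], t, areas[row_idx[j]] / t)
      c(x + t, y, w - t, h)
    } else {                   # row strip against the top edge
      t <- s / w
      xs <- x + c(0, cumsum(areas[row_idx] / t))
      for (j in seq_along(row_idx))
        out[row_idx[j], ] <<- c(xs[j], y, areas[row_idx[j]] / t, t)
      c(x, y + t, w, h - t)
    }
  }
  row <- integer(0)
  rect <- c(x, y, w, h)
  for (i in seq_len(n)) {
    side <- min(rect[3L], rect[4L])
    if (!length(row) ||
        worst(areas[c(row, i)], side) <= worst(areas[row], side)) {
      row <- c(row, i)
    } else {
      rect <- lay_row(row, rect[1L], rect[2L], rect[3L], rect[4L])
      row <- i
    }
  }
  if (length(row)) lay_row(row, rect[1L], rect[2L], rect[3L], rect[4L])
  out
}

#' Lay out a weighted tree as nested rectangles
#'
#' Squarified treemap recursion: inside each parent, an `inner_pad` margin
#' is applied, children are sorted by descending weight (ties by name) and
#' subdivided so each child's area share of the parent interior equals its
#' weight share. Labels are drawn as render-level overlays, so the
#' subdivision tiles the interior exactly.
#'
#' @param root A `TreeNode` with positive weight.
#' @param canvas Numeric `(x, y, width, height)` rectangle.
#' @param inner_pad Padding inside each parent before subdividing.
#' @return List of laid-out nodes (class `LaidOutNode`): `name`, `depth`
#'   (root = 0), `path` (names from root), `x`, `y`, `w`, `h`, `weight`,
#'   `fill`, `highlight`, `is_leaf`, `node` (the `TreeNode`).
#' @export
treemap_layout <- function(root, canvas = c(0, 0, 1000, 700), inner_pad = 4) {
  if (root$weight <= 0) stop2("cannot lay out a tree of zero total weight")
  out <- list()
  recurse <- function(node, rect, depth, path) {
    rect <- unname(rect)
    out[[length(out) + 1L]] <<- structure(
      list(name = node$name, depth = depth, path = path,
           x = rect[1L], y = rect[2L], w = rect[3L], h = rect[4L],
           weight = node$weight, fill = node$fill,
           highlight = node$highlight,
           is_leaf = length(node$children) == 0L, node = node),
      class = "LaidOutNode")
    if (!length(node$children)) return(invisible())
    ix <- rect[1L] + inner_pad
    iy <- rect[2L] + inner_pad
    iw <- rect[3L] - 2 * inner_pad
    ih <- rect[4L] - 2 * inner_pad
    if (iw <= 0 || ih <= 0)
      stop2("rectangle of '%s' is too small for inner_pad = %g; use a smaller inner_pad",
            node$name, inner_pad)
    wts <- vapply(node$children, `[[`, 0, "weight")
    nms <- vapply(node$children, `[[`, "", "name")
    ord <- order(-wts, nms, method = "radix")
    areas <- wts[ord] / sum(wts) * (iw * ih)
    rects <- squarify_rects(areas, ix, iy, iw, ih)
    for (j in seq_along(ord))
      recurse(node$children[[ord[j]]], rects[j, ], depth + 1L,
              c(path, node$children[[ord[j]]]$name))
  }
  recurse(root, as.numeric(canvas), 0L, root$name)
  out
}

#' Chunk and place icons inside treemap leaves
#'
#' The leaf rectangles act as compartments: the view-wide entities-per-icon
#' factor `g` is solved across all leaves, then each leaf's entities are
#' grouped (ascending by value), binned on the shared scale, and placed on
#' the leaf's grid.
#'
#' @param laid List of `LaidOutNode` from [treemap_layout()]; only leaves
#'   carrying entities are used.
#' @param v The displayed `ValueVector`.
#' @param scale A `ColorScale`.
#' @param icon_size,padding,max_per_icon As in [build_cell_groups()].
#' @return List with `groups` (each `IconGroup$region` is the leaf's path
#'   collapsed with `" / "`) and `plan`.
#' @export
place_leaf_icons <- function(laid, v, scale, icon_size = 8, padding = 2,
                             max_per_icon = NULL) {
  vals <- stats::setNames(v$v, v$entity_ids)
  leaves <- Filter(function(nd) nd$is_leaf && !is.null(nd$node$entities), laid)
  keys <- vapply(leaves, function(nd) paste(nd$path, collapse = " / "), "")
  ents <- lapply(leaves, function(nd)
    intersect(nd$node$entities, v$entity_ids))
  counts <- stats::setNames(lengths(ents), keys)
  caps <- stats::setNames(vapply(leaves, function(nd)
    compartment_capacity(list(x = nd$x, y = nd$y, width = nd$w, height = nd$h),
                         icon_size, padding), integer(1)), keys)
  plan <- solve_group_size(counts, caps, icon_size = icon_size)
  if (!is.null(max_per_icon) && max_per_icon < plan$g)
    stop2("max_per_icon = %d is below the minimal feasible group size %d",
          max_per_icon, plan$g)
  groups <- list()
  for (i in seq_along(leaves)) {
    if (!length(ents[[i]])) next
    sub <- value_vector(ents[[i]], vals[ents[[i]]], v$label)
    grs <- group_entities(sub, plan$g)
    grs <- assign_bins(grs, scale)
    grs <- place_icons(grs, list(x = leaves[[i]]$x, y = leaves[[i]]$y,
                                 width = leaves[[i]]$w, height = leaves[[i]]$h),
                       icon_size, padding)
    grs <- lapply(grs, function(g) { g$region <- keys[[i]]; g })
    groups <- c(groups, grs)
  }
  list(groups = groups, plan = plan)
}
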