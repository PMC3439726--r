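# Automatic scaling: how many entities one icon stands for, and where the
# icons go. A single entity is drawn as a disc; a group of entities as a
# rectangle colored by the group's mean value. The group size g is solved
# view-wide so that every compartment can display all of its entities.

#' Icon capacity of a rectangular region
#'
#' Number of icon grid cells that fit in a region: each cell is
#' `icon_size + padding` on a side and the usable area is the region minus a
#' `padding` margin on every edge.
#'
#' @param region List or named vector with `x`, `y`, `width`, `height`.
#' @param icon_size Icon side/diameter in canvas units (> 0).
#' @param padding Gap between icons and to the region edge.
#' @return Non-negative integer capacity.
#' @export
compartment_capacity <- function(region, icon_size, padding = 2) {
  if (icon_size <= 0) stop2("icon_size must be positive")
  cell <- icon_size + padding
  usable_w <- region[["width"]] - 2 * padding
  usable_h <- region[["height"]] - 2 * padding
  ncol <- max(0, floor(usable_w / cell))
  nrow <- max(0, floor(usable_h / cell))
  as.integer(ncol * nrow)
}

#' Solve the minimal view-wide entities-per-icon factor
#'
#' Finds the smallest integer `g` such that every compartment can display
#' all of its entities: `ceil(n_c / g) <= capacity_c` for every compartment
#' `c`, i.e. `g = max_c ceil(n_c / capacity_c)` (floored at 1).
#'
#' @param counts Named integer vector: entities per compartment.
#' @param capacities Named integer vector: icon capacity per compartment
#'   (names must cover `names(counts)`).
#' @param icon_size Icon size recorded in the plan (cosmetic; default 8).
#' @return An object of class `PackingPlan`: `g`, `icon_size`, `capacities`.
#' @export
solve_group_size <- function(counts, capacities, icon_size = 8) {
  counts <- counts[counts > 0]
  missing_cap <- setdiff(names(counts), names(capacities))
  if (length(missing_cap))
    stop2("no capacity given for compartment '%s'", missing_cap[1L])
  cap <- capacities[names(counts)]
  starved <- cap == 0L
  if (any(starved))
    stop2("compartment '%s' holds %d entities but fits no icon (icon size too large)",
          names(counts)[starved][1L], counts[starved][1L])
  g <- if (length(counts)) max(1, ceiling(counts / cap)) else 1
  structure(list(g = as.integer(g), icon_size = icon_size,
                 capacities = capacities),
            class = "PackingPlan")
}

#' @export
print.PackingPlan <- function(x, ...) {
  cat(sprintf("<PackingPlan> g = %d entities/icon, icon size %g\n",
              x$g, x$icon_size))
  invisible(x)
}

new_icon_group <- function(members, value, bin = NA_integer_,
                           x = NA_real_, y = NA_real_, region = NA_character_) {
  structure(list(members = members, value = value,
                 shape = if (length(members) == 1L) "disc" else "rectangle",
                 bin = bin, x = x, y = y, region = region),
            class = "IconGroup")
}

#' Group a compartment's entities into icons
#'
#' Entities are sorted ascending by value (ties broken by entity id) so that
#' icons run from light to dark within a compartment, then chunked into
#' consecutive runs of `g` (the last run may be shorter). Each group's
#' representative value is the arithmetic mean of its members.
#'
#' @param v A `ValueVector` restricted to one compartment/region.
#' @param g Entities per icon (>= 1).
#' @return List of `IconGroup` objects (fields `members`, `value`, `shape`;
#'   `shape` is `"disc"` iff the group has a single member).
#' @export
group_entities <- function(v, g) {
  g <- as.integer(g)
  if (g < 1L) stop2("g must be >= 1")
  n <- length(v$v)
  if (n == 0L) return(list())
  ord <- order(v$v, v$entity_ids, method = "radix")
  ids <- v$entity_ids[ord]
  vals <- v$v[ord]
  starts <- seq(1L, n, by = g)
  lapply(starts, function(s) {
    idx <- s:min(s + g - 1L, n)
    new_icon_group(ids[idx], mean(vals[idx]))
  })
}

#' Assign color bins to icon groups
#' @param groups List of `IconGroup`.
#' @param scale A `ColorScale` shared across the whole view.
#' @return The groups with `bin` filled in.
#' @export
assign_bins <- function(groups, scale) {
  lapply(groups, function(gr) { gr$bin <- bin_index(scale, gr$value); gr })
}

#' Place icons on a region's grid
#'
#' Row-major placement (left to right, top to bottom) on the capacity grid
#' of [compartment_capacity()]; positions are the top-left corners of the
#' icon cells, so icons never overlap and stay inside the region.
#'
#' @param groups List of `IconGroup` (at most the region's capacity).
#' @param region List/named vector with `x`, `y`, `width`, `height`.
#' @param icon_size,padding As in [compartment_capacity()].
#' @return The groups with `x`, `y` filled in.
#' @export
place_icons <- function(groups, region, icon_size, padding = 2) {
  cap <- compartment_capacity(region, icon_size, padding)
  if (length(groups) > cap)
    stop2("%d icons exceed the region capacity of %d", length(groups), cap)
  if (!length(groups)) return(groups)
  cell <- icon_size + padding
  ncol <- max(1L, floor((region[["width"]] - 2 * padding) / cell))
  i <- seq_along(groups) - 1L
  xs <- region[["x"]] + padding + (i %% ncol) * cell
  ys <- region[["y"]] + padding + (i %/% ncol) * cell
  Map(function(gr, x, y) { gr$x <- x; gr$y <- y; gr }, groups, xs, ys)
}

#' Build all icon groups for the cellular map view
#'
#' Drives the whole chunking pipeline for the cell view: entities are placed
#' in every compartment they are annotated to (multi-location entities are
#' duplicated; entities with unknown location are not displayed), the
#' minimal shared `g` is solved from compartment sizes, and icons are
#' grouped, binned, and placed.
#'
#' @param v The displayed `ValueVector`.
#' @param catalog An `AnnotationCatalog`.
#' @param layout A `CellLayout`.
#' @param scale A `ColorScale` (for bin assignment).
#' @param icon_size,padding Icon geometry (canvas units).
#' @param max_per_icon Optional user cap on entities per icon; it is an
#'   error for it to be below the solved minimal `g`.
#' @return List with `groups` (each `IconGroup` carries its `region`
#'   compartment name) and `plan` (the `PackingPlan`).
#' @export
build_cell_groups <- function(v, catalog, layout, scale, icon_size = 8,
                              padding = 2, max_per_icon = NULL) {
  comp <- layout$compartments
  members <- lapply(comp$name, function(cn) {
    keep <- vapply(v$entity_ids, function(e)
      cn %in% (catalog$entity_compartments[[e]] %||% character(0)), logical(1))
    which(keep)
  })
  names(members) <- comp$name
  counts <- lengths(members)
  caps <- vapply(seq_len(nrow(comp)), function(i)
    compartment_capacity(comp[i, ], icon_size, padding), integer(1))
  names(caps) <- comp$name
  plan <- solve_group_size(counts, caps, icon_size = icon_size)
  if (!is.null(max_per_icon) && max_per_icon < plan$g)
    stop2("max_per_icon = %d is below the minimal feasible group size %d",
          max_per_icon, plan$g)
  groups <- list()
  for (i in seq_len(nrow(comp))) {
    cn <- comp$name[i]
    idx <- members[[cn]]
    if (!length(idx)) next
    sub <- value_vector(v$entity_ids[idx], v$v[idx], v$label)
    grs <- group_entities(sub, plan$g)
    grs <- assign_bins(grs, scale)
    grs <- place_icons(grs, comp[i, ], icon_size, padding)
    grs <- lapply(grs, function(g) { g$region <- cn; g })
    groups <- c(groups, grs)
  }
  list(groups = groups, plan = plan)
}
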