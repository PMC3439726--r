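# Deterministic SVG emission for the three views, the legend, side-by-side
# combined views, and TSV annotation reports. Output is plain text and
# byte-identical across runs with identical inputs; every icon element
# carries machine-readable data- attributes for downstream inspection.

new_svg_document <- function(width, height, lines, scale = NULL, meta = "") {
  structure(list(width = width, height = height, lines = lines,
                 scale = scale, meta = meta),
            class = "SvgDocument")
}

#' @export
print.SvgDocument <- function(x, ...) {
  cat(sprintf("<SvgDocument> %g x %g, %d elements\n",
              x$width, x$height, length(x$lines)))
  invisible(x)
}

#' Serialize an SVG document to text
#' @param x An `SvgDocument`.
#' @param ... Unused.
#' @return A character vector of SVG lines.
#' @export
as.character.SvgDocument <- function(x, ...) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(x$width), fmt_num(x$height),
            fmt_num(x$width), fmt_num(x$height)),
    if (nzchar(x$meta)) sprintf("<!-- %s -->", xml_escape(x$meta)),
    x$lines,
    "</svg>")
}

#' Write an SVG document
#' @param doc An `SvgDocument`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) write_lines_utf8(as.character(doc), path)

scale_signature <- function(scale) {
  paste(scale$palette_id, fmt_val(scale$vmin), fmt_val(scale$vmax),
        scale$n_bins, scale$reversed, sep = "|")
}

svg_rect <- function(x, y, w, h, fill, extra = "") {
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          fmt_num(x), fmt_num(y), fmt_num(w), fmt_num(h), fill,
          if (nzchar(extra)) paste0(" ", extra) else "")
}

svg_text <- function(x, y, label, size = 12, fill = "#333333", extra = "") {
  sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="%s" fill="%s"%s>%s</text>',
          fmt_num(x), fmt_num(y), fmt_num(size), fill,
          if (nzchar(extra)) paste0(" ", extra) else "",
          xml_escape(label))
}

# Truncate a label to roughly the available pixel width (full name belongs
# in the surrounding <title> element).
truncate_label <- function(label, width, size = 12) {
  fits <- max(1L, floor(width / (size * 0.58)))
  ifelse(nchar(label) > fits,
         paste0(substr(label, 1L, max(1L, fits - 1L)), "…"), label)
}

icon_elements <- function(groups, scale, icon_size) {
  unlist(lapply(groups, function(gr) {
    fill <- palette_color(scale, gr$bin)
    attrs <- sprintf('data-entities="%s" data-value="%s" data-bin="%d"',
                     xml_escape(paste(gr$members, collapse = ";")),
                     fmt_val(gr$value), gr$bin)
    if (gr$shape == "disc") {
      r <- icon_size / 2
      sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#666666" stroke-width="0.5" %s/>',
              fmt_num(gr$x + r), fmt_num(gr$y + r), fmt_num(r), fill, attrs)
    } else {
      sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#666666" stroke-width="0.5" %s/>',
              fmt_num(gr$x), fmt_num(gr$y), fmt_num(icon_size),
              fmt_num(icon_size), fill, attrs)
    }
  }), use.names = FALSE)
}

legend_height <- function() 80

legend_elements <- function(scale, g, y0, width) {
  pal <- ylorrd_palette(scale$n_bins)
  if (scale$reversed) pal <- rev(pal)
  sw <- 24; sh <- 16
  x0 <- 20
  out <- c(sprintf('<g class="legend">'),
           svg_rect(0, y0, width, legend_height(), "#FFFFFF"),
           svg_text(x0, y0 + 16, "value", size = 11))
  for (i in seq_len(scale$n_bins))
    out <- c(out, svg_rect(x0 + (i - 1L) * sw, y0 + 22, sw, sh, pal[i],
                           extra = 'stroke="#999999" stroke-width="0.5"'))
  out <- c(out,
           svg_text(x0, y0 + 52, fmt_val(scale$vmin), size = 11),
           svg_text(x0 + scale$n_bins * sw - 10, y0 + 52, fmt_val(scale$vmax),
                    size = 11, extra = 'text-anchor="end"'))
  kx <- x0 + scale$n_bins * sw + 50
  out <- c(out,
           sprintf('<circle cx="%s" cy="%s" r="5" fill="#CCCCCC" stroke="#666666" stroke-width="0.5"/>',
                   fmt_num(kx), fmt_num(y0 + 30)),
           svg_text(kx + 12, y0 + 34, "1 entity", size = 11),
           svg_rect(kx - 5, y0 + 44, 10, 10, "#CCCCCC",
                    extra = 'stroke="#666666" stroke-width="0.5"'),
           svg_text(kx + 12, y0 + 53,
                    sprintf("up to %d entities per icon", g), size = 11),
           "</g>")
  out
}

#' Render the cellular map view
#'
#' Compartment regions with their fill colors and labels, entity icons
#' (discs for single entities, squares for groups) colored on the shared
#' scale, and an optional legend strip below the canvas.
#'
#' @param layout A `CellLayout`.
#' @param groups Icon groups from [build_cell_groups()].
#' @param scale The shared `ColorScale`.
#' @param plan The `PackingPlan` (for icon size and the legend's `g`).
#' @param legend Draw the legend strip (default `TRUE`).
#' @param title Document title comment.
#' @return An `SvgDocument`.
#' @export
render_cell_view <- function(layout, groups, scale, plan, legend = TRUE,
                             title = "cellular map") {
  W <- layout$canvas[1L]
  H <- layout$canvas[2L] + if (legend) legend_height() else 0
  lines <- c(svg_rect(0, 0, W, layout$canvas[2L], "#FFFFFF"))
  comp <- layout$compartments
  for (i in seq_len(nrow(comp))) {
    lines <- c(lines,
               "<g>",
               sprintf("<title>%s</title>", xml_escape(comp$name[i])),
               svg_rect(comp$x[i], comp$y[i], comp$width[i], comp$height[i],
                        comp$fill[i],
                        extra = 'stroke="#888888" stroke-width="1"'),
               svg_text(comp$x[i] + 4, comp$y[i] + 12,
                        truncate_label(comp$name[i], comp$width[i] - 8,
                                       size = 11), size = 11),
               "</g>")
  }
  lines <- c(lines, icon_elements(groups, scale, plan$icon_size))
  if (legend)
    lines <- c(lines, legend_elements(scale, plan$g, layout$canvas[2L], W))
  new_svg_document(W, H, lines, scale = scale,
                   meta = sprintf("%s | scale %s | g=%d",
                                  title, scale_signature(scale), plan$g))
}

#' Render a treemap view (pathway or GO)
#'
#' Nested rectangles drawn in layout order (parents before children), each
#' with a `<title>` carrying its full name, weight, and — for tested
#' pathways — the enrichment p-value (the static analog of mouse-over
#' text). Pathways highlighted by the enrichment test get a 2-unit red
#' border.
#'
#' @param laid List of `LaidOutNode` from [treemap_layout()].
#' @param groups Icon groups from [place_leaf_icons()].
#' @param scale The shared `ColorScale`.
#' @param plan The `PackingPlan`.
#' @param enrichment Optional `EnrichmentResult`; rows with
#'   `highlighted == TRUE` drive the red borders, matched by leaf name.
#' @param legend Draw the legend strip.
#' @param title Document title comment.
#' @return An `SvgDocument`.
#' @export
render_treemap_view <- function(laid, groups, scale, plan, enrichment = NULL,
                                legend = TRUE, title = "treemap") {
  root <- laid[[1L]]
  W <- root$x + root$w
  H <- root$y + root$h + if (legend) legend_height() else 0
  p_of <- character(0)
  hot <- character(0)
  if (!is.null(enrichment) && nrow(enrichment)) {
    p_of <- stats::setNames(formatC(enrichment$p_value, format = "g",
                                    digits = 4), enrichment$pathway)
    hot <- enrichment$pathway[enrichment$highlighted]
  }
  lines <- character(0)
  for (nd in laid) {
    fill <- if (!is.na(nd$fill)) nd$fill else
      c("#FFFFFF", "#EEEEEE", "#F7F7F7")[min(nd$depth + 1L, 3L)]
    ttl <- sprintf("%s (n=%s)", nd$name, fmt_val(nd$weight))
    if (nd$name %in% names(p_of))
      ttl <- sprintf("%s, p=%s", ttl, p_of[[nd$name]])
    lines <- c(lines,
               "<g>",
               sprintf("<title>%s</title>", xml_escape(ttl)),
               svg_rect(nd$x, nd$y, nd$w, nd$h, fill,
                        extra = 'stroke="#888888" stroke-width="0.75"'),
               if (nd$depth > 0L)
                 svg_text(nd$x + 3, nd$y + 11,
                          truncate_label(nd$name, nd$w - 6, size = 10),
                          size = 10),
               "</g>")
    if (nd$is_leaf && nd$name %in% hot)
      lines <- c(lines,
                 svg_rect(nd$x, nd$y, nd$w, nd$h, "none",
                          extra = 'stroke="#FF0000" stroke-width="2" class="highlight"'))
  }
  lines <- c(lines, icon_elements(groups, scale, plan$icon_size))
  if (legend)
    lines <- c(lines, legend_elements(scale, plan$g, root$y + root$h, W))
  new_svg_document(W, H, lines, scale = scale,
                   meta = sprintf("%s | scale %s | g=%d",
                                  title, scale_signature(scale), plan$g))
}

#' Combine two rendered views side by side
#'
#' Places two views next to each other with a single shared legend, so
#' cellular, pathway and/or GO properties can be compared simultaneously.
#' Each view gets half the combined width: callers render each view at
#' half-width geometry (as [run()] does for `view = "combined"`), which
#' re-solves chunking at the reduced area — with less screen space per
#' view, `g` may increase and fewer details are visible. Both views must
#' share one color scale.
#'
#' @param left,right `SvgDocument`s rendered with `legend = FALSE`.
#' @param g Entities-per-icon reported in the shared legend.
#' @return An `SvgDocument`.
#' @export
render_combined <- function(left, right, g = 1L) {
  if (is.null(left$scale) || is.null(right$scale) ||
      scale_signature(left$scale) != scale_signature(right$scale))
    stop2("cannot combine views rendered with different color scales")
  W <- left$width + right$width
  H <- max(left$height, right$height) + legend_height()
  lines <- c('<g class="left-view">', left$lines, "</g>",
             sprintf('<g class="right-view" transform="translate(%s)">',
                     fmt_num(left$width)),
             right$lines, "</g>",
             legend_elements(left$scale, g, H - legend_height(), W))
  new_svg_document(W, H, lines, scale = left$scale,
                   meta = sprintf("combined | scale %s | g=%d",
                                  scale_signature(left$scale), g))
}

#' Tabulate annotations for a set of entities
#'
#' Static stand-in for the interactive annotation panel: one row per unique
#' requested entity (duplicates collapsed) with its label, per-sample
#' values, compartments and pathways. Unknown ids get a warning flag
#' instead of an error.
#'
#' @param ids Character vector of entity ids (possibly with repeats).
#' @param catalog An `AnnotationCatalog`.
#' @param ds An `ExpressionDataset`.
#' @return A data frame with columns `id`, `label`, `values`,
#'   `compartments`, `pathways`, `flag`.
#' @export
describe_entities <- function(ids, catalog, ds) {
  ids <- unique(as.character(ids))
  labels <- catalog$entity_labels
  rows <- lapply(ids, function(e) {
    known <- e %in% ds$entity_ids
    vals <- if (known) {
      v <- ds$values[e, ]
      paste(sprintf("%s=%s", ds$sample_ids,
                    ifelse(is.na(v), "NA", fmt_val(v))), collapse = "; ")
    } else ""
    data.frame(
      id = e,
      label = if (e %in% names(labels)) labels[[e]] else e,
      values = vals,
      compartments = paste(catalog$entity_compartments[[e]] %||% character(0),
                           collapse = "; "),
      pathways = paste(catalog$entity_pathways[[e]] %||% character(0),
                       collapse = "; "),
      flag = if (known) "" else "unknown id",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a data frame as a TSV report
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  header <- paste(names(df), collapse = "\t")
  body <- apply(df, 1L, function(r) paste(as.character(r), collapse = "\t"))
  write_lines_utf8(c(header, if (nrow(df)) body), path)
}
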