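# Pipeline driver: ties the modules into the user-facing workflows
# (read -> probe-map -> filter -> extract/compare -> scale -> view build ->
# chunk -> enrich -> render -> report). The thin command-line wrapper in
# inst/scripts/cellviews.R parses flags into run_config() and calls run().

#' Build a validated run configuration
#'
#' @param view One of `"cellmap"`, `"pathways"`, `"go-bp"`, `"go-mf"`,
#'   `"combined"` (cell map + pathway tree side by side).
#' @param matrix_path,samples_path Expression inputs (see
#'   [read_expression()]).
#' @param loc_path,pw_path,pwcomp_path,universe_path Annotation inputs.
#' @param layout_path Optional cell-layout config (default built-in).
#' @param obo_path,gaf_path GO inputs (required for the GO views).
#' @param probe_map_path Optional probe-to-gene map applied first.
#' @param sample Sample id for single-sample display; or
#' @param compare Character vector `c(a, b)` plus `mode` for a two-sample
#'   comparison (exactly one of `sample`/`compare` must be given).
#' @param mode Comparison statistic (see [compare_samples()]).
#' @param min_value Min-value filter threshold (`NULL` to skip): entities
#'   with a value over it in at least one sample are kept.
#' @param keep_over,keep_under Displayed-value filters (see
#'   [filter_value_range()]).
#' @param color_range Optional `c(lo, hi)` user color range (default auto).
#' @param n_bins,reversed Color-scale parameters.
#' @param p_threshold Enrichment highlight threshold.
#' @param fdr Use Benjamini-Hochberg adjusted p-values for highlighting.
#' @param icon_size,padding,inner_pad,max_per_icon Geometry parameters.
#' @param expand_depth GO views: expand all populated terms down to this
#'   depth.
#' @param out Output SVG path.
#' @param report Optional TSV path for the enrichment report (pathways
#'   view).
#' @param log_path Optional path for the machine-parseable run log.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(view, matrix_path, samples_path = NULL,
                       loc_path = NULL, pw_path = NULL, pwcomp_path = NULL,
                       universe_path = NULL, layout_path = NULL,
                       obo_path = NULL, gaf_path = NULL,
                       probe_map_path = NULL,
                       sample = NULL, compare = NULL,
                       mode = "difference", min_value = NULL,
                       keep_over = NULL, keep_under = NULL,
                       color_range = NULL, n_bins = 9L, reversed = FALSE,
                       p_threshold = 0.05, fdr = FALSE,
                       icon_size = 8, padding = 2, inner_pad = 4,
                       max_per_icon = NULL, expand_depth = 2L,
                       out = "view.svg", report = NULL, log_path = NULL) {
  view <- match.arg(view, c("cellmap", "pathways", "go-bp", "go-mf",
                            "combined"))
  if (is.null(sample) == is.null(compare))
    stop2("specify exactly one of 'sample' or 'compare'")
  if (!is.null(compare) && length(compare) != 2L)
    stop2("'compare' must name exactly two samples")
  if (view %in% c("go-bp", "go-mf") && (is.null(obo_path) || is.null(gaf_path)))
    stop2("GO views need obo_path and gaf_path")
  if (view %in% c("pathways", "combined", "cellmap") &&
      (is.null(loc_path) || is.null(pw_path) || is.null(pwcomp_path) ||
       is.null(universe_path)))
    stop2("view '%s' needs loc_path, pw_path, pwcomp_path and universe_path",
          view)
  cfg <- as.list(environment())
  structure(cfg, class = "RunConfig")
}

#' Execute a configured pipeline run
#'
#' Runs the fixed pipeline order and writes the requested artifacts. The
#' log records entity counts at each stage, the solved entities-per-icon
#' factor, and exclusion tallies.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the written artifact paths, the log
#'   lines, the solved plan(s) and (for the pathways view) the enrichment
#'   table.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  log <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message(line)
  }

  ds <- read_expression(config$matrix_path, config$samples_path)
  note("stage=read entities=%d samples=%d", length(ds$entity_ids),
       length(ds$sample_ids))
  if (!is.null(config$probe_map_path)) {
    ds <- apply_probe_map(ds, config$probe_map_path)
    note("stage=probe_map entities=%d dropped=%d", length(ds$entity_ids),
         attr(ds, "n_dropped"))
  }
  if (!is.null(config$min_value)) {
    ds <- filter_min_value(ds, config$min_value)
    note("stage=min_value threshold=%s entities=%d",
         fmt_val(config$min_value), length(ds$entity_ids))
  }
  v <- if (!is.null(config$sample)) extract_sample(ds, config$sample)
       else compare_samples(ds, config$compare[1L], config$compare[2L],
                            config$mode)
  note("stage=values label='%s' entities=%d excluded=%d", v$label,
       length(v$v), v$n_excluded %||% 0L)
  if (!is.null(config$keep_over) || !is.null(config$keep_under)) {
    v <- filter_value_range(v, config$keep_over, config$keep_under)
    note("stage=value_filter entities=%d", length(v$v))
  }
  scale <- if (is.null(config$color_range))
    auto_scale(v, n_bins = config$n_bins, reversed = config$reversed)
  else
    color_scale(config$color_range[1L], config$color_range[2L],
                n_bins = config$n_bins, reversed = config$reversed)
  note("stage=scale vmin=%s vmax=%s bins=%d", fmt_val(scale$vmin),
       fmt_val(scale$vmax), scale$n_bins)

  layout <- read_cell_layout(config$layout_path)
  need_catalog <- config$view %in% c("cellmap", "pathways", "combined")
  catalog <- if (need_catalog)
    read_annotations(config$loc_path, config$pw_path, config$pwcomp_path,
                     config$universe_path)

  enrichment <- NULL
  plans <- list()

  # Automatic scaling for treemap leaves: proportional subdivision can
  # produce slivers too small for one icon at the requested size, which no
  # entities-per-icon factor can fix; halve the icon size (floor 2 units)
  # until every populated leaf holds at least one icon.
  place_with_autoscale <- function(laid, view_name) {
    s <- config$icon_size
    repeat {
      pl <- tryCatch(
        place_leaf_icons(laid, v, scale, icon_size = s,
                         padding = config$padding,
                         max_per_icon = config$max_per_icon),
        error = function(e) e)
      if (!inherits(pl, "error")) break
      if (s <= 2) stop2("view %s: %s", view_name, conditionMessage(pl))
      s <- max(2, s / 2)
      note("stage=autoscale view=%s icon_size=%g", view_name, s)
    }
    pl
  }

  make_cell <- function(scale_canvas = 1, legend = TRUE) {
    lay <- layout
    lay$compartments$x <- lay$compartments$x * scale_canvas
    lay$compartments$width <- lay$compartments$width * scale_canvas
    lay$canvas[1L] <- lay$canvas[1L] * scale_canvas
    cg <- build_cell_groups(v, catalog, lay, scale,
                            icon_size = config$icon_size,
                            padding = config$padding,
                            max_per_icon = config$max_per_icon)
    plans[["cellmap"]] <<- cg$plan
    note("stage=chunk view=cellmap g=%d icons=%d", cg$plan$g,
         length(cg$groups))
    render_cell_view(lay, cg$groups, scale, cg$plan, legend = legend)
  }
  make_pathways <- function(scale_canvas = 1, legend = TRUE) {
    root <- build_pathway_tree(catalog, v, layout)
    if (root$weight <= 0) stop2("no displayed entity has pathway annotation")
    displayed <- intersect(v$entity_ids, catalog$universe)
    enrichment <<- test_all_pathways(catalog, displayed,
                                     threshold = config$p_threshold,
                                     fdr = config$fdr)
    note("stage=enrich pathways=%d highlighted=%d n=%d", nrow(enrichment),
         sum(enrichment$highlighted), length(displayed))
    laid <- treemap_layout(root,
                           canvas = c(0, 0, layout$canvas[1L] * scale_canvas,
                                      layout$canvas[2L]),
                           inner_pad = config$inner_pad)
    pl <- place_with_autoscale(laid, "pathways")
    plans[["pathways"]] <<- pl$plan
    note("stage=chunk view=pathways g=%d icons=%d", pl$plan$g,
         length(pl$groups))
    render_treemap_view(laid, pl$groups, scale, pl$plan,
                        enrichment = enrichment, legend = legend,
                        title = "pathway tree")
  }
  make_go <- function(namespace) {
    go <- read_obo(config$obo_path)
    go <- read_annotations_gaf(config$gaf_path, go)
    state <- go_view_state(go, namespace)
    displayed <- v$entity_ids
    state <- expand_to_depth(state, go, displayed, config$expand_depth)
    root <- build_go_tree(go, state, displayed)
    if (root$weight <= 0)
      stop2("no displayed entity has %s annotation", namespace)
    laid <- treemap_layout(root, canvas = c(0, 0, layout$canvas[1L],
                                            layout$canvas[2L]),
                           inner_pad = config$inner_pad)
    pl <- place_with_autoscale(laid, paste0("go-", namespace))
    plans[[paste0("go-", namespace)]] <<- pl$plan
    note("stage=chunk view=go-%s g=%d icons=%d", namespace, pl$plan$g,
         length(pl$groups))
    render_treemap_view(laid, pl$groups, scale, pl$plan,
                        title = paste("GO", namespace))
  }

  doc <- switch(config$view,
    cellmap = make_cell(),
    pathways = make_pathways(),
    "go-bp" = make_go("biological_process"),
    "go-mf" = make_go("molecular_function"),
    combined = {
      left <- make_cell(scale_canvas = 0.5, legend = FALSE)
      right <- make_pathways(scale_canvas = 0.5, legend = FALSE)
      g <- max(vapply(plans, `[[`, 0L, "g"))
      render_combined(left, right, g = g)
    })

  write_svg(doc, config$out)
  note("stage=write out=%s", config$out)
  if (!is.null(config$report) && !is.null(enrichment)) {
    write_enrichment_report(enrichment, config$report)
    note("stage=write report=%s", config$report)
  }
  if (!is.null(config$log_path)) write_lines_utf8(log, config$log_path)
  invisible(list(out = config$out, report = config$report, log = log,
                 plans = plans, enrichment = enrichment, scale = scale,
                 document = doc))
}
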