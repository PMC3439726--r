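# Input readers and validated containers.
#
# All tabular inputs are tab-separated UTF-8 text; lines starting with '#'
# are comments; the first column is always the entity/pathway key.

#' Construct a validated expression dataset
#'
#' The central data container: a numeric entity-by-sample matrix of the
#' displayed quantity (expression levels, log ratios, fold changes,
#' p-values, ...). Missing cells are allowed and recorded as `NA`.
#'
#' @param values Numeric matrix, entities in rows, samples in columns.
#' @param entity_ids Character vector of unique entity (gene/locus) ids.
#' @param sample_ids Character vector of unique sample names.
#' @return An object of class `ExpressionDataset` with elements
#'   `entity_ids`, `sample_ids`, and `values` (a dimnamed matrix).
#' @export
expression_dataset <- function(values, entity_ids, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  entity_ids <- as.character(entity_ids)
  sample_ids <- as.character(sample_ids)
  if (length(entity_ids) < 1L) stop2("dataset must contain at least one entity")
  if (length(sample_ids) < 1L) stop2("dataset must contain at least one sample")
  if (anyDuplicated(entity_ids))
    stop2("duplicate entity id: '%s'", entity_ids[duplicated(entity_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop2("duplicate sample id: '%s'", sample_ids[duplicated(sample_ids)][1L])
  if (nrow(values) != length(entity_ids) || ncol(values) != length(sample_ids))
    stop2("matrix is %d x %d but there are %d entities and %d samples",
          nrow(values), ncol(values), length(entity_ids), length(sample_ids))
  dimnames(values) <- list(entity_ids, sample_ids)
  structure(list(entity_ids = entity_ids, sample_ids = sample_ids,
                 values = values),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("<ExpressionDataset> %d entities x %d samples (%d missing cells)\n",
              length(x$entity_ids), length(x$sample_ids), sum(is.na(x$values))))
  invisible(x)
}

#' Read an expression matrix (with optional separate sample list)
#'
#' Two dialects are supported. With `samples_path` supplied, the matrix file
#' is headerless (`entity<TAB>v1<TAB>v2...`) and sample names and order come
#' from the sample list (one name per line). With `samples_path = NULL`, the
#' first non-comment row of the matrix file is a header naming the samples
#' (the "combined file" convenience).
#'
#' @param matrix_path Path to the TSV value matrix.
#' @param samples_path Optional path to the sample list file.
#' @return An [expression_dataset()]. Blank or `NA` cells become missing.
#' @export
read_expression <- function(matrix_path, samples_path = NULL) {
  body <- read_body_lines(matrix_path)
  rows <- split_tsv(body$lines)
  if (length(rows) == 0L) stop2("'%s' contains no data rows", matrix_path)

  if (is.null(samples_path)) {
    header <- rows[[1L]]
    if (length(header) < 2L)
      stop2("'%s': header row must name at least one sample", matrix_path)
    sample_ids <- header[-1L]
    rows <- rows[-1L]
    lineno <- body$lineno[-1L]
  } else {
    sbody <- read_body_lines(samples_path)
    sample_ids <- trimws(sbody$lines)
    lineno <- body$lineno
  }
  n_s <- length(sample_ids)
  if (length(rows) == 0L) stop2("'%s' contains no value rows", matrix_path)

  ncols <- lengths(rows) - 1L
  bad <- which(ncols != n_s)
  if (length(bad))
    stop2("'%s' line %d: %d samples vs %d value columns",
          matrix_path, lineno[bad[1L]], n_s, ncols[bad[1L]])

  entity_ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(entity_ids))
    stop2("'%s': duplicate entity id '%s'",
          matrix_path, entity_ids[duplicated(entity_ids)][1L])

  cells <- t(vapply(rows, function(r) r[-1L], character(n_s)))
  if (n_s == 1L) cells <- matrix(vapply(rows, `[[`, "", 2L), ncol = 1L)
  cells_trim <- trimws(cells)
  is_missing <- cells_trim == "" | cells_trim == "NA"
  vals <- suppressWarnings(as.numeric(cells_trim))
  bad_cell <- which(is.na(vals) & !is_missing, arr.ind = TRUE)
  if (nrow(bad_cell))
    stop2("'%s' line %d, value column %d: non-numeric cell '%s'",
          matrix_path, lineno[bad_cell[1L, 1L]], bad_cell[1L, 2L],
          cells_trim[bad_cell[1L, , drop = FALSE]])
  vals[is_missing] <- NA_real_
  expression_dataset(matrix(vals, ncol = n_s), entity_ids, sample_ids)
}

#' Write an expression dataset (round-trip counterpart of [read_expression()])
#'
#' @param ds An `ExpressionDataset`.
#' @param matrix_path Output path for the headerless value matrix.
#' @param samples_path Output path for the one-name-per-line sample list.
#' @return The matrix path, invisibly.
#' @export
write_expression <- function(ds, matrix_path, samples_path) {
  cells <- apply(ds$values, c(1, 2), function(v)
    if (is.na(v)) "" else formatC(v, format = "g", digits = 17))
  lines <- paste(ds$entity_ids, apply(cells, 1L, paste, collapse = "\t"),
                 sep = "\t")
  if (ncol(ds$values) == 0L) lines <- ds$entity_ids
  write_lines_utf8(ds$sample_ids, samples_path)
  write_lines_utf8(lines, matrix_path)
}

read_two_col <- function(path, what) {
  body <- read_body_lines(path)
  rows <- split_tsv(body$lines)
  bad <- which(lengths(rows) < 2L)
  if (length(bad))
    stop2("'%s' line %d: expected 2 tab-separated columns (%s)",
          path, body$lineno[bad[1L]], what)
  data.frame(key = vapply(rows, `[[`, "", 1L),
             value = vapply(rows, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

collapse_map <- function(df) {
  sp <- split(df$value, df$key)
  lapply(sp, function(v) sort(unique(v)))
}

#' Construct a validated annotation catalog
#'
#' Holds the flat-file stand-ins for a curated annotation database:
#' entity-to-compartment and entity-to-pathway memberships, the
#' pathway-to-compartment placement, and the genome background ("universe")
#' that over-representation tests are computed against.
#'
#' @param entity_compartments Named list: entity id -> character vector of
#'   compartment names.
#' @param entity_pathways Named list: entity id -> character vector of
#'   pathway names.
#' @param pathway_compartments Named list: pathway -> character vector of
#'   compartment names. Every pathway referenced by `entity_pathways` must
#'   appear here.
#' @param universe Character vector of background entity ids; must contain
#'   every entity appearing in `entity_pathways`.
#' @param entity_labels Optional named character vector of display names.
#' @return An object of class `AnnotationCatalog`.
#' @export
annotation_catalog <- function(entity_compartments, entity_pathways,
                               pathway_compartments, universe,
                               entity_labels = NULL) {
  universe <- unique(as.character(universe))
  pw_used <- unique(unlist(entity_pathways, use.names = FALSE))
  orphan <- setdiff(pw_used, names(pathway_compartments))
  if (length(orphan))
    stop2("pathways with no compartment assignment: %s",
          paste(orphan, collapse = ", "))
  outside <- setdiff(names(entity_pathways), universe)
  if (length(outside))
    stop2("entities with pathway annotation missing from the universe: %s",
          paste(utils::head(outside, 5L), collapse = ", "))
  empty <- function(m) any(lengths(m) == 0L)
  if (empty(entity_compartments) || empty(entity_pathways) ||
      empty(pathway_compartments))
    stop2("annotation maps must not contain empty sets")
  structure(list(entity_compartments = entity_compartments,
                 entity_pathways = entity_pathways,
                 pathway_compartments = pathway_compartments,
                 universe = universe,
                 entity_labels = entity_labels %||% character(0)),
            class = "AnnotationCatalog")
}

#' @export
print.AnnotationCatalog <- function(x, ...) {
  cat(sprintf(paste0("<AnnotationCatalog> %d located entities, %d pathway-",
                     "annotated entities, %d pathways, universe %d\n"),
              length(x$entity_compartments), length(x$entity_pathways),
              length(x$pathway_compartments), length(x$universe)))
  invisible(x)
}

#' Read annotation tables into a catalog
#'
#' @param loc_path 2-column TSV `entity<TAB>compartment` (repeat rows for
#'   multiple locations).
#' @param pw_path 2-column TSV `entity<TAB>pathway`.
#' @param pwcomp_path 2-column TSV `pathway<TAB>compartment`.
#' @param universe_path One entity id per line (genome background).
#' @return An [annotation_catalog()]; multi-row keys collapse to sets.
#' @export
read_annotations <- function(loc_path, pw_path, pwcomp_path, universe_path) {
  loc <- collapse_map(read_two_col(loc_path, "entity, compartment"))
  pw <- collapse_map(read_two_col(pw_path, "entity, pathway"))
  pwc <- collapse_map(read_two_col(pwcomp_path, "pathway, compartment"))
  uni <- trimws(read_body_lines(universe_path)$lines)
  tryCatch(
    annotation_catalog(loc, pw, pwc, uni),
    error = function(e) stop2("invalid annotations (%s / %s / %s / %s): %s",
                              loc_path, pw_path, pwcomp_path, universe_path,
                              conditionMessage(e)))
}

write_map_tsv <- function(m, path) {
  keys <- names(m)
  lines <- unlist(lapply(keys, function(k) paste(k, m[[k]], sep = "\t")),
                  use.names = FALSE)
  write_lines_utf8(lines %||% character(0), path)
}

#' Write a catalog back to its four flat files
#' @param catalog An `AnnotationCatalog`.
#' @param loc_path,pw_path,pwcomp_path,universe_path Output paths.
#' @return `loc_path`, invisibly.
#' @export
write_annotations <- function(catalog, loc_path, pw_path, pwcomp_path,
                              universe_path) {
  write_map_tsv(catalog$entity_compartments, loc_path)
  write_map_tsv(catalog$entity_pathways, pw_path)
  write_map_tsv(catalog$pathway_compartments, pwcomp_path)
  write_lines_utf8(catalog$universe, universe_path)
}

#' Collapse microarray probes to genes
#'
#' Replaces probe-level entity ids with gene ids using a 2-column
#' `probe<TAB>gene` map. Probes mapping to the same gene are aggregated by
#' the per-sample arithmetic mean; unmapped probes are dropped and the drop
#' count is reported via a message and the `"n_dropped"` attribute.
#'
#' @param ds An `ExpressionDataset` keyed by probe ids.
#' @param map_path Path to the probe-to-gene TSV.
#' @return A gene-keyed `ExpressionDataset`.
#' @export
apply_probe_map <- function(ds, map_path) {
  map <- read_two_col(map_path, "probe, gene")
  if (nrow(map) == 0L) stop2("'%s': empty probe map", map_path)
  map <- map[!duplicated(map$key), , drop = FALSE]
  gene <- map$value[match(ds$entity_ids, map$key)]
  keep <- !is.na(gene)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop2("no probe in the dataset is present in '%s'", map_path)
  vals <- ds$values[keep, , drop = FALSE]
  gene <- gene[keep]
  genes <- sort(unique(gene))
  agg <- matrix(NA_real_, length(genes), ncol(vals),
                dimnames = list(genes, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    m <- tapply(vals[, j], gene, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    agg[names(m), j] <- m
  }
  if (n_dropped > 0L)
    message(sprintf("apply_probe_map: dropped %d unmapped probe(s)", n_dropped))
  out <- expression_dataset(agg, genes, ds$sample_ids)
  attr(out, "n_dropped") <- n_dropped
  out
}

# The ten fixed compartments of the plant-cell diagram.
cell_compartment_names <- function() {
  c("nucleus", "vacuole", "mitochondria/cristae", "golgi apparatus",
    "endoplasmic reticulum", "apoplast", "plastids/thylakoids",
    "chloroplast", "cytosol", "plasma membrane")
}

#' Construct a validated cell layout
#'
#' @param compartments Data frame with columns `name`, `x`, `y`, `width`,
#'   `height`, `fill` (hex color); regions in abstract canvas units.
#' @param canvas Numeric length-2 `(width, height)`.
#' @return An object of class `CellLayout`.
#' @export
cell_layout <- function(compartments, canvas) {
  canvas <- as.numeric(canvas)
  stopifnot(length(canvas) == 2L, all(canvas > 0))
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "width", "height", "fill")
  if (!all(need %in% names(compartments)))
    stop2("layout table needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(compartments$name))
    stop2("duplicate compartment name: '%s'",
          compartments$name[duplicated(compartments$name)][1L])
  bad <- compartments$width <= 0 | compartments$height <= 0
  if (any(bad))
    stop2("compartment '%s' has non-positive size", compartments$name[bad][1L])
  out_of <- compartments$x < 0 | compartments$y < 0 |
    compartments$x + compartments$width > canvas[1L] |
    compartments$y + compartments$height > canvas[2L]
  if (any(out_of))
    stop2("compartment '%s' lies outside the %g x %g canvas",
          compartments$name[out_of][1L], canvas[1L], canvas[2L])
  structure(list(compartments = compartments, canvas = canvas),
            class = "CellLayout")
}

#' Built-in plant-cell layout
#'
#' Ten compartments (nucleus, vacuole, mitochondria/cristae, golgi
#' apparatus, endoplasmic reticulum, apoplast, plastids/thylakoids,
#' chloroplast, cytosol, plasma membrane) arranged on a 1000 x 700 canvas.
#'
#' @return A `CellLayout`.
#' @export
default_cell_layout <- function() {
  comp <- data.frame(
    name = c("plasma membrane", "nucleus", "vacuole", "chloroplast",
             "plastids/thylakoids", "mitochondria/cristae", "golgi apparatus",
             "endoplasmic reticulum", "cytosol", "apoplast"),
    x = c(10, 20, 260, 500, 750, 20, 350, 680, 20, 10),
    y = c(10, 90, 90, 90, 90, 270, 270, 270, 450, 630),
    width = c(980, 220, 220, 230, 230, 310, 310, 300, 960, 980),
    height = c(60, 160, 160, 160, 160, 160, 160, 160, 160, 60),
    fill = c("#DEEBF7", "#C6DBEF", "#D9F0D3", "#A8DDB5", "#CCEBC5",
             "#FDD0A2", "#E7D4E8", "#FEE0D2", "#FFF7BC", "#F0F0F0"),
    stringsAsFactors = FALSE)
  cell_layout(comp, c(1000, 700))
}

#' Read a cell-layout geometry config
#'
#' Tab-separated key/value text: one `canvas<TAB>width<TAB>height` line and
#' one `compartment<TAB>name<TAB>x<TAB>y<TAB>width<TAB>height<TAB>fill` line
#' per region. With `path = NULL` the built-in plant-cell layout is returned.
#'
#' @param path Config path, or `NULL` for [default_cell_layout()].
#' @return A `CellLayout`.
#' @export
read_cell_layout <- function(path = NULL) {
  if (is.null(path)) return(default_cell_layout())
  body <- read_body_lines(path)
  rows <- split_tsv(body$lines)
  kinds <- vapply(rows, `[[`, "", 1L)
  ci <- which(kinds == "canvas")
  if (length(ci) != 1L || length(rows[[ci]]) != 3L)
    stop2("'%s': expected exactly one 'canvas<TAB>width<TAB>height' line", path)
  canvas <- as.numeric(rows[[ci]][2:3])
  ri <- which(kinds == "compartment")
  if (!length(ri)) stop2("'%s': no compartment lines", path)
  bad <- ri[lengths(rows[ri]) != 7L]
  if (length(bad))
    stop2("'%s' line %d: compartment line needs 7 fields",
          path, body$lineno[bad[1L]])
  comp <- do.call(rbind, lapply(rows[ri], function(r)
    data.frame(name = r[2L], x = as.numeric(r[3L]), y = as.numeric(r[4L]),
               width = as.numeric(r[5L]), height = as.numeric(r[6L]),
               fill = r[7L], stringsAsFactors = FALSE)))
  tryCatch(cell_layout(comp, canvas),
           error = function(e) stop2("'%s': %s", path, conditionMessage(e)))
}

#' Write a cell layout config (round-trip counterpart of [read_cell_layout()])
#' @param layout A `CellLayout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_layout <- function(layout, path) {
  num <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c(paste("canvas", num(layout$canvas[1L]), num(layout$canvas[2L]),
                   sep = "\t"),
             with(layout$compartments,
                  paste("compartment", name, num(x), num(y), num(width),
                        num(height), fill, sep = "\t")))
  write_lines_utf8(lines, path)
}
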