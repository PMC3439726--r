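# Seeded synthetic-fixture generator: self-consistent expression matrix,
# annotation tables, genome universe, GO ontology/annotations, probe map
# and cell layout, with controllable planted over-representation, so every
# module is testable offline.

#' Describe a synthetic fixture
#'
#' The generative model: each entity joins each pathway independently
#' (expected pathway size 30), a per-entity "high expression" flag is drawn
#' with baseline probability 0.2 — multiplied on the odds scale for members
#' of planted pathways. Each entity gets one base expression level (high
#' entities shifted up by 2 on the log scale, so a min-value filter at 50
#' separates them) and per-sample values are the base times lognormal
#' replicate noise (sdlog 0.25). With all multipliers at 1 the high flag is
#' independent of pathway membership, so enrichment p-values are
#' null-distributed.
#'
#' @param n_entities,n_samples,n_pathways,n_compartments,n_go_terms Sizes.
#'   Compartments are taken from the built-in plant-cell layout (max 10);
#'   GO terms are split evenly between biological_process and
#'   molecular_function.
#' @param frac_annotated Fraction of entities receiving location and GO
#'   annotation.
#' @param enriched_pathways List of `list(index =, multiplier =)` entries
#'   planting over-representation of high-value entities in the chosen
#'   pathways (multiplier >= 1 on the odds of being high-value).
#' @param value_distribution `list(law = "lognormal", meanlog =, sdlog =)`
#'   or `list(law = "uniform", lo =, hi =)`.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return An object of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_entities = 2000L, n_samples = 4L, n_pathways = 20L,
                         n_compartments = 10L, n_go_terms = 120L,
                         frac_annotated = 0.8, enriched_pathways = list(),
                         value_distribution = list(law = "lognormal",
                                                   meanlog = 3, sdlog = 1),
                         seed = 1L) {
  counts <- c(n_entities, n_samples, n_pathways, n_compartments, n_go_terms)
  if (any(counts < 1L)) stop2("all fixture counts must be positive")
  if (n_compartments > 10L)
    stop2("at most 10 compartments (the built-in cell layout)")
  if (frac_annotated < 0 || frac_annotated > 1)
    stop2("frac_annotated must lie in [0, 1]")
  for (ep in enriched_pathways) {
    if (is.null(ep$index) || is.null(ep$multiplier) || ep$multiplier < 1 ||
        ep$index < 1L || ep$index > n_pathways)
      stop2("enriched_pathways entries need index in 1..n_pathways and multiplier >= 1")
  }
  structure(list(n_entities = as.integer(n_entities),
                 n_samples = as.integer(n_samples),
                 n_pathways = as.integer(n_pathways),
                 n_compartments = as.integer(n_compartments),
                 n_go_terms = as.integer(n_go_terms),
                 frac_annotated = frac_annotated,
                 enriched_pathways = enriched_pathways,
                 value_distribution = value_distribution,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Generate fixture objects in memory
#'
#' @param spec A [fixture_spec()].
#' @return List with `dataset` (`ExpressionDataset`), `catalog`
#'   (`AnnotationCatalog`), `layout` (`CellLayout`), `go` (`GoGraph` with
#'   annotations), `probe_map` (2-column data frame), and `high` (the
#'   latent high-expression flags, for diagnostics).
#' @export
generate_fixture_data <- function(spec) {
  with_seed(spec$seed, {
    ents <- sprintf("g%05d", seq_len(spec$n_entities))
    samples <- sprintf("S%d", seq_len(spec$n_samples))
    pathways <- sprintf("pw%02d", seq_len(spec$n_pathways))
    layout <- default_cell_layout()
    comp_names <- layout$compartments$name[seq_len(spec$n_compartments)]
    layout$compartments <- layout$compartments[
      layout$compartments$name %in% comp_names, , drop = FALSE]

    # pathway membership: iid per (entity, pathway), expected size 30
    p0 <- min(0.5, 30 / spec$n_entities)
    mem <- matrix(stats::runif(spec$n_entities * spec$n_pathways) < p0,
                  spec$n_entities, spec$n_pathways,
                  dimnames = list(ents, pathways))

    # latent high-expression flag, odds boosted inside planted pathways
    q <- rep(0.2, spec$n_entities)
    for (ep in spec$enriched_pathways) {
      in_pw <- mem[, ep$index]
      odds <- (q[in_pw] / (1 - q[in_pw])) * ep$multiplier
      q[in_pw] <- odds / (1 + odds)
    }
    high <- stats::runif(spec$n_entities) < q

    # entity-level base expression plus smaller per-sample replicate noise
    # (entity variance dominates replicate variance, as in real data)
    vd <- spec$value_distribution
    base <- if (identical(vd$law, "uniform"))
      stats::runif(spec$n_entities, vd$lo, vd$hi)
    else
      stats::rlnorm(spec$n_entities, vd$meanlog + 2 * high, vd$sdlog)
    vals <- matrix(0, spec$n_entities, spec$n_samples,
                   dimnames = list(ents, samples))
    for (s in seq_len(spec$n_samples))
      vals[, s] <- base * stats::rlnorm(spec$n_entities, 0, 0.25)

    # locations: frac_annotated of entities get 1-2 compartments
    has_loc <- stats::runif(spec$n_entities) < spec$frac_annotated
    entity_compartments <- list()
    for (i in which(has_loc)) {
      n_loc <- sample.int(2L, 1L)
      entity_compartments[[ents[i]]] <-
        sort(sample(comp_names, min(n_loc, length(comp_names))))
    }
    entity_pathways <- apply(mem, 1L, function(row)
      pathways[row], simplify = FALSE)
    entity_pathways <- entity_pathways[lengths(entity_pathways) > 0L]
    pathway_compartments <- stats::setNames(lapply(pathways, function(p)
      sort(sample(comp_names, min(sample.int(2L, 1L), length(comp_names))))),
      pathways)
    catalog <- annotation_catalog(entity_compartments, entity_pathways,
                                  pathway_compartments, universe = ents)

    go <- generate_go_graph(spec, ents)

    n_probes <- min(100L, spec$n_entities * 2L)
    probe_map <- data.frame(
      probe = sprintf("p%04d_at", seq_len(n_probes)),
      gene = ents[((seq_len(n_probes) - 1L) %/% 2L) + 1L],
      stringsAsFactors = FALSE)

    list(dataset = expression_dataset(vals, ents, samples),
         catalog = catalog, layout = layout, go = go,
         probe_map = probe_map, high = high)
  })
}

# random rooted DAG per namespace (1-2 parents among earlier terms) plus
# annotations for frac_annotated of the entities
generate_go_graph <- function(spec, ents) {
  namespaces <- c("biological_process", "molecular_function")
  n_per <- pmax(1L, c(ceiling(spec$n_go_terms / 2),
                      floor(spec$n_go_terms / 2)))
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  offset <- 0L
  for (w in seq_along(namespaces)) {
    ns <- namespaces[w]
    tid <- sprintf("GO:%07d", offset + seq_len(n_per[w]))
    ids <- c(ids, tid)
    nms <- c(nms, sprintf("%s term %d", sub("_", " ", ns), seq_len(n_per[w])))
    nss <- c(nss, rep(ns, n_per[w]))
    for (i in seq_len(n_per[w])[-1]) {
      k <- min(sample.int(2L, 1L), i - 1L)
      parents[[tid[i]]] <- sort(tid[sample.int(i - 1L, k)])
    }
    offset <- offset + n_per[w]
  }
  ann <- list()
  annotated <- stats::runif(length(ents)) < spec$frac_annotated
  non_root <- ids[vapply(ids, function(t) length(parents[[t]]) > 0L,
                         logical(1))]
  pool <- if (length(non_root)) non_root else ids
  for (i in which(annotated)) {
    k <- sample.int(3L, 1L)
    ann[[ents[i]]] <- sort(unique(sample(pool, min(k, length(pool)))))
  }
  go_graph(data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE), parents, ann)
}

obo_lines <- function(go) {
  lines <- c("format-version: 1.2", "ontology: synthetic-go")
  nm <- stats::setNames(go$terms$name, go$terms$id)
  for (i in seq_len(nrow(go$terms))) {
    id <- go$terms$id[i]
    lines <- c(lines, "", "[Term]",
               paste0("id: ", id),
               paste0("name: ", go$terms$name[i]),
               paste0("namespace: ", go$terms$namespace[i]),
               if (length(go$parents[[id]]))
                 sprintf("is_a: %s ! %s", go$parents[[id]],
                         nm[go$parents[[id]]]))
  }
  lines
}

gaf_lines <- function(go) {
  lines <- c("!gaf-version: 2.1")
  for (e in names(go$annotations)) {
    for (t in go$annotations[[e]]) {
      ns <- go$terms$namespace[match(t, go$terms$id)]
      aspect <- c(biological_process = "P", molecular_function = "F",
                  cellular_component = "C")[[ns]]
      lines <- c(lines,
                 paste(c("SYN", e, e, "", t, "SYN:0000001", "IEA", "",
                         aspect, e, "", "protein", "taxon:0001", "20260101",
                         "SYN", "", ""), collapse = "\t"))
    }
  }
  lines
}

#' Generate fixture files on disk
#'
#' Writes every input file in the package's own dialects: headerless value
#' matrix + sample list, the three annotation TSVs, the universe list, the
#' cell-layout config, a probe map, an OBO 1.2 ontology and a GAF 2.1
#' annotation file. Identical seeds give byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Manifest data frame (`file`, `rows`), invisibly the fixture
#'   objects as the `"data"` attribute.
#' @export
generate_fixtures <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- generate_fixture_data(spec)
  p <- function(f) file.path(out_dir, f)
  write_expression(fx$dataset, p("matrix.tsv"), p("samples.txt"))
  write_annotations(fx$catalog, p("locations.tsv"), p("pathways.tsv"),
                    p("pathway_compartments.tsv"), p("universe.txt"))
  write_cell_layout(fx$layout, p("layout.tsv"))
  write_lines_utf8(paste(fx$probe_map$probe, fx$probe_map$gene, sep = "\t"),
                   p("probe_map.tsv"))
  write_lines_utf8(obo_lines(fx$go), p("go.obo"))
  write_lines_utf8(gaf_lines(fx$go), p("go_annotations.gaf"))
  files <- c("matrix.tsv", "samples.txt", "locations.tsv", "pathways.tsv",
             "pathway_compartments.tsv", "universe.txt", "layout.tsv",
             "probe_map.tsv", "go.obo", "go_annotations.gaf")
  manifest <- data.frame(
    file = files,
    rows = vapply(files, function(f)
      length(readLines(p(f), warn = FALSE)), integer(1)),
    stringsAsFactors = FALSE)
  attr(manifest, "data") <- fx
  manifest
}
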