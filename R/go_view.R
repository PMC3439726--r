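# Gene Ontology: OBO DAG parsing, GAF/TSV annotation reading, true-path
# propagation of annotations to ancestors, and the expand/collapse state
# that the treemap engine renders.

#' Construct a validated GO graph
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param parents Named list: term id -> character vector of `is_a` parents.
#' @param annotations Named list: entity id -> character vector of term ids.
#' @return An object of class `GoGraph` with a precomputed `children` map.
#' @export
go_graph <- function(terms, parents, annotations = list()) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id))
    stop2("duplicate term id '%s'", terms$id[duplicated(terms$id)][1L])
  known <- terms$id
  for (ch in names(parents)) {
    miss <- setdiff(parents[[ch]], known)
    if (length(miss))
      stop2("term '%s' has unknown parent '%s'", ch, miss[1L])
  }
  bad_ann <- setdiff(unlist(annotations, use.names = FALSE), known)
  if (length(bad_ann))
    stop2("annotation refers to unknown term '%s'", bad_ann[1L])
  # Kahn's algorithm: every term must be emitted or the edge set has a cycle.
  indeg <- stats::setNames(integer(length(known)), known)
  children <- stats::setNames(vector("list", length(known)), known)
  for (ch in names(parents)) for (pa in parents[[ch]]) {
    children[[pa]] <- c(children[[pa]], ch)
    indeg[[ch]] <- indeg[[ch]] + 1L
  }
  queue <- known[indeg[known] == 0L]
  seen <- 0L
  indeg2 <- indeg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg2[[ch]] <- indeg2[[ch]] - 1L
      if (indeg2[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(known)) {
    cyc <- names(indeg2)[indeg2 > 0L]
    stop2("is_a relation contains a cycle involving: %s",
          paste(utils::head(cyc, 5L), collapse = ", "))
  }
  structure(list(terms = terms, parents = parents, children = children,
                 annotations = annotations),
            class = "GoGraph")
}

#' @export
print.GoGraph <- function(x, ...) {
  cat(sprintf("<GoGraph> %d terms (%s), %d annotated entities\n",
              nrow(x$terms),
              paste(sprintf("%s: %d", names(table(x$terms$namespace)),
                            table(x$terms$namespace)), collapse = ", "),
              length(x$annotations)))
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a` edges
#' (trailing `! comments` stripped); obsolete terms are skipped; the `is_a`
#' relation is verified acyclic. Only `is_a` edges are read: `part_of` and
#' other relationships are ignored.
#'
#' @param path Path to the OBO file.
#' @return A `GoGraph` with empty annotations.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop2("file not found: '%s'", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  stanza_starts <- c(grep("^\\[", raw), length(raw) + 1L)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  for (si in seq_len(length(stanza_starts) - 1L)) {
    from <- stanza_starts[si]
    if (raw[from] != "[Term]") next
    block <- raw[(from + 1L):(stanza_starts[si + 1L] - 1L)]
    field <- function(key) {
      hit <- grep(paste0("^", key, ": "), block, value = TRUE)
      sub(paste0("^", key, ": "), "", hit)
    }
    if (any(grepl("^is_obsolete: true", block))) next
    first_or <- function(x, default) if (length(x)) x[[1L]] else default
    id <- first_or(field("id"), NA_character_)
    if (is.na(id)) next
    ids <- c(ids, id)
    nms <- c(nms, first_or(field("name"), id))
    nss <- c(nss, first_or(field("namespace"), NA_character_))
    isa <- field("is_a")
    if (length(isa))
      parents[[id]] <- trimws(sub("\\s*!.*$", "", isa))
  }
  if (!length(ids)) stop2("'%s': no [Term] stanzas found", path)
  # drop dangling is_a edges pointing at obsolete/absent terms
  parents <- lapply(parents, function(p) intersect(p, ids))
  parents <- parents[lengths(parents) > 0L]
  g <- go_graph(data.frame(id = ids, name = nms, namespace = nss,
                           stringsAsFactors = FALSE), parents)
  for (ns in unique(stats::na.omit(g$terms$namespace))) {
    if (length(namespace_roots(g, ns)) == 0L)
      stop2("'%s': namespace '%s' has no root term", path, ns)
  }
  g
}

namespace_roots <- function(graph, namespace) {
  ids <- graph$terms$id[graph$terms$namespace == namespace]
  ids[!vapply(ids, function(t) length(graph$parents[[t]]) > 0L, logical(1))]
}

#' Root term of a namespace
#' @param graph A `GoGraph`.
#' @param namespace `"biological_process"` or `"molecular_function"` (the
#'   cellular-component namespace is parsed but not offered as a view).
#' @return The root term id.
#' @export
go_root <- function(graph, namespace) {
  roots <- namespace_roots(graph, namespace)
  if (length(roots) == 0L) stop2("namespace '%s' has no root term", namespace)
  if (length(roots) > 1L)
    message(sprintf("namespace '%s' has %d parentless terms; using '%s'",
                    namespace, length(roots), sort(roots)[1L]))
  sort(roots)[1L]
}

#' Read GO annotations (GAF 2.x or 2-column TSV)
#'
#' GAF rows use column 2 (DB object id) and column 5 (GO id); rows whose
#' qualifier (column 4) contains `NOT` are skipped per GAF semantics. A
#' 2-column `entity<TAB>term` TSV is accepted as a fallback. Annotations to
#' terms absent from the graph are skipped with a messaged count
#' (also in the `"n_unknown_terms"` attribute).
#'
#' @param path Annotation file path (`!`-prefixed comment lines ignored).
#' @param graph A `GoGraph` (terms/edges already read).
#' @return The graph with `annotations` filled (merged with any existing).
#' @export
read_annotations_gaf <- function(path, graph) {
  if (!file.exists(path)) stop2("file not found: '%s'", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^!", raw) & nzchar(trimws(raw))
  rows <- split_tsv(raw[keep])
  lineno <- which(keep)
  if (!length(rows)) stop2("'%s': no annotation rows", path)
  nc <- lengths(rows)
  ok_gaf <- nc >= 15L & nc <= 17L
  ok_tsv <- nc == 2L
  bad <- which(!(ok_gaf | ok_tsv))
  if (length(bad))
    stop2("'%s' line %d: %d columns (expected 2, or 15-17 for GAF)",
          path, lineno[bad[1L]], nc[bad[1L]])
  ent <- character(0); term <- character(0)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) == 2L) {
      ent <- c(ent, r[1L]); term <- c(term, r[2L])
    } else {
      if (grepl("\\bNOT\\b", r[4L])) next
      ent <- c(ent, r[2L]); term <- c(term, r[5L])
    }
  }
  known <- term %in% graph$terms$id
  n_unknown <- sum(!known)
  if (n_unknown > 0L)
    message(sprintf("read_annotations_gaf: skipped %d annotation(s) to unknown terms",
                    n_unknown))
  ann <- graph$annotations
  for (i in which(known))
    ann[[ent[i]]] <- c(ann[[ent[i]]], term[i])
  graph$annotations <- lapply(ann, function(t) sort(unique(t)))
  attr(graph, "n_unknown_terms") <- n_unknown
  graph
}

# term and all descendants (ids), via the precomputed children map
term_descendants <- function(graph, term) {
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, graph$children[[t]])
  }
  seen
}

#' Displayed entities at a GO term (true-path rule)
#'
#' An entity annotated to a term is implicitly annotated to every ancestor,
#' so the entities "at" a term are those annotated to the term or to any of
#' its descendants; each entity counts once per term.
#'
#' @param graph A `GoGraph` with annotations.
#' @param term Term id.
#' @param displayed Character vector of displayed entity ids.
#' @return Sorted character vector of entity ids.
#' @export
entities_at_term <- function(graph, term, displayed) {
  if (!term %in% graph$terms$id) stop2("unknown term '%s'", term)
  closure <- term_descendants(graph, term)
  hits <- vapply(displayed, function(e)
    any(graph$annotations[[e]] %in% closure), logical(1))
  sort(displayed[hits])
}

#' Create a fresh GO view state
#'
#' The view starts fully collapsed: all entities in one big rectangle for
#' the namespace root. Terms are then opened with [go_expand()] /
#' [expand_to_depth()] and closed with [go_collapse()].
#'
#' @param graph A `GoGraph`.
#' @param namespace Ontology namespace of the view.
#' @return An object of class `GoViewState` (`namespace`, `root`,
#'   `expanded`).
#' @export
go_view_state <- function(graph, namespace) {
  structure(list(namespace = namespace, root = go_root(graph, namespace),
                 expanded = character(0)),
            class = "GoViewState")
}

#' Visible terms of a view state
#'
#' The expansion frontier: the root, plus — inside every expanded term —
#' its children, recursively.
#'
#' @param state A `GoViewState`.
#' @param graph A `GoGraph`.
#' @return Character vector of visible term ids.
#' @export
visible_terms <- function(state, graph) {
  out <- character(0)
  walk <- function(t) {
    out <<- c(out, t)
    if (t %in% state$expanded)
      for (ch in sort(unique(graph$children[[t]]))) walk(ch)
  }
  walk(state$root)
  unique(out)
}

#' Expand a visible term (open its sub-rectangles)
#'
#' @param state A `GoViewState`.
#' @param term A currently visible term id. Expanding a childless term is a
#'   no-op with a notice.
#' @param graph A `GoGraph`.
#' @return The updated state.
#' @export
go_expand <- function(state, term, graph) {
  if (!term %in% visible_terms(state, graph))
    stop2("term '%s' is not currently visible", term)
  if (!length(graph$children[[term]])) {
    message(sprintf("term '%s' has no children; nothing to expand", term))
    return(state)
  }
  state$expanded <- sort(unique(c(state$expanded, term)))
  state
}

#' Collapse an expanded term (delete its sub-rectangles)
#'
#' Also collapses every expanded descendant, so the state invariant — each
#' expanded term is reachable from the root through expanded ancestors —
#' is preserved.
#'
#' @param state A `GoViewState`.
#' @param term A currently expanded term id.
#' @param graph A `GoGraph`.
#' @return The updated state.
#' @export
go_collapse <- function(state, term, graph) {
  if (!term %in% state$expanded) stop2("term '%s' is not expanded", term)
  desc <- term_descendants(graph, term)
  state$expanded <- setdiff(state$expanded, desc)
  state
}

#' Expand all populated terms down to a depth
#'
#' Non-interactive stand-in for repeatedly pressing the "low" button: every
#' visible term with at least one displayed entity and depth (shortest path
#' from the root) `< depth` is expanded, breadth-first.
#'
#' @param state A `GoViewState`.
#' @param graph A `GoGraph`.
#' @param displayed Displayed entity ids.
#' @param depth Maximum depth to open (0 leaves the root closed).
#' @return The updated state.
#' @export
expand_to_depth <- function(state, graph, displayed, depth) {
  if (depth < 1L) return(state)
  level <- state$root
  d <- 0L
  seen <- character(0)
  while (length(level) && d < depth) {
    nxt <- character(0)
    for (t in level) {
      if (t %in% seen) next
      seen <- c(seen, t)
      if (!length(graph$children[[t]])) next
      if (!length(entities_at_term(graph, t, displayed))) next
      state$expanded <- sort(unique(c(state$expanded, t)))
      nxt <- c(nxt, graph$children[[t]])
    }
    level <- unique(nxt)
    d <- d + 1L
  }
  state
}

# depth-dependent rectangle fills, distinct from the YlOrRd icon colors
go_depth_fills <- function() {
  c("#F7FBFF", "#DEEBF7", "#C6DBEF", "#9ECAE1", "#6BAED6", "#4292C6")
}

#' Build the treemap tree for a GO view
#'
#' Mirrors the expansion frontier. An expanded term's rectangle holds one
#' child rectangle per child term with at least one displayed entity, plus a
#' residual leaf (`"<name> (other)"`) for entities at the term not covered
#' by any shown child, so entity conservation holds inside every expanded
#' rectangle. An entity under several children appears under each. Node
#' weights are entity counts via [entities_at_term()]; rectangle fills
#' depend on depth and are distinct from the icon palette.
#'
#' @param graph A `GoGraph` with annotations.
#' @param state A `GoViewState`.
#' @param displayed Displayed entity ids.
#' @return The root `TreeNode` (weight 0 if no displayed entity is
#'   annotated in the namespace).
#' @export
build_go_tree <- function(graph, state, displayed) {
  nm <- stats::setNames(graph$terms$name, graph$terms$id)
  fills <- go_depth_fills()
  build <- function(term, depth) {
    ents <- entities_at_term(graph, term, displayed)
    fill <- fills[[min(depth + 1L, length(fills))]]
    if (!term %in% state$expanded || !length(ents))
      return(tree_node(nm[[term]], weight = length(ents), fill = fill,
                       entities = ents))
    kids <- list()
    covered <- character(0)
    for (ch in sort(unique(graph$children[[term]]))) {
      ch_ents <- entities_at_term(graph, ch, displayed)
      if (!length(ch_ents)) next
      kids <- c(kids, list(build(ch, depth + 1L)))
      covered <- union(covered, ch_ents)
    }
    residual <- setdiff(ents, covered)
    if (length(residual))
      kids <- c(kids, list(tree_node(paste0(nm[[term]], " (other)"),
                                     weight = length(residual),
                                     fill = fills[[min(depth + 2L, length(fills))]],
                                     entities = sort(residual))))
    if (!length(kids))
      return(tree_node(nm[[term]], weight = length(ents), fill = fill,
                       entities = ents))
    tree_node(nm[[term]], children = kids, fill = fill)
  }
  prune_tree(build(state$root, 0L))
}
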