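#' Construct and validate an ontology graph
#'
#' An `ontology_graph` holds one ontology (or one hierarchy of an ontology) as
#' three tables: concepts (`id`, `label`), is-a edges (`child`, `parent`,
#' pointing upward from the child to its parent), and lateral relationship
#' assertions (`source`, `rel_type`, `target`). Lateral targets are opaque
#' identifiers: they may lie in a different hierarchy and are never validated
#' against the loaded concept set — only the *types* of a concept's lateral
#' relationships matter for taxonomy derivation.
#'
#' Validation enforces: unique non-empty concept ids; is-a edges that resolve
#' to loaded concepts with `child != parent`; acyclicity of the is-a graph
#' (multiple parents are allowed); at least one root (a concept with no
#' parent); and lateral sources that resolve to loaded concepts.
#'
#' @param concepts data frame with columns `id`, `label`.
#' @param isa data frame with columns `child`, `parent` (concept ids).
#' @param lateral data frame with columns `source`, `rel_type`, `target`.
#' @return An object of class `ontology_graph`: a list with the validated
#'   tables plus precomputed `roots`, per-concept `parents`/`children`
#'   adjacency lists and a topological order (`topo`, parents first).
#' @examples
#' g <- ontology_graph(
#'   concepts = data.frame(id = c("A", "B"), label = c("A", "B")),
#'   isa = data.frame(child = "B", parent = "A"),
#'   lateral = data.frame(source = "A", rel_type = "Finding site", target = "X")
#' )
#' g$roots
#' @seealso [load_ontology()] to read the TSV representation from disk.
#' @export
ontology_graph <- function(concepts, isa = NULL, lateral = NULL) {
  concepts <- .as_table(concepts, c("id", "label"), "concepts")
  if (is.null(isa)) isa <- .df(child = character(0), parent = character(0))
  if (is.null(lateral))
    lateral <- .df(source = character(0), rel_type = character(0), target = character(0))
  isa <- .as_table(isa, c("child", "parent"), "isa")
  lateral <- .as_table(lateral, c("source", "rel_type", "target"), "lateral")

  if (nrow(concepts) == 0L) .stopf("an ontology graph needs at least one concept")
  if (any(is.na(concepts$id)) || any(concepts$id == ""))
    .stopf("concept ids must be non-empty")
  dup <- unique(concepts$id[duplicated(concepts$id)])
  if (length(dup))
    .stopf("duplicate concept id(s): %s", paste(dup, collapse = ", "))

  ids <- concepts$id
  bad <- setdiff(c(isa$child, isa$parent), ids)
  if (length(bad))
    .stopf("is-a edge references unknown concept(s): %s", paste(bad, collapse = ", "))
  if (any(isa$child == isa$parent))
    .stopf("self is-a edge(s) on: %s",
           paste(unique(isa$child[isa$child == isa$parent]), collapse = ", "))
  if (nrow(isa) > 0L && anyDuplicated(paste(isa$child, isa$parent, sep = "\r")))
    isa <- unique(isa)
  bad <- setdiff(lateral$source, ids)
  if (length(bad))
    .stopf("lateral assertion from unknown concept(s): %s", paste(bad, collapse = ", "))
  if (any(is.na(lateral$rel_type)) || any(lateral$rel_type == ""))
    .stopf("lateral relationship types must be non-empty")

  # acyclicity via igraph; report one offending cycle if present
  ig <- igraph::graph_from_data_frame(
    .df(from = isa$child, to = isa$parent), directed = TRUE,
    vertices = .df(name = ids))
  if (!igraph::is_dag(ig)) {
    comp <- igraph::components(ig, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1L)[1L]]
    .stopf("is-a edges contain a cycle through: %s", paste(sort(cyc), collapse = " -> "))
  }

  parents <- .adjacency(ids, isa$child, isa$parent)
  children <- .adjacency(ids, isa$parent, isa$child)
  roots <- ids[vapply(parents[ids], length, 1L) == 0L]
  if (length(roots) == 0L) .stopf("no root concept found")
  topo <- names(igraph::topo_sort(ig, mode = "in"))  # parents before children

  structure(
    list(concepts = concepts, isa = isa, lateral = lateral,
         roots = roots, parents = parents, children = children, topo = topo),
    class = "ontology_graph")
}

.as_table <- function(x, cols, what) {
  if (!is.data.frame(x)) .stopf("`%s` must be a data frame", what)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols))
    .stopf("`%s` is missing column(s): %s", what, paste(missing_cols, collapse = ", "))
  x <- x[, cols, drop = FALSE]
  x[] <- lapply(x, as.character)
  rownames(x) <- NULL
  x
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d concepts, %d is-a edges, %d lateral assertions (%d types), %d root(s)\n",
              nrow(x$concepts), nrow(x$isa), nrow(x$lateral),
              length(unique(x$lateral$rel_type)), length(x$roots)))
  invisible(x)
}

#' Load an ontology from TSV tables
#'
#' Reads the three-table TSV representation (UTF-8, header row,
#' tab-separated): `concepts.tsv` with columns `id`, `label`; `isa.tsv` with
#' `child_id`, `parent_id`; `lateral.tsv` with `source_id`, `rel_type`,
#' `target_id`; then validates via [ontology_graph()].
#'
#' @param concepts_path,isa_path,lateral_path paths to the three TSV files;
#'   `isa_path`/`lateral_path` may be `NULL` for an edgeless/lateral-free
#'   graph.
#' @return An `ontology_graph`.
#' @export
load_ontology <- function(concepts_path, isa_path = NULL, lateral_path = NULL) {
  rd <- function(p) read.delim(p, sep = "\t", header = TRUE,
                               colClasses = "character", quote = "",
                               fileEncoding = "UTF-8")
  concepts <- rd(concepts_path)
  isa <- if (is.null(isa_path)) NULL else {
    x <- rd(isa_path); names(x)[match(c("child_id", "parent_id"), names(x))] <- c("child", "parent"); x
  }
  lateral <- if (is.null(lateral_path)) NULL else {
    x <- rd(lateral_path)
    names(x)[match(c("source_id", "target_id"), names(x))] <- c("source", "target")
    x
  }
  ontology_graph(concepts, isa, lateral)
}

#' Write an ontology to TSV tables
#'
#' Inverse of [load_ontology()]: writes `concepts.tsv`, `isa.tsv` and
#' `lateral.tsv` into `dir`. Loading the written files yields a graph with
#' identical tables (round-trip).
#'
#' @param g an `ontology_graph`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_ontology <- function(g, dir) {
  stopifnot(inherits(g, "ontology_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                       row.names = FALSE, fileEncoding = "UTF-8")
  paths <- file.path(dir, c("concepts.tsv", "isa.tsv", "lateral.tsv"))
  wr(g$concepts, paths[1L])
  wr(stats::setNames(g$isa, c("child_id", "parent_id")), paths[2L])
  wr(stats::setNames(g$lateral, c("source_id", "rel_type", "target_id")), paths[3L])
  invisible(paths)
}

#' Read an OBO flat file into an ontology graph
#'
#' Minimal reader for the OBO 1.2/1.4 flat-file format mapping `[Term]`
#' stanzas onto the three-table model: `id` -> concept id, `name` -> label,
#' `is_a` -> is-a edge, `relationship: <type> <target>` -> lateral assertion.
#' Obsolete terms are dropped. Everything else (synonyms, xrefs, header
#' directives) is ignored.
#'
#' @param path path to a `.obo` file.
#' @return An `ontology_graph`.
#' @export
read_obo_graph <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("!.*$", "", lines)           # strip trailing comments
  lines <- trimws(lines)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) .stopf("no [Term] stanza found in %s", path)
  ends <- vapply(term_starts, function(s) {
    nxt <- stanza_starts[stanza_starts > s]
    if (length(nxt)) nxt[1L] - 1L else length(lines)
  }, 1L)
  concepts <- list(); isa <- list(); lateral <- list()
  for (k in seq_along(term_starts)) {
    block <- lines[term_starts[k]:ends[k]]
    field <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
                               grep(paste0("^", tag, ":"), block, value = TRUE))
    if (length(field("is_obsolete")) && any(field("is_obsolete") == "true")) next
    id <- field("id")[1L]
    if (is.na(id) || !length(id)) next
    nm <- field("name")
    concepts[[length(concepts) + 1L]] <-
      .df(id = id, label = if (length(nm)) nm[1L] else id)
    for (p in field("is_a"))
      isa[[length(isa) + 1L]] <- .df(child = id, parent = trimws(p))
    for (r in field("relationship")) {
      parts <- strsplit(trimws(r), "\\s+")[[1L]]
      if (length(parts) >= 2L)
        lateral[[length(lateral) + 1L]] <-
          .df(source = id, rel_type = parts[1L], target = parts[2L])
    }
  }
  ontology_graph(do.call(rbind, concepts),
                 if (length(isa)) do.call(rbind, isa) else NULL,
                 if (length(lateral)) do.call(rbind, lateral) else NULL)
}

#' Effective lateral relationship-type sets
#'
#' For each concept, the set of lateral relationship types that defines its
#' area membership. With `mode = "asserted"` this is simply the set of
#' distinct `rel_type` values asserted on the concept — appropriate for
#' inferred/materialized releases where inheritance has already been expanded
#' by a reasoner (the default, matching how SNOMED CT and NCIt inferred
#' releases are analyzed). With `mode = "inherited"` each concept's set is
#' the union of asserted sets over itself and all of its ancestors, since
#' lateral relationships are inherited from parent to child.
#'
#' @param g an `ontology_graph`.
#' @param mode `"asserted"` (default) or `"inherited"`.
#' @return A named list mapping every concept id to a sorted character vector
#'   of relationship-type names (possibly empty — the Ø case).
#' @examples
#' g <- build_fig1_fixture()
#' effective_rel_types(g)[["MicroRNA Gene"]]
#' @export
effective_rel_types <- function(g, mode = c("asserted", "inherited")) {
  stopifnot(inherits(g, "ontology_graph"))
  mode <- match.arg(mode)
  ids <- g$concepts$id
  asserted <- lapply(
    split(g$lateral$rel_type, factor(g$lateral$source, levels = ids)),
    function(x) sort(unique(as.character(x))))
  names(asserted) <- ids
  if (mode == "asserted") return(asserted[ids])
  eff <- asserted
  for (id in g$topo) {  # parents precede children
    ps <- g$parents[[id]]
    if (length(ps))
      eff[[id]] <- sort(unique(c(eff[[id]], unlist(eff[ps], use.names = FALSE))))
  }
  eff[ids]
}

#' Descendants of a concept
#'
#' Transitive closure below a concept along is-a edges, excluding the concept
#' itself.
#'
#' @param g an `ontology_graph`.
#' @param id a concept id present in `g`.
#' @return Sorted character vector of descendant concept ids.
#' @export
descendants <- function(g, id) {
  stopifnot(inherits(g, "ontology_graph"))
  if (!id %in% g$concepts$id) .stopf("unknown concept id: %s", id)
  seen <- character(0)
  queue <- g$children[[id]]
  while (length(queue)) {
    nxt <- queue[[1L]]; queue <- queue[-1L]
    if (nxt %in% seen) next
    seen <- c(seen, nxt)
    queue <- c(queue, g$children[[nxt]])
  }
  sort(seen)
}

# ancestors (excluding id), used by inherited-mode oracles and frame checks
.ancestors <- function(g, id) {
  seen <- character(0)
  queue <- g$parents[[id]]
  while (length(queue)) {
    nxt <- queue[[1L]]; queue <- queue[-1L]
    if (nxt %in% seen) next
    seen <- c(seen, nxt)
    queue <- c(queue, g$parents[[nxt]])
  }
  sort(seen)
}

#' Complexity ratio of an ontology
#'
#' The complexity of an ontology is the ratio of the number of relationships
#' connecting its concepts (is-a edges plus lateral assertions) to the number
#' of concepts. For example, 569,810 relationships over 138,291 concepts give
#' a complexity of about 4.12.
#'
#' @param g an `ontology_graph`, or `NULL` when explicit counts are given.
#' @param n_relationships,n_concepts explicit counts, used when `g` is `NULL`.
#' @return A single nonnegative number.
#' @examples
#' complexity_ratio(n_relationships = 569810, n_concepts = 138291)
#' @export
complexity_ratio <- function(g = NULL, n_relationships = NULL, n_concepts = NULL) {
  if (!is.null(g)) {
    stopifnot(inherits(g, "ontology_graph"))
    n_relationships <- nrow(g$isa) + nrow(g$lateral)
    n_concepts <- nrow(g$concepts)
  }
  n_relationships <- .check_count(n_relationships, "n_relationships")
  n_concepts <- .check_count(n_concepts, "n_concepts", min = 1L)
  n_relationships / n_concepts
}

#' Extract the sub-hierarchy rooted at a concept
#'
#' Per-hierarchy analysis of a multi-rooted graph: restricts the graph to a
#' root concept and its descendants. Lateral assertions whose sources fall in
#' the sub-hierarchy are retained even when their targets lie outside it
#' (only the relationship-type set matters for derivation).
#'
#' @param g an `ontology_graph`.
#' @param root a concept id; the extracted hierarchy is `root` plus its
#'   descendants.
#' @return An `ontology_graph`.
#' @export
extract_hierarchy <- function(g, root) {
  keep <- c(root, descendants(g, root))
  ontology_graph(
    g$concepts[g$concepts$id %in% keep, , drop = FALSE],
    g$isa[g$isa$child %in% keep & g$isa$parent %in% keep, , drop = FALSE],
    g$lateral[g$lateral$source %in% keep, , drop = FALSE])
}
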