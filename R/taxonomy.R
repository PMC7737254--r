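# Area / partial-area taxonomy derivation — the summarization networks.

# Shared core: derive both taxonomies from a precomputed mapping
# concept id -> effective relationship-type set.
.derive_taxonomies <- function(g, typesets) {
  ids <- g$concepts$id
  keys <- vapply(typesets[ids], .set_key, "")
  names(keys) <- ids

  # ---- areas: bucket by exact type-set key -------------------------------
  area_members <- split(ids, keys)
  area_ids <- names(area_members)

  # a member is an area root iff every parent lies outside the area
  area_roots <- lapply(area_ids, function(a) {
    ms <- area_members[[a]]
    is_root <- vapply(ms, function(m) {
      ps <- g$parents[[m]]
      length(ps) == 0L || !any(keys[ps] == a)
    }, TRUE)
    sort(ms[is_root])
  })
  names(area_roots) <- area_ids

  # area child-of links: root of A has a parent in B  =>  A child-of B
  alinks <- list()
  for (a in area_ids) {
    pk <- unique(keys[unlist(g$parents[area_roots[[a]]], use.names = FALSE)])
    pk <- setdiff(pk, a)
    if (length(pk)) alinks[[a]] <- .df(child = a, parent = pk)
  }
  alinks <- if (length(alinks)) unique(do.call(rbind, alinks))
  else .df(child = character(0), parent = character(0))

  areas <- .df(area_id = area_ids,
               label = .key_to_label(area_ids),
               size = vapply(area_members, length, 1L),
               n_roots = vapply(area_roots, length, 1L))
  ord <- order(-areas$size, areas$label)
  areas <- areas[ord, , drop = FALSE]
  rownames(areas) <- NULL

  alinks <- alinks[order(alinks$child, alinks$parent), , drop = FALSE]
  rownames(alinks) <- NULL
  at <- structure(
    list(areas = areas,
         members = lapply(area_members, sort)[areas$area_id],
         roots = area_roots[areas$area_id],
         concept_area = keys,
         links = alinks),
    class = "area_taxonomy")

  # ---- partial-areas: per area root, within-area reachability ------------
  pa_members <- list()
  pa_meta <- list()
  labels <- stats::setNames(g$concepts$label, ids)
  for (a in areas$area_id) {
    for (r in at$roots[[a]]) {
      mem <- r
      queue <- g$children[[r]]
      while (length(queue)) {
        nxt <- queue[[1L]]; queue <- queue[-1L]
        if (keys[nxt] != a || nxt %in% mem) next
        mem <- c(mem, nxt)
        queue <- c(queue, g$children[[nxt]])
      }
      pa_members[[r]] <- sort(mem)
      pa_meta[[r]] <- .df(pa_id = r, root = r,
                          label = sprintf("%s (%d)", labels[[r]], length(mem)),
                          area_id = a, size = length(mem))
    }
  }
  pareas <- do.call(rbind, pa_meta)
  ord <- order(-pareas$size, pareas$label)
  pareas <- pareas[ord, , drop = FALSE]
  rownames(pareas) <- NULL
  pa_members <- pa_members[pareas$pa_id]

  # concept -> containing partial-areas
  inv <- .df(concept = unlist(pa_members, use.names = FALSE),
             pa = rep(pareas$pa_id, vapply(pa_members, length, 1L)))
  concept_pas <- lapply(split(inv$pa, factor(inv$concept, levels = ids)), sort)

  # partial-area child-of links: root's parent concept sits in partial-area B
  plinks <- list()
  for (i in seq_len(nrow(pareas))) {
    r <- pareas$root[[i]]
    pas <- unique(unlist(concept_pas[g$parents[[r]]], use.names = FALSE))
    pas <- setdiff(pas, pareas$pa_id[[i]])
    if (length(pas)) plinks[[r]] <- .df(child = pareas$pa_id[[i]], parent = pas)
  }
  plinks <- if (length(plinks)) unique(do.call(rbind, plinks))
  else .df(child = character(0), parent = character(0))

  plinks <- plinks[order(plinks$child, plinks$parent), , drop = FALSE]
  rownames(plinks) <- NULL
  pat <- structure(
    list(pareas = pareas, members = pa_members, concept_pas = concept_pas,
         links = plinks,
         area_taxonomy = at,
         concepts = g$concepts),
    class = "partial_area_taxonomy")
  list(area = at, partial_area = pat)
}

#' Derive the area taxonomy
#'
#' Partitions the concepts of an ontology graph into *areas* — maximal groups
#' of concepts having exactly the same set of lateral relationship types —
#' and connects them by child-of links: if a root concept of area A (a member
#' all of whose parents lie outside A) has a parent in area B, then A is
#' child-of B. The area whose type set is empty is labeled Ø.
#'
#' @param g an `ontology_graph`.
#' @param mode how effective relationship-type sets are computed; see
#'   [effective_rel_types()].
#' @return An object of class `area_taxonomy`: `areas` (data frame with
#'   `area_id`, `label`, `size`, `n_roots`, sorted by size descending then
#'   label), `members` and `roots` (named lists keyed by `area_id`),
#'   `concept_area` (named vector concept -> area), and `links`
#'   (child/parent area ids).
#' @examples
#' at <- derive_area_taxonomy(build_fig1_fixture())
#' at$areas
#' @export
derive_area_taxonomy <- function(g, mode = c("asserted", "inherited")) {
  stopifnot(inherits(g, "ontology_graph"))
  .derive_taxonomies(g, effective_rel_types(g, match.arg(mode)))$area
}

#' Derive the partial-area taxonomy
#'
#' Splits every area into *partial-areas*: for each area root r, the
#' partial-area of r contains r plus every area member reachable from r by an
#' is-a path that stays inside the area. Partial-areas are labeled by their
#' root concept's label with the size in parentheses, e.g. `"Antigen Gene
#' (4)"`, and connected by child-of links derived from the root's parents.
#' A concept with multiple parents can belong to several partial-areas of the
#' same area (an *overlapping concept*, see [find_overlapping_concepts()]).
#'
#' @inheritParams derive_area_taxonomy
#' @return An object of class `partial_area_taxonomy`: `pareas` (data frame
#'   with `pa_id` (= root concept id), `root`, `label`, `area_id`, `size`,
#'   sorted by size descending then label), `members` and `concept_pas`
#'   (named lists), `links`, and the enclosing `area_taxonomy`.
#' @examples
#' pat <- derive_partial_area_taxonomy(build_fig1_fixture())
#' pat$pareas[, c("label", "size")]
#' @export
derive_partial_area_taxonomy <- function(g, mode = c("asserted", "inherited")) {
  stopifnot(inherits(g, "ontology_graph"))
  .derive_taxonomies(g, effective_rel_types(g, match.arg(mode)))$partial_area
}

#' Derive a subtaxonomy restricted to a subset of relationship types
#'
#' Coarsens the summarization by intersecting every concept's effective
#' relationship-type set with `rel_subset` before derivation. Restricting to
#' fewer types merges uncommonly modeled concepts into larger partial-areas,
#' reducing the number of small partial-areas when there are too many to
#' audit. With `rel_subset` equal to all observed types the result is
#' identical to [derive_partial_area_taxonomy()].
#'
#' @inheritParams derive_area_taxonomy
#' @param rel_subset character vector of relationship-type names to keep; a
#'   warning is issued for names not observed in the graph.
#' @return A `partial_area_taxonomy`.
#' @export
derive_subtaxonomy <- function(g, rel_subset, mode = c("asserted", "inherited")) {
  stopifnot(inherits(g, "ontology_graph"))
  mode <- match.arg(mode)
  observed <- unique(g$lateral$rel_type)
  unknown <- setdiff(rel_subset, observed)
  if (length(unknown))
    .warnf("relationship type(s) not observed in the graph: %s",
           paste(unknown, collapse = ", "))
  typesets <- lapply(effective_rel_types(g, mode), intersect, y = rel_subset)
  .derive_taxonomies(g, typesets)$partial_area
}

#' @export
print.area_taxonomy <- function(x, ...) {
  cat(sprintf("<area_taxonomy> %d areas over %d concepts, %d child-of links\n",
              nrow(x$areas), length(x$concept_area), nrow(x$links)))
  invisible(x)
}

#' @export
print.partial_area_taxonomy <- function(x, ...) {
  cat(sprintf("<partial_area_taxonomy> %d partial-areas in %d areas over %d concepts, %d child-of links\n",
              nrow(x$pareas), nrow(x$area_taxonomy$areas),
              length(x$concept_pas), nrow(x$links)))
  invisible(x)
}

#' Find overlapping concepts
#'
#' Overlapping concepts belong to two or more partial-areas of a partial-area
#' taxonomy (which requires multiple parents). They are a separate, known
#' error-prone class and are excluded from the small-partial-area sampling
#' frame to avoid biasing the audit.
#'
#' @param pat a `partial_area_taxonomy`.
#' @return A list of class `overlap_report` with `overlapping` (sorted ids)
#'   and `memberships` (named list: concept -> containing partial-area ids).
#' @export
find_overlapping_concepts <- function(pat) {
  stopifnot(inherits(pat, "partial_area_taxonomy"))
  n <- vapply(pat$concept_pas, length, 1L)
  ov <- sort(names(n)[n >= 2L])
  structure(list(overlapping = ov, memberships = pat$concept_pas[ov]),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d overlapping concept(s)\n", length(x$overlapping)))
  invisible(x)
}

#' Distribution of partial-areas and concepts by size
#'
#' Tabulates, for each observed partial-area size, the number of
#' partial-areas and the number of distinct concepts they summarize. With a
#' `bound`, sizes above it are aggregated into a single `"> bound"` row. A
#' `"Total"` row closes the table. With `exclude_overlapping = TRUE` the
#' concept counts include only non-overlapping members (the sampling-frame
#' view); the partial-area counts are unaffected.
#'
#' @param pat a `partial_area_taxonomy`.
#' @param exclude_overlapping drop overlapping concepts from concept counts?
#' @param bound optional positive integer; sizes above it are aggregated.
#' @return A data frame with columns `size_label`, `size` (NA for aggregate
#'   and total rows), `n_partial_areas`, `n_concepts`.
#' @export
size_distribution <- function(pat, exclude_overlapping = FALSE, bound = NULL) {
  stopifnot(inherits(pat, "partial_area_taxonomy"))
  .check_flag(exclude_overlapping, "exclude_overlapping")
  drop <- if (exclude_overlapping) find_overlapping_concepts(pat)$overlapping
  else character(0)
  sizes <- sort(unique(pat$pareas$size))
  if (!is.null(bound)) {
    bound <- .check_count(bound, "bound", min = 1L)
    below <- sizes[sizes <= bound]
  } else below <- sizes
  count_row <- function(pa_sel, label, size) {
    mem <- setdiff(unique(unlist(pat$members[pa_sel], use.names = FALSE)), drop)
    .df(size_label = label, size = size,
        n_partial_areas = length(pa_sel), n_concepts = length(mem))
  }
  rows <- lapply(below, function(s)
    count_row(pat$pareas$pa_id[pat$pareas$size == s], as.character(s), s))
  if (!is.null(bound) && any(sizes > bound)) {
    rows <- c(rows, list(count_row(pat$pareas$pa_id[pat$pareas$size > bound],
                                   paste0("> ", bound), NA_real_)))
  }
  out <- do.call(rbind, rows)
  total <- .df(size_label = "Total", size = NA_real_,
               n_partial_areas = sum(out$n_partial_areas),
               n_concepts = length(setdiff(
                 unique(unlist(pat$members, use.names = FALSE)), drop)))
  rbind(out, total)
}

#' Partition partial-areas into small and large
#'
#' A partial-area is *small* if its size (number of concepts, root included)
#' is at most the bound `b`; its concepts are the outlier, uncommonly modeled
#' concepts the audit targets. Typical bounds range from 1 to 10.
#'
#' @param pat a `partial_area_taxonomy`.
#' @param b positive integer size bound.
#' @return A list with `small` and `large`: character vectors of partial-area
#'   ids (every partial-area lands in exactly one side), plus `b`.
#' @export
classify_small_large <- function(pat, b) {
  stopifnot(inherits(pat, "partial_area_taxonomy"))
  b <- .check_count(b, "b", min = 1L)
  list(small = pat$pareas$pa_id[pat$pareas$size <= b],
       large = pat$pareas$pa_id[pat$pareas$size > b],
       b = b)
}

#' Export a taxonomy as node/link TSV tables
#'
#' Writes `nodes.tsv` (`node_id`, `kind`, `label`, `size`, `rel_types`) and
#' `links.tsv` (`child_node_id`, `parent_node_id`) for an area or
#' partial-area taxonomy; partial-area exports include the area nodes as
#' well, with `child-of` links only among nodes of the same kind.
#'
#' @param tx an `area_taxonomy` or `partial_area_taxonomy`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_taxonomy <- function(tx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(tx, "area_taxonomy")) {
    nodes <- .df(node_id = paste0("area:", tx$areas$area_id), kind = "area",
                 label = tx$areas$label, size = tx$areas$size,
                 rel_types = gsub("|", ", ", tx$areas$area_id, fixed = TRUE))
    links <- .df(child_node_id = paste0("area:", tx$links$child),
                 parent_node_id = paste0("area:", tx$links$parent))
  } else if (inherits(tx, "partial_area_taxonomy")) {
    at <- tx$area_taxonomy
    nodes <- rbind(
      .df(node_id = paste0("area:", at$areas$area_id), kind = "area",
          label = at$areas$label, size = at$areas$size,
          rel_types = gsub("|", ", ", at$areas$area_id, fixed = TRUE)),
      .df(node_id = paste0("pa:", tx$pareas$pa_id), kind = "partial_area",
          label = tx$pareas$label, size = tx$pareas$size,
          rel_types = gsub("|", ", ", tx$pareas$area_id, fixed = TRUE)))
    links <- rbind(
      .df(child_node_id = paste0("area:", at$links$child),
          parent_node_id = paste0("area:", at$links$parent)),
      .df(child_node_id = paste0("pa:", tx$links$child),
          parent_node_id = paste0("pa:", tx$links$parent)))
  } else .stopf("`tx` must be an area_taxonomy or partial_area_taxonomy")
  paths <- file.path(dir, c("nodes.tsv", "links.tsv"))
  write.table(nodes, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(links, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(paths)
}

#' Render a partial-area taxonomy as Graphviz DOT
#'
#' @param pat a `partial_area_taxonomy`.
#' @return A character scalar with the DOT source (areas as clusters,
#'   partial-areas as boxes, child-of links as edges).
#' @export
taxonomy_to_dot <- function(pat) {
  stopifnot(inherits(pat, "partial_area_taxonomy"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  at <- pat$area_taxonomy
  out <- c("digraph partial_area_taxonomy {", "  rankdir=BT;",
           "  node [shape=box];")
  for (i in seq_len(nrow(at$areas))) {
    a <- at$areas$area_id[[i]]
    pas <- pat$pareas[pat$pareas$area_id == a, , drop = FALSE]
    out <- c(out,
             sprintf("  subgraph cluster_%d {", i),
             sprintf("    label=%s;", q(sprintf("%s (%d)", at$areas$label[[i]],
                                                at$areas$size[[i]]))),
             sprintf("    %s;", q(paste0("pa:", pas$pa_id))),
             "  }")
    for (j in seq_len(nrow(pas)))
      out <- c(out, sprintf("  %s [label=%s];",
                            q(paste0("pa:", pas$pa_id[[j]])), q(pas$label[[j]])))
  }
  for (i in seq_len(nrow(pat$links)))
    out <- c(out, sprintf("  %s -> %s;", q(paste0("pa:", pat$links$child[[i]])),
                          q(paste0("pa:", pat$links$parent[[i]]))))
  paste(c(out, "}"), collapse = "\n")
}
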