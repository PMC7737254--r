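# Brute-force oracles, independent of the package's derivation path: they
# work directly off the raw edge / assertion tables.

# ancestors of `id` by repeated expansion over the raw is-a table
oracle_ancestors <- function(g, id) {
  isa <- g$isa
  acc <- character(0)
  frontier <- id
  repeat {
    nxt <- setdiff(unique(isa$parent[isa$child %in% frontier]), acc)
    if (!length(nxt)) break
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

oracle_descendants <- function(g, id) {
  isa <- g$isa
  acc <- character(0)
  frontier <- id
  repeat {
    nxt <- setdiff(unique(isa$child[isa$parent %in% frontier]), acc)
    if (!length(nxt)) break
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

# inherited effective sets: union of asserted sets over self and ancestors
oracle_inherited <- function(g) {
  asserted <- split(g$lateral$rel_type, factor(g$lateral$source, levels = g$concepts$id))
  out <- lapply(g$concepts$id, function(id) {
    ids <- c(id, oracle_ancestors(g, id))
    sort(unique(unlist(asserted[ids], use.names = FALSE)))
  })
  names(out) <- g$concepts$id
  out
}

# bucket concepts by exact type set; compute roots and area links by scanning
# every (member, parent) pair in the raw is-a table
oracle_areas <- function(g, typesets) {
  key <- vapply(typesets[g$concepts$id],
                function(t) paste0("{", paste(sort(t), collapse = "//"), "}"), "")
  names(key) <- g$concepts$id
  buckets <- split(g$concepts$id, key)
  roots <- lapply(buckets, function(ms) {
    sort(Filter(function(m) {
      ps <- g$isa$parent[g$isa$child == m]
      length(ps) == 0L || !any(key[ps] == key[[m]])
    }, ms))
  })
  links <- unique(do.call(rbind, c(list(data.frame(child = character(0), parent = character(0))),
    lapply(names(buckets), function(a) {
      ps <- unique(unlist(lapply(roots[[a]], function(r) g$isa$parent[g$isa$child == r])))
      pk <- setdiff(unique(key[ps]), a)
      if (length(pk)) data.frame(child = a, parent = pk) else NULL
    }))))
  list(key = key, members = lapply(buckets, sort), roots = roots, links = links)
}

# partial-area member set of root r: least fixpoint of
#   M = {r} union {c in same area : some parent of c in M}
oracle_pa_members <- function(g, key, r) {
  a <- key[[r]]
  area <- names(key)[key == a]
  m <- r
  repeat {
    grow <- Filter(function(c) {
      any(g$isa$parent[g$isa$child == c] %in% m)
    }, setdiff(area, m))
    if (!length(grow)) break
    m <- c(m, grow)
  }
  sort(m)
}

# all partial-areas (named by root) from the raw tables
oracle_partial_areas <- function(g, typesets) {
  oa <- oracle_areas(g, typesets)
  roots <- unlist(oa$roots, use.names = FALSE)
  out <- lapply(roots, function(r) oracle_pa_members(g, oa$key, r))
  names(out) <- roots
  out
}

# small random multi-parent DAGs with several relationship types; mutation
# and multi-parent rates are high so areas fragment and overlaps occur
random_test_graph <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(5:100, 1)
  generate_ontology(n_concepts = n, n_rel_types = 3, p_multiparent = 0.3,
                    p_mutation = 0.35, seed = seed)
}

expect_same_taxonomy <- function(g, mode = "asserted") {
  typesets <- effective_rel_types(g, mode)
  oa <- oracle_areas(g, typesets)
  at <- derive_area_taxonomy(g, mode)
  # members agree (compare as sets of member-sets)
  canon <- function(l) unname(l[order(vapply(l, paste, "", collapse = "\r"))])
  expect_identical(canon(at$members), canon(oa$members))
  expect_identical(canon(at$roots), canon(oa$roots))
  # links agree under the label translation
  key_of <- function(impl_id) paste0("{", paste(sort(.key_to_types_test(impl_id)),
                                                collapse = "//"), "}")
  impl_links <- unique(paste(vapply(at$links$child, key_of, ""),
                             vapply(at$links$parent, key_of, "")))
  or_links <- unique(paste(oa$links$child, oa$links$parent))
  expect_setequal(impl_links, or_links)
  # partial-areas agree
  opa <- oracle_partial_areas(g, typesets)
  pat <- derive_partial_area_taxonomy(g, mode)
  expect_setequal(pat$pareas$pa_id, names(opa))
  for (r in names(opa)) expect_identical(pat$members[[r]], opa[[r]])
  invisible(pat)
}

# test-side copy of the key decoding (kept separate from the implementation)
.key_to_types_test <- function(key) {
  if (key == "Ø") character(0) else strsplit(key, "|", fixed = TRUE)[[1]]
}
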