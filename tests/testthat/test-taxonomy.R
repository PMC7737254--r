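test_that("the worked-example fixture derives the canonical area taxonomy", {
  g <- build_fig1_fixture()
  at <- derive_area_taxonomy(g)
  # four areas; the Ø area exists and is the taxonomy root (no outgoing link)
  expect_equal(nrow(at$areas), 4L)
  expect_true("Ø" %in% at$areas$area_id)
  expect_false("Ø" %in% at$links$child)
  # "Gene Found In Organism" area has 2 concepts rooted at MicroRNA Gene,
  # child-of the Ø area
  gfio <- "Gene Found In Organism"
  expect_identical(sort(at$members[[gfio]]), c("MIR1243 Gene", "MicroRNA Gene"))
  expect_identical(at$roots[[gfio]], "MicroRNA Gene")
  expect_true(any(at$links$child == gfio & at$links$parent == "Ø"))
  # the two-type area has two roots
  two <- at$areas$area_id[grepl("|", at$areas$area_id, fixed = TRUE)]
  expect_identical(sort(at$roots[[two]]), c("CAGE1 wt Allele", "GAGE6 wt Allele"))
})

test_that("the worked-example fixture derives the canonical partial-area taxonomy", {
  pat <- derive_partial_area_taxonomy(build_fig1_fixture())
  expect_setequal(pat$pareas$label,
                  c("Gene (2)", "MicroRNA Gene (2)", "Antigen Gene (4)",
                    "GAGE6 wt Allele (1)", "CAGE1 wt Allele (3)"))
  # Gene (2) is the root of the partial-area taxonomy
  expect_false("Gene" %in% pat$links$child)
  expect_setequal(unique(pat$links$child), setdiff(pat$pareas$pa_id, "Gene"))
  # GAGE6 wt Allele (1) is child-of Antigen Gene (4)
  expect_true(any(pat$links$child == "GAGE6 wt Allele" &
                    pat$links$parent == "Antigen Gene"))
  expect_identical(sort(pat$pareas$size), c(1L, 2L, 2L, 3L, 4L))
})

test_that("a lateral-free graph collapses to a single Ø area with no links", {
  g <- ontology_graph(data.frame(id = c("A", "B", "C"), label = c("a", "b", "c")),
                      isa = data.frame(child = c("B", "C"), parent = c("A", "A")))
  at <- derive_area_taxonomy(g)
  expect_identical(at$areas$area_id, "Ø")
  expect_equal(at$areas$size, 3L)
  expect_equal(nrow(at$links), 0L)
  # single-root area: one partial-area equal to the area
  pat <- derive_partial_area_taxonomy(g)
  expect_equal(nrow(pat$pareas), 1L)
  expect_identical(pat$members[[pat$pareas$pa_id]], at$members[["Ø"]])
})

test_that("derivation equals the brute-force oracles on random graphs, both modes", {
  for (seed in 1:30) {
    g <- random_test_graph(seed)
    expect_same_taxonomy(g, "asserted")
  }
  for (seed in 31:35) expect_same_taxonomy(random_test_graph(seed), "inherited")
})

test_that("areas partition the concepts; partial-areas cover each area", {
  for (seed in 1:10) {
    g <- random_test_graph(seed)
    at <- derive_area_taxonomy(g)
    expect_equal(sum(at$areas$size), nrow(g$concepts))
    all_members <- unlist(at$members, use.names = FALSE)
    expect_equal(length(all_members), length(unique(all_members)))
    pat <- derive_partial_area_taxonomy(g)
    for (a in at$areas$area_id) {
      pas <- pat$pareas$pa_id[pat$pareas$area_id == a]
      expect_setequal(unique(unlist(pat$members[pas], use.names = FALSE)),
                      at$members[[a]])
      # sum of partial-area sizes >= area size; equality iff no overlap in area
      s <- sum(pat$pareas$size[pat$pareas$area_id == a])
      expect_gte(s, at$areas$size[at$areas$area_id == a])
    }
  }
})

test_that("partial-area child-of links are acyclic and a root partial-area holds a hierarchy root", {
  # note: partial-area links are provably acyclic (a cycle would lift to a
  # directed is-a cycle); area links can interleave through multi-rooted
  # areas, so only self-loop freedom is asserted for them
  for (seed in c(3, 14, 27)) {
    g <- random_test_graph(seed)
    pat <- derive_partial_area_taxonomy(g)
    at <- pat$area_taxonomy
    if (nrow(pat$links))
      expect_true(igraph::is_dag(igraph::graph_from_data_frame(pat$links)))
    expect_false(any(at$links$child == at$links$parent))
    top <- setdiff(pat$pareas$pa_id, pat$links$child)  # taxonomy roots
    expect_true(any(vapply(top, function(p)
      any(g$roots %in% pat$members[[p]]), TRUE)))
  }
})

test_that("derivation output is identical across repeated runs", {
  g <- random_test_graph(99)
  p1 <- derive_partial_area_taxonomy(g)
  p2 <- derive_partial_area_taxonomy(g)
  expect_identical(p1$pareas, p2$pareas)
  expect_identical(p1$members, p2$members)
  expect_identical(p1$links, p2$links)
})

test_that("overlapping concepts are exactly those in two or more partial-areas", {
  # forced overlap: area with roots r1, r2 and a member below both
  g <- ontology_graph(
    data.frame(id = c("top", "r1", "r2", "m"), label = c("top", "r1", "r2", "m")),
    isa = data.frame(child = c("r1", "r2", "m", "m"),
                     parent = c("top", "top", "r1", "r2")),
    lateral = data.frame(source = c("r1", "r2", "m"), rel_type = "T",
                         target = "x"))
  pat <- derive_partial_area_taxonomy(g)
  ov <- find_overlapping_concepts(pat)
  expect_identical(ov$overlapping, "m")
  expect_setequal(ov$memberships[["m"]], c("r1", "r2"))
  # tree-shaped hierarchies cannot overlap
  for (seed in 1:5) {
    gt <- generate_ontology(n_concepts = 60, n_rel_types = 3, p_multiparent = 0,
                            p_mutation = 0.35, seed = seed)
    expect_length(find_overlapping_concepts(derive_partial_area_taxonomy(gt))$overlapping, 0L)
  }
  # random multi-parent DAGs: equals the membership-count oracle
  for (seed in 6:12) {
    gr <- random_test_graph(seed)
    patr <- derive_partial_area_taxonomy(gr)
    opa <- oracle_partial_areas(gr, effective_rel_types(gr))
    counts <- table(unlist(opa, use.names = FALSE))
    expect_setequal(find_overlapping_concepts(patr)$overlapping,
                    names(counts)[counts >= 2])
  }
})

test_that("size distribution conserves counts and honors the bound and exclusion", {
  pat <- derive_partial_area_taxonomy(build_fig1_fixture())
  sd <- size_distribution(pat)
  tot <- sd[sd$size_label == "Total", ]
  per <- sd[sd$size_label != "Total", ]
  expect_equal(tot$n_partial_areas, sum(per$n_partial_areas))
  expect_equal(tot$n_concepts, 12)
  # single-area single-root graph of n concepts -> one row (n, 1, n)
  g1 <- ontology_graph(data.frame(id = letters[1:5], label = letters[1:5]),
                       isa = data.frame(child = letters[2:5], parent = letters[1:4]))
  sd1 <- size_distribution(derive_partial_area_taxonomy(g1))
  expect_equal(sd1$n_partial_areas, c(1, 1))
  expect_equal(sd1$n_concepts, c(5, 5))
  expect_equal(sd1$size[1], 5)
  # bound aggregates the tail
  sdb <- size_distribution(pat, bound = 2)
  expect_true("> 2" %in% sdb$size_label)
  agg <- sdb[sdb$size_label == "> 2", ]
  expect_equal(agg$n_partial_areas, 2)  # sizes 3 and 4
  # exclusion drops overlapping concepts from concept counts only
  g <- random_test_graph(8)
  patg <- derive_partial_area_taxonomy(g)
  ov <- find_overlapping_concepts(patg)$overlapping
  sd_all <- size_distribution(patg)
  sd_ex <- size_distribution(patg, exclude_overlapping = TRUE)
  expect_identical(sd_all$n_partial_areas, sd_ex$n_partial_areas)
  expect_equal(sd_ex[sd_ex$size_label == "Total", "n_concepts"],
               sd_all[sd_all$size_label == "Total", "n_concepts"] - length(ov))
})

test_that("subtaxonomy with the full type set is the identity", {
  for (seed in c(2, 9)) {
    g <- random_test_graph(seed)
    full <- derive_partial_area_taxonomy(g)
    sub <- derive_subtaxonomy(g, unique(g$lateral$rel_type))
    expect_identical(full$pareas, sub$pareas)
    expect_identical(full$members, sub$members)
    expect_identical(full$links, sub$links)
  }
})

test_that("restricting types merges a lone two-type concept into its ancestor's partial-area", {
  # ENV-style: X has {T1, T2} and sits alone; its ancestor chain carries {T2}
  g <- ontology_graph(
    data.frame(id = c("root", "Viral Gene", "VG child", "X"),
               label = c("root", "Viral Gene", "VG child", "X")),
    isa = data.frame(child = c("Viral Gene", "VG child", "X"),
                     parent = c("root", "Viral Gene", "VG child")),
    lateral = rbind(
      data.frame(source = c("Viral Gene", "VG child", "X"),
                 rel_type = "Gene Plays Role In Process", target = "p"),
      data.frame(source = "X", rel_type = "Gene Found In Organism", target = "o")))
  full <- derive_partial_area_taxonomy(g)
  expect_equal(full$pareas$size[full$pareas$root == "X"], 1L)
  sub <- derive_subtaxonomy(g, "Gene Plays Role In Process")
  expect_false("X" %in% sub$pareas$root)
  expect_true("X" %in% sub$members[["Viral Gene"]])
  expect_equal(sub$pareas$size[sub$pareas$root == "Viral Gene"], 3L)
  expect_warning(derive_subtaxonomy(g, c("Gene Plays Role In Process", "nope")),
                 "not observed")
})

test_that("random subtaxonomies equal full derivation on the intersected graph", {
  for (seed in c(4, 17, 23)) {
    g <- random_test_graph(seed)
    types <- unique(g$lateral$rel_type)
    keep <- sample(types, max(1, length(types) - 1))
    sub <- derive_subtaxonomy(g, keep)
    # oracle: physically drop the assertions of the removed types, re-derive
    g2 <- ontology_graph(g$concepts, g$isa,
                         g$lateral[g$lateral$rel_type %in% keep, , drop = FALSE])
    full2 <- derive_partial_area_taxonomy(g2)
    expect_identical(sub$pareas, full2$pareas)
    expect_identical(sub$members, full2$members)
  }
})

test_that("small/large classification partitions partial-areas at the bound", {
  pat <- derive_partial_area_taxonomy(build_fig1_fixture())
  cl <- classify_small_large(pat, 10)
  expect_setequal(c(cl$small, cl$large), pat$pareas$pa_id)
  expect_length(cl$large, 0L)  # all sizes <= 4
  cl2 <- classify_small_large(pat, max(pat$pareas$size) - 1)
  expect_identical(cl2$large,
                   pat$pareas$pa_id[pat$pareas$size == max(pat$pareas$size)])
  expect_error(classify_small_large(pat, 0), ">= 1")
})

test_that("re-pointing an outlier's odd parent merges it into the sibling partial-area", {
  # Tendon biopsy sample: two parents in different areas make it a
  # single-concept partial-area; correcting the second parent to the sibling
  # subtree moves it into that larger partial-area
  base <- list(
    concepts = data.frame(
      id = c("Specimen", "Tendon sample", "Biopsy sample",
             "Soft tissue biopsy sample", "Fascia biopsy sample",
             "Muscle biopsy sample", "Tendon biopsy sample"),
      label = c("Specimen", "Tendon sample", "Biopsy sample",
                "Soft tissue biopsy sample", "Fascia biopsy sample",
                "Muscle biopsy sample", "Tendon biopsy sample")),
    lateral = rbind(
      data.frame(source = c("Tendon sample"),
                 rel_type = "Specimen source topography", target = "tendon"),
      data.frame(source = "Biopsy sample", rel_type = "Specimen procedure",
                 target = "biopsy"),
      data.frame(source = c("Soft tissue biopsy sample", "Fascia biopsy sample",
                            "Muscle biopsy sample", "Tendon biopsy sample"),
                 rel_type = "Specimen source topography", target = "soft tissue"),
      data.frame(source = c("Soft tissue biopsy sample", "Fascia biopsy sample",
                            "Muscle biopsy sample", "Tendon biopsy sample"),
                 rel_type = "Specimen procedure", target = "biopsy")))
  isa_before <- data.frame(
    child = c("Tendon sample", "Biopsy sample", "Soft tissue biopsy sample",
              "Fascia biopsy sample", "Muscle biopsy sample",
              "Tendon biopsy sample", "Tendon biopsy sample"),
    parent = c("Specimen", "Specimen", "Biopsy sample",
               "Soft tissue biopsy sample", "Soft tissue biopsy sample",
               "Tendon sample", "Biopsy sample"))
  g_before <- ontology_graph(base$concepts, isa_before, base$lateral)
  pat_before <- derive_partial_area_taxonomy(g_before)
  expect_equal(pat_before$pareas$size[pat_before$pareas$root == "Tendon biopsy sample"], 1L)
  isa_after <- isa_before
  isa_after$parent[isa_after$child == "Tendon biopsy sample" &
                     isa_after$parent == "Biopsy sample"] <- "Soft tissue biopsy sample"
  g_after <- ontology_graph(base$concepts, isa_after, base$lateral)
  pat_after <- derive_partial_area_taxonomy(g_after)
  expect_false("Tendon biopsy sample" %in% pat_after$pareas$root)
  expect_true("Tendon biopsy sample" %in% pat_after$members[["Soft tissue biopsy sample"]])
  expect_gt(pat_after$pareas$size[pat_after$pareas$root == "Soft tissue biopsy sample"],
            pat_before$pareas$size[pat_before$pareas$root == "Soft tissue biopsy sample"])
})

test_that("taxonomy export writes consistent node and link tables", {
  pat <- derive_partial_area_taxonomy(build_fig1_fixture())
  d <- withr::local_tempdir()
  write_taxonomy(pat, d)
  nodes <- read.delim(file.path(d, "nodes.tsv"), colClasses = "character")
  links <- read.delim(file.path(d, "links.tsv"), colClasses = "character")
  expect_setequal(unique(nodes$kind), c("area", "partial_area"))
  expect_equal(sum(nodes$kind == "partial_area"), nrow(pat$pareas))
  expect_true(all(links$child_node_id %in% nodes$node_id))
  expect_true(all(links$parent_node_id %in% nodes$node_id))
  dot <- taxonomy_to_dot(pat)
  expect_match(dot, "digraph")
  expect_match(dot, "Antigen Gene \\(4\\)")
})
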