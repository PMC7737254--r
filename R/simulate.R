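# Synthetic ontologies, planted modeling errors and simulated audits, so the
# whole study design can be exercised and calibrated without any licensed
# terminology release.

#' Generate a synthetic ontology graph
#'
#' Grows a rooted is-a DAG by preferential attachment: each new concept picks
#' a parent among existing concepts with probability proportional to
#' (number of children + 1), and with probability `p_multiparent` also a
#' second, distinct parent (always an earlier concept, so acyclicity is
#' guaranteed). Effective relationship-type sets are inherited: a child
#' starts from the union of its parents' sets, and with probability
#' `p_mutation` one uniformly chosen type from the pool is toggled (added if
#' absent, dropped if present). Each concept's set is materialized as lateral
#' assertions (one per type, with an opaque out-of-hierarchy target), the way
#' an inferred release materializes inheritance — so the default
#' `"asserted"` derivation mode applies.
#'
#' The defaults emulate a Specimen-scale hierarchy: 1500 concepts and 5
#' relationship types, with multi-parent and mutation probabilities chosen
#' to yield a dominant Ø root area, a few dozen areas, several hundred
#' partial-areas and both small and large strata well populated.
#'
#' @param n_concepts number of concepts (`>= 1`).
#' @param n_rel_types size of the relationship-type pool.
#' @param p_multiparent probability a concept gets a second parent.
#' @param p_mutation probability a concept's type set differs from its
#'   parents' union by one toggled type.
#' @param seed integer seed; generation is a pure function of the seed.
#' @return An `ontology_graph`.
#' @export
generate_ontology <- function(n_concepts = 1500, n_rel_types = 5,
                              p_multiparent = 0.08, p_mutation = 0.12, seed) {
  n_concepts <- .check_count(n_concepts, "n_concepts", min = 1L)
  n_rel_types <- .check_count(n_rel_types, "n_rel_types", min = 0L)
  p_multiparent <- .check_prob(p_multiparent, "p_multiparent")
  p_mutation <- .check_prob(p_mutation, "p_mutation")
  seed <- .check_seed(seed)
  ids <- sprintf("C%05d", seq_len(n_concepts))
  pool <- sprintf("RT%02d", seq_len(n_rel_types))
  withr::with_seed(seed, {
    typesets <- vector("list", n_concepts)
    typesets[[1L]] <- character(0)               # root area is Ø
    child_count <- numeric(n_concepts)
    edges_child <- character(0); edges_parent <- character(0)
    for (k in seq_len(n_concepts)[-1L]) {
      prev <- seq_len(k - 1L)
      w <- child_count[prev] + 1
      p1 <- sample(prev, 1L, prob = w)
      parents <- p1
      if (k > 2L && runif(1) < p_multiparent) {
        rest <- setdiff(prev, p1)
        w2 <- child_count[rest] + 1
        parents <- c(p1, if (length(rest) == 1L) rest
                     else sample(rest, 1L, prob = w2))
      }
      child_count[parents] <- child_count[parents] + 1
      edges_child <- c(edges_child, rep(ids[k], length(parents)))
      edges_parent <- c(edges_parent, ids[parents])
      ts <- sort(unique(unlist(typesets[parents], use.names = FALSE)))
      if (length(pool) && runif(1) < p_mutation) {
        t <- sample(pool, 1L)
        ts <- if (t %in% ts) setdiff(ts, t) else sort(c(ts, t))
      }
      typesets[[k]] <- ts
    }
    all_types <- unlist(typesets, use.names = FALSE)
    lateral <- if (length(all_types)) .df(
      source = rep(ids, vapply(typesets, length, 1L)),
      rel_type = all_types,
      target = paste0("X:", all_types))
    ontology_graph(
      .df(id = ids, label = ids),
      if (length(edges_child)) .df(child = edges_child, parent = edges_parent)
      else NULL,
      lateral)
  })
}

#' The 12-concept gene worked-example fixture
#'
#' A hand-built excerpt-style graph of 12 gene concepts with two lateral
#' relationship types, reproducing the canonical worked example of taxonomy
#' derivation: the Ø root area contains *Gene* and *Regulatory Gene*
#' (partial-area "Gene (2)", the taxonomy root); the *Gene Found In
#' Organism* area holds *MicroRNA Gene* and its child *MIR1243 Gene*; the
#' *Gene Plays Role In Process* area holds the four concepts of partial-area
#' "Antigen Gene (4)"; and the two-type area has the two roots *GAGE6 wt
#' Allele* (partial-area of size 1, child-of "Antigen Gene (4)") and *CAGE1
#' wt Allele* (size 3). Memberships not pinned down by the canonical facts
#' (the CAGE1-side descendants and the Antigen Gene internal structure) are
#' fixed by construction.
#'
#' @return An `ontology_graph` with 12 concepts.
#' @export
build_fig1_fixture <- function() {
  gfio <- "Gene Found In Organism"
  gprp <- "Gene Plays Role In Process"
  concepts <- .df(
    id = c("Gene", "Regulatory Gene",
           "MicroRNA Gene", "MIR1243 Gene",
           "Antigen Gene", "GAGE Gene", "GAGE6 Gene", "CAGE1 Gene",
           "GAGE6 wt Allele",
           "CAGE1 wt Allele", "CAGE1 Mutant Allele", "CAGE1 Polymorphic Allele"))
  concepts$label <- concepts$id
  isa <- .df(
    child = c("Regulatory Gene", "MicroRNA Gene", "MIR1243 Gene",
              "Antigen Gene", "GAGE Gene", "GAGE6 Gene", "CAGE1 Gene",
              "GAGE6 wt Allele", "CAGE1 wt Allele",
              "CAGE1 Mutant Allele", "CAGE1 Polymorphic Allele"),
    parent = c("Gene", "Gene", "MicroRNA Gene",
               "Regulatory Gene", "Antigen Gene", "GAGE Gene", "Antigen Gene",
               "GAGE6 Gene", "CAGE1 Gene",
               "CAGE1 wt Allele", "CAGE1 wt Allele"))
  one_type <- function(idv, type, target)
    .df(source = idv, rel_type = type, target = target)
  lateral <- rbind(
    one_type(c("MicroRNA Gene", "MIR1243 Gene"), gfio, "Human"),
    one_type(c("Antigen Gene", "GAGE Gene", "GAGE6 Gene", "CAGE1 Gene"),
             gprp, "Immune Response Process"),
    one_type(c("GAGE6 wt Allele", "CAGE1 wt Allele", "CAGE1 Mutant Allele",
               "CAGE1 Polymorphic Allele"), gprp, "Immune Response Process"),
    one_type(c("GAGE6 wt Allele", "CAGE1 wt Allele", "CAGE1 Mutant Allele",
               "CAGE1 Polymorphic Allele"), gfio, "Human"))
  ontology_graph(concepts, isa, lateral)
}

#' Plant ground-truth modeling errors by stratum
#'
#' Flags each concept as erroneous by an independent Bernoulli draw whose
#' rate depends on the concept's stratum: `rate_small` for concepts whose
#' (smallest containing) partial-area has size `<= bound`, `rate_large`
#' otherwise. The defaults are the stratum error rates observed in the
#' Specimen-scale audit (22.4% vs 5.9%) at the broad bound 10.
#'
#' @param pat a `partial_area_taxonomy`.
#' @param rate_small,rate_large per-stratum error probabilities.
#' @param bound small/large size bound (default 10).
#' @param seed integer seed.
#' @return A data frame of class `error_truth`: `concept_id`, `stratum`,
#'   `has_error`.
#' @export
plant_errors <- function(pat, rate_small = 0.224, rate_large = 0.059,
                         bound = 10, seed) {
  stopifnot(inherits(pat, "partial_area_taxonomy"))
  rate_small <- .check_prob(rate_small, "rate_small")
  rate_large <- .check_prob(rate_large, "rate_large")
  bound <- .check_count(bound, "bound", min = 1L)
  seed <- .check_seed(seed)
  sizes <- stats::setNames(pat$pareas$size, pat$pareas$pa_id)
  pa_size <- vapply(pat$concept_pas, function(p) min(sizes[p]), 1)
  stratum <- ifelse(pa_size <= bound, "small", "large")
  rate <- ifelse(stratum == "small", rate_small, rate_large)
  flags <- withr::with_seed(seed, rbinom(length(rate), 1L, rate) == 1L)
  out <- .df(concept_id = names(pa_size), stratum = stratum, has_error = flags)
  out <- out[order(out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("error_truth", "data.frame"))
}

#' Simulate a blinded audit
#'
#' Emulates the human domain expert: each truly erroneous sampled concept is
#' flagged with probability `sensitivity`; each error-free one is flagged
#' with probability `false_positive_rate`. A perfect auditor
#' (`sensitivity = 1`, `false_positive_rate = 0`) reports the truth.
#'
#' @param sample an `audit_sample` (or character vector of concept ids).
#' @param truth an `error_truth` table covering every sampled concept.
#' @param sensitivity probability a planted error is flagged.
#' @param false_positive_rate probability an error-free concept is flagged.
#' @param seed integer seed (may be omitted for the deterministic perfect
#'   auditor).
#' @return `audit_records` for the sampled concepts.
#' @export
simulate_audit <- function(sample, truth, sensitivity = 1,
                           false_positive_rate = 0, seed = NULL) {
  ids <- if (is.data.frame(sample)) sample$concept_id else as.character(sample)
  sensitivity <- .check_prob(sensitivity, "sensitivity")
  false_positive_rate <- .check_prob(false_positive_rate, "false_positive_rate")
  missing_ids <- setdiff(ids, truth$concept_id)
  if (length(missing_ids))
    .stopf("truth flags missing for sampled concept(s): %s",
           paste(missing_ids, collapse = ", "))
  tr <- stats::setNames(truth$has_error, truth$concept_id)[ids]
  deterministic <- sensitivity %in% c(0, 1) && false_positive_rate %in% c(0, 1)
  flag_fun <- function() {
    u <- runif(length(ids))
    ifelse(tr, u < sensitivity, u < false_positive_rate)
  }
  flagged <- if (deterministic) ifelse(tr, sensitivity == 1, false_positive_rate == 1)
  else withr::with_seed(.check_seed(seed), flag_fun())
  audit_records(.df(
    concept_id = ids, has_error = flagged,
    issue = ifelse(flagged, "modeling issue identified in review", ""),
    suggested_correction = ifelse(flagged, "see review notes", "")))
}

#' Power / type-I-error experiment for the audit design
#'
#' Generates one synthetic ontology, derives its partial-area taxonomy and
#' sampling frame once, then replicates the full study `reps` times: plant
#' stratum-specific errors, draw a fresh blinded stratified sample
#' (proportional allocation, `n_small`/`n_large`), audit it with the given
#' auditor model, and test the small-vs-large error-rate difference by the
#' two-tailed Fisher exact test *at the fixed pre-specified bound* (no
#' adaptive threshold scan, so the null calibration is a true type-I error
#' rate). Returns the fraction of replicates rejecting at the 0.05 level —
#' the empirical power (or, with `rate_small == rate_large`, the type-I
#' error rate).
#'
#' @param n_concepts,n_rel_types,p_multiparent,p_mutation generator
#'   parameters, see [generate_ontology()].
#' @param rate_small,rate_large planted stratum error rates.
#' @param bound small/large size bound used both for planting and analysis.
#' @param n_small,n_large per-stratum sample sizes.
#' @param sensitivity,false_positive_rate auditor model.
#' @param reps number of replicates.
#' @param seed integer seed driving the whole experiment.
#' @return A list of class `power_experiment`: `rejection_rate`, `reps`,
#'   `p_values`, `frame_sizes` (eligible small/large counts).
#' @export
power_experiment <- function(n_concepts = 1500, n_rel_types = 5,
                             p_multiparent = 0.08, p_mutation = 0.12,
                             rate_small = 0.224, rate_large = 0.059,
                             bound = 10, n_small = 50, n_large = 50,
                             sensitivity = 1, false_positive_rate = 0,
                             reps = 500, seed) {
  reps <- .check_count(reps, "reps", min = 1L)
  seed <- .check_seed(seed)
  g <- generate_ontology(n_concepts, n_rel_types, p_multiparent, p_mutation,
                         seed = seed)
  pat <- derive_partial_area_taxonomy(g)
  frame <- build_frame(pat, exclude_overlapping = TRUE, bound = bound)
  alloc <- allocate_proportional(frame, n_small = n_small, n_large = n_large)
  # independent per-replicate sub-seeds, all below 2^31
  sub <- withr::with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                                  3L * reps), nrow = 3L))
  pvals <- vapply(seq_len(reps), function(r) {
    truth <- plant_errors(pat, rate_small, rate_large, bound = bound,
                          seed = sub[1L, r])
    smp <- draw_sample(frame, alloc, seed = sub[2L, r])
    rec <- simulate_audit(smp, truth, sensitivity, false_positive_rate,
                          seed = if (sensitivity %in% c(0, 1) &&
                                     false_positive_rate %in% c(0, 1)) NULL
                          else sub[3L, r])
    tab <- size_error_table(rec, frame, bound = bound, sample = smp)
    fisher_exact_two_tailed(contingency_at_threshold(tab, bound))
  }, 1)
  structure(list(rejection_rate = mean(pvals < 0.05), reps = reps,
                 p_values = pvals,
                 frame_sizes = c(small = sum(frame$stratum == "small"),
                                 large = sum(frame$stratum == "large"))),
            class = "power_experiment")
}

#' @export
print.power_experiment <- function(x, ...) {
  cat(sprintf("<power_experiment> rejection rate %.3f over %d replicates (frame: %d small / %d large)\n",
              x$rejection_rate, x$reps, x$frame_sizes[["small"]],
              x$frame_sizes[["large"]]))
  invisible(x)
}
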