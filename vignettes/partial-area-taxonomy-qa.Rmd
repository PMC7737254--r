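---
title: "Partial-area taxonomies and outlier-concept quality assurance"
author: "paqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-area taxonomies and outlier-concept quality assurance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paqa)
```

## The problem

Large clinical ontologies (SNOMED CT, the NCI Thesaurus, and hundreds of
BioPortal ontologies) organize concepts into is-a hierarchies that are
directed acyclic graphs — a concept may have several parents — and decorate
them with *lateral* relationships ("attribute relationships" in SNOMED CT,
"roles" in NCIt) pointing at concepts in other hierarchies. At this scale,
modeling errors are unavoidable and full manual review is infeasible, so
auditing must be *targeted*: spend reviewer hours where the error density is
highest.

The targeting signal implemented here is structural. An **area** is the set
of all concepts that carry exactly the same set of lateral relationship
types; areas partition the ontology. Within an area, a **root** is a member
whose parents all lie outside the area, and the **partial-area** of a root
is the root plus every area member reachable from it by an is-a path that
stays inside the area. Concepts in *small* partial-areas (size at most a
bound `b`, in practice `b` between 1 and 10) carry a combination of
structure and semantics shared by almost nothing else in the ontology. Such
outlier modeling is often *mis*-modeling: empirically, small partial-areas
harbor significantly more errors than large ones, so they are efficient
audit targets.

## Derivation semantics

`derive_area_taxonomy()` and `derive_partial_area_taxonomy()` implement the
summarization networks with the following precise choices, all of which are
visible in the worked 12-concept example (`build_fig1_fixture()`):

* **Area identity is exact set equality** of effective relationship-type
  sets. No subset or superset merging is performed; the empty set is a
  legitimate area (labeled `Ø`) and typically sits at the top of the
  taxonomy.
* **Effective type sets** default to the *asserted* sets
  (`mode = "asserted"`), because production releases of SNOMED CT and NCIt
  are *inferred* releases in which inheritance has already been materialized
  by a reasoner. For raw authoring files, `mode = "inherited"` takes the
  union of asserted sets over each concept and all its ancestors (lateral
  relationships are inherited along is-a).
* **Partial-area membership requires a within-area path.** A concept
  belongs to the partial-area of root `r` only if some is-a path from `r`
  down to it stays entirely inside the area. The looser alternative —
  "any descendant of `r` that happens to share the area" — would let a
  membership tunnel through a region with different semantics and would
  break the correspondence between child-of links and root parentage, so it
  was rejected. (The two definitions coincide on every graph in which areas
  are "convex" along is-a, which covers the common case.)
* **Child-of links** follow root parentage: partial-area A is child-of
  partial-area B when A's root has a parent concept inside B; likewise for
  areas. Partial-area child-of links are provably acyclic — a cycle would
  lift, via the within-area member paths, to a directed is-a cycle, which
  validation forbids. *Area-level* links, however, are not guaranteed
  acyclic: two multi-rooted areas can interleave (a root of area A has its
  parent in B while a *different* root of B has its parent in A) without
  any underlying is-a cycle, and randomly generated DAGs exhibit exactly
  this. The package reports such links as derived; tests assert acyclicity
  only where it is a theorem.
* **Determinism.** All outputs are sorted (size descending, then label) so
  that derivation is byte-identical across runs and machines.

A concept with several parents can enter two partial-areas of the same area:
an **overlapping concept**. Overlapping concepts are a separately studied
error-prone class, so the audit design excludes them from the sampling frame
(`build_frame(exclude_overlapping = TRUE)`) rather than letting them inflate
the small-stratum error rate.

`derive_subtaxonomy()` intersects every effective set with a chosen subset
of relationship types before derivation. This is the escape hatch for
hierarchies in which more than half of all concepts end up in singleton
partial-areas (many leaf genes, each with a freshly asserted role): deriving
against the single dominant relationship type collapses most singletons into
their ancestors' partial-areas, leaving an auditable number of outliers.

## The audit study design

The hypothesis under test is: *concepts in small partial-areas of the
partial-area taxonomy have a significantly higher error rate than concepts
in large partial-areas.* The design is a blinded, stratified audit:

1. **Frame.** Eligible concepts are annotated with their partial-area size
   and a small/large stratum at an initial broad bound of 10. If a concept
   (with exclusion off) belongs to several partial-areas, its stratum uses
   the *smallest* containing size — the most conservative reading of
   "outlier".
2. **Allocation.** Either proportional — the small-stratum total is split
   over sizes 1..10 proportionally to their eligible populations, rounded by
   largest remainder (Hamilton), the natural choice when no rounding rule is
   canonical — or fixed per-size quotas (e.g. 10 concepts of size 1 and 5 of
   each size 2..10) when the size-1 population dwarfs everything else. A
   quota exceeding a size's population takes the whole population with a
   warning rather than failing.
3. **Blinded draw.** `draw_sample()` draws uniformly without replacement per
   stratum, then shuffles all strata into one list. The exported worksheet
   carries only order, concept id and label — the reviewer sees neither the
   hypothesis nor any stratum information. An explicit integer seed is
   mandatory; there is no hidden global randomness.
4. **Analysis.** `size_error_table()` tabulates sampled/erroneous counts per
   size; `select_threshold()` scans candidate bounds 1..10, forms the 2x2
   table (erroneous/error-free x small/large) at each, and selects the bound
   with the smallest two-tailed Fisher exact p (ties break toward the
   smaller bound, the stronger "small" claim). The study verdict applies the
   fixed two-sided 0.05 level at the selected bound.

**Fisher convention.** `fisher_exact_two_tailed()` uses the point-probability
("minimum-likelihood") two-sided convention: the p-value sums the
hypergeometric point probabilities of all tables with the observed margins
that are no more likely than the observed table, with a relative tolerance
of `1e-7` in the comparison so that floating-point representations of
exactly tied tables are included. This is the convention of R's
`fisher.test()` and the one under which the bundled study tables reproduce
their reported significances; tests verify it against both `fisher.test()`
and an exhaustive log-binomial enumeration for all margins up to 12.

**A caveat on adaptive thresholds.** Selecting the bound that maximizes
significance and then quoting that same p-value is a multiple-comparison
step: across the candidate set the type-I error is no longer the nominal
0.05. The threshold scan is therefore presented as an *exploratory* device
for choosing a bound to use going forward. The calibration experiment below
deliberately analyzes at one fixed, pre-specified bound so that its null
rejection rate is a true type-I error; users who want a confirmatory p-value
for a scanned threshold should validate it on a fresh sample.

## Family applicability

Whether the technique "works" for a given ontology is a binary outcome, so a
set of per-ontology studies in one structural family is a sequence of
Bernoulli trials with success probability `p`:

$$\binom{n}{i} p^i (1-p)^{n-i}$$

Because family study counts are tiny, the package uses exact
(Clopper–Pearson) *central* confidence intervals rather than normal
approximations, via the beta-quantile characterization
(`qbeta(alpha/2, i, n-i+1)` and `qbeta(1-alpha/2, i+1, n-i)`), cross-checked
in tests against the defining binomial tail equations. The applicability
criterion is strict: the technique is declared applicable to at least half
of the family only when the 95% lower bound *exceeds* 0.5. Consequences,
computed exhaustively by `min_studies_required()`:

* 6 of 6 successes — lower bound 0.541 — is the minimum all-success design;
* 8 of 9 is the minimum with one failure (lower bound 0.518);
* 10 of 12 with two failures; and so on.

`classify_structural_family()` reduces an ontology to the two features that
decide which summarization network applies — does it have outgoing lateral
relationships (object properties), and is the hierarchy a multi-parent DAG
rather than a tree — yielding the labels `OP+DAG`, `OP+tree`, `noOP+DAG`,
`noOP+tree`. Data properties are deliberately not part of the grid: no
technique here depends on them.

## What the synthetic generator emulates — and what it does not

`generate_ontology()` grows a rooted DAG by preferential attachment (child
counts act as weights, giving the right-skewed branching real hierarchies
show), attaches a second parent with probability `p_multiparent`, and
propagates relationship-type sets down the hierarchy, toggling one type with
probability `p_mutation` per concept. Sets are materialized as per-concept
assertions, mimicking an inferred release, so the default `"asserted"`
derivation mode applies. The defaults — 1500 concepts, 5 relationship
types, `p_multiparent = 0.08`, `p_mutation = 0.12` — were chosen once to
emulate a Specimen-scale hierarchy: a dominant Ø root area, tens of areas,
a couple hundred partial-areas, and both strata populated far beyond the
50 + 50 design. `plant_errors()` assigns independent Bernoulli error flags
at stratum-specific rates, defaulting to the 22.4% (small) versus 5.9%
(large) rates observed in the bundled Specimen-scale audit; and
`simulate_audit()` models the reviewer as a sensitivity / false-positive
process.

The generator does **not** emulate: real terminological labels or any
semantic plausibility of the planted errors; correlation of errors within a
partial-area or along subtrees (flags are independent); reviewer drift,
fatigue, or disagreement; and description-logic classification (the input
is taken as already-classified). Passing tests therefore certify the
*derivation algebra and the statistical machinery* under the stated error
model — they do not certify that any particular real hierarchy has
error-concentrated small partial-areas; that remains an empirical question
per ontology, which is exactly what the audit design is for.

## Calibration

`power_experiment()` builds one synthetic hierarchy, then replicates the
full pipeline — plant, draw, audit, tabulate, test at the fixed bound 10 —
and reports the rejection rate. At the default study conditions (50 + 50
design, planted rates 22.4%/5.9%), 500 replicates give a power well above
one half; with equal planted rates the rejection rate sits below the nominal
0.05 (Fisher's exact test is conservative on discrete tables). The
validation suite runs the derivation against brute-force oracles
(independent fixpoint/bucketing re-implementations working directly off the
raw edge tables) on 200 random graphs of up to 100 concepts, checks the
Fisher implementation against exhaustive enumeration for all margins up to
12, and checks Clopper–Pearson coverage on 2000 simulated draws per
parameter point — sizes chosen to keep the whole suite comfortably
re-runnable on a laptop.

## Worked example

```{r example}
g <- build_fig1_fixture()
pat <- derive_partial_area_taxonomy(g)
pat$pareas[, c("label", "size")]

spec <- example_specimen_audit()
scan <- select_threshold(spec)
scan$selected
fisher_exact_two_tailed(contingency_at_threshold(spec, scan$selected))

family_applicability(6, 6)
```

## Known limitations

* Area-level child-of links may contain cycles on adversarial inputs (see
  above); consumers that require a DAG should operate on the partial-area
  links.
* The OBO reader covers `id`/`name`/`is_a`/`relationship` lines only — it is
  a convenience mapping onto the three-table model, not a full OBO parser.
* Lateral targets are opaque and never validated; range/domain checking is
  out of scope.
* The threshold scan's p-value is exploratory (see the caveat above).
* `min_studies_required()` assumes the per-ontology studies are independent
  and exchangeable; hierarchies of one ontology maintained by one team
  stretch that assumption.
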