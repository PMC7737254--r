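# paqa — partial-area taxonomy summarization and outlier-concept QA

`paqa` is an R toolkit for structure-driven quality assurance of biomedical
ontologies whose concepts carry outgoing lateral relationships (SNOMED CT's
"attribute relationships", NCIt's "roles"). It is aimed at ontology curators
and QA researchers who need to decide *which* concepts to spend scarce
reviewer hours on, and at methodologists who want to test whether a QA
technique generalizes across a structural family of ontologies.

## The model

An ontology hierarchy is a rooted DAG of concepts under is-a, plus lateral
assertions `(source, rel_type, target)`. From it `paqa` derives two
summarization networks:

* **Area taxonomy** — an *area* is the set of all concepts with exactly the
  same set of lateral relationship types; areas partition the ontology. An
  area *root* is a member whose parents all lie outside the area; area A is
  *child-of* area B when a root of A has a parent in B.
* **Partial-area taxonomy** — each area splits into *partial-areas*: a root
  plus every area member reachable from it by an is-a path staying inside
  the area. A partial-area is labeled `Root label (size)`.

Concepts in **small partial-areas** (size ≤ b, with b ∈ 1..10) are
uncommonly modeled outliers; the package implements the blinded stratified
audit design for the hypothesis that they harbor significantly more
modeling errors than concepts of large partial-areas: sampling frame
(excluding overlapping concepts), proportional or fixed per-size quota
allocation, seeded blinded draws, per-size error tables, a threshold scan,
and the two-tailed Fisher exact test (point-probability convention) on the
2×2 table

|                      | erroneous | error-free |
|----------------------|-----------|------------|
| small (size ≤ b)     | a         | b          |
| large (size > b)     | c         | d          |

For scaling a demonstrated technique to a whole family, per-ontology
successes are modeled as Bernoulli trials, `C(n, i) p^i (1-p)^(n-i)`, with
exact Clopper–Pearson central confidence intervals; the technique is
declared applicable to at least half the family when the 95% lower bound on
`p` exceeds 0.5 — which needs 6 of 6 successes, 8 of 9, 10 of 12, ….
A synthetic-ontology generator with planted stratum-specific error rates
closes the loop, letting the whole design be power- and type-I-calibrated
end to end.

## Worked example

```r
library(paqa)

g <- build_fig1_fixture()          # 12-concept worked example
derive_partial_area_taxonomy(g)$pareas[, c("label", "size")]
#>                 label size
#> 1    Antigen Gene (4)    4
#> 2 CAGE1 wt Allele (3)    3
#> 3            Gene (2)    2
#> 4   MicroRNA Gene (2)    2
#> 5 GAGE6 wt Allele (1)    1

select_threshold(example_specimen_audit())
#> <threshold_scan> selected bound b* = 9 (p = 0.02149)
#>  bound small_err small_ok large_err large_ok small_pct large_pct p_value
#>      1         3       19        11       67     13.64    14.103 1.00000
#>  ...
#>      9        11       38         3       48     22.45     5.882 0.02149
#>     10        11       39         3       47     22.00     6.000 0.04071

family_applicability(6, 6)
#> 6/6 successes: 95% exact CI [0.541, 1.000]
#> Lower bound 0.541 > 0.50: applicable to at least half of the family.
```

Reading the output: the bundled Specimen-hierarchy audit summary
(100 blinded concepts) is most significant when "small" means size ≤ 9 —
the small stratum's error rate is 22.4% against 5.9% for the large stratum,
two-tailed Fisher exact p ≈ 0.021 (p ≈ 0.041 at bound 10). And six
successful studies out of six suffice to conclude, at the 95% level, that
the technique applies to at least half of the ontologies in the family.

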