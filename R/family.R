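# Family-based scalability statistics: exact binomial model of per-ontology
# success, Clopper-Pearson central intervals, minimum-study-count rule, and
# structural-family classification.

#' Exact binomial point mass
#'
#' Probability of exactly `i` successes in `n` independent per-ontology
#' experiments with success probability `p`:
#' `choose(n, i) * p^i * (1 - p)^(n - i)`.
#'
#' @param i number of successes, `0 <= i <= n`.
#' @param n number of experiments (ontologies studied).
#' @param p success probability in `[0, 1]`.
#' @return The point probability.
#' @examples
#' binomial_pmf(6, 6, 0.5)  # 1/64
#' @export
binomial_pmf <- function(i, n, p) {
  n <- .check_count(n, "n")
  i <- .check_count(i, "i")
  p <- .check_prob(p, "p")
  if (i > n) .stopf("`i` must not exceed `n`")
  dbinom(i, n, p)
}

#' Clopper-Pearson exact central confidence interval
#'
#' The exact central (equal-tailed) confidence interval for a binomial
#' success probability, preferred over normal approximations when the number
#' of experiments is small. Computed via the standard beta-quantile
#' characterization: lower = `qbeta(alpha/2, i, n - i + 1)` (0 when `i = 0`),
#' upper = `qbeta(1 - alpha/2, i + 1, n - i)` (1 when `i = n`).
#'
#' @param i number of successes.
#' @param n number of trials (`n >= 1`).
#' @param confidence confidence level, default 0.95.
#' @return A list of class `exact_ci` with `lower`, `upper`, `confidence`,
#'   `i`, `n`.
#' @examples
#' clopper_pearson_ci(6, 6)   # lower ~ 0.541
#' clopper_pearson_ci(8, 9)   # ~ (0.518, 0.997)
#' @export
clopper_pearson_ci <- function(i, n, confidence = 0.95) {
  n <- .check_count(n, "n", min = 1L)
  i <- .check_count(i, "i")
  if (i > n) .stopf("`i` must not exceed `n`")
  confidence <- .check_prob(confidence, "confidence")
  alpha <- 1 - confidence
  lower <- if (i == 0L) 0 else qbeta(alpha / 2, i, n - i + 1)
  upper <- if (i == n) 1 else qbeta(1 - alpha / 2, i + 1, n - i)
  structure(list(lower = lower, upper = upper, confidence = confidence,
                 i = i, n = n),
            class = "exact_ci")
}

#' @export
print.exact_ci <- function(x, ...) {
  cat(sprintf("%d/%d successes: %.0f%% exact CI [%.3f, %.3f]\n",
              x$i, x$n, 100 * x$confidence, x$lower, x$upper))
  invisible(x)
}

#' Minimum number of studies for family applicability
#'
#' Smallest number of per-ontology studies `n` such that, with at most
#' `failures` of them unsuccessful, the Clopper-Pearson lower confidence
#' bound on the success probability still exceeds `p0` (chance, 0.5). With
#' no failures the answer is 6 (six-of-six); with one failure, 9
#' (eight-of-nine); with two, 12 (ten-of-twelve).
#'
#' @param failures allowed number of unsuccessful studies (`>= 0`).
#' @param p0 probability to exclude (default 0.5).
#' @param confidence confidence level (default 0.95).
#' @return The minimal `n`.
#' @examples
#' min_studies_required(0)  # 6
#' @export
min_studies_required <- function(failures, p0 = 0.5, confidence = 0.95) {
  failures <- .check_count(failures, "failures")
  p0 <- .check_prob(p0, "p0")
  n <- failures + 1L
  repeat {
    if (clopper_pearson_ci(n - failures, n, confidence)$lower > p0) return(n)
    n <- n + 1L
    if (n > 100000L) .stopf("no attainable n (p0 too close to 1?)")
  }
}

#' Family-applicability decision
#'
#' Decides whether a QA technique demonstrated successful on
#' `successes` out of `n` ontologies of a structural family is applicable to
#' at least half of the family: the criterion is that the Clopper-Pearson
#' lower confidence bound on the per-ontology success probability strictly
#' exceeds `p0 = 0.5`.
#'
#' @param successes,n successes out of n per-ontology studies.
#' @param p0 excluded probability (default 0.5).
#' @param confidence confidence level (default 0.95).
#' @return A list of class `family_applicability`: `ci` (an `exact_ci`),
#'   `applicable` (logical), `p0`.
#' @examples
#' family_applicability(6, 6)$applicable  # TRUE, lower bound 0.541
#' @export
family_applicability <- function(successes, n, p0 = 0.5, confidence = 0.95) {
  ci <- clopper_pearson_ci(successes, n, confidence)
  structure(list(ci = ci, applicable = ci$lower > p0, p0 = p0),
            class = "family_applicability")
}

#' @export
print.family_applicability <- function(x, ...) {
  print(x$ci)
  cat(if (x$applicable)
    sprintf("Lower bound %.3f > %.2f: applicable to at least half of the family.\n",
            x$ci$lower, x$p0)
    else sprintf("Lower bound %.3f <= %.2f: applicability to half the family NOT established.\n",
                 x$ci$lower, x$p0))
  invisible(x)
}

#' Classify an ontology into a structural family
#'
#' Determines the two structural features that drive which summarization
#' network (and hence which QA technique) applies: whether any concept has
#' outgoing lateral relationships (object properties), and whether the is-a
#' hierarchy is a DAG with multi-parent concepts rather than a tree. The
#' family label is the deterministic combination of the two feature flags
#' (`"OP+DAG"`, `"OP+tree"`, `"noOP+DAG"`, `"noOP+tree"`). Data properties
#' are intentionally not part of the classification.
#'
#' @param g an `ontology_graph`.
#' @return A list of class `structural_family`:
#'   `has_object_properties`, `is_multiparent_dag`, `family_label`.
#' @export
classify_structural_family <- function(g) {
  stopifnot(inherits(g, "ontology_graph"))
  has_op <- nrow(g$lateral) > 0L
  multi <- anyDuplicated(g$isa$child) > 0L
  structure(list(has_object_properties = has_op,
                 is_multiparent_dag = multi,
                 family_label = paste0(if (has_op) "OP" else "noOP", "+",
                                       if (multi) "DAG" else "tree")),
            class = "structural_family")
}

#' @export
print.structural_family <- function(x, ...) {
  cat(sprintf("<structural_family> %s (object properties: %s; multi-parent DAG: %s)\n",
              x$family_label, x$has_object_properties, x$is_multiparent_dag))
  invisible(x)
}
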