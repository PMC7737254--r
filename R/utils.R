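# internal helpers shared across modules

# stable key for a set of relationship-type names; the empty set (no lateral
# relationships) gets the non-empty sentinel "Ø" so it is a usable list name
.set_key <- function(types) {
  types <- sort(unique(types))
  if (length(types) == 0L) "Ø" else paste(types, collapse = "|")
}

.key_to_label <- function(key) {
  ifelse(key == "Ø", "Ø", gsub("|", ", ", key, fixed = TRUE))
}

.key_to_types <- function(key) {
  if (key == "Ø") character(0) else strsplit(key, "|", fixed = TRUE)[[1]]
}

# named list id -> character vector of neighbours, for every id in `ids`
.adjacency <- function(ids, from, to) {
  adj <- split(to, factor(from, levels = ids))
  lapply(adj, as.character)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    .stopf("`%s` must be TRUE or FALSE", name)
  x
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x))
    .stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("`%s` must be a single probability in [0, 1]", name)
  as.numeric(x)
}

.check_seed <- function(seed) {
  if (missing(seed) || is.null(seed))
    .stopf("an explicit integer `seed` is required for any randomized step")
  .check_count(seed, "seed", min = 0L)
}

.df <- function(...) data.frame(..., stringsAsFactors = FALSE)
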