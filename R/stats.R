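#' Welch two-sample t-test
#'
#' Two-sided t-test with unequal variances, as used for comparing mean
#' conservation values between protein sets.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List: `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples without ties
#' (`max(n) < exact_below`) the exact null distribution is used; otherwise
#' the normal approximation with tie-corrected variance.
#'
#' @param a,b Numeric vectors.
#' @param exact_below Use the exact distribution when both groups are
#'   smaller than this and there are no ties (default 20).
#' @return List: `U` (for the first sample), `p`, `exact` (logical).
#' @export
mann_whitney <- function(a, b, exact_below = 20L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) stop("each group needs n >= 1")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && max(length(a), length(b)) < exact_below
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided",
                exact = use_exact, correct = FALSE))
  list(U = unname(ht$statistic), p = unname(ht$p.value), exact = use_exact)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform.
#' Pairs with an NA (e.g. undefined-flagged scores) are dropped first.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List: `r`, `p`, `n` (complete pairs used).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}

# Deterministic thirds partition: descending rank; with n = 3q + r the top
# third takes the first extra member, then the bottom third.
thirds_sizes <- function(n) {
  q <- n %/% 3L; r <- n %% 3L
  c(top = q + (r >= 1L), middle = q, bottom = q + (r == 2L))
}

assign_thirds <- function(values, ids) {
  ord <- order(-values, ids)           # descending, ties by id
  sizes <- thirds_sizes(length(values))
  labels <- rep(c("top", "middle", "bottom"), times = sizes)
  setNames(labels[match(seq_along(ids), ord)], ids)
}

#' Consistency of conservation thirds across taxonomic levels
#'
#' At each level, proteins are ranked by mean conservation (descending,
#' ties broken by id) and split into top / middle / bottom thirds. Reports
#' the per-protein third at each level, the fraction of proteins that stay
#' in the same third at every level, and the proteins that visit all three
#' thirds.
#'
#' @param values_by_level Named list (level -> named numeric vector of mean
#'   conservation, names = protein ids). All levels must cover the same
#'   proteins; at least 3 proteins.
#' @return List: `thirds` (data.frame, one row per protein, one column per
#'   level), `fraction_stable`, `stable_ids`, `traverse_all_ids`.
#' @export
thirds_consistency <- function(values_by_level) {
  stopifnot(is.list(values_by_level), length(values_by_level) >= 2L)
  ids <- sort(names(values_by_level[[1L]]))
  if (length(ids) < 3L) stop("need at least 3 proteins per level")
  for (lv in names(values_by_level)) {
    if (!setequal(names(values_by_level[[lv]]), ids)) {
      stop("level '", lv, "' covers a different protein set")
    }
  }
  lab <- sapply(values_by_level, function(v) assign_thirds(unname(v[ids]), ids))
  lab <- matrix(lab, nrow = length(ids),
                dimnames = list(ids, names(values_by_level)))
  stable <- apply(lab, 1L, function(r) length(unique(r)) == 1L)
  traverse <- apply(lab, 1L, function(r) length(unique(r)) == 3L)
  list(thirds = as.data.frame(lab, stringsAsFactors = FALSE),
       fraction_stable = mean(stable),
       stable_ids = ids[stable],
       traverse_all_ids = ids[traverse])
}

#' Top-k ranking table
#'
#' Sorts domain summaries descending on the chosen key with a
#' deterministic tie-break on id; rows with an NA key (undefined-flagged
#' scores) are excluded.
#'
#' @param summaries `data.frame` with an id column (`ref_id`) and the key
#'   column.
#' @param key Column name to rank on (e.g. `"ewps_pc"`, `"ewps_bs"`,
#'   `"domain_mean_cons"`).
#' @param k Number of rows to keep.
#' @return The top-k rows of `summaries`, sorted.
#' @export
top_k_table <- function(summaries, key, k = 10L) {
  stopifnot(is.data.frame(summaries), key %in% names(summaries),
            "ref_id" %in% names(summaries), k >= 1L)
  keep <- summaries[!is.na(summaries[[key]]), , drop = FALSE]
  keep <- keep[order(-keep[[key]], keep$ref_id), , drop = FALSE]
  out <- head(keep, k)
  rownames(out) <- NULL
  out
}
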