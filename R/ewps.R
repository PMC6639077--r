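#' Percent-identity ("PC") evolutionary weighting
#'
#' `w = 1 - pct_identity/100`: an ortholog identical to the reference
#' carries no weight, a fully diverged one carries weight 1.
#'
#' @param pct_identity Percent identity in `[0, 100]`.
#' @return Numeric weight in `[0, 1]`.
#' @export
weight_pc <- function(pct_identity) {
  if (any(pct_identity < 0 | pct_identity > 100)) {
    stop("pct_identity must be within [0, 100]")
  }
  1 - pct_identity / 100
}

#' Bitscore-ratio ("BS") evolutionary weighting
#'
#' `w = bitscore / self_bitscore`, the ortholog's bitscore against the
#' reference divided by the reference's self-alignment bitscore. Values
#' slightly above the self-bitscore are clamped with a warning.
#'
#' @param bitscore Bitscore of the ortholog vs the reference.
#' @param self_bitscore Self-alignment bitscore of the reference (> 0).
#' @return Numeric weight in `[0, 1]`.
#' @export
weight_bs <- function(bitscore, self_bitscore) {
  if (any(self_bitscore <= 0)) stop("self_bitscore must be positive")
  if (any(bitscore < 0)) stop("bitscore must be non-negative")
  over <- bitscore > self_bitscore
  if (any(over)) {
    warning("bitscore exceeds self_bitscore for ", sum(over),
            " ortholog(s); clamped to 1")
    bitscore[over] <- self_bitscore[if (length(self_bitscore) > 1) over else TRUE]
  }
  bitscore / self_bitscore
}

#' Evolutionarily weighted prion score (EWPS) of an ortholog family
#'
#' `EWPS = sum(w_i * P_i) / sum(w_i)` over the reference protein's
#' orthologs, where `P_i` is the i-th ortholog's (clamped, so possibly
#' zero) prion propensity score and `w_i` its evolutionary weight under the
#' PC or BS scheme. Zero scores are retained in the summation; the
#' reference itself is not a term. If the family has no orthologs, or the
#' weights sum to zero (e.g. all orthologs identical under PC), the EWPS is
#' undefined and the result is flagged.
#'
#' @param family An `ortholog_family` from [build_families()].
#' @param scores Numeric vector of prion propensity scores, one per
#'   ortholog, in family order (e.g. `prd_score` from [score_family()]
#'   minus its reference row).
#' @param scheme `"PC"` or `"BS"`.
#' @return Object of class `ewps_result`: `ref_id`, `scheme`, `ewps`
#'   (NA when undefined), `n`, `undefined`, `terms` (data.frame:
#'   `ortholog_id`, `P`, `w`).
#' @export
compute_ewps <- function(family, scores, scheme = c("PC", "BS")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(family, "ortholog_family"))
  orth <- family$orthologs
  if (length(scores) != nrow(orth)) {
    stop("got ", length(scores), " scores for ", nrow(orth), " orthologs")
  }
  if (any(scores < 0)) stop("prion propensity scores must be clamped at 0")
  if (nrow(orth) == 0L) {
    return(structure(list(ref_id = family$ref$id, scheme = scheme,
                          ewps = NA_real_, n = 0L, undefined = TRUE,
                          terms = data.frame(ortholog_id = character(),
                                             P = numeric(), w = numeric())),
                     class = "ewps_result"))
  }
  w <- switch(scheme,
              PC = weight_pc(orth$pct_identity),
              BS = weight_bs(orth$bitscore, orth$self_bitscore))
  terms <- data.frame(ortholog_id = orth$id, P = as.numeric(scores), w = w,
                      stringsAsFactors = FALSE)
  sw <- sum(w)
  if (sw <= 0) {
    return(structure(list(ref_id = family$ref$id, scheme = scheme,
                          ewps = NA_real_, n = nrow(orth), undefined = TRUE,
                          terms = terms),
                     class = "ewps_result"))
  }
  structure(list(ref_id = family$ref$id, scheme = scheme,
                 ewps = sum(w * scores) / sw, n = nrow(orth),
                 undefined = FALSE, terms = terms),
            class = "ewps_result")
}

#' @export
print.ewps_result <- function(x, ...) {
  cat("EWPS(", x$scheme, ") ", x$ref_id, ": ",
      if (x$undefined) "undefined" else format(x$ewps, digits = 5),
      " over ", x$n, " ortholog(s)\n", sep = "")
  invisible(x)
}

#' Compare PC- and BS-weighted EWPS results
#'
#' Per-protein absolute differences between the two weighting schemes plus
#' the Spearman rank correlation of the two score vectors; proteins with an
#' undefined EWPS under either scheme are excluded.
#'
#' @param results_pc,results_bs Lists of `ewps_result` objects over the
#'   same proteins (matched by `ref_id`).
#' @return List: `per_protein` (data.frame: `ref_id`, `ewps_pc`, `ewps_bs`,
#'   `delta`), `spearman_rho`, `n`.
#' @export
compare_schemes <- function(results_pc, results_bs) {
  tab <- function(rs) {
    data.frame(ref_id = vapply(rs, `[[`, character(1), "ref_id"),
               ewps = vapply(rs, `[[`, numeric(1), "ewps"),
               undefined = vapply(rs, `[[`, logical(1), "undefined"),
               stringsAsFactors = FALSE)
  }
  a <- tab(results_pc); b <- tab(results_bs)
  if (!setequal(a$ref_id, b$ref_id)) {
    stop("the two scheme result sets cover different proteins")
  }
  b <- b[match(a$ref_id, b$ref_id), ]
  keep <- !a$undefined & !b$undefined
  per <- data.frame(ref_id = a$ref_id[keep], ewps_pc = a$ewps[keep],
                    ewps_bs = b$ewps[keep],
                    delta = abs(a$ewps[keep] - b$ewps[keep]),
                    stringsAsFactors = FALSE)
  rho <- if (nrow(per) >= 3L) {
    suppressWarnings(cor(per$ewps_pc, per$ewps_bs, method = "spearman"))
  } else NA_real_
  list(per_protein = per, spearman_rho = rho, n = nrow(per))
}
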