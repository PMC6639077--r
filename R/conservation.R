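#' Per-column conservation of a multiple alignment
#'
#' Entropy-based conservation in the AL2CO style: per column, amino-acid
#' frequencies are estimated with unweighted counts over the non-gap
#' symbols, and the raw score is `S(i) = sum_a p_ia * ln(p_ia)` -- 0 for a
#' fully conserved column, increasingly negative with diversity. Columns
#' whose gap fraction exceeds `gap_mask` are masked. Raw scores over the
#' unmasked columns are then normalized to mean 0, SD 1.
#'
#' @param block An [alignment_block()] with at least 2 rows.
#' @param gap_mask Gap-fraction threshold above which a column is masked
#'   (default 0.5).
#' @return An object of class `conservation_profile`: `raw` (raw scores,
#'   NA where no residues), `normalized`, `masked` (logical), `n_rows`,
#'   `n_columns`.
#' @export
column_conservation <- function(block, gap_mask = 0.5) {
  n <- length(block$ids)
  if (n < 2L) stop("conservation needs an alignment with at least 2 rows")
  mat <- do.call(rbind, strsplit(block$seqs, "", fixed = TRUE))
  ncols <- ncol(mat)
  raw <- numeric(ncols)
  gapfrac <- numeric(ncols)
  for (j in seq_len(ncols)) {
    col <- mat[, j]
    res <- col[col != "-"]
    gapfrac[j] <- 1 - length(res) / n
    if (length(res) == 0L) {
      raw[j] <- NA_real_
      next
    }
    p <- tabulate(match(res, aa_alphabet()), nbins = length(aa_alphabet()))
    p <- p[p > 0] / length(res)
    raw[j] <- sum(p * log(p))
  }
  masked <- gapfrac > gap_mask | is.na(raw)
  usable <- raw[!masked]
  if (length(usable) == 0L) stop("all columns masked; cannot normalize")
  mu <- mean(usable)
  sdev <- sd(usable)
  if (length(usable) < 2L || sdev == 0 || is.na(sdev)) {
    warning("zero variance across unmasked columns; normalized scores set to 0")
    normalized <- ifelse(masked, NA_real_, 0)
    sdev <- 0
  } else {
    normalized <- (raw - mu) / sdev
    normalized[masked] <- NA_real_
  }
  structure(list(raw = raw, normalized = normalized, masked = masked,
                 gap_fraction = gapfrac, n_rows = n, n_columns = ncols),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation_profile: ", x$n_columns, " columns (",
      sum(x$masked), " masked), ", x$n_rows, " rows\n", sep = "")
  invisible(x)
}

#' Mean conservation over a set of alignment columns
#'
#' Arithmetic mean and SD of the normalized column scores over the unmasked
#' columns of the set (typically the columns of a prion-like domain from
#' [map_domain_to_columns()], or all columns for a whole-sequence mean).
#' If every requested column is masked the result is flagged undefined and
#' should be excluded from downstream statistics.
#'
#' @param profile A [column_conservation()] result.
#' @param domain_columns 1-based column indices (default: all columns).
#' @return List: `mean`, `sd`, `n_used` (unmasked columns used),
#'   `undefined`.
#' @export
domain_mean_conservation <- function(profile, domain_columns = NULL) {
  if (is.null(domain_columns)) domain_columns <- seq_len(profile$n_columns)
  domain_columns <- as.integer(domain_columns)
  if (any(domain_columns < 1L | domain_columns > profile$n_columns)) {
    stop("domain columns outside the profile")
  }
  vals <- profile$normalized[domain_columns]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, n_used = 0L, undefined = TRUE))
  }
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
       n_used = length(vals), undefined = FALSE)
}

#' Conservation profile as a per-column table
#'
#' @param profile A [column_conservation()] result.
#' @return `data.frame`: `column`, `raw`, `normalized`, `masked`.
#' @export
conservation_table <- function(profile) {
  data.frame(column = seq_len(profile$n_columns), raw = profile$raw,
             normalized = profile$normalized, masked = profile$masked)
}
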