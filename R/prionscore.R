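#' Frequency tables for the prion-likeness scorer
#'
#' The scorer compares each residue's frequency in prion-forming domains
#' against a proteome background; the per-residue log-odds
#' `ln(prion/background)` drive both the HMM decoding and all scores.
#' Tables must cover the 20 canonical residues with strictly positive
#' probabilities (a small pseudocount is applied before normalization). X
#' carries log-odds 0, contributing nothing in either direction.
#'
#' @param prion Named numeric vector: residue -> probability in
#'   prion-forming domains.
#' @param background Named numeric vector: residue -> background
#'   probability.
#' @param pseudocount Added to every entry before renormalization.
#' @return Object of class `frequency_tables` with elements `prion`,
#'   `background` and `log_odds` (length 21, X last, log-odds 0 for X).
#' @export
frequency_tables <- function(prion, background, pseudocount = 1e-4) {
  canon <- aa_alphabet()[1:20]
  for (nm in c("prion", "background")) {
    v <- get(nm)
    if (!all(canon %in% names(v))) {
      stop("'", nm, "' table must name all 20 canonical residues")
    }
    if (any(v < 0)) stop("'", nm, "' table has negative entries")
  }
  prion <- prion[canon] + pseudocount
  prion <- prion / sum(prion)
  background <- background[canon] + pseudocount
  background <- background / sum(background)
  lo <- c(log(prion / background), X = 0)
  structure(list(prion = prion, background = background, log_odds = lo),
            class = "frequency_tables")
}

#' Read a two-column frequency table (residue TAB probability)
#'
#' @param path Path to the TSV (header row: `residue`, `probability`).
#' @return Named numeric vector.
#' @export
read_frequency_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "probability") %in% names(tab))) {
    stop("frequency table needs 'residue' and 'probability' columns")
  }
  setNames(tab$probability, tab$residue)
}

#' Default frequency tables shipped with the package
#'
#' The prion-domain table approximates the N/Q-biased amino-acid
#' composition of the experimentally characterized yeast prion-forming
#' domains, and the background table approximates the overall
#' S. cerevisiae proteome composition. Both are reconstructions assembled
#' for this package (hence the `_synthetic` file names), not files
#' redistributed from any scorer; substitute your own tables via
#' [frequency_tables()] for strict fidelity to a particular predictor.
#'
#' @return A [frequency_tables()] object.
#' @export
default_frequency_tables <- function() {
  if (is.null(.pkg_env$default_tables)) {
    pr <- read_frequency_table(system.file(
      "extdata", "prion_domain_freqs_synthetic.tsv", package = "prionevo"))
    bg <- read_frequency_table(system.file(
      "extdata", "background_freqs_synthetic.tsv", package = "prionevo"))
    .pkg_env$default_tables <- frequency_tables(pr, bg)
  }
  .pkg_env$default_tables
}

seq_log_odds <- function(seq, tables) {
  unname(tables$log_odds[encode_seq(seq) + 1L])
}

#' Scan for the best-scoring fixed-length window (LLR)
#'
#' Exhaustive scan of all windows of the given length; the maximum window
#' log-odds sum is the LLR. Ties are broken by the smallest start. A
#' sequence shorter than the window is scored as one full-length window.
#'
#' @param seq Protein record or sequence string.
#' @param tables [frequency_tables()].
#' @param window Window length (default 60).
#' @return List: `llr` (max window score), `start` (1-based).
#' @export
llr_window_scan <- function(seq, tables = default_frequency_tables(),
                            window = 60L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  rec <- as_record(seq, "seq")
  lo <- seq_log_odds(rec$seq, tables)
  L <- length(lo)
  if (L <= window) {
    return(list(llr = sum(lo), start = 1L))
  }
  cs <- c(0, cumsum(lo))
  sums <- cs[(window + 1L):(L + 1L)] - cs[1L:(L - window + 1L)]
  best <- max(sums)
  # earliest start among ties (to within accumulated rounding)
  start <- which(sums >= best - 1e-9)[1L]
  list(llr = best, start = start)
}

# Viterbi decoding of the two-state composition HMM with a minimum
# prion-state run length enforced by a chain of `core` prion sub-states.
# Emissions are rescaled by the background, so the background state emits 0
# and the prion states emit the per-residue log-odds.
viterbi_prion <- function(lo, core, p_enter, p_exit) {
  L <- length(lo)
  lBB <- log1p(-p_enter); lBP <- log(p_enter)
  lPP <- log1p(-p_exit); lPB <- log(p_exit)
  nst <- core + 1L                      # 1 = background, 2..nst = chain
  v <- c(0, rep(-Inf, core))
  from_chain_B <- logical(L)            # B reached from chain end (exit)?
  self_loop_C <- logical(L)             # chain end reached by self-loop?
  if (L == 0L) return(logical(0))
  for (t in seq_len(L)) {
    new <- rep(-Inf, nst)
    # background
    stay <- v[1L] + lBB
    exitc <- v[nst] + lPB
    from_chain_B[t] <- exitc > stay
    new[1L] <- max(stay, exitc)
    if (core == 1L) {
      enter <- v[1L] + lBP
      self <- v[2L] + lPP
      self_loop_C[t] <- self > enter
      new[2L] <- max(enter, self) + lo[t]
    } else {
      new[2L] <- v[1L] + lBP + lo[t]
      if (core > 2L) new[3L:(nst - 1L)] <- v[2L:(nst - 2L)] + lo[t]
      advance <- v[nst - 1L]
      self <- v[nst] + lPP
      self_loop_C[t] <- self > advance
      new[nst] <- max(advance, self) + lo[t]
    }
    v <- new
  }
  # end in background or at the chain end only (a mid-chain end would mean
  # a decoded run shorter than the core length)
  end_state <- if (v[1L] >= v[nst]) 1L else nst
  prion <- logical(L)
  st <- end_state
  for (t in rev(seq_len(L))) {
    if (st == 1L) {
      prion[t] <- FALSE
      st <- if (from_chain_B[t]) nst else 1L
    } else if (st == nst) {
      prion[t] <- TRUE
      st <- if (core == 1L) {
        if (self_loop_C[t]) nst else 1L
      } else {
        if (self_loop_C[t]) nst else nst - 1L
      }
    } else {
      prion[t] <- TRUE
      st <- if (st == 2L) 1L else st - 1L
    }
  }
  prion
}

#' Prion-likeness score of one sequence
#'
#' Scores a sequence with a two-state composition hidden Markov model
#' (background vs prion-like) whose prion state has a minimum run length of
#' `core_length` residues. The Viterbi parse yields the predicted
#' prion-domain interval; the PRD score is the sum of per-residue log-odds
#' over all decoded prion-state residues, clamped at zero. The LLR is the
#' best `core_length`-window log-odds sum ([llr_window_scan()]). For the
#' reference organism's own protein the clamped PRD score is the SCPS.
#'
#' @param seq Protein record or sequence string.
#' @param tables [frequency_tables()].
#' @param core_length Minimum prion-state run length (default 60).
#' @param p_enter,p_exit HMM transition probabilities into / out of the
#'   prion state; the default `1/core_length` exit makes the expected
#'   prion-state run equal the core length.
#' @return Object of class `prion_score`: `prd_score` (clamped at 0),
#'   `unclamped`, `llr`, `llr_start`, `domain_interval` (1-based inclusive
#'   or NULL).
#' @export
score_sequence <- function(seq, tables = default_frequency_tables(),
                           core_length = 60L,
                           p_enter = 1 / core_length,
                           p_exit = 1 / core_length) {
  core_length <- as.integer(core_length)
  stopifnot(core_length >= 1L, p_enter > 0, p_enter < 1, p_exit > 0, p_exit < 1)
  rec <- as_record(seq, "seq")
  lo <- seq_log_odds(rec$seq, tables)
  prion <- viterbi_prion(lo, core_length, p_enter, p_exit)
  unclamped <- sum(lo[prion])
  interval <- NULL
  if (any(prion) && unclamped > 0) {
    r <- rle(prion)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    run_scores <- vapply(runs, function(k) sum(lo[starts[k]:ends[k]]), numeric(1))
    best <- runs[which.max(run_scores)]
    interval <- c(starts[best], ends[best])
  }
  scan <- llr_window_scan(rec$seq, tables, core_length)
  structure(list(
    id = rec$id,
    prd_score = max(unclamped, 0),
    unclamped = unclamped,
    llr = scan$llr, llr_start = scan$start,
    domain_interval = interval
  ), class = "prion_score")
}

#' @export
print.prion_score <- function(x, ...) {
  cat("prion_score ", x$id, ": PRD = ", format(x$prd_score, digits = 4),
      ", LLR = ", format(x$llr, digits = 4), sep = "")
  if (!is.null(x$domain_interval)) {
    cat(", domain ", x$domain_interval[1L], "-", x$domain_interval[2L], sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Prion-likeness scores for a whole protein table
#'
#' @param proteins Protein table ([read_fasta()] format).
#' @inheritParams score_sequence
#' @return `data.frame`: `id`, `species`, `prd_score`, `llr`,
#'   `domain_start`, `domain_end` (NA when no domain).
#' @export
score_proteome <- function(proteins, tables = default_frequency_tables(),
                           core_length = 60L,
                           p_enter = 1 / core_length,
                           p_exit = 1 / core_length) {
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- score_sequence(proteins[i, ], tables, core_length, p_enter, p_exit)
    data.frame(id = proteins$id[i],
               species = if ("species" %in% names(proteins)) proteins$species[i] else NA,
               prd_score = s$prd_score, llr = s$llr,
               domain_start = if (is.null(s$domain_interval)) NA_integer_ else s$domain_interval[1L],
               domain_end = if (is.null(s$domain_interval)) NA_integer_ else s$domain_interval[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Prion-likeness scores for an ortholog family
#'
#' Scores the reference and every ortholog on their ungapped sequences
#' (alignment-independent), in family order (reference first).
#'
#' @param family An `ortholog_family` from [build_families()].
#' @inheritParams score_sequence
#' @return `data.frame` as in [score_proteome()].
#' @export
score_family <- function(family, tables = default_frequency_tables(),
                         core_length = 60L,
                         p_enter = 1 / core_length,
                         p_exit = 1 / core_length) {
  stopifnot(inherits(family, "ortholog_family"))
  tab <- data.frame(
    id = c(family$ref$id, family$orthologs$id),
    species = c(family$ref$species, family$orthologs$species),
    seq = c(family$ref$seq, family$orthologs$seq),
    stringsAsFactors = FALSE)
  score_proteome(tab, tables, core_length, p_enter, p_exit)
}
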