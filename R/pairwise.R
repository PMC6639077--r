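#' Default pairwise alignment parameters
#'
#' Exact Smith--Waterman with BLOSUM62, affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_ext`), and ungapped Karlin--Altschul
#' parameters for the bitscore / E-value conversion. The defaults reproduce
#' BLASTP's defaults (BLOSUM62, open 11, extend 1, lambda = 0.267,
#' K = 0.041). E-values use `K * m * n * exp(-lambda * S)` with `m`, `n` the
#' two sequence lengths.
#'
#' @param gap_open Gap opening penalty.
#' @param gap_ext Gap extension penalty (per residue).
#' @param lambda Karlin--Altschul lambda (per raw-score unit).
#' @param K Karlin--Altschul K.
#' @return A list of alignment parameters.
#' @export
align_params <- function(gap_open = 11L, gap_ext = 1L,
                         lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= 0, gap_ext >= 0, lambda > 0, K > 0)
  list(gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
       lambda = lambda, K = K)
}

raw_to_bitscore <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

raw_to_evalue <- function(raw, m, n, params) {
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * raw)
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith--Waterman under BLOSUM62 with affine gaps. Percent identity
#' is computed over aligned columns in which both sequences carry a residue
#' (gap columns excluded from the denominator); `aligned_length` counts all
#' alignment columns including gaps. A pair with no positive-scoring cell
#' yields the empty alignment: raw score 0, identity 0, aligned length 0.
#'
#' @param a,b Protein records (one-row data.frames with `id` and `seq`) or
#'   plain sequence strings.
#' @param params [align_params()].
#' @return A list of class `pairwise_hit`: `query_id`, `subject_id`,
#'   `raw_score`, `bitscore`, `evalue`, `pct_identity`, `aligned_length`,
#'   `n_identical`.
#' @export
local_align <- function(a, b, params = align_params()) {
  a <- as_record(a, "a"); b <- as_record(b, "b")
  if (nchar(a$seq) < 2L || nchar(b$seq) < 2L) {
    stop("sequences must have at least 2 residues")
  }
  ea <- encode_seq(a$seq); eb <- encode_seq(b$seq)
  tb <- .sw_traceback(ea, eb, blosum62(), params$gap_open, params$gap_ext)
  apos <- tb$a_pos; bpos <- tb$b_pos
  both <- apos >= 0L & bpos >= 0L
  nid <- sum(ea[apos[both] + 1L] == eb[bpos[both] + 1L])
  nalncol <- sum(both)
  pid <- if (nalncol > 0L) 100 * nid / nalncol else 0
  structure(list(
    query_id = a$id, subject_id = b$id,
    raw_score = tb$score,
    bitscore = raw_to_bitscore(tb$score, params),
    evalue = raw_to_evalue(tb$score, nchar(a$seq), nchar(b$seq), params),
    pct_identity = pid,
    aligned_length = length(apos),
    n_identical = nid
  ), class = "pairwise_hit")
}

as_record <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    return(list(id = what, seq = toupper(x)))
  }
  if (is.data.frame(x) && nrow(x) == 1L) return(list(id = x$id, seq = x$seq))
  if (is.list(x) && !is.null(x$seq)) return(list(id = x$id, seq = x$seq))
  stop("cannot interpret '", what, "' as a protein record")
}

#' Smith--Waterman raw-score matrix between two proteomes
#'
#' Score-only alignment of every query against every subject; the workhorse
#' behind [best_hits()] and [bdbh()].
#'
#' @param queries,subjects Protein tables ([read_fasta()] format).
#' @param params [align_params()].
#' @return Integer matrix of raw scores, rows = queries, cols = subjects,
#'   dimnames = ids.
#' @export
sw_score_matrix <- function(queries, subjects, params = align_params()) {
  qenc <- lapply(queries$seq, encode_seq)
  senc <- lapply(subjects$seq, encode_seq)
  m <- .sw_score_matrix(qenc, senc, blosum62(), params$gap_open, params$gap_ext)
  dimnames(m) <- list(queries$id, subjects$id)
  m
}

# Raw self-alignment score: the Smith-Waterman score of a sequence against
# itself is the sum of its diagonal BLOSUM62 entries (all positive).
self_score <- function(seq) {
  e <- encode_seq(seq)
  sum(blosum62()[cbind(e + 1L, e + 1L)])
}

#' Best hit per query in a subject proteome
#'
#' For each query, the subject with maximal bitscore among hits with
#' `evalue <= evalue_max`. Bitscore ties are broken by higher percent
#' identity, then lexicographically smaller subject id. Queries with no
#' qualifying hit are absent from the result.
#'
#' @param queries,subjects Protein tables.
#' @param evalue_max E-value threshold (default 0.001).
#' @param params [align_params()].
#' @param score_matrix Optional precomputed [sw_score_matrix()] (rows =
#'   queries, cols = subjects) to avoid recomputation.
#' @return `data.frame` with columns `query_id`, `subject_id`, `raw_score`,
#'   `bitscore`, `evalue`.
#' @export
best_hits <- function(queries, subjects, evalue_max = 0.001,
                      params = align_params(), score_matrix = NULL) {
  stopifnot(nrow(queries) > 0L, nrow(subjects) > 0L)
  if (is.null(score_matrix)) {
    score_matrix <- sw_score_matrix(queries, subjects, params)
  }
  qlen <- nchar(queries$seq); slen <- nchar(subjects$seq)
  out <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    raw <- score_matrix[i, ]
    ev <- raw_to_evalue(raw, qlen[i], slen, params)
    ok <- which(ev <= evalue_max)
    if (length(ok) == 0L) next
    best_raw <- max(raw[ok])
    cand <- ok[raw[ok] == best_raw]
    if (length(cand) > 1L) {
      pid <- vapply(cand, function(j) {
        local_align(queries[i, ], subjects[j, ], params)$pct_identity
      }, numeric(1))
      cand <- cand[order(-pid, subjects$id[cand])]
    }
    j <- cand[1L]
    out[[i]] <- data.frame(
      query_id = queries$id[i], subject_id = subjects$id[j],
      raw_score = raw[j],
      bitscore = raw_to_bitscore(raw[j], params),
      evalue = ev[j], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), bitscore = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Read tabular alignment hits (BLAST outfmt-6 layout)
#'
#' Alternative to the built-in aligner: ingest precomputed pairwise hits in
#' the standard 12-column tabular layout (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#'
#' @param path Path to the TSV (no header).
#' @return `data.frame` with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) stop("expected 12 tab-separated columns, got ", ncol(tab))
  names(tab) <- cols
  tab
}
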