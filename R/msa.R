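# Internal alignment representation during progressive alignment: an
# integer matrix, rows = sequences, columns = alignment columns, entries
# 0-based indices into aa_alphabet(), -1 for gap.

seq_to_row <- function(seq) matrix(encode_seq(seq), nrow = 1L)

matrix_to_block <- function(mat, ids) {
  alpha <- c(aa_alphabet(), "-")
  seqs <- apply(mat, 1L, function(r) {
    r[r < 0L] <- length(alpha) - 1L
    paste(alpha[r + 1L], collapse = "")
  })
  alignment_block(ids, seqs)
}

merge_alignments <- function(A, B, params) {
  p <- .nw_profile(A, B, blosum62() * 1.0,
                   as.numeric(params$gap_open), as.numeric(params$gap_ext))
  ncolo <- length(p$a_col)
  out <- matrix(-1L, nrow = nrow(A) + nrow(B), ncol = ncolo)
  ka <- p$a_col >= 0L
  out[seq_len(nrow(A)), ka] <- A[, p$a_col[ka] + 1L, drop = FALSE]
  kb <- p$b_col >= 0L
  out[nrow(A) + seq_len(nrow(B)), kb] <- B[, p$b_col[kb] + 1L, drop = FALSE]
  out
}

#' Global pairwise alignment of two sequences
#'
#' Needleman--Wunsch with BLOSUM62 and affine gaps (ends penalized); the
#' single-sequence case of the progressive profile aligner.
#'
#' @param a,b Protein records or sequence strings.
#' @param params [align_params()].
#' @return An [alignment_block()] with two rows.
#' @export
global_align <- function(a, b, params = align_params()) {
  a <- as_record(a, "a"); b <- as_record(b, "b")
  m <- merge_alignments(seq_to_row(a$seq), seq_to_row(b$seq), params)
  matrix_to_block(m, c(a$id, b$id))
}

#' Progressive multiple alignment of an ortholog family
#'
#' Aligns the reference and its orthologs with a progressive profile
#' aligner: all-pairs local-alignment identities give distances
#' `1 - pid/100`, a UPGMA guide tree orders the merges, and each merge is a
#' global profile--profile Needleman--Wunsch under BLOSUM62 with affine
#' gaps. Column frequencies are counts over all profile rows (gaps
#' contribute nothing). For a two-member family the result equals the
#' global pairwise alignment of the two sequences. Externally computed
#' alignments can be used instead via [read_aligned_fasta()].
#'
#' @param family An `ortholog_family` from [build_families()], or a protein
#'   table (data.frame with `id`, `seq`) to align directly.
#' @param params [align_params()].
#' @return An [alignment_block()]; rows in input order (reference first for
#'   a family). A single-member family yields a one-row block with a
#'   warning.
#' @export
progressive_align <- function(family, params = align_params()) {
  if (inherits(family, "ortholog_family")) {
    ids <- c(family$ref$id, family$orthologs$id)
    seqs <- c(family$ref$seq, family$orthologs$seq)
  } else {
    stopifnot(is.data.frame(family), all(c("id", "seq") %in% names(family)))
    ids <- family$id; seqs <- family$seq
  }
  n <- length(ids)
  if (n == 0L) stop("empty family")
  if (n == 1L) {
    warning("single-sequence family '", ids, "': trivial alignment")
    return(alignment_block(ids, seqs))
  }
  if (n == 2L) {
    A <- merge_alignments(seq_to_row(seqs[1L]), seq_to_row(seqs[2L]), params)
    return(matrix_to_block(A, ids))
  }
  # UPGMA guide tree on 1 - pid/100
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pid <- local_align(list(id = ids[i], seq = seqs[i]),
                         list(id = ids[j], seq = seqs[j]), params)$pct_identity
      d[i, j] <- d[j, i] <- 1 - pid / 100
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  clusters <- lapply(seq_len(n), function(i) {
    list(mat = seq_to_row(seqs[i]), ids = ids[i])
  })
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) clusters[[-x]] else merged[[x]]
    a <- pick(hc$merge[k, 1L]); b <- pick(hc$merge[k, 2L])
    merged[[k]] <- list(mat = merge_alignments(a$mat, b$mat, params),
                        ids = c(a$ids, b$ids))
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- match(ids, final$ids)
  matrix_to_block(final$mat[ord, , drop = FALSE], ids)
}

#' Map an ungapped reference domain interval to alignment columns
#'
#' Returns the alignment columns in which the reference row carries the
#' residues `domain_start .. domain_end` (1-based inclusive, ungapped
#' reference coordinates). Exactly `domain_end - domain_start + 1` strictly
#' increasing column indices are returned.
#'
#' @param block An [alignment_block()].
#' @param ref_id Identifier of the reference row.
#' @param domain_interval Length-2 integer vector `c(start, end)`.
#' @return Integer vector of 1-based column indices.
#' @export
map_domain_to_columns <- function(block, ref_id, domain_interval) {
  stopifnot(length(domain_interval) == 2L)
  start <- as.integer(domain_interval[1L]); end <- as.integer(domain_interval[2L])
  if (start < 1L || end < start) stop("invalid domain interval")
  i <- match(ref_id, block$ids)
  if (is.na(i)) stop("no row with id ", ref_id)
  chars <- strsplit(block$seqs[i], "", fixed = TRUE)[[1]]
  residue <- cumsum(chars != "-")
  reflen <- residue[length(residue)]
  if (end > reflen) {
    stop("domain interval [", start, ",", end, "] exceeds reference length ", reflen)
  }
  which(chars != "-" & residue >= start & residue <= end)
}
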