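#' Bidirectional best hits between two proteomes
#'
#' A pair (r, s) is reported iff s is r's best hit in `other` and r is s's
#' best hit in `reference`, both with E-value at or below `evalue_max`.
#' Raw Smith--Waterman scores are symmetric, so a single score matrix
#' serves both directions.
#'
#' @param reference,other Protein tables ([read_fasta()] format), from two
#'   different species.
#' @param evalue_max E-value threshold (default 0.001).
#' @param params [align_params()].
#' @param score_matrix Optional precomputed [sw_score_matrix()]
#'   (rows = reference, cols = other).
#' @return `data.frame` with columns `ref_id`, `other_id`, `raw_score`,
#'   `bitscore`, `evalue`.
#' @export
bdbh <- function(reference, other, evalue_max = 0.001,
                 params = align_params(), score_matrix = NULL) {
  stopifnot(nrow(reference) > 0L, nrow(other) > 0L)
  if (is.null(score_matrix)) {
    score_matrix <- sw_score_matrix(reference, other, params)
  }
  fwd <- best_hits(reference, other, evalue_max, params, score_matrix)
  rev <- best_hits(other, reference, evalue_max, params, t(score_matrix))
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    return(data.frame(ref_id = character(), other_id = character(),
                      raw_score = numeric(), bitscore = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  key_f <- paste(fwd$query_id, fwd$subject_id, sep = "\r")
  key_r <- paste(rev$subject_id, rev$query_id, sep = "\r")
  keep <- fwd[key_f %in% key_r, , drop = FALSE]
  names(keep)[names(keep) == "query_id"] <- "ref_id"
  names(keep)[names(keep) == "subject_id"] <- "other_id"
  rownames(keep) <- NULL
  keep
}

#' Build ortholog families for reference proteins at one taxonomic level
#'
#' Runs whole-proteome BDBH between the reference species and every other
#' species of the level, then assembles, per reference protein, the family
#' of its orthologs with the pairwise metadata downstream stages need
#' (percent identity, bitscore against the reference, and the reference's
#' self-bitscore). Each species contributes at most one ortholog. Families
#' with zero orthologs are retained with `flagged = TRUE` (the EWPS is
#' undefined for them).
#'
#' @param reference_ids Accessions of the reference proteins to track.
#' @param proteomes Named list of protein tables, one per species.
#' @param level Character vector of species in the level (must include
#'   `ref_species`).
#' @param ref_species Name of the reference species in `proteomes`.
#' @param evalue_max E-value threshold for BDBH.
#' @param params [align_params()].
#' @return List of `ortholog_family` objects, one per reference id, each
#'   with elements `ref` (id, species, seq), `level_species`, `orthologs`
#'   (data.frame: id, species, seq, pct_identity, bitscore, self_bitscore)
#'   and `flagged`.
#' @export
build_families <- function(reference_ids, proteomes, level, ref_species,
                           evalue_max = 0.001, params = align_params()) {
  stopifnot(ref_species %in% names(proteomes), all(level %in% names(proteomes)))
  ref_tab <- proteomes[[ref_species]]
  missing <- setdiff(reference_ids, ref_tab$id)
  if (length(missing)) {
    stop("reference ids absent from the reference proteome: ",
         paste(missing, collapse = ", "))
  }
  others <- setdiff(level, ref_species)
  # one BDBH pass per species, shared by all families
  hits_by_species <- lapply(others, function(sp) {
    bdbh(ref_tab, proteomes[[sp]], evalue_max, params)
  })
  names(hits_by_species) <- others

  self_bits <- setNames(
    raw_to_bitscore(vapply(ref_tab$seq, self_score, numeric(1)), params),
    ref_tab$id)

  lapply(reference_ids, function(rid) {
    ref_row <- ref_tab[ref_tab$id == rid, ]
    orth <- list()
    for (sp in others) {
      h <- hits_by_species[[sp]]
      k <- which(h$ref_id == rid)
      if (length(k) == 0L) next
      orow <- proteomes[[sp]][proteomes[[sp]]$id == h$other_id[k], ]
      la <- local_align(ref_row, orow, params)
      orth[[sp]] <- data.frame(
        id = orow$id, species = sp, seq = orow$seq,
        pct_identity = la$pct_identity,
        bitscore = la$bitscore,
        self_bitscore = unname(self_bits[rid]),
        stringsAsFactors = FALSE)
    }
    orth <- if (length(orth)) do.call(rbind, orth) else
      data.frame(id = character(), species = character(), seq = character(),
                 pct_identity = numeric(), bitscore = numeric(),
                 self_bitscore = numeric(), stringsAsFactors = FALSE)
    rownames(orth) <- NULL
    structure(list(
      ref = list(id = rid, species = ref_species, seq = ref_row$seq),
      level_species = level,
      orthologs = orth,
      flagged = nrow(orth) == 0L
    ), class = "ortholog_family")
  })
}

#' @export
print.ortholog_family <- function(x, ...) {
  cat("ortholog_family: ", x$ref$id, " (", x$ref$species, "), ",
      nrow(x$orthologs), " ortholog(s)",
      if (x$flagged) " [flagged: empty]", "\n", sep = "")
  invisible(x)
}

#' Serialize ortholog families as a TSV table
#'
#' @param families List of `ortholog_family` objects.
#' @return `data.frame` with one row per (family, ortholog): `ref_id`,
#'   `species`, `ortholog_id`, `pct_identity`, `bitscore`, `self_bitscore`.
#' @export
families_table <- function(families) {
  rows <- lapply(families, function(f) {
    if (nrow(f$orthologs) == 0L) return(NULL)
    data.frame(ref_id = f$ref$id, species = f$orthologs$species,
               ortholog_id = f$orthologs$id,
               pct_identity = f$orthologs$pct_identity,
               bitscore = f$orthologs$bitscore,
               self_bitscore = f$orthologs$self_bitscore,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ref_id = character(), species = character(),
                      ortholog_id = character(), pct_identity = numeric(),
                      bitscore = numeric(), self_bitscore = numeric())
  }
  rownames(out) <- NULL
  out
}
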