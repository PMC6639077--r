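#' Read a protein FASTA file
#'
#' Parses a FASTA file into a protein table: one row per entry, in file
#' order. The identifier is the first whitespace-delimited token of the
#' description line; the full description line is retained verbatim.
#' Sequences are upper-cased. The ambiguity codes B, Z, U, O and J are mapped
#' to X with a warning (`nonstandard = "map"`, the default) or rejected
#' (`nonstandard = "error"`); any other non-alphabet letter is always an
#' error.
#'
#' @param path Path to a FASTA file.
#' @param species Species/proteome tag stored with every record (default:
#'   file name without extension).
#' @param nonstandard `"map"` or `"error"`; treatment of ambiguity codes.
#' @return A `data.frame` with columns `id`, `species`, `desc`, `seq`.
#' @export
read_fasta <- function(path, species = NULL,
                       nonstandard = c("map", "error")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  desc <- names(set)
  id <- vapply(strsplit(desc, "[ \t]+"), `[`, character(1), 1L)
  if (any(!nzchar(id)) || anyNA(id)) stop("FASTA entry with empty identifier in ", path)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate FASTA identifiers in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- clean_protein_seq(seqs, nonstandard)
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in ", path)
  if (is.null(species)) {
    species <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  }
  data.frame(id = id, species = species, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

clean_protein_seq <- function(seqs, nonstandard = "map") {
  amb <- aa_ambiguous()
  has_amb <- grepl(paste0("[", paste(amb, collapse = ""), "]"), seqs)
  if (any(has_amb)) {
    if (nonstandard == "error") {
      stop("ambiguity codes (", paste(amb, collapse = ","),
           ") present and nonstandard = \"error\"")
    }
    warning(sum(has_amb), " sequence(s) contain ambiguity codes ",
            paste(amb, collapse = "/"), "; mapped to X")
    seqs <- chartr(paste(amb, collapse = ""),
                   strrep("X", length(amb)), seqs)
  }
  ok <- paste0("^[", paste(aa_alphabet(), collapse = ""), "]*$")
  bad <- !grepl(ok, seqs)
  if (any(bad)) {
    letters_found <- unique(unlist(strsplit(seqs[bad], "")))
    letters_found <- setdiff(letters_found, aa_alphabet())
    stop("non-amino-acid letters in input: ", paste(letters_found, collapse = ", "))
  }
  seqs
}

#' Write a protein table to FASTA
#'
#' @param proteins A protein table as returned by [read_fasta()]; the `desc`
#'   column, if present, is used as the description line, otherwise `id`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(is.data.frame(proteins), all(c("id", "seq") %in% names(proteins)))
  nm <- if ("desc" %in% names(proteins)) proteins$desc else proteins$id
  set <- Biostrings::BStringSet(setNames(proteins$seq, nm))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Alignment block
#'
#' A multiple alignment held as equal-length gapped rows. `'.'` gap
#' characters are converted to `'-'`; rows are validated for equal length.
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Character vector of gapped sequences (same length as `ids`).
#' @return An object of class `alignment_block` with elements `ids`, `seqs`
#'   and `ncol`.
#' @export
alignment_block <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  if (anyDuplicated(ids)) stop("duplicate row ids in alignment")
  seqs <- chartr(".", "-", toupper(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])
    stop("ragged alignment rows: ", paste(sprintf("%s (%d)", ids[off], lens[off]),
                                          collapse = ", "),
         " vs ", ids[1L], " (", lens[1L], ")")
  }
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 ncol = lens[1L]),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("alignment_block: ", length(x$ids), " rows x ", x$ncol, " columns\n", sep = "")
  show <- head(seq_along(x$ids), 6L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], s))
  }
  if (length(x$ids) > 6L) cat("  ...\n")
  invisible(x)
}

#' Remove gaps from one alignment row
#'
#' @param block An `alignment_block`.
#' @param id Row identifier.
#' @return The ungapped sequence string.
#' @export
ungap_row <- function(block, id) {
  i <- match(id, block$ids)
  if (is.na(i)) stop("no row with id ", id)
  gsub("-", "", block$seqs[i], fixed = TRUE)
}

#' Read a gapped (aligned) FASTA file
#'
#' @param path Path to an aligned FASTA file; `'-'` (or `'.'`) marks gaps.
#' @return An [alignment_block()].
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  alignment_block(ids, as.character(set))
}

#' Write an alignment block as gapped FASTA
#'
#' @param block An [alignment_block()].
#' @param path Output path.
#' @export
write_aligned_fasta <- function(block, path) {
  set <- Biostrings::BStringSet(setNames(block$seqs, block$ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Load the species-to-level membership table
#'
#' Reads a TSV with a `species` column and one 0/1 flag column per
#' taxonomic level (e.g. `genus`, `wgd`, `class`). Levels may be declared
#' nested, in which case every species flagged at a narrower level must also
#' be flagged at every broader one (broader = more species).
#'
#' @param path Path to the TSV.
#' @param proteomes Optional character vector of available proteome/species
#'   names; species in the table but not in `proteomes` trigger a warning.
#' @param nested Validate nesting (default `TRUE`).
#' @return Named list: level name -> character vector of species.
#' @export
load_level_table <- function(path, proteomes = NULL, nested = TRUE) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(tab)) stop("level table needs a 'species' column")
  level_cols <- setdiff(names(tab), "species")
  if (length(level_cols) == 0L) stop("level table has no level columns")
  levels <- lapply(level_cols, function(cn) tab$species[tab[[cn]] %in% c(1, "1", TRUE)])
  names(levels) <- level_cols
  empty <- names(levels)[lengths(levels) == 0L]
  if (length(empty)) stop("empty level(s): ", paste(empty, collapse = ", "))
  if (!is.null(proteomes)) {
    missing <- setdiff(unique(unlist(levels)), proteomes)
    if (length(missing)) {
      warning("species in level table without a proteome: ",
              paste(missing, collapse = ", "))
    }
  }
  if (nested) {
    ord <- order(lengths(levels))  # narrowest first
    for (k in seq_len(length(ord) - 1L)) {
      inner <- levels[[ord[k]]]; outer <- levels[[ord[k + 1L]]]
      extra <- setdiff(inner, outer)
      if (length(extra)) {
        stop("level nesting violated: species ", paste(extra, collapse = ", "),
             " in '", names(levels)[ord[k]], "' but not in '",
             names(levels)[ord[k + 1L]], "'")
      }
    }
  }
  levels
}

#' Load the reference protein-set table
#'
#' Reads a TSV assigning reference accessions to the KP (known prion),
#' PFP (prion-forming) or PLP (prion-like) category, with optional
#' experimentally determined domain boundaries (1-based inclusive, ungapped
#' reference coordinates). KP rows are part of the PFP set by definition;
#' [set_members()] resolves category labels into analysis sets.
#'
#' @param path Path to a TSV with columns `accession`, `category` and
#'   optionally `domain_start`, `domain_end`.
#' @return A `data.frame` with columns `accession`, `category`,
#'   `domain_start`, `domain_end` (NA when absent).
#' @export
load_protein_sets <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "category")
  if (!all(need %in% names(tab))) {
    stop("protein-set table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(tab$category %in% c("KP", "PFP", "PLP"))) {
    stop("category must be one of KP, PFP, PLP")
  }
  if (anyDuplicated(tab$accession)) stop("duplicate accessions in protein-set table")
  for (cn in c("domain_start", "domain_end")) {
    if (!cn %in% names(tab)) tab[[cn]] <- NA_integer_
    tab[[cn]] <- as.integer(tab[[cn]])
  }
  has <- !is.na(tab$domain_start) | !is.na(tab$domain_end)
  bad <- has & (is.na(tab$domain_start) | is.na(tab$domain_end) |
                  tab$domain_start < 1L | tab$domain_end < tab$domain_start)
  if (any(bad)) {
    stop("invalid domain interval for: ", paste(tab$accession[bad], collapse = ", "))
  }
  tab[c("accession", "category", "domain_start", "domain_end")]
}

#' Resolve a protein-set category label into an analysis set
#'
#' `KP` returns known prions only; `PFP` returns known prions plus the other
#' prion-forming proteins (KP is a subset of PFP); `PLP` returns the
#' prion-like set; `PFP_minus_KP` returns the prion-formers that are not
#' known prions (used when comparing against KP).
#'
#' @param table Output of [load_protein_sets()].
#' @param set One of `"KP"`, `"PFP"`, `"PLP"`, `"PFP_minus_KP"`.
#' @return Character vector of accessions.
#' @export
set_members <- function(table, set = c("KP", "PFP", "PLP", "PFP_minus_KP")) {
  set <- match.arg(set)
  switch(set,
    KP = table$accession[table$category == "KP"],
    PFP = table$accession[table$category %in% c("KP", "PFP")],
    PLP = table$accession[table$category == "PLP"],
    PFP_minus_KP = table$accession[table$category == "PFP"])
}
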