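# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles (naive dynamic programming, direct
# formula evaluation) and never call the package's own kernels.

AAS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
         "M", "F", "P", "S", "T", "W", "Y", "V")

blosum_ref <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

random_seq <- function(len, alphabet = AAS) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Naive Smith-Waterman with affine gaps (gap of length L costs go + L*ge),
# full matrices, no tricks.
sw_oracle <- function(a, b, go = 11, ge = 1) {
  ea <- strsplit(a, "")[[1]]; eb <- strsplit(b, "")[[1]]
  m <- length(ea); n <- length(eb)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-1e9, m + 1, n + 1)
  F <- matrix(-1e9, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - go - ge, E[i - 1, j] - ge)
      F[i, j] <- max(H[i, j - 1] - go - ge, F[i, j - 1] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + blosum_ref[ea[i - 1], eb[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Direct evaluation of the weighted-mean equation, term by term.
ewps_oracle <- function(P, w) {
  num <- 0; den <- 0
  for (k in seq_along(P)) {
    num <- num + w[k] * P[k]
    den <- den + w[k]
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Fabricate an ortholog_family directly (bypassing BDBH) with prescribed
# identities and bitscores, for EWPS and scheme tests.
fake_family <- function(ids, pct_identity, bitscore, self_bitscore,
                        ref_id = "REF") {
  orth <- data.frame(
    id = ids,
    species = if (length(ids)) paste0("sp_", ids) else character(0),
    seq = vapply(seq_along(ids), function(i) random_seq(30), character(1)),
    pct_identity = pct_identity, bitscore = bitscore,
    self_bitscore = self_bitscore, stringsAsFactors = FALSE)
  structure(list(ref = list(id = ref_id, species = "ref", seq = random_seq(30)),
                 level_species = c("ref", orth$species),
                 orthologs = orth, flagged = nrow(orth) == 0L),
            class = "ortholog_family")
}

# Write a protein table to a temporary FASTA and return the path.
tmp_fasta <- function(tab, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0(tab$species[1], ".fasta"))
  writeLines(paste0(">", tab$id, "\n", tab$seq), path)
  path
}
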