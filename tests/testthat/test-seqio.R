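test_that("FASTA parsing preserves order, ids and sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first protein", "MNQ", ">b", "QQN"), f)
  tab <- read_fasta(f, species = "sp")
  expect_equal(tab$id, c("a", "b"))
  expect_equal(tab$seq, c("MNQ", "QQN"))
  expect_equal(tab$desc[1], "a first protein")
  expect_equal(tab$species, c("sp", "sp"))
})

test_that("line-wrapped entries are concatenated to full length", {
  set.seed(1)
  full <- random_seq(125)
  wrapped <- substring(full, seq(1, 125, 60), pmin(seq(60, 184, 60), 125))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", wrapped), f)
  tab <- read_fasta(f)
  expect_equal(nrow(tab), 1L)
  expect_equal(nchar(tab$seq), 125L)
  expect_equal(tab$seq, full)  # concatenation oracle
})

test_that("FASTA round-trip is lossless for sequence content", {
  set.seed(2)
  tab <- data.frame(id = c("p1", "p2", "p3"), species = "s",
                    seq = vapply(c(10, 80, 125), random_seq, character(1)))
  f <- withr::local_tempfile(fileext = ".fasta")
  tab$desc <- tab$id
  write_fasta(tab, f)
  back <- read_fasta(f, species = "s")
  expect_equal(back$seq, tab$seq)
  expect_equal(back$id, tab$id)
})

test_that("empty files and duplicate ids are rejected by name", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">dup", "MNQ", ">dup", "QQN"), f)
  expect_error(read_fasta(f), "dup")
})

test_that("ambiguity codes map to X with a warning, or error on request", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MNBQZ"), f)
  expect_warning(tab <- read_fasta(f), "ambiguity")
  expect_equal(tab$seq, "MNXQX")
  expect_error(suppressWarnings(read_fasta(f, nonstandard = "error")), "ambiguity")
})

test_that("alignment blocks validate shape and ungap to their sources", {
  b <- alignment_block(c("r1", "r2"), c("MN-Q", "M-NQ"))
  expect_equal(b$ncol, 4L)
  expect_equal(ungap_row(b, "r1"), "MNQ")
  expect_error(alignment_block(c("r1", "r2"), c("MN-Q", "MNQ")), "ragged")
  f <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">r1", "MN.Q", ">r2", "M-NQ"), f)
  b2 <- read_aligned_fasta(f)
  expect_equal(b2$seqs[1], "MN-Q")  # '.' normalized to '-'
  writeLines(c(">r1", "MN-Q", ">r2", "MNQ"), f)
  expect_error(read_aligned_fasta(f), "r2")
})

test_that("aligned round-trip through disk reproduces ungapped sequences", {
  set.seed(3)
  fam <- simulate_family(sim_config(seed = 3))
  blk <- progressive_align(fam$records)
  f <- withr::local_tempfile(fileext = ".afa")
  write_aligned_fasta(blk, f)
  back <- read_aligned_fasta(f)
  for (i in seq_len(nrow(fam$records))) {
    expect_equal(ungap_row(back, fam$records$id[i]), fam$records$seq[i])
  }
})

test_that("level tables load, nest and flag unknown species", {
  f <- withr::local_tempfile(fileext = ".tsv")
  sp <- sprintf("sp%02d", 1:8)
  tab <- data.frame(species = sp, genus = as.integer(1:8 <= 2),
                    wgd = as.integer(1:8 <= 4), class = 1L)
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  lv <- load_level_table(f)
  expect_equal(lengths(lv), c(genus = 2L, wgd = 4L, class = 8L))
  expect_true(all(lv$genus %in% lv$wgd) && all(lv$wgd %in% lv$class))
  # all species flagged everywhere -> identical sets
  tab2 <- data.frame(species = sp[1:3], a = 1L, b = 1L, c = 1L)
  write.table(tab2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  lv2 <- load_level_table(f)
  expect_equal(unname(lengths(lv2)), c(3L, 3L, 3L))
  # nesting violation
  tab$class[1] <- 0L
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_level_table(f), "nesting")
  # unknown species warning, empty level error
  tab$class[1] <- 1L
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(load_level_table(f, proteomes = sp[-8]), "sp08")
  tab$genus <- 0L
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_level_table(f), "empty level")
})

test_that("protein-set tables resolve KP as a subset of PFP", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(accession = c("P1", "P2", "P3", "P4"),
                    category = c("KP", "PFP", "PLP", "KP"),
                    domain_start = c(5L, NA, 1L, NA),
                    domain_end = c(60L, NA, 80L, NA))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ps <- load_protein_sets(f)
  expect_setequal(set_members(ps, "KP"), c("P1", "P4"))
  expect_setequal(set_members(ps, "PFP"), c("P1", "P2", "P4"))
  expect_true(all(set_members(ps, "KP") %in% set_members(ps, "PFP")))
  expect_setequal(set_members(ps, "PFP_minus_KP"), "P2")
  tab$domain_end[1] <- 2L
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_protein_sets(f), "P1")
})
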