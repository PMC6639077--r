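mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- sample(AAS, k, replace = TRUE)
  paste(ch, collapse = "")
}

test_that("identical proteomes pair every protein with its copy", {
  set.seed(20)
  tab <- data.frame(id = sprintf("p%d", 1:6), species = "a",
                    seq = vapply(rep(70, 6), random_seq, character(1)))
  other <- tab; other$species <- "b"
  pairs <- bdbh(tab, other)
  expect_equal(nrow(pairs), 6L)
  expect_equal(pairs$ref_id, pairs$other_id)
})

test_that("bdbh is symmetric under proteome swap", {
  set.seed(21)
  a <- data.frame(id = sprintf("a%d", 1:5), species = "a",
                  seq = vapply(rep(90, 5), random_seq, character(1)))
  b <- data.frame(id = sprintf("b%d", 1:5), species = "b",
                  seq = vapply(a$seq, mutate_seq, k = 18, character(1)))
  fwd <- bdbh(a, b)
  rev <- bdbh(b, a)
  expect_setequal(paste(fwd$ref_id, fwd$other_id),
                  paste(rev$other_id, rev$ref_id))
})

test_that("a recent duplicate outbidding the reference breaks the pair", {
  set.seed(22)
  base <- random_seq(100)
  r <- mutate_seq(base, 20)   # diverged copy
  r2 <- base                  # close copy, wins s's best hit
  s <- mutate_seq(base, 5)
  ref <- data.frame(id = c("r", "r2"), species = "a", seq = c(r, r2))
  other <- data.frame(id = "s", species = "b", seq = s)
  pairs <- bdbh(ref, other)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$ref_id, "r2")      # (r, s) excluded: asymmetric
})

test_that("planted orthologs are recovered and paralog decoys excluded", {
  set.seed(23)
  n <- 8
  bases <- vapply(rep(100, n), random_seq, character(1))
  ref <- data.frame(id = sprintf("r%d", 1:n), species = "a", seq = bases)
  # orthologs at 60-80% identity; paralog decoys at ~40%
  osubs <- sample(20:40, n, replace = TRUE)
  other <- data.frame(
    id = c(sprintf("o%d", 1:n), sprintf("par%d", 1:n)), species = "b",
    seq = c(mapply(mutate_seq, bases, osubs),
            vapply(bases, mutate_seq, k = 60, character(1))))
  pairs <- bdbh(ref, other)
  got <- setNames(pairs$other_id, pairs$ref_id)
  expect_equal(unname(got[sprintf("r%d", 1:n)]), sprintf("o%d", 1:n))
})

test_that("families carry at most one ortholog per species with metadata", {
  set.seed(24)
  sim <- simulate_proteome_set(sim_config(seed = 24), n_families = 4,
                               decoy_factor = 1)
  fams <- build_families(
    sim$truth_pairs$ref_id[!duplicated(sim$truth_pairs$ref_id)],
    sim$proteomes, sim$levels$class, sim$reference)
  for (f in fams) {
    expect_lte(max(table(f$orthologs$species)), 1L)
    expect_false(sim$reference %in% f$orthologs$species)
    expect_true(all(f$orthologs$pct_identity > 0 & f$orthologs$pct_identity <= 100))
    expect_true(all(f$orthologs$bitscore <= f$orthologs$self_bitscore))
  }
  # nested levels: genus ortholog sets are subsets of class sets
  fams_g <- build_families(
    sim$truth_pairs$ref_id[!duplicated(sim$truth_pairs$ref_id)],
    sim$proteomes, sim$levels$genus, sim$reference)
  for (k in seq_along(fams)) {
    expect_true(all(fams_g[[k]]$orthologs$id %in% fams[[k]]$orthologs$id))
  }
})

test_that("a level with no other species yields an empty, flagged family", {
  set.seed(25)
  tab <- data.frame(id = "p1", species = "a", seq = random_seq(80))
  fams <- build_families("p1", list(a = tab), "a", "a")
  expect_true(fams[[1]]$flagged)
  expect_equal(nrow(fams[[1]]$orthologs), 0L)
})

test_that("families serialize to the expected table layout", {
  fam <- fake_family(c("o1", "o2"), c(80, 40), c(100, 60), 200)
  tab <- families_table(list(fam))
  expect_equal(names(tab), c("ref_id", "species", "ortholog_id",
                             "pct_identity", "bitscore", "self_bitscore"))
  expect_equal(nrow(tab), 2L)
})
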