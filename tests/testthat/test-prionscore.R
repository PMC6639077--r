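nq_tract <- function(len, frac_n = 0.6) {
  paste(sample(c("N", "Q"), len, replace = TRUE, prob = c(frac_n, 1 - frac_n)),
        collapse = "")
}

test_that("frequency tables validate, normalize and zero out X", {
  tbl <- default_frequency_tables()
  expect_equal(sum(tbl$prion), 1, tolerance = 1e-9)
  expect_equal(sum(tbl$background), 1, tolerance = 1e-9)
  expect_true(all(tbl$prion > 0) && all(tbl$background > 0))
  expect_equal(unname(tbl$log_odds["X"]), 0)
  expect_gt(tbl$log_odds[["N"]], 0)     # N/Q enriched in prion domains
  expect_gt(tbl$log_odds[["Q"]], 0)
  expect_lt(tbl$log_odds[["L"]], 0)
  expect_error(frequency_tables(c(A = 1), c(A = 1)), "20 canonical")
})

test_that("window scan equals brute force over all windows", {
  set.seed(50)
  tbl <- default_frequency_tables()
  for (k in 1:20) {
    s <- random_seq(sample(10:200, 1))
    w <- sample(c(5L, 10L, 60L), 1)
    got <- llr_window_scan(s, tbl, w)
    lo <- unname(tbl$log_odds[strsplit(s, "")[[1]]])
    L <- length(lo)
    if (L <= w) {
      expect_equal(got$llr, sum(lo))
      expect_equal(got$start, 1L)
    } else {
      sums <- vapply(1:(L - w + 1), function(i) sum(lo[i:(i + w - 1)]), numeric(1))
      expect_equal(got$llr, max(sums))
      expect_equal(got$start, which.max(sums))
    }
  }
})

test_that("window ties resolve to the smallest start; full window = total", {
  tbl <- default_frequency_tables()
  s <- strrep("N", 30)
  expect_equal(llr_window_scan(s, tbl, 10L)$start, 1L)
  full <- llr_window_scan(s, tbl, 30L)
  lo_n <- tbl$log_odds[["N"]]
  expect_equal(full$llr, 30 * lo_n, tolerance = 1e-9)
})

test_that("planted N/Q tracts are recovered; hydrophobic controls score 0", {
  set.seed(51)
  hits <- 0L
  for (k in 1:20) {
    tract <- nq_tract(80)
    s <- paste0(strrep("L", 100), tract, strrep("V", 100))
    ps <- score_sequence(s)
    if (!is.null(ps$domain_interval) && ps$prd_score > 0) {
      truth <- 101:180
      got <- ps$domain_interval[1]:ps$domain_interval[2]
      jac <- length(intersect(truth, got)) / length(union(truth, got))
      if (jac >= 0.8) hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
  ctrl <- score_sequence(strrep("L", 200))
  expect_identical(ctrl$prd_score, 0)
  expect_null(ctrl$domain_interval)
})

test_that("PRD score is clamped at 0 and intervals respect the core length", {
  set.seed(52)
  for (k in 1:20) {
    s <- paste0(random_seq(60), nq_tract(sample(c(0, 30, 70, 100), 1)),
                random_seq(60))
    ps <- score_sequence(s)
    expect_gte(ps$prd_score, 0)
    if (!is.null(ps$domain_interval)) {
      expect_gte(ps$domain_interval[2] - ps$domain_interval[1] + 1L, 60L)
      expect_gt(ps$unclamped, 0)
    }
  }
})

test_that("sequences shorter than the core cannot parse a prion domain", {
  ps <- score_sequence(strrep("N", 40))       # shorter than core 60
  expect_identical(ps$prd_score, 0)
  expect_null(ps$domain_interval)
  expect_equal(ps$llr, 40 * default_frequency_tables()$log_odds[["N"]],
               tolerance = 1e-9)              # one full-length window
})

test_that("lengthening an N/Q segment never lowers the PRD score", {
  set.seed(53)
  tract <- nq_tract(200)
  scores <- vapply(c(60, 90, 120, 160, 200), function(L) {
    s <- paste0(strrep("L", 50), substr(tract, 1, L), strrep("L", 50))
    score_sequence(s)$prd_score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("appending zero-log-odds residues leaves the PRD score unchanged", {
  set.seed(54)
  s <- paste0(strrep("L", 80), nq_tract(80), strrep("L", 80))
  base <- score_sequence(s)$prd_score
  padded <- score_sequence(paste0(s, strrep("X", 30)))$prd_score
  expect_equal(padded, base)
})

test_that("family scoring is alignment-independent and per-member", {
  set.seed(55)
  s <- paste0(strrep("L", 60), nq_tract(70), strrep("V", 60))
  bare <- random_seq(190)
  fam <- fake_family(c("o1", "o2", "o3", "o4"), c(80, 70, 60, 50),
                     c(50, 40, 30, 20), 100)
  fam$ref$seq <- s
  fam$orthologs$seq <- c(s, bare, s, bare)    # half lost the tract
  res <- score_family(fam)
  expect_equal(res$id, c("REF", "o1", "o2", "o3", "o4"))
  expect_true(all(res$prd_score[c(2, 4)] > 0))
  expect_true(all(res$prd_score[c(3, 5)] == 0))
  # identical sequences -> identical results
  expect_equal(res$prd_score[2], res$prd_score[4])
  expect_equal(res$prd_score[1], res$prd_score[2])
})
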